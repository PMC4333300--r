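# NDCG@k evaluation.

#' Discounted cumulative gain at depth k
#'
#' \deqn{DCG@k = \sum_{r=1}^{\min(k, n)} \frac{2^{y(r)} - 1}{\log_2(1 + r)}}
#' where \eqn{y(r)} is the integer relevance grade of the item at (1-based)
#' rank r. Lists shorter than k are summed over their full length.
#'
#' @param grades integer vector of non-negative grades, in predicted rank
#'   order (best-ranked first).
#' @param k integer truncation depth, >= 1.
#' @return the DCG@k value.
#' @examples
#' dcgAtK(c(4, 3, 2), 3)  # 15/1 + 7/log2(3) + 3/2
#' @export
dcgAtK <- function(grades, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("'k' must be >= 1")
  if (length(grades) == 0L) return(0)
  if (any(grades < 0)) stop("grades must be non-negative")
  r <- seq_len(min(as.integer(k), length(grades)))
  sum((2^grades[r] - 1) / log2(1 + r))
}

#' Normalized DCG at depth k
#'
#' DCG@k of the predicted ordering divided by DCG@k of the ideal
#' (descending-grade) ordering of the same items. When every grade is 0 the
#' ideal DCG is 0 and the NDCG is defined as 0: such a query carries no
#' ranking signal and should not inflate averages. A prediction identical
#' to the ideal ordering scores exactly 1.
#'
#' @param grades integer grades in predicted rank order.
#' @param k truncation depth (default 10).
#' @return NDCG@k in [0, 1].
#' @export
ndcgAtK <- function(grades, k = 10) {
  if (length(grades) == 0L) stop("empty ranked list")
  ideal <- dcgAtK(sort(grades, decreasing = TRUE), k)
  if (ideal == 0) return(0)
  dcgAtK(grades, k) / ideal
}

#' Deterministic ranking order from scores
#'
#' Orders items by descending predicted score; ties are broken by the
#' lexicographic order of the item ids (stable and reproducible).
#'
#' @param scores numeric predicted scores.
#' @param ids character item identifiers (tie-break key).
#' @return integer permutation putting the items in rank order.
#' @export
rankOrder <- function(scores, ids) {
  stopifnot(length(scores) == length(ids))
  order(-scores, ids)
}

#' NDCG@k of a scored item list
#'
#' @param scores numeric predicted scores.
#' @param grades integer true grades, aligned with \code{scores}.
#' @param ids item ids used for deterministic tie-breaking.
#' @param k truncation depth (default 10).
#' @return NDCG@k in [0, 1].
#' @export
ndcgFromScores <- function(scores, grades, ids = as.character(seq_along(scores)),
                           k = 10) {
  ndcgAtK(grades[rankOrder(scores, ids)], k)
}

#' Evaluate a fitted ranker over ranking groups
#'
#' Scores every group's compounds, sorts them by descending score with the
#' deterministic compound-id tie-break, and computes NDCG@k per group plus
#' the arithmetic mean over groups.
#'
#' @param model a fitted \linkS4class{RankerModel}.
#' @param groups list of \linkS4class{RankingGroup}.
#' @param k truncation depth (default 10, i.e. NDCG@10).
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(model, groups, k = 10) {
  stopifnot(is(model, "RankerModel"))
  if (!model@fitted) stop("model is not fitted")
  if (!length(groups)) stop("no groups to evaluate")
  per <- vapply(groups, function(g) {
    if (!nrow(g@features)) stop("empty group '", g@targetId, "'")
    s <- scoreFeatures(model, g@features)
    ndcgFromScores(s, g@grades, g@compoundIds, k)
  }, numeric(1))
  names(per) <- vapply(groups, function(g) g@targetId, character(1))
  new("EvalReport", perQuery = per, k = as.integer(k), mean = mean(per))
}

#' Write an EvalReport to JSON and CSV
#'
#' @param report an \linkS4class{EvalReport}.
#' @param jsonPath,csvPath output paths (either may be NULL to skip).
#' @return invisibly, the report.
#' @export
writeEvalReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "EvalReport"))
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(k = report@k, mean = report@mean,
           per_query = as.list(report@perQuery)),
      jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    utils::write.csv(
      data.frame(target_id = names(report@perQuery),
                 ndcg_at_k = signif(report@perQuery, 6)),
      csvPath, row.names = FALSE)
  invisible(report)
}
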