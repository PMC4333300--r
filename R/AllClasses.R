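#' @importFrom methods new validObject is slot setValidity show
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.MEASUREMENTS <- c("pIC50", "pKi", "pKd")

.ALGORITHMS <- c("prank", "ranknet", "rankboost", "svmrank", "adarank",
                 "listnet", "svr_baseline")

#' RankingDataset: targets, compounds and graded affinities
#'
#' The central container of the package. It bundles protein targets
#' (identifier, amino-acid sequence, optional family annotation), compounds
#' (identifier, optional SMILES, a fixed-length descriptor vector each) and
#' target-compound affinity records on the negative log10 molar scale
#' (pIC50 / pKi / pKd) together with their five-level relevance grade.
#'
#' @slot targets data.frame with columns \code{target_id}, \code{sequence},
#'   \code{family} (may be \code{NA}).
#' @slot compounds data.frame with columns \code{compound_id}, \code{smiles}
#'   (may be \code{NA}).
#' @slot descriptors numeric matrix, one row per compound (rownames =
#'   compound ids), \code{descriptorDim} columns.
#' @slot descriptorDim integer, the configured compound-descriptor length
#'   (32 for the built-in descriptor set).
#' @slot affinities data.frame with columns \code{target_id},
#'   \code{compound_id}, \code{measurement}, \code{value}, \code{grade}.
#'
#' @seealso [RankingDataset()] for the validating constructor,
#'   [applyCurationFilters()], [harmonizeLabels()], [makeRankingGroups()].
#' @export
setClass("RankingDataset",
  representation(
    targets       = "data.frame",
    compounds     = "data.frame",
    descriptors   = "matrix",
    descriptorDim = "integer",
    affinities    = "data.frame"
  ),
  prototype(
    targets       = data.frame(target_id = character(), sequence = character(),
                               family = character()),
    compounds     = data.frame(compound_id = character(), smiles = character()),
    descriptors   = matrix(numeric(), nrow = 0, ncol = 32),
    descriptorDim = 32L,
    affinities    = data.frame(target_id = character(), compound_id = character(),
                               measurement = character(), value = numeric(),
                               grade = integer())
  )
)

setValidity("RankingDataset", function(object) {
  msgs <- character()
  tg <- object@targets; cp <- object@compounds; af <- object@affinities
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      sprintf("%s must have columns: %s", what, paste(cols, collapse = ", "))
    else NULL
  msgs <- c(msgs,
            need(tg, c("target_id", "sequence"), "targets"),
            need(cp, "compound_id", "compounds"),
            need(af, c("target_id", "compound_id", "measurement", "value",
                       "grade"), "affinities"))
  if (length(msgs)) return(msgs)
  if (anyDuplicated(tg$target_id)) msgs <- c(msgs, "duplicate target ids")
  if (anyDuplicated(cp$compound_id)) msgs <- c(msgs, "duplicate compound ids")
  if (nrow(tg) && any(!nzchar(tg$sequence)))
    msgs <- c(msgs, "empty target sequence")
  if (ncol(object@descriptors) != object@descriptorDim)
    msgs <- c(msgs, sprintf("descriptor matrix has %d columns, expected %d",
                            ncol(object@descriptors), object@descriptorDim))
  if (nrow(object@descriptors) != nrow(cp))
    msgs <- c(msgs, "descriptor matrix rows must match compounds")
  if (nrow(cp) && !identical(rownames(object@descriptors), cp$compound_id))
    msgs <- c(msgs, "descriptor rownames must equal compound ids, in order")
  if (nrow(object@descriptors) && !all(is.finite(object@descriptors)))
    msgs <- c(msgs, "non-finite descriptor entries")
  if (nrow(af)) {
    if (!all(af$measurement %in% .MEASUREMENTS))
      msgs <- c(msgs, "measurement must be one of pIC50, pKi, pKd")
    if (!all(is.finite(af$value))) msgs <- c(msgs, "non-finite affinity value")
    if (!all(af$grade %in% 0:4)) msgs <- c(msgs, "grades must be in 0..4")
    if (!all(af$target_id %in% tg$target_id))
      msgs <- c(msgs, "affinity references unknown target")
    if (!all(af$compound_id %in% cp$compound_id))
      msgs <- c(msgs, "affinity references unknown compound")
    if (anyDuplicated(paste(af$target_id, af$compound_id, sep = "\r")))
      msgs <- c(msgs, "duplicate (target, compound) affinity rows")
  }
  if (length(msgs)) msgs else TRUE
})

#' RankingGroup: one ranking query
#'
#' One query of the ranking problem: a protein target together with the
#' pair-feature vectors and integer relevance grades of its compounds.
#' Lists of \code{RankingGroup} objects are the training/test unit consumed
#' by every ranker.
#'
#' @slot targetId character scalar.
#' @slot features numeric matrix, one row per compound.
#' @slot grades integer vector of relevance grades (0-4).
#' @slot compoundIds character vector, same length as \code{grades}.
#' @export
setClass("RankingGroup",
  representation(targetId = "character", features = "matrix",
                 grades = "integer", compoundIds = "character"))

setValidity("RankingGroup", function(object) {
  n <- nrow(object@features)
  if (length(object@targetId) != 1L) return("targetId must be a scalar")
  if (length(object@grades) != n || length(object@compoundIds) != n)
    return("features rows, grades and compoundIds must agree")
  if (n && !all(is.finite(object@features))) return("non-finite features")
  if (n && !all(object@grades >= 0L)) return("negative grades")
  TRUE
})

#' RankerModel: a fitted ranking function
#'
#' Wraps the learned state of one ranking algorithm behind a uniform
#' scoring contract: \code{scoreFeatures(model, X)} maps a feature matrix to
#' real-valued ranking scores (higher = predicted stronger binder).
#'
#' @slot algorithm one of \code{prank}, \code{ranknet}, \code{rankboost},
#'   \code{svmrank}, \code{adarank}, \code{listnet}, \code{svr_baseline}.
#' @slot params algorithm-specific learned state (weights, thresholds,
#'   weak-ranker tables, support vectors, ...).
#' @slot hyper hyperparameters the model was fitted with.
#' @slot seed integer RNG seed used during fitting.
#' @slot dim integer feature dimension seen at fit time.
#' @slot fitted logical; set only after successful training.
#' @export
setClass("RankerModel",
  representation(algorithm = "character", params = "list", hyper = "list",
                 seed = "integer", dim = "integer", fitted = "logical"),
  prototype(params = list(), hyper = list(), seed = NA_integer_,
            dim = NA_integer_, fitted = FALSE))

setValidity("RankerModel", function(object) {
  if (!object@algorithm %in% .ALGORITHMS)
    return(sprintf("unknown algorithm '%s'", object@algorithm))
  TRUE
})

#' EvalReport: per-query NDCG@k and its mean
#'
#' @slot perQuery named numeric vector of per-query NDCG@k values in [0, 1];
#'   names are target ids.
#' @slot k integer truncation depth of the NDCG.
#' @slot mean arithmetic mean of \code{perQuery}.
#' @export
setClass("EvalReport",
  representation(perQuery = "numeric", k = "integer", mean = "numeric"))

setValidity("EvalReport", function(object) {
  if (length(object@perQuery) &&
      !isTRUE(all.equal(object@mean, mean(object@perQuery))))
    return("mean must equal the arithmetic mean of perQuery")
  if (length(object@perQuery) &&
      (any(object@perQuery < -1e-12) || any(object@perQuery > 1 + 1e-12)))
    return("NDCG values must lie in [0, 1]")
  TRUE
})

setMethod("show", "RankingDataset", function(object) {
  cat(sprintf("RankingDataset: %d targets, %d compounds, %d affinities (%d-dim descriptors)\n",
              nrow(object@targets), nrow(object@compounds),
              nrow(object@affinities), object@descriptorDim))
  if (nrow(object@affinities)) {
    tb <- table(factor(object@affinities$grade, levels = 0:4))
    cat("  grade histogram:", paste(sprintf("%s:%d", names(tb), tb),
                                    collapse = " "), "\n")
  }
})

setMethod("show", "RankingGroup", function(object) {
  cat(sprintf("RankingGroup '%s': %d compounds x %d features, grades %s\n",
              object@targetId, nrow(object@features), ncol(object@features),
              paste(range(object@grades), collapse = "-")))
})

setMethod("show", "RankerModel", function(object) {
  cat(sprintf("RankerModel <%s>%s, feature dim %s, seed %s\n",
              object@algorithm, if (object@fitted) " (fitted)" else " (unfitted)",
              object@dim, object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: NDCG@%d over %d queries, mean %.4f\n",
              object@k, length(object@perQuery), object@mean))
})
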