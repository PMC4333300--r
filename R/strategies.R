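# The four cross-target / heterogeneous-data experiment strategies, as
# reproducible seeded runners over a RankingDataset.

# Deterministic 32-bit string hash, used to give every target its own
# reproducible RNG substream regardless of which other targets are present.
.stringHash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1299709) %% 2147483647)
}

#' Grade-stratified fold assignment
#'
#' Splits one target's compounds into \code{folds} parts, stratified by
#' grade: within each grade the compounds are shuffled (seeded per target,
#' so the assignment does not depend on which other targets are in the
#' dataset) and dealt round-robin. Per grade, fold sizes differ by at most
#' one. Strategies that share a seed therefore share identical test
#' partitions.
#'
#' @param grades integer grades of one target's compounds.
#' @param folds number of folds.
#' @param seed master seed.
#' @param targetId target identifier (keys the per-target RNG substream).
#' @return integer fold labels in 1..folds.
#' @export
stratifiedFolds <- function(grades, folds, seed, targetId) {
  stopifnot(folds >= 2L)
  n <- length(grades)
  set.seed(.subSeed(seed, .stringHash(targetId)))
  fold <- integer(n)
  counter <- 0L
  for (g in sort(unique(grades))) {
    idx <- which(grades == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((counter + seq_along(idx) - 1L) %% folds) + 1L
    counter <- counter + length(idx)
  }
  fold
}

#' Build per-target ranking groups from a dataset
#'
#' Featurizes every (target, compound) affinity record with the chosen
#' pair-feature mapping — CTD features for the target, the stored
#' descriptor vector for the compound — and assembles one
#' \linkS4class{RankingGroup} per target.
#'
#' @param dataset a \linkS4class{RankingDataset}.
#' @param mapping \code{"concat"} (default; 147 + 32 = 179 features) or
#'   \code{"cross_term"} (Kronecker product, 147 x 32 = 4704 features).
#' @param targetFeatures optional precomputed matrix of per-target feature
#'   vectors (rownames = target ids); computed with [ctdFeatures()] when
#'   missing.
#' @return named list of \linkS4class{RankingGroup}, one per target with
#'   at least one affinity record.
#' @export
makeRankingGroups <- function(dataset, mapping = c("concat", "cross_term"),
                              targetFeatures = NULL) {
  mapping <- match.arg(mapping)
  stopifnot(is(dataset, "RankingDataset"))
  af <- dataset@affinities
  if (!nrow(af)) stop("dataset has no affinity records")
  if (is.null(targetFeatures)) {
    targetFeatures <- t(vapply(dataset@targets$sequence, ctdFeatures,
                               numeric(147)))
    rownames(targetFeatures) <- dataset@targets$target_id
  }
  mapFun <- if (mapping == "concat") mapConcat else mapCrossTerm
  groups <- lapply(split(af, af$target_id), function(sub) {
    tvec <- targetFeatures[sub$target_id[1L], ]
    feats <- t(vapply(sub$compound_id, function(cid)
      mapFun(tvec, dataset@descriptors[cid, ]),
      numeric(if (mapping == "concat") length(tvec) + dataset@descriptorDim
              else length(tvec) * dataset@descriptorDim)))
    rownames(feats) <- NULL
    RankingGroup(sub$target_id[1L], feats, sub$grade, sub$compound_id)
  })
  groups[order(names(groups))]
}

#' Configuration for an experiment strategy run
#'
#' @param algorithms character vector of ranker names (see [fitRanker()]).
#' @param mapping pair-feature mapping, \code{"concat"} or
#'   \code{"cross_term"}.
#' @param k NDCG truncation depth (default 10).
#' @param folds cross-validation folds / test parts (default 5).
#' @param seed master seed; all randomness in a run flows from it.
#' @param familyMap named character vector target id -> family (required
#'   for the family-restricted strategy).
#' @param standardize center/scale features on the training rows and apply
#'   the same transform to the test rows (default TRUE).
#' @param hyper named list of per-algorithm hyperparameter override lists.
#' @return a list of class \code{strategyConfig}.
#' @export
strategyConfig <- function(algorithms = "svmrank",
                           mapping = c("concat", "cross_term"),
                           k = 10L, folds = 5L, seed = 1L,
                           familyMap = NULL, standardize = TRUE,
                           hyper = list()) {
  mapping <- match.arg(mapping)
  structure(list(algorithms = algorithms, mapping = mapping, k = as.integer(k),
                 folds = as.integer(folds), seed = as.integer(seed),
                 familyMap = familyMap, standardize = standardize,
                 hyper = hyper),
            class = "strategyConfig")
}

.fitOn <- function(algorithm, trainGroups, config) {
  hy <- config$hyper[[algorithm]]
  if (is.null(hy)) hy <- list()
  fitRanker(algorithm, trainGroups, hy, seed = config$seed)
}

.subsetGroup <- function(g, idx) {
  RankingGroup(g@targetId, g@features[idx, , drop = FALSE],
               g@grades[idx], g@compoundIds[idx])
}

.standardizeGroups <- function(trainGroups, testGroups, on = TRUE) {
  if (!on) return(list(train = trainGroups, test = testGroups))
  Xtr <- do.call(rbind, lapply(trainGroups, function(g) g@features))
  tr <- standardizeFeatures(Xtr)
  rescale <- function(g) RankingGroup(g@targetId,
                                      applyTransform(tr, g@features),
                                      g@grades, g@compoundIds)
  list(train = lapply(trainGroups, rescale),
       test = lapply(testGroups, rescale))
}

.newStrategyResult <- function(strategy, report, audit, config) {
  report <- report[do.call(order, report[intersect(
    c("algorithm", "mapping", "target_id", "fold"), names(report))]), ,
    drop = FALSE]
  rownames(report) <- NULL
  structure(list(strategy = strategy, report = report, audit = audit,
                 config = config), class = "strategyResult")
}

#' Per-target summary of a strategy result
#'
#' Fold-averaged (macro) NDCG@k per target and algorithm/mapping, the
#' headline number of each strategy; per-fold values remain available in
#' \code{result$report}.
#'
#' @param result a \code{strategyResult}.
#' @return data.frame with one row per (algorithm, mapping, target).
#' @export
summarizeStrategy <- function(result) {
  stopifnot(inherits(result, "strategyResult"))
  rp <- result$report
  keys <- intersect(c("algorithm", "mapping", "target_id"), names(rp))
  agg <- stats::aggregate(rp["ndcg"], rp[keys], mean)
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

#' Strategy: within-target cross-validation
#'
#' The classical single-target screening scenario: each target is an
#' independent task, its compounds are split into seeded grade-stratified
#' folds, every algorithm is trained on folds-1 folds and evaluated by
#' NDCG@k on the held-out fold, and the fold-averaged NDCG per target is
#' reported. Targets with fewer compounds than folds are skipped with a
#' warning.
#'
#' @param dataset a \linkS4class{RankingDataset}.
#' @param config a [strategyConfig()].
#' @return a \code{strategyResult} with elements \code{report} (data.frame:
#'   algorithm, target_id, fold, ndcg), \code{audit} (train/test membership
#'   per run) and \code{config}.
#' @export
runStrategyWithinTarget <- function(dataset, config = strategyConfig()) {
  groups <- makeRankingGroups(dataset, config$mapping)
  rows <- list(); audit <- list()
  for (tid in names(groups)) {
    g <- groups[[tid]]
    n <- length(g@grades)
    if (n < config$folds) {
      warning("target ", tid, " has fewer compounds than folds; skipped")
      next
    }
    fold <- stratifiedFolds(g@grades, config$folds, config$seed, tid)
    for (f in seq_len(config$folds)) {
      trIdx <- which(fold != f); teIdx <- which(fold == f)
      if (!length(teIdx) || length(unique(g@grades[trIdx])) < 2L) next
      std <- .standardizeGroups(list(.subsetGroup(g, trIdx)),
                                list(.subsetGroup(g, teIdx)),
                                config$standardize)
      audit[[length(audit) + 1L]] <- list(
        target = tid, fold = f,
        train = paste(tid, g@compoundIds[trIdx]),
        test = paste(tid, g@compoundIds[teIdx]))
      for (alg in config$algorithms) {
        model <- .fitOn(alg, std$train, config)
        nd <- evaluateModel(model, std$test, config$k)@mean
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, target_id = tid, fold = f, ndcg = nd)
      }
    }
  }
  .newStrategyResult("within_target", do.call(rbind, rows), audit, config)
}

#' Strategy: leave-one-target-out screening
#'
#' The novel-target scenario: for each target, one model per algorithm is
#' trained on every other target's full group and evaluated on the held-out
#' target's compounds, split into the same seeded parts as the
#' within-target strategy (identical test partitions at equal seed, for
#' fair comparison); the part-averaged NDCG@k is reported.
#'
#' @inheritParams runStrategyWithinTarget
#' @param trainTargets optional restriction of the training pool (used by
#'   the family-restricted strategy).
#' @param testTargets optional subset of targets to hold out.
#' @param strategyName label stored on the result.
#' @return a \code{strategyResult}.
#' @export
runStrategyLeaveOneOut <- function(dataset, config = strategyConfig(),
                                   trainTargets = NULL, testTargets = NULL,
                                   strategyName = "leave_one_target_out") {
  groups <- makeRankingGroups(dataset, config$mapping)
  if (length(groups) < 2L) stop("leave-one-target-out needs >= 2 targets")
  if (is.null(testTargets)) testTargets <- names(groups)
  rows <- list(); audit <- list()
  for (tid in testTargets) {
    g <- groups[[tid]]
    if (is.null(g)) stop("unknown test target ", tid)
    pool <- setdiff(if (is.null(trainTargets)) names(groups)
                    else intersect(names(groups), trainTargets), tid)
    if (!length(pool)) stop("no training targets left for ", tid)
    trGroups <- groups[pool]
    fold <- stratifiedFolds(g@grades, config$folds, config$seed, tid)
    parts <- lapply(seq_len(config$folds), function(f)
      .subsetGroup(g, which(fold == f)))
    parts <- parts[vapply(parts, function(p) length(p@grades) > 0L,
                          logical(1))]
    std <- .standardizeGroups(trGroups, parts, config$standardize)
    audit[[length(audit) + 1L]] <- list(
      target = tid,
      train = unlist(lapply(trGroups, function(tg)
        paste(tg@targetId, tg@compoundIds))),
      test = paste(tid, g@compoundIds))
    for (alg in config$algorithms) {
      model <- .fitOn(alg, std$train, config)
      nd <- vapply(std$test, function(p)
        evaluateModel(model, list(p), config$k)@mean, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, target_id = tid, fold = seq_along(nd), ndcg = nd)
    }
  }
  .newStrategyResult(strategyName, do.call(rbind, rows), audit, config)
}

#' Strategy: family-restricted training
#'
#' Like leave-one-target-out, but the training pool is restricted to the
#' held-out target's own protein family (the target itself excluded),
#' probing whether phylogenetically related targets make better teachers.
#' Test partitions are identical to the leave-one-target-out strategy at
#' equal seed.
#'
#' @inheritParams runStrategyLeaveOneOut
#' @param testTargets targets to evaluate; defaults to every target whose
#'   family has at least one other member.
#' @return a \code{strategyResult}.
#' @export
runStrategyFamily <- function(dataset, config = strategyConfig(),
                              testTargets = NULL) {
  fm <- config$familyMap
  if (is.null(fm)) stop("the family-restricted strategy requires a familyMap")
  if (is.null(testTargets)) {
    counts <- table(fm)
    testTargets <- names(fm)[fm %in% names(counts)[counts >= 2L]]
    testTargets <- intersect(testTargets, dataset@targets$target_id)
  }
  rows <- list(); audits <- list()
  for (tid in testTargets) {
    if (!tid %in% names(fm)) stop("familyMap does not cover target ", tid)
    members <- setdiff(names(fm)[fm == fm[[tid]]], tid)
    if (!length(members))
      stop("family of ", tid, " has no other member to train on")
    res <- runStrategyLeaveOneOut(dataset, config, trainTargets = members,
                                  testTargets = tid,
                                  strategyName = "family_restricted")
    rows[[tid]] <- res$report
    audits <- c(audits, res$audit)
  }
  .newStrategyResult("family_restricted", do.call(rbind, rows), audits, config)
}

#' Strategy: heterogeneous-platform integration
#'
#' The data-integration scenario: targets are assayed on different
#' platforms (pIC50 for some, pKi for others), labels are harmonized
#' per target with [harmonizeLabels()], and for each held-out target a
#' ranking SVM is trained on the remaining (heterogeneous) targets — once
#' with the side-by-side concatenation mapping and once with the Kronecker
#' cross-term mapping — and evaluated by NDCG@k on the held-out target.
#' Only within-query order pairs reach the fitter, so the mixed measurement
#' scales never get compared to each other.
#'
#' @inheritParams runStrategyWithinTarget
#' @return a \code{strategyResult} with a \code{mapping} column in the
#'   report.
#' @export
runStrategyHeterogeneous <- function(dataset, config = strategyConfig()) {
  dataset <- harmonizeLabels(dataset)
  nT <- nrow(dataset@targets)
  if (nT < 3L) stop("heterogeneous-data strategy needs >= 3 targets")
  rows <- list(); audit <- list()
  for (mp in c("concat", "cross_term")) {
    groups <- makeRankingGroups(dataset, mp)
    for (tid in names(groups)) {
      trGroups <- groups[setdiff(names(groups), tid)]
      std <- .standardizeGroups(trGroups, groups[tid], config$standardize)
      audit[[length(audit) + 1L]] <- list(
        target = tid, mapping = mp,
        train = unlist(lapply(trGroups, function(tg)
          paste(tg@targetId, tg@compoundIds))),
        test = paste(tid, groups[[tid]]@compoundIds))
      for (alg in config$algorithms) {
        model <- .fitOn(alg, std$train, config)
        nd <- evaluateModel(model, std$test, config$k)@mean
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, mapping = mp, target_id = tid, ndcg = nd)
      }
    }
  }
  .newStrategyResult("heterogeneous", do.call(rbind, rows), audit, config)
}

#' Write a strategy result to disk
#'
#' Emits \code{report.csv} (6 significant digits), \code{report.json}
#' (full precision) and \code{manifest.json} (command label, config,
#' seed, package version, timestamp, input digests) into \code{dir}.
#'
#' @param result a \code{strategyResult}.
#' @param dir output directory (created if missing).
#' @param command free-text label recorded in the manifest.
#' @param inputPaths optional character vector of input files whose md5
#'   digests go into the manifest.
#' @return invisibly, the paths written.
#' @export
writeStrategyResult <- function(result, dir, command = result$strategy,
                                inputPaths = character()) {
  stopifnot(inherits(result, "strategyResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "report.csv")
  js <- file.path(dir, "report.json")
  rp <- result$report
  rpOut <- rp; rpOut$ndcg <- signif(rpOut$ndcg, 6)
  utils::write.csv(rpOut, csv, row.names = FALSE)
  jsonlite::write_json(
    list(strategy = result$strategy,
         config = result$config[c("algorithms", "mapping", "k", "folds",
                                  "seed")],
         report = rp, summary = summarizeStrategy(result)),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  mf <- writeRunManifest(file.path(dir, "manifest.json"), command,
                         config = result$config, seed = result$config$seed,
                         inputPaths = inputPaths)
  invisible(c(csv = csv, json = js, manifest = mf))
}
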