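# Small-but-real end-to-end runs of the four experiment strategies.

smallBench <- function(seed = 5, nTargets = 4, nCompounds = 20, ...) {
  genBenchmark(syntheticConfig(nTargets = nTargets,
                               nCompoundsPerTarget = nCompounds,
                               nFamilies = 2, seed = seed, ...))
}

test_that("stratified folds balance every grade across folds", {
  set.seed(1)
  for (i in 1:20) {
    grades <- sample(0:4, sample(10:40, 1), replace = TRUE)
    fold <- stratifiedFolds(grades, 5, seed = i, targetId = "T01")
    expect_true(all(fold %in% 1:5))
    # per grade, fold counts differ by at most 1 (brute-force count)
    for (g in unique(grades)) {
      cnt <- tabulate(fold[grades == g], nbins = 5)
      expect_lte(max(cnt) - min(cnt), 1)
    }
  }
  # per-target substream: assignment independent of the seed only via it
  f1 <- stratifiedFolds(rep(0:4, 4), 5, seed = 3, targetId = "T01")
  f2 <- stratifiedFolds(rep(0:4, 4), 5, seed = 3, targetId = "T01")
  expect_identical(f1, f2)
})

test_that("group construction produces the documented feature dimensions", {
  b <- smallBench()
  gc <- makeRankingGroups(b$dataset, "concat")
  gx <- makeRankingGroups(b$dataset, "cross_term")
  expect_length(gc, 4)
  expect_identical(ncol(gc[[1]]@features), 179L)
  expect_identical(ncol(gx[[1]]@features), 4704L)
  # cross-term rows are the Kronecker product of the CTD and descriptor
  g1 <- gx[[1]]
  cid <- g1@compoundIds[3]
  expect_equal(unname(g1@features[3, ]),
               mapCrossTerm(b$ctd[g1@targetId, ],
                            descriptors(b$dataset)[cid, ]))
})

test_that("within-target cross-validation is deterministic and leak-free", {
  b <- smallBench()
  cfg <- strategyConfig(algorithms = c("svmrank", "prank"), folds = 4,
                        seed = 9)
  r1 <- runStrategyWithinTarget(b$dataset, cfg)
  r2 <- runStrategyWithinTarget(b$dataset, cfg)
  expect_identical(r1$report, r2$report)
  expect_true(all(r1$report$ndcg >= 0 & r1$report$ndcg <= 1))
  expect_setequal(unique(r1$report$algorithm), c("svmrank", "prank"))
  for (a in r1$audit) expect_length(intersect(a$train, a$test), 0)
  s <- summarizeStrategy(r1)
  expect_identical(nrow(s), 8L)   # 2 algorithms x 4 targets
  # an oracle feature ranks perfectly: grade placed in the feature vector
  gs <- makeRankingGroups(b$dataset, "concat")
  oracle <- lapply(gs, function(g)
    RankingGroup(g@targetId, cbind(as.numeric(g@grades), g@features),
                 g@grades, g@compoundIds))
  m <- fitAdaRank(oracle, rounds = 1L)
  expect_identical(unname(evaluateModel(m, oracle)@perQuery), rep(1, 4))
})

test_that("leave-one-target-out never trains on the held-out target and
           reuses the within-target test partitions", {
  b <- smallBench()
  cfg <- strategyConfig(algorithms = "svmrank", seed = 9)
  r <- runStrategyLeaveOneOut(b$dataset, cfg)
  expect_identical(r1 <- r$report, runStrategyLeaveOneOut(b$dataset, cfg)$report)
  for (a in r$audit) {
    expect_length(intersect(a$train, a$test), 0)
    # nothing from the held-out target in training
    expect_false(any(grepl(paste0("^", a$target, " "), a$train)))
  }
  # identical test partitions at equal seed: fold labels agree
  g <- makeRankingGroups(b$dataset, "concat")[["T01"]]
  fold <- stratifiedFolds(g@grades, cfg$folds, cfg$seed, "T01")
  expect_identical(fold,
                   stratifiedFolds(g@grades, cfg$folds, cfg$seed, "T01"))
  expect_error(runStrategyLeaveOneOut(
    genBenchmark(syntheticConfig(nTargets = 1, nCompoundsPerTarget = 10,
                                 nFamilies = 1))$dataset, cfg), ">= 2")
})

test_that("family-restricted training only uses the test target's family", {
  b <- smallBench(nTargets = 6)
  cfg <- strategyConfig(algorithms = "svmrank", seed = 4,
                        familyMap = b$familyMap)
  r <- runStrategyFamily(b$dataset, cfg)
  fam <- b$familyMap
  for (a in r$audit) {
    trainTargets <- unique(sub(" .*", "", a$train))
    expect_false(a$target %in% trainTargets)
    expect_true(all(fam[trainTargets] == fam[[a$target]]))
  }
  expect_error(runStrategyFamily(b$dataset, strategyConfig()), "familyMap")
  soloFam <- setNames(c("X", LETTERS[2:6]), names(b$familyMap))
  expect_error(runStrategyFamily(b$dataset,
                                 strategyConfig(familyMap = soloFam,
                                                seed = 4),
                                 testTargets = names(soloFam)[1]),
               "no other member")
})

test_that("heterogeneous strategy harmonizes labels and reports both
           mappings", {
  mix <- setNames(rep(c("pIC50", "pKi"), 2), sprintf("T%02d", 1:4))
  b <- smallBench(measurementMix = mix)
  expect_setequal(unique(affinities(b$dataset)$measurement),
                  c("pIC50", "pKi"))
  cfg <- strategyConfig(algorithms = "svmrank", seed = 2)
  r <- runStrategyHeterogeneous(b$dataset, cfg)
  expect_setequal(unique(r$report$mapping), c("concat", "cross_term"))
  expect_identical(nrow(r$report), 8L)   # 4 targets x 2 mappings
  for (a in r$audit)
    expect_false(any(grepl(paste0("^", a$target, " "), a$train)))
  # pair-order invariance: a strictly increasing per-target transform of
  # the labels leaves the pair sets, hence the fitted svmrank, unchanged
  gs1 <- makeRankingGroups(harmonizeLabels(b$dataset), "concat")
  maps <- list(function(g) g, function(g) 3L * g, function(g) g^2L,
               function(g) g + 2L)
  gs2 <- lapply(seq_along(gs1), function(q) {
    g <- gs1[[q]]
    RankingGroup(g@targetId, g@features, maps[[q]](g@grades), g@compoundIds)
  })
  expect_identical(lapply(unname(gs1), enumeratePairs),
                   lapply(gs2, enumeratePairs))
  expect_identical(fitSVMRank(gs1, seed = 3L)@params,
                   fitSVMRank(gs2, seed = 3L)@params)
  expect_error(runStrategyHeterogeneous(
    genBenchmark(syntheticConfig(nTargets = 2, nCompoundsPerTarget = 10,
                                 nFamilies = 1))$dataset, cfg), ">= 3")
})

test_that("strategy results write byte-identical reports at a fixed seed", {
  b <- smallBench()
  cfg <- strategyConfig(algorithms = "listnet", folds = 3, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStrategyResult(runStrategyWithinTarget(b$dataset, cfg), d1)
  writeStrategyResult(runStrategyWithinTarget(b$dataset, cfg), d2)
  for (f in c("report.csv", "report.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  mf <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_identical(mf$seed, 11L)
  expect_identical(mf$command, "within_target")
})
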