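test_that("enumeratePairs equals brute-force double-loop enumeration", {
  brute <- function(g) {
    out <- NULL
    for (i in seq_along(g)) for (j in seq_along(g))
      if (g[i] > g[j]) out <- rbind(out, c(i, j))
    if (is.null(out)) matrix(integer(0), ncol = 2) else out
  }
  expect_identical(nrow(enumeratePairs(c(2, 1, 1, 0))), 5L)
  expect_identical(nrow(enumeratePairs(c(3, 3, 3))), 0L)
  p <- enumeratePairs(c(1, 0))
  expect_identical(unname(p), matrix(c(1L, 2L), 1))
  set.seed(6)
  for (i in 1:50) {
    g <- sample(0:4, sample(1:30, 1), replace = TRUE)
    expect_identical(unname(enumeratePairs(g)), unname(brute(g)),
                     label = paste("grades", paste(g, collapse = ",")))
  }
})

test_that("PRank reproduces the worked single update and its invariants", {
  # K=3, w=[0], b=[0,0], x=[1], true rank 1 (grade 0): after one update
  # w = [-2], b = [1, 1]
  g <- RankingGroup("T", matrix(1, 1, 1), 0L, "c1")
  m <- fitPRank(list(g, RankingGroup("T3", matrix(0, 2, 1), c(2L, 1L),
                                     c("a", "b"))), epochs = 0L)
  # epochs = 0: untrained weights score everything identically
  expect_identical(unique(scoreFeatures(m, matrix(c(-3, 0, 7)))), 0)
  upd <- prankSingleUpdate(w = 0, b = c(0, 0), x = 1, rank = 1)
  expect_identical(upd$w, -2)
  expect_identical(upd$b, c(1, 1))
  expect_error(fitPRank(list(RankingGroup("T", matrix(0, 2, 1), c(1L, 1L),
                                          c("a", "b")))), "2 distinct")
})

test_that("PRank thresholds stay sorted and it solves separable data", {
  # linearly rank-separable 1-D data
  x <- matrix(c(0, 0.1, 1, 1.1, 2, 2.1, 3, 3.1, 4, 4.1), ncol = 1)
  g <- RankingGroup("T", x, rep(0:4, each = 2), sprintf("c%d", 1:10))
  m <- fitPRank(list(g), epochs = 50L, seed = 3L)
  expect_true(all(diff(m@params$b) >= 0))
  expect_identical(predictRank(m, x), rep(0:4, each = 2))
  # threshold monotonicity along the whole trajectory
  traj <- prankThresholdTrace(list(g), epochs = 5L, seed = 3L)
  for (b in traj) expect_true(all(diff(b) >= -1e-12))
})

test_that("RankNet loss values and gradients match the closed forms", {
  # equal scores: P_ij = 0.5, per-pair loss = ln 2, d loss/d(f_i-f_j) = -0.5
  expect_equal(log(1 + exp(0)), log(2))
  gs <- list(RankingGroup("T", matrix(c(0, 0), 2, 1), c(1L, 0L),
                          c("a", "b")))
  m0 <- fitRankNet(gs, epochs = 0L, seed = 1L)
  d <- 1e-6
  lossAt <- function(delta) log(1 + exp(-delta))
  expect_equal((lossAt(d) - lossAt(-d)) / (2 * d), -0.5, tolerance = 1e-6)
  # training on a separable 1-D pair set finds the preference direction
  g1 <- RankingGroup("T", matrix(c(1, 0), 2, 1), c(1L, 0L), c("a", "b"))
  m <- fitRankNet(list(g1), epochs = 100L, seed = 2L)
  expect_gt(m@params$w[1], 0)
  # the loss trace is non-increasing (guaranteed by step halving)
  expect_true(all(diff(m@params$loss) <= 1e-10))
  expect_error(fitRankNet(list(RankingGroup("T", matrix(0, 2, 1),
                                            c(1L, 1L), c("a", "b")))),
               "no ordered pairs")
  # hidden-layer variant trains and is reproducible
  gs2 <- randomGroups(2, n = 8, d = 3, seed = 30)
  h1 <- fitRankNet(gs2, hiddenUnits = 4L, epochs = 30L, seed = 5L)
  h2 <- fitRankNet(gs2, hiddenUnits = 4L, epochs = 30L, seed = 5L)
  expect_identical(h1@params$W1, h2@params$W1)
  expect_true(all(diff(h1@params$loss) <= 1e-10))
})

test_that("RankBoost alpha, distribution and perfect-weak-ranker behaviour", {
  # alpha at r = 0.8 is 0.5 ln 9
  expect_equal(0.5 * log((1 + 0.8) / (1 - 0.8)), 0.5 * log(9),
               tolerance = 1e-12)
  expect_equal(0.5 * log(9), 1.0986, tolerance = 1e-4)
  # a weak ranker that orders every pair correctly (two grade levels, one
  # separating threshold): all pairs satisfied after round 1
  g <- RankingGroup("T", matrix(c(1:5, rnorm(5)), 5, 2),
                    c(0L, 0L, 1L, 1L, 1L), sprintf("c%d", 1:5))
  m <- fitRankBoost(list(g), rounds = 1L)
  s <- scoreFeatures(m, g@features)
  p <- enumeratePairs(g)
  expect_true(all(s[p[, 1]] > s[p[, 2]]))
  # the pair distribution stays a probability distribution every round
  gs <- randomGroups(2, n = 10, d = 3, seed = 40)
  dTrace <- rankboostDistributionTrace(gs, rounds = 5L)
  for (D in dTrace) expect_equal(sum(D), 1, tolerance = 1e-9)
  expect_error(fitRankBoost(list(RankingGroup("T", matrix(0, 2, 1),
                                              c(1L, 1L), c("a", "b")))),
               "no ordered pairs")
})

test_that("ranking SVM learns the preference direction and matches the
           brute-force pair-violation count", {
  g <- RankingGroup("T", matrix(c(1, 0), 2, 1), c(1L, 0L), c("a", "b"))
  m <- fitSVMRank(list(g))
  expect_gt(m@params$w[1], 0)
  expect_gt(scoreFeatures(m, matrix(1)), scoreFeatures(m, matrix(0)))
  # duplicating every pair leaves the decision direction unchanged
  m2 <- fitSVMRank(list(g, g))
  expect_equal(sign(m2@params$w), sign(m@params$w))
  # violation count on a random group matches brute force over all pairs
  set.seed(50)
  gr <- RankingGroup("T", matrix(rnorm(40), 20, 2),
                     sample(0:2, 20, replace = TRUE), sprintf("c%02d", 1:20))
  mf <- fitSVMRank(list(gr))
  s <- scoreFeatures(mf, gr@features)
  p <- enumeratePairs(gr)
  viaPairs <- sum(s[p[, 1]] <= s[p[, 2]])
  brute <- 0L
  for (i in seq_along(s)) for (j in seq_along(s))
    if (gr@grades[i] > gr@grades[j] && s[i] <= s[j]) brute <- brute + 1L
  expect_identical(viaPairs, brute)
})

test_that("AdaRank alpha formula, perfect feature and weight renormalization", {
  # one query, E = 0.5, P = 1: alpha = 0.5 ln 3
  expect_equal(0.5 * log((1 * (1 + 0.5)) / (1 * (1 - 0.5))), 0.5 * log(3))
  expect_equal(0.5 * log(3), 0.5493, tolerance = 1e-4)
  # a feature equal to the grades is selected in round 1 with E = 1
  gs <- lapply(1:3, function(q) {
    set.seed(60 + q)
    grd <- sample(0:4, 8, replace = TRUE)
    RankingGroup(sprintf("T%d", q), cbind(grd, rnorm(8)), grd,
                 sprintf("T%d_c%d", q, 1:8))
  })
  m <- fitAdaRank(gs, rounds = 3L)
  expect_identical(m@params$feature[1], 1L)
  e <- evaluateModel(m, gs)
  expect_identical(unname(e@perQuery), rep(1, 3))
  # query weights renormalize every round
  wTrace <- adarankWeightTrace(gs, rounds = 4L)
  for (P in wTrace) expect_equal(sum(P), 1, tolerance = 1e-9)
  degenerate <- list(RankingGroup("T", matrix(rnorm(4), 2), c(0L, 0L),
                                  c("a", "b")))
  expect_error(fitAdaRank(degenerate), "degenerate")
})

test_that("ListNet loss matches the closed form and its invariances hold", {
  # zero scorer, one query of 2 items: uniform model distribution,
  # loss = ln 2 regardless of the target distribution
  g <- RankingGroup("T", matrix(0, 2, 2), c(1L, 0L), c("a", "b"))
  m0 <- fitListNet(list(g), epochs = 0L, seed = 1L)
  expect_equal(listnetLoss(numeric(2), list(g)), log(2), tolerance = 1e-12)
  # constant shift of scores leaves the loss unchanged
  gs <- randomGroups(2, n = 6, d = 3, seed = 70)
  w <- rnorm(3)
  expect_equal(listnetLossFromScores(lapply(gs, function(g)
                 drop(g@features %*% w)), gs),
               listnetLossFromScores(lapply(gs, function(g)
                 drop(g@features %*% w) + 5), gs),
               tolerance = 1e-9)
  # equal grades: the uniform target is already minimized by a zero scorer
  gEq <- RankingGroup("T", matrix(rnorm(6), 3, 2), c(2L, 2L, 2L),
                      c("a", "b", "c"))
  expect_lte(listnetLoss(numeric(2), list(gEq)),
             listnetLoss(rnorm(2), list(gEq)) + 1e-9)
  m <- fitListNet(gs, epochs = 100L, seed = 2L)
  expect_true(all(diff(m@params$loss) <= 1e-10))
  # single-item groups are skipped with a message
  g1 <- RankingGroup("T1", matrix(1, 1, 2), 2L, "x")
  expect_message(fitListNet(c(gs, list(g1)), epochs = 2L), "skipped")
})

test_that("the SVR baseline regresses grades and beats random scoring", {
  # exact-fit toy data: grades linear in one feature, epsilon ~ 0
  x <- matrix(rep(0:4, each = 2), ncol = 1)
  g <- RankingGroup("T", x, rep(0:4, each = 2), sprintf("c%d", 1:10))
  m <- fitSVRBaseline(list(g), kernel = "linear", epsilon = 0.01, cost = 100)
  expect_lt(max(abs(scoreFeatures(m, x) - g@grades)), 0.15)
  # constant grades are rejected
  expect_error(fitSVRBaseline(list(RankingGroup("T", matrix(rnorm(4), 2),
                                                c(1L, 1L), c("a", "b")))),
               "single grade")
  # RBF fit on a 30-point group beats the random-permutation NDCG
  set.seed(80)
  X <- matrix(rnorm(60), 30, 2)
  grd <- gradeAffinity(4.5 + 3 * plogis(X[, 1] + 0.5 * X[, 2]) * 2)
  g30 <- RankingGroup("T", X, grd, sprintf("c%02d", 1:30))
  mr <- fitSVRBaseline(list(g30))
  ndModel <- evaluateModel(mr, list(g30))@mean
  ndRand <- replicate(100, ndcgAtK(sample(grd), 10))
  expect_gt(ndModel, quantile(ndRand, 0.95))
})

test_that("fits are reproducible and scoring is deterministic", {
  gs <- randomGroups(3, n = 10, d = 4, seed = 90)
  for (alg in c("prank", "ranknet", "rankboost", "svmrank", "adarank",
                "listnet")) {
    m1 <- fitRanker(alg, gs, seed = 7L)
    m2 <- fitRanker(alg, gs, seed = 7L)
    expect_identical(m1@params, m2@params, label = alg)
    X <- gs[[1]]@features
    expect_identical(scoreFeatures(m1, X), scoreFeatures(m1, X), label = alg)
  }
  # linear model scores equal the brute-force dot product
  m <- fitRanker("listnet", gs, seed = 7L)
  X <- gs[[2]]@features
  expect_equal(scoreFeatures(m, X),
               apply(X, 1, function(r) sum(r * m@params$w)),
               tolerance = 1e-12)
  expect_error(scoreFeatures(m, matrix(0, 2, 5)), "dimension")
})

test_that("models round-trip through JSON with identical scores", {
  gs <- randomGroups(2, n = 8, d = 3, seed = 100)
  tmp <- withr::local_tempdir()
  for (alg in c("prank", "ranknet", "rankboost", "svmrank", "adarank",
                "listnet", "svr_baseline")) {
    m <- fitRanker(alg, gs, seed = 3L)
    f <- file.path(tmp, paste0(alg, ".json"))
    writeRankerModel(m, f)
    m2 <- readRankerModel(f)
    X <- gs[[1]]@features
    expect_equal(scoreFeatures(m2, X), scoreFeatures(m, X),
                 tolerance = 1e-12, label = alg)
  }
})

test_that("pair-based fitters are invariant to increasing label transforms", {
  # the heterogeneity argument: a strictly increasing per-query transform
  # of the labels leaves the ordered-pair set, hence the fit, unchanged
  set.seed(110)
  for (i in 1:100) {
    g <- sample(0:4, sample(3:15, 1), replace = TRUE)
    f <- sort(sample(1:50, 5))          # arbitrary increasing step map
    expect_identical(enumeratePairs(g), enumeratePairs(f[g + 1L]))
  }
  gs <- randomGroups(3, n = 8, d = 3, seed = 120)
  trans <- list(function(g) 2L * g, function(g) g^2L, function(g) g + 3L)
  gsT <- lapply(seq_along(gs), function(q) {
    g <- gs[[q]]
    RankingGroup(g@targetId, g@features, trans[[q]](g@grades), g@compoundIds)
  })
  for (alg in c("ranknet", "rankboost", "svmrank")) {
    m1 <- fitRanker(alg, gs, seed = 9L)
    m2 <- fitRanker(alg, gsT, seed = 9L)
    expect_identical(m1@params, m2@params, label = alg)
  }
})
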