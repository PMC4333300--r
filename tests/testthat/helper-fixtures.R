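# Small in-code fixtures shared across test files.

# a random ranking group with controllable size/grades
randomGroup <- function(n = 12, d = 3, targetId = "T", seed = 1,
                        grades = NULL) {
  set.seed(seed)
  if (is.null(grades)) grades <- sample(0:4, n, replace = TRUE)
  RankingGroup(targetId, matrix(rnorm(n * d), n, d), grades,
               sprintf("%s_c%02d", targetId, seq_len(n)))
}

# a list of groups that together contain at least one ordered pair
randomGroups <- function(nGroups = 3, n = 10, d = 3, seed = 1) {
  lapply(seq_len(nGroups), function(q)
    randomGroup(n, d, sprintf("T%02d", q), seed + q))
}

# a tiny valid dataset built by hand (no generator involved)
toyDataset <- function(nTargets = 2, nCompounds = 8, seed = 42) {
  set.seed(seed)
  tg <- data.frame(
    target_id = sprintf("T%d", seq_len(nTargets)),
    sequence = vapply(seq_len(nTargets), function(i)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                   replace = TRUE), collapse = ""), character(1)),
    family = rep(c("A", "B"), length.out = nTargets))
  cp <- data.frame(compound_id = sprintf("C%02d", seq_len(nCompounds)))
  D <- matrix(rnorm(nCompounds * 32), nCompounds, 32)
  af <- expand.grid(target_id = tg$target_id, compound_id = cp$compound_id,
                    stringsAsFactors = FALSE)
  af$measurement <- "pIC50"
  af$value <- runif(nrow(af), 4.2, 10.8)
  RankingDataset(tg, cp, D, af)
}

# trace wrappers over the fitters' diagnostic options
prankThresholdTrace <- function(groups, epochs, seed)
  fitPRank(groups, epochs = epochs, seed = seed, trace = TRUE)@params$bTrace
rankboostDistributionTrace <- function(groups, rounds)
  fitRankBoost(groups, rounds = rounds, trace = TRUE)@params$DTrace
adarankWeightTrace <- function(groups, rounds)
  fitAdaRank(groups, rounds = rounds, trace = TRUE)@params$PTrace

# standardize a group list on its own pooled rows (training-side scaling)
scaleGroups <- function(groups) {
  tr <- standardizeFeatures(do.call(rbind,
                                    lapply(groups, function(g) g@features)))
  lapply(groups, function(g)
    RankingGroup(g@targetId, applyTransform(tr, g@features), g@grades,
                 g@compoundIds))
}

# a hand-built linear scorer (bypasses training)
linModel <- function(w) {
  new("RankerModel", algorithm = "listnet", params = list(w = w),
      hyper = list(), seed = 1L, dim = length(w), fitted = TRUE)
}

# literal transcription of the DCG definition, kept independent of dcgAtK
bruteDcg <- function(grades, k) {
  tot <- 0
  for (r in seq_len(min(k, length(grades))))
    tot <- tot + (2^grades[r] - 1) / log2(1 + r)
  tot
}
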