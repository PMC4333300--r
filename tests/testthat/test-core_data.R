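test_that("affinity grading reproduces the five-level boundaries", {
  expect_identical(gradeAffinity(6.5), 1L)
  expect_identical(gradeAffinity(9.2), 4L)
  expect_identical(gradeAffinity(5.999), 0L)
  # left-closed boundaries: a boundary value takes the higher grade
  expect_identical(gradeAffinity(c(6, 7, 8, 9)), 1:4)
  expect_identical(gradeAffinity(c(4, 6.99, 7.5, 8.2, 11)),
                   c(0L, 1L, 2L, 3L, 4L))
  expect_error(gradeAffinity(NaN), "finite")
  expect_error(gradeAffinity(Inf), "finite")
})

test_that("grading is monotone and consistent with the activity rule", {
  v <- sort(runif(200, 3, 12))
  g <- gradeAffinity(v)
  expect_true(all(diff(g) >= 0))
  expect_identical(labelActive(v), g >= 1L)
  expect_true(labelActive(6.0))
  expect_false(labelActive(5.0))
  expect_true(labelActive(8.3))
})

test_that("sequence validation enforces the canonical-residue policy", {
  expect_identical(validateSequences("mkvl"), "MKVL")
  expect_error(validateSequences("MKXL"), "non-canonical")
  expect_identical(validateSequences("MKXL", nonCanonical = "map"), "MKAL")
  expect_error(validateSequences(""), "empty")
})

test_that("RankingDataset constructor validates and dedupes", {
  ds <- toyDataset()
  expect_s4_class(ds, "RankingDataset")
  expect_true(all(affinities(ds)$grade %in% 0:4))
  # duplicate affinity rows collapse, keeping the first
  af <- affinities(ds)[c(1, 1, 2), 1:4]
  af$value[2] <- 99  # the duplicate that must be dropped
  expect_warning(
    ds2 <- RankingDataset(targets(ds), compounds(ds), descriptors(ds), af),
    "duplicate")
  expect_identical(nrow(affinities(ds2)), 2L)
  expect_identical(affinities(ds2)$value[1], affinities(ds)$value[1])
  # referential integrity is enforced
  afBad <- affinities(ds)[1, 1:4]
  afBad$target_id <- "nope"
  expect_error(RankingDataset(targets(ds), compounds(ds), descriptors(ds),
                              afBad), "unknown target")
  # wrong descriptor width is rejected
  expect_error(RankingDataset(targets(ds), compounds(ds),
                              descriptors(ds)[, 1:31], affinities(ds)[1:4]),
               "expected 32")
})

test_that("curation filters implement the grade-coverage rules", {
  mkds <- function(values) {
    tg <- data.frame(target_id = "T1", sequence = "MKVLAARG")
    n <- length(values)
    cp <- data.frame(compound_id = sprintf("C%02d", seq_len(n)))
    RankingDataset(tg, cp, matrix(0, n, 32),
                   data.frame(target_id = "T1", compound_id = cp$compound_id,
                              measurement = "pIC50", value = values))
  }
  # target with only 0/1 grades is deleted
  low <- mkds(c(5, 5.5, 6.2, 6.8))
  expect_identical(nrow(targets(applyCurationFilters(low))), 0L)
  # 10 compounds, grades 0..4, exactly one (10%) at the top grade,
  # count window [5, 100]: retained
  ok <- mkds(c(4.5, 5.5, 6.2, 6.8, 7.3, 7.7, 8.1, 8.6, 5.9, 9.4))
  kept <- applyCurationFilters(ok, curationRules(minLigands = 5,
                                                 maxLigands = 100))
  expect_identical(targets(kept)$target_id, "T1")
  # top-grade fraction below 5% is deleted
  vals <- c(rep(5, 10), rep(6.5, 5), rep(7.5, 4), rep(8.5, 2), 9.5,
            rep(5.2, 3))  # 1/25 = 4% at grade 4
  expect_identical(nrow(targets(applyCurationFilters(mkds(vals)))), 0L)
  # empty dataset passes through with a warning
  empty <- new("RankingDataset")
  expect_warning(res <- applyCurationFilters(empty), "empty")
  expect_identical(nrow(affinities(res)), 0L)
})

test_that("curation is idempotent", {
  ds <- toyDataset(nTargets = 3, nCompounds = 20)
  once <- applyCurationFilters(ds)
  twice <- expect_silent(applyCurationFilters(once))
  expect_identical(affinities(twice), affinities(once))
  expect_identical(targets(twice), targets(once))
})

test_that("label harmonization grades each target on its own scale", {
  tg <- data.frame(target_id = c("A", "B"),
                   sequence = c("MKVLAARG", "GGHHLLKK"))
  cp <- data.frame(compound_id = sprintf("C%d", 1:4))
  af <- data.frame(target_id = rep(c("A", "B"), each = 2),
                   compound_id = c("C1", "C2", "C3", "C4"),
                   measurement = rep(c("pIC50", "pKi"), each = 2),
                   value = c(6.5, 9.2, 5.1, 7.4))
  ds <- harmonizeLabels(RankingDataset(tg, cp, matrix(0, 4, 32), af))
  expect_identical(affinities(ds)$grade, c(1L, 4L, 0L, 2L))
  # within-target ordering of raw values is preserved by the grades
  a <- affinities(ds)
  for (t in unique(a$target_id)) {
    sub <- a[a$target_id == t, ]
    o <- order(sub$value)
    expect_true(all(diff(sub$grade[o]) >= 0))
  }
  # mixed measurement types within one target are ambiguous
  afBad <- af
  afBad$measurement <- c("pIC50", "pKi", "pKi", "pKi")
  expect_error(harmonizeLabels(RankingDataset(tg, cp, matrix(0, 4, 32),
                                              afBad)), "mixed")
})
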