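test_that("base-pair complementarity covers Watson-Crick and wobble", {
  expect_true(pair_complementary("G", "C"))
  expect_true(pair_complementary("A", "T"))
  expect_false(pair_complementary("A", "C"))
  expect_true(pair_complementary("G", "T", allow_gu = TRUE))
  expect_true(pair_complementary("T", "G", allow_gu = TRUE))
  expect_false(pair_complementary("G", "T", allow_gu = FALSE))
  expect_error(pair_complementary("G", "X"), "bases")
})

test_that("structure_model enforces its invariants", {
  expect_error(structure_model(tibble::tibble(i = 5L, j = 3L,
                                              type = "canonical",
                                              stem = "S"), 10),
               "i < j")
  expect_error(structure_model(tibble::tibble(i = c(1L, 2L), j = c(4L, 4L),
                                              type = "canonical",
                                              stem = "S"), 10),
               "at most one pair")
  expect_error(structure_model(tibble::tibble(i = 1L, j = 40L,
                                              type = "canonical",
                                              stem = "S"), 10),
               "within")
})

test_that("formable_pairs counts complementary stem positions", {
  ref <- apollon_reference()
  st <- apollon_structure()
  fp <- formable_pairs(ref, st, "Stem3")
  expect_equal(fp$formable, 8L)
  expect_equal(fp$total, 8L)

  broken <- substitute_base(ref, 34, "T")   # (34,64) was G:C -> T:C
  expect_equal(formable_pairs(broken, st, "Stem3")$formable, 7L)
  compensated <- substitute_base(broken, 64, "A")  # T:A restores the pair
  expect_equal(formable_pairs(compensated, st, "Stem3")$formable, 8L)

  expect_error(formable_pairs("ACGT", st, "Stem3"), "length")
  expect_error(formable_pairs(ref, st, "StemX"), "unknown stem")
})

test_that("every packaged stem is fully formable on the packaged reference", {
  ref <- apollon_reference()
  st <- apollon_structure()
  for (s in unique(st$pairs$stem)) {
    fp <- formable_pairs(ref, st, s)
    expect_equal(fp$formable, fp$total)
  }
})

test_that("stem_statistic summarizes abundant variants and handles empties", {
  ts <- toy_stem_setup()
  pool <- sample_pool(ts$model, 500, seed = 3)
  high_floor <- stem_statistic(pool, ts$structure, "S1",
                               read_floor = max(pool$count) + 1L)
  expect_true(is.na(high_floor$min_k))
  expect_equal(nrow(high_floor$variants), 0L)

  all_vars <- stem_statistic(pool, ts$structure, "S1", read_floor = 1L)
  expect_equal(sum(all_vars$histogram$n_variants), nrow(pool))
  # unselected pools fall below perfect pairing
  expect_lt(all_vars$min_k, 4L)
})

test_that("per-pair null probabilities match an independent enumeration", {
  ref <- apollon_reference()
  st <- apollon_structure()
  model <- doping_model(ref, 0.21)
  nd <- null_pairing_distribution(model, st, "Stem3")
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  sp <- st$pairs[st$pairs$stem == "Stem3", ]
  for (r in seq_len(nrow(sp))) {
    expect_equal(nd$per_pair_prob[[r]],
                 oracle_pair_prob(chars[sp$i[r]], chars[sp$j[r]], 0.21))
  }
  # the G:C reference pair value, frozen from the 16-outcome enumeration
  expect_equal(nd$per_pair_prob[[1]], 0.699, tolerance = 1e-3)
  expect_equal(sum(nd$distribution$prob), 1, tolerance = 1e-12)
  # degenerate doping concentrates all mass at k = n
  nd0 <- null_pairing_distribution(doping_model(ref, 0), st, "Stem3")
  expect_equal(nd0$distribution$prob[[9]], 1)
})

test_that("exact Poisson-binomial tail matches Monte Carlo at every threshold", {
  ts <- toy_stem_setup()
  nd <- null_pairing_distribution(ts$model, ts$structure, "S1")
  B <- 20000L
  pool <- sample_pool(ts$model, B, seed = 11)
  stat <- stem_statistic(pool, ts$structure, "S1", read_floor = 1L)
  k <- rep(stat$variants$k, stat$variants$count)
  for (t in 0:4) {
    emp <- mean(k >= t)
    exact <- nd$distribution$tail[nd$distribution$k == t]
    se <- sqrt(exact * (1 - exact) / B)
    expect_lt(abs(emp - exact), 3 * se + 1e-9)
  }
})

test_that("the chance that m independent variants all pass is tail^m", {
  ts <- toy_stem_setup()
  nd <- null_pairing_distribution(ts$model, ts$structure, "S1")
  tail3 <- nd$distribution$tail[nd$distribution$k == 3L]
  m <- 3L
  groups <- 1500L
  pool <- sample_pool(ts$model, groups * m, seed = 21)
  stat <- stem_statistic(pool, ts$structure, "S1", read_floor = 1L)
  k <- rep(stat$variants$k, stat$variants$count)
  set.seed(22)
  k <- sample(k)  # molecules are i.i.d., so random grouping is valid
  all_pass <- colSums(matrix(k >= 3L, nrow = m)) == m
  p_joint <- tail3^m
  se <- sqrt(p_joint * (1 - p_joint) / groups)
  expect_lt(abs(mean(all_pass) - p_joint), 3 * se + 1e-9)
})

test_that("imino-signal expectations follow the pair composition", {
  st <- apollon_structure()
  expect_equal(expected_imino_signals(st), 20L)          # 12 + 2*4
  no_stem2 <- delete_stem(st, "Stem2")
  expect_equal(expected_imino_signals(no_stem2), 16L)    # 8 + 2*4
  empty <- structure_model(tibble::tibble(i = integer(), j = integer(),
                                          type = character(),
                                          stem = character()), 10L)
  expect_equal(expected_imino_signals(empty), 0L)
  # additive over disjoint stems
  per_stem <- vapply(unique(st$pairs$stem), function(s) {
    keep <- st$pairs[st$pairs$stem == s, ]
    expected_imino_signals(structure_model(keep, st$length))
  }, integer(1))
  expect_equal(sum(per_stem), expected_imino_signals(st))
  expect_error(delete_stem(st, "StemX"), "unknown stem")
})

test_that("structure models round-trip through TSV and export dot-bracket", {
  st <- apollon_structure()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_structure(st, p)
  back <- read_structure(p)
  expect_equal(back$pairs, st$pairs)
  expect_equal(back$length, st$length)
  db <- as_dot_bracket(st)
  expect_equal(nchar(db), c(85L, 85L))
  expect_equal(sum(strsplit(db[[1]], "")[[1]] == "("), 16L)
  expect_equal(sum(strsplit(db[[2]], "")[[1]] == "w"), 8L)
})
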