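test_that("pearson_correlation matches the closed-form oracle and t transform", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    x <- runif(n, 0, 30)
    y <- 2 + 0.5 * x + rnorm(n)
    got <- pearson_correlation(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, unname(want["r"]), tolerance = 1e-10)
    expect_equal(got$p_value, unname(want["p"]), tolerance = 1e-10)
  }
  expect_error(pearson_correlation(1:2, 1:2), class = "spatgeno_invalid_input")
  expect_error(pearson_correlation(rep(1, 5), 1:5),
               class = "spatgeno_invalid_input")
})

test_that("a correlation of 0.63 over 8 pairs gives a two-sided p near 0.09", {
  # reconstruct a dataset with exactly r = 0.63 at n = 8, then test it
  set.seed(33)
  x <- c(5, 6, 8, 10, 12, 15, 18, 21)
  e <- rnorm(8)
  e <- resid(lm(e ~ x)) # orthogonal to x
  r_target <- 0.63
  xs <- scale(x)[, 1]
  y <- r_target * xs + sqrt(1 - r_target^2) * e / sd(e) * sqrt(7 / 7)
  y <- y / sd(y) # unit scale; correlation with x is exactly 0.63 up to fp
  got <- pearson_correlation(x, y)
  expect_equal(got$r, 0.63, tolerance = 1e-10)
  expect_equal(round(got$p_value, 2), 0.09)
})

test_that("ols_fit reproduces exact lines and the normal-equation oracle", {
  x <- c(5, 8, 11, 14, 20, 26)
  y_meth <- 5.27 + 0.18 * x
  fit <- ols_fit(x, y_meth)
  expect_equal(fit$slope, 0.18, tolerance = 1e-12)
  expect_equal(fit$intercept, 5.27, tolerance = 1e-12)
  y_mut <- -11.6 + 1.7 * x
  fit2 <- ols_fit(x, y_mut)
  expect_equal(fit2$slope, 1.7, tolerance = 1e-12)
  expect_equal(fit2$intercept, -11.6, tolerance = 1e-12)

  two <- ols_fit(c(0, 10), c(1, 21))
  expect_equal(two$slope, 2)
  expect_equal(two$intercept, 1)

  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    x <- runif(n, 0, 30); y <- rnorm(n, 3 + 0.7 * x, 2)
    fit <- ols_fit(x, y)
    want <- oracle_ols(x, y)
    expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(want["intercept"]), tolerance = 1e-10)
    # residuals orthogonal to x
    resid <- y - fit$intercept - fit$slope * x
    expect_equal(sum(resid * x), 0, tolerance = 1e-8)
    # scale equivariance
    fit3 <- ols_fit(x, 3 * y)
    expect_equal(fit3$slope, 3 * fit$slope, tolerance = 1e-10)
    expect_equal(pearson_correlation(x, 3 * y)$r, pearson_correlation(x, y)$r,
                 tolerance = 1e-12)
  }
  expect_error(ols_fit(rep(2, 5), 1:5), class = "spatgeno_invalid_input")
})

test_that("derived_equivalences converts slopes to the reported constants", {
  mut <- derived_equivalences(1.7)
  expect_equal(mut$per_10mm_rounded, 17)
  expect_equal(mut$mm_per_unit_rounded, 0.6)
  meth <- derived_equivalences(0.18)
  expect_equal(meth$per_10mm_rounded, 1.8)
  expect_equal(meth$mm_per_unit_rounded, 5.6)
  unit <- derived_equivalences(1)
  expect_equal(unit$per_10mm, 10)
  expect_equal(unit$mm_per_unit, 1)
  zero <- derived_equivalences(0)
  expect_true(is.na(zero$mm_per_unit))
  raw <- derived_equivalences(list(slope = 3), digits = NA)
  expect_equal(raw$mm_per_unit_rounded, 1 / 3)
})

test_that("assemble_records inner-joins pairs with distances per modality", {
  pairs <- tibble::tibble(patient_id = "P1",
                          sample_a = c("S1", "S1", "S2"),
                          sample_b = c("S2", "S3", "S3"),
                          euclidean_mm = c(5, 12, 9),
                          pair_kind = "coordinate")
  mut <- tibble::tibble(patient_id = "P1", sample_a = c("S1", "S1", "S2"),
                        sample_b = c("S2", "S3", "S3"),
                        jaccard_distance = c(0.2, 0.5, 0.4),
                        count_distance = c(2, 9, 6),
                        n_union_mutations = c(10L, 12L, 11L),
                        n_shared = c(8L, 3L, 5L))
  meth <- tibble::tibble(patient_id = "P1", sample_a = c("S1", "S1"),
                         sample_b = c("S2", "S3"),
                         l1_distance = c(4, 11), n_probes_used = 500L)
  rec <- assemble_records(pairs, mutation = mut, methylation = meth)
  expect_equal(nrow(rec), 5)
  expect_equal(sum(rec$modality == "mutation"), 3)
  expect_equal(sum(rec$modality == "methylation"), 2)
  expect_equal(attr(rec, "n_unmatched"), 1L)
  expect_equal(rec$genomic_distance[rec$modality == "mutation"], c(2, 9, 6))
  recj <- assemble_records(pairs, mutation = mut, mutation_measure = "jaccard")
  expect_equal(recj$genomic_distance, c(0.2, 0.5, 0.4))
  dup <- dplyr::bind_rows(mut, mut[1, ])
  expect_error(assemble_records(pairs, mutation = dup),
               class = "spatgeno_invalid_input")
})

test_that("subgroup labels mark concordant pairs", {
  pairs <- tibble::tibble(patient_id = "P1", sample_a = c("S1", "S1"),
                          sample_b = c("S2", "S3"), euclidean_mm = c(5, 8),
                          pair_kind = "coordinate")
  meth <- tibble::tibble(patient_id = "P1", sample_a = c("S1", "S1"),
                         sample_b = c("S2", "S3"), l1_distance = c(1, 2),
                         n_probes_used = 10L)
  meta <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                         patient_id = "P1",
                         idh_status = c("mutant", "mutant", "wildtype"))
  rec <- assemble_records(pairs, methylation = meth, sample_meta = meta)
  expect_equal(rec$idh_status_concordant, c(TRUE, FALSE))
  expect_equal(rec$idh_status_pair, c("mutant", NA))
})

test_that("associate pools per modality and flags insufficient n", {
  set.seed(14)
  x <- runif(30, 5, 25)
  rec <- tibble::tibble(patient_id = rep(paste0("P", 1:6), each = 5),
                        sample_a = "a", sample_b = "b",
                        euclidean_mm = x, pair_kind = "coordinate",
                        modality = "methylation",
                        genomic_distance = 5.27 + 0.18 * x + rnorm(30, 0, 0.4))
  res <- associate(rec)$methylation
  expect_false(res$insufficient_n)
  expect_equal(res$n_pairs, 30)
  expect_equal(res$slope, 0.18, tolerance = 0.15)
  expect_equal(res$per_10mm, 10 * res$slope)
  expect_equal(res$mm_per_unit * res$slope, 1)

  tiny <- rec[1:2, ]
  out <- associate(tiny)$methylation
  expect_true(out$insufficient_n)
  expect_true(is.na(out$pearson_r))
})

test_that("the within-patient permutation p-value tracks the analytic one", {
  set.seed(15)
  x <- runif(40, 5, 25)
  rec <- tibble::tibble(patient_id = rep(paste0("P", 1:8), each = 5),
                        sample_a = "a", sample_b = "b",
                        euclidean_mm = x, pair_kind = "coordinate",
                        modality = "cnv",
                        genomic_distance = 2 + 1.5 * x + rnorm(40, 0, 4))
  res <- associate(rec, permutation = TRUE, n_perm = 199)$cnv
  expect_lte(res$perm_p_value, 0.05)
  # null data: permutation p should not be extreme
  recnull <- rec
  recnull$genomic_distance <- rnorm(40, 10, 2)
  resnull <- associate(recnull, permutation = TRUE, n_perm = 199)$cnv
  expect_gte(resnull$perm_p_value, 0.05)
})
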