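small_cfg <- function(seed = 3, n_patients = 4, ...) {
  simulation_config(seed = seed, n_patients = n_patients,
                    methylation = list(n_probes = 1500, n_informative = 200),
                    ...)
}

test_that("the generator is bit-identical under a fixed seed", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$sites, b$sites)
  expect_identical(a$calls, b$calls)
  expect_identical(a$segments, b$segments)
  expect_identical(a$beta, b$beta)
  c2 <- simulate_cohort(small_cfg(seed = 4))
  expect_false(identical(a$sites, c2$sites))
})

test_that("extending the cohort leaves existing patients untouched", {
  a <- simulate_coordinates(small_cfg(n_patients = 3))
  b <- simulate_coordinates(small_cfg(n_patients = 5))
  expect_identical(a, b[b$patient_id %in% unique(a$patient_id), ])
})

test_that("site geometry respects the tumor radius and split offsets", {
  cfg <- small_cfg(seed = 5, n_patients = 10)
  sites <- simulate_coordinates(cfg)
  r <- sqrt(sites$x^2 + sites$y^2 + sites$z^2)
  expect_true(all(r <= cfg$tumor_radius_mm + cfg$shallow_deep_mm / 2 + 1e-9))
  pairs <- enumerate_pairs(sites)
  expect_true(all(pairs$euclidean_mm <= 2 * cfg$tumor_radius_mm +
                    cfg$shallow_deep_mm + 1e-9))
  # split needle samples are genuinely 5 mm apart in coordinates
  split <- sites[sites$depth_label %in% c("shallow", "deep") &
                   sites$instrument == "needle", ]
  for (src in unique(split$source_site_id)) {
    two <- split[split$source_site_id == src, ]
    expect_equal(euclidean_distance(unlist(two[1, c("x", "y", "z")]),
                                    unlist(two[2, c("x", "y", "z")])),
                 cfg$shallow_deep_mm)
  }
})

test_that("mean pair distance agrees with an independent rejection sampler", {
  cfg <- simulation_config(seed = 6, n_patients = 150,
                           tracks_per_patient = c(2L, 2L),
                           shallow_deep_fraction = 0, forceps_split_fraction = 0)
  sites <- simulate_coordinates(cfg)
  pairs <- enumerate_pairs(sites)
  # oracle: rejection sampling from the cube into the sphere
  set.seed(99)
  draw <- function(n) {
    pts <- matrix(runif(3 * n * 3, -30, 30), ncol = 3)
    pts[rowSums(pts^2) <= 30^2, , drop = FALSE]
  }
  a <- draw(4000); b <- draw(4000)
  m <- min(nrow(a), nrow(b))
  oracle_d <- sqrt(rowSums((a[1:m, ] - b[1:m, ])^2))
  se <- sd(oracle_d) / sqrt(m) + sd(pairs$euclidean_mm) / sqrt(nrow(pairs))
  expect_lt(abs(mean(pairs$euclidean_mm) - mean(oracle_d)), 3 * se)
})

test_that("generated variant calls carry exact pass/fail ground truth", {
  cfg <- small_cfg(seed = 7)
  sites <- simulate_coordinates(cfg)
  calls <- simulate_mutations(cfg, sites)
  kept <- filter_variants(calls)
  expect_equal(nrow(kept), sum(calls$intended_pass))
  expect_setequal(paste(kept$sample_id, kept$chrom, kept$pos),
                  with(calls[calls$intended_pass, ],
                       paste(sample_id, chrom, pos)))
  # each retention criterion is exercised by at least one decoy
  decoys <- calls[!calls$intended_pass, ]
  expect_gte(nrow(decoys), 5)
  expect_true(any(decoys$region_class != "exonic"))
  expect_true(any(decoys$func_class == "synonymous SNV"))
  expect_true(any(decoys$ref_reads < 10))
  expect_true(any(decoys$alt_reads < 8))
  expect_true(any(decoys$alt_freq < 0.1 & decoys$alt_reads >= 8 &
                    decoys$ref_reads >= 10))
})

test_that("zero spatial signal collapses every genomic distance to zero", {
  cfg <- simulation_config(seed = 8, n_patients = 3,
                           mutation = list(target_slope = 0),
                           cnv = list(target_slope = 0, extra_breakpoint_prob = 0),
                           methylation = list(n_probes = 800, n_informative = 100,
                                              target_slope = 0,
                                              noise_sd_beta = 0, missing_rate = 0))
  sites <- simulate_coordinates(cfg)
  calls <- filter_variants(simulate_mutations(cfg, sites))
  for (pid in unique(calls$patient_id)) {
    tab <- mutation_pair_distances(build_af_matrix(calls[calls$patient_id == pid, ]))
    expect_true(all(tab$count_distance == 0))
    expect_true(all(tab$n_shared == tab$n_union_mutations))
  }
  segs <- simulate_cnv(cfg, sites)
  for (pid in unique(segs$patient_id)) {
    s <- segs[segs$patient_id == pid, ]
    tab <- cnv_pair_distances(build_event_matrix(union_breakpoints(s), s))
    expect_true(all(tab$canberra_distance == 0))
  }
  beta <- simulate_methylation(cfg, sites)
  meta <- simulate_sample_meta(cfg, sites)
  tab <- methylation_pair_distances(beta, meta, k = 100)
  expect_true(all(tab$l1_distance == 0))
})

test_that("truncal AFs exceed subclonal AFs and betas stay in range", {
  cfg <- small_cfg(seed = 9)
  sites <- simulate_coordinates(cfg)
  calls <- simulate_mutations(cfg, sites)
  pass <- calls[calls$intended_pass, ]
  key <- paste(pass$patient_id, pass$chrom, pass$pos)
  n_samples <- table(sites$patient_id)
  per_key <- tapply(pass$sample_id, key, length)
  truncal <- names(per_key)[per_key == n_samples[sub(" .*", "", names(per_key))]]
  af_truncal <- mean(pass$alt_freq[key %in% truncal])
  af_sub <- mean(pass$alt_freq[!key %in% truncal])
  expect_gt(af_truncal, af_sub)

  beta <- simulate_methylation(cfg, sites)
  vals <- beta[!is.na(beta)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_gt(sum(is.na(beta)), 0)
})

test_that("raising the spatial signal raises mean genomic distance", {
  res <- sapply(c(0.5, 1.7, 4), function(sl) {
    cfg <- simulation_config(seed = 10, n_patients = 5,
                             mutation = list(target_slope = sl))
    sites <- simulate_coordinates(cfg)
    calls <- filter_variants(simulate_mutations(cfg, sites))
    mean(dplyr::bind_rows(lapply(unique(calls$patient_id), function(pid) {
      mutation_pair_distances(build_af_matrix(calls[calls$patient_id == pid, ]))
    }))$count_distance)
  })
  expect_true(all(diff(res) > 0))
  res_meth <- sapply(c(0.05, 0.18, 0.5), function(sl) {
    cfg <- simulation_config(seed = 10, n_patients = 5,
                             methylation = list(n_probes = 1200,
                                                n_informative = 150,
                                                target_slope = sl))
    sites <- simulate_coordinates(cfg)
    beta <- simulate_methylation(cfg, sites)
    meta <- simulate_sample_meta(cfg, sites)
    mean(methylation_pair_distances(beta, meta, k = 150)$l1_distance)
  })
  expect_true(all(diff(res_meth) > 0))
})

test_that("simulate_distance_pairs recovers its generating line", {
  exact <- simulate_distance_pairs(5.27, 0.18, 0, 50, seed = 16)
  fit <- ols_fit(exact$euclidean_mm, exact$genomic_distance)
  expect_equal(fit$slope, 0.18, tolerance = 1e-10)
  expect_equal(fit$intercept, 5.27, tolerance = 1e-10)

  noisy <- simulate_distance_pairs(-11.6, 1.7, 1, 200, seed = 17)
  fit2 <- ols_fit(noisy$euclidean_mm, noisy$genomic_distance)
  expect_lt(abs(fit2$slope - 1.7) / 1.7, 0.05)
  expect_true(all(noisy$genomic_distance >= 0))
  expect_error(simulate_distance_pairs(0, 1, 0, 2),
               class = "spatgeno_invalid_input")
})

test_that("written cohorts round-trip through the file readers", {
  cfg <- small_cfg(seed = 18, n_patients = 2)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  sites <- read_coordinates(file.path(dir, "coordinates.tsv"))
  expect_equal(nrow(sites), nrow(sim$sites))
  expect_equal(sites$x, sim$sites$x)
  calls <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(nrow(calls), nrow(sim$calls))
  manifest <- readr::read_tsv(file.path(dir, "cns_manifest.tsv"),
                              show_col_types = FALSE)
  seg1 <- read_cns(manifest$path[1], manifest$patient_id[1],
                   manifest$sample_id[1])
  orig <- sim$segments[sim$segments$sample_id == manifest$sample_id[1], ]
  expect_equal(seg1$log2, orig$log2)
  beta <- read_beta_matrix(file.path(dir, "beta.csv"))
  expect_equal(dim(beta), dim(sim$beta))
  expect_equal(unname(beta[, 1]), unname(sim$beta[, 1]))
})
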