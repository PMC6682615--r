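# Seed-reproducible synthetic multi-site biopsy cohorts.
#
# Spatial signal enters every modality through the same mechanism: spatially
# segregated subclonal alterations bounded by random planes ("fronts") through
# the tumor. A front with unit normal u and offset t separates samples on
# either side of the plane u.x = t. With u uniform on the sphere and t uniform
# on [-T, T] (T = tumor radius plus half the shallow/deep offset, so every
# site is inside the slab), the probability that a front separates two sites a
# distance d apart is exactly E|u.(a-b)| / (2T) = d / (4T) -- linear in d.
# Summing per-alteration weights w over fronts therefore gives
# E[genomic distance] = (sum w / 4T) * d, so a configured target slope is hit
# by budgeting sum w = 4 T slope. No small-perturbation approximation is
# involved, which keeps pooled OLS slope recovery unbiased.

#' Simulation configuration for a synthetic biopsy cohort
#'
#' @param seed Master seed; fixes all outputs bit-for-bit. Per-patient,
#'   per-modality child seeds are derived from it, so adding patients never
#'   perturbs existing ones.
#' @param n_patients Number of patients (default 25).
#' @param tracks_per_patient Integer range (min, max) of physical biopsy
#'   tracks per patient (default 2-4; shallow/deep splits then yield roughly
#'   3-6 samples).
#' @param tumor_radius_mm Radius of the spherical tumor volume sites are drawn
#'   from (default 30).
#' @param shallow_deep_mm Offset between the shallow and deep halves of a
#'   split needle core (default 5).
#' @param needle_fraction Fraction of tracks sampled with a needle rather than
#'   forceps (default 0.8).
#' @param shallow_deep_fraction Fraction of needle tracks split into
#'   shallow/deep sub-samples (default 0.5).
#' @param forceps_split_fraction Fraction of forceps tracks yielding a
#'   same-location shallow/deep pair (default 0.1).
#' @param mutation,cnv,methylation Named lists overriding per-modality model
#'   parameters; see Details.
#' @details Mutation model: `n_truncal` truncal mutations (default 10) with
#'   allele frequencies around `truncal_af_mean` (0.4), subclonal front
#'   mutations with AFs around `private_af_mean` (0.2, below truncal),
#'   `read_depth` (100), a `decoy_fraction` (0.2) of filter-failing calls
#'   exercising each retention criterion, and `target_slope` (1.7 mutations
#'   per mm). CNV model: `n_segments` (1200) segments over `n_chrom` (12)
#'   chromosomes of `segment_length` (1 Mb) bins, baseline log2 ratios
#'   N(0, `base_log2_sd` = 0.4), subclonal switch magnitudes uniform on
#'   [`switch_min`, `switch_max`] = [1.5, 2.5], optional measurement noise
#'   `noise_sd` (0), occasional sample-private breakpoints
#'   (`extra_breakpoint_prob` = 0.5 per sample) and `target_slope` (6.9
#'   Canberra units per mm). Methylation model: `n_probes` (10000) probes with
#'   bimodal baseline betas, `n_informative` (500) mid-range probes carrying
#'   subclonal switches whose beta-scale weights are scaled to `target_slope`
#'   (0.18 L1 units per mm), measurement noise `noise_sd_beta` (0.002) and
#'   `missing_rate` (0.005).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 25L,
                              tracks_per_patient = c(2L, 4L),
                              tumor_radius_mm = 30,
                              shallow_deep_mm = 5,
                              needle_fraction = 0.8,
                              shallow_deep_fraction = 0.5,
                              forceps_split_fraction = 0.1,
                              mutation = list(),
                              cnv = list(),
                              methylation = list()) {
  assert_scalar_number(tumor_radius_mm, "tumor_radius_mm", min = 1e-9)
  assert_scalar_number(n_patients, "n_patients", min = 1)
  mut <- utils::modifyList(list(
    n_truncal = 10L, truncal_af_mean = 0.4, truncal_af_sd = 0.08,
    private_af_mean = 0.2, private_af_sd = 0.05, af_sample_sd = 0.02,
    read_depth = 100L, decoy_fraction = 0.2, target_slope = 1.7), mutation)
  cnvm <- utils::modifyList(list(
    n_segments = 1200L, n_chrom = 12L, segment_length = 1e6,
    base_log2_sd = 0.4, switch_min = 1.5, switch_max = 2.5,
    noise_sd = 0, extra_breakpoint_prob = 0.5, target_slope = 6.9), cnv)
  meth <- utils::modifyList(list(
    n_probes = 10000L, n_informative = 500L, noise_sd_beta = 0.002,
    missing_rate = 0.005, target_slope = 0.18), methylation)
  for (v in c(mut[c("truncal_af_sd", "private_af_sd", "af_sample_sd",
                    "decoy_fraction", "target_slope")],
              cnvm[c("base_log2_sd", "noise_sd", "target_slope")],
              meth[c("noise_sd_beta", "missing_rate", "target_slope")])) {
    if (v < 0) stop_spatgeno("rates and standard deviations must be non-negative",
                             class = "spatgeno_invalid_input")
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 tracks_per_patient = as.integer(tracks_per_patient),
                 tumor_radius_mm = tumor_radius_mm,
                 shallow_deep_mm = shallow_deep_mm,
                 needle_fraction = needle_fraction,
                 shallow_deep_fraction = shallow_deep_fraction,
                 forceps_split_fraction = forceps_split_fraction,
                 mutation = mut, cnv = cnvm, methylation = meth),
            class = "simulation_config")
}

# Slab half-width: every site (including split offsets) satisfies |u.x| <= T.
slab_halfwidth <- function(cfg) cfg$tumor_radius_mm + cfg$shallow_deep_mm / 2

# Expected number of samples per patient under the track/split configuration.
expected_samples_per_patient <- function(cfg) {
  mean_tracks <- mean(cfg$tracks_per_patient)
  per_track <- cfg$needle_fraction * (1 + cfg$shallow_deep_fraction) +
    (1 - cfg$needle_fraction) * (1 + cfg$forceps_split_fraction)
  mean_tracks * per_track
}

random_unit_vector <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Uniform points in a sphere of radius r.
runif_sphere <- function(n, r) {
  u <- random_unit_vector(n)
  u * (r * stats::runif(n)^(1 / 3))
}

patient_ids <- function(cfg) sprintf("P%02d", seq_len(cfg$n_patients))

#' Simulate biopsy site coordinates
#'
#' Sites are uniform within a sphere of `tumor_radius_mm` centred at the
#' patient-level origin. A configured fraction of needle tracks is split into
#' shallow/deep sub-samples offset by `shallow_deep_mm` along a random axis
#' (so their true geometric separation equals the conventional 5 mm);
#' occasional forceps tracks yield a same-location shallow/deep pair.
#'
#' @param cfg A [simulation_config()].
#' @return Site tibble in the [read_coordinates()] schema.
#' @export
simulate_coordinates <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  out <- list()
  for (i in seq_len(cfg$n_patients)) {
    set.seed(child_seed(cfg$seed, i * 10L + 1L))
    pid <- patient_ids(cfg)[i]
    n_tracks <- sample(seq(cfg$tracks_per_patient[1], cfg$tracks_per_patient[2]), 1)
    centers <- runif_sphere(n_tracks, cfg$tumor_radius_mm)
    rows <- list()
    s_idx <- 0L
    for (tr in seq_len(n_tracks)) {
      instrument <- if (stats::runif(1) < cfg$needle_fraction) "needle" else "forceps"
      track_id <- sprintf("%s_T%d", pid, tr)
      split <- if (instrument == "needle") {
        stats::runif(1) < cfg$shallow_deep_fraction
      } else {
        stats::runif(1) < cfg$forceps_split_fraction
      }
      if (split) {
        axis <- if (instrument == "needle") {
          drop(random_unit_vector(1)) * cfg$shallow_deep_mm / 2
        } else {
          c(0, 0, 0) # forceps split: same spatial location
        }
        for (side in c(1, -1)) {
          s_idx <- s_idx + 1L
          xyz <- centers[tr, ] + side * axis
          rows[[length(rows) + 1L]] <- tibble::tibble(
            patient_id = pid, sample_id = sprintf("%sS%d", pid, s_idx),
            x = xyz[1], y = xyz[2], z = xyz[3], instrument = instrument,
            depth_label = if (side == 1) "shallow" else "deep",
            source_site_id = track_id)
        }
      } else {
        s_idx <- s_idx + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = pid, sample_id = sprintf("%sS%d", pid, s_idx),
          x = centers[tr, 1], y = centers[tr, 2], z = centers[tr, 3],
          instrument = instrument, depth_label = "whole",
          source_site_id = track_id)
      }
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  sites <- dplyr::bind_rows(out)
  sites$has_coordinates <- TRUE
  sites
}

# Presence matrix of planar fronts: fronts x samples, TRUE on the u.x > t side.
front_sides <- function(n_fronts, coords, T_half) {
  u <- random_unit_vector(n_fronts)
  t_off <- stats::runif(n_fronts, -T_half, T_half)
  proj <- u %*% t(coords) # n_fronts x n_samples
  proj > t_off
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate somatic variant calls
#'
#' Per patient: `n_truncal` truncal mutations present in every sample with
#' allele frequencies around `truncal_af_mean`; subclonal mutations on planar
#' fronts (one mutation per front, budgeted so the expected mutation-count
#' distance between two samples is `target_slope` times their separation),
#' with lower AFs around `private_af_mean`; read counts consistent with the
#' five retention criteria for intended-pass calls; plus a `decoy_fraction` of
#' labelled filter-failing calls cycling through the five criteria.
#'
#' @param cfg A [simulation_config()].
#' @param sites Site tibble from [simulate_coordinates()].
#' @return Variant-call tibble with a ground-truth `intended_pass` column.
#' @export
simulate_mutations <- function(cfg, sites) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- cfg$mutation
  T_half <- slab_halfwidth(cfg)
  n_sub <- round(4 * T_half * p$target_slope)
  out <- list()
  for (i in seq_len(cfg$n_patients)) {
    set.seed(child_seed(cfg$seed, i * 10L + 2L))
    pid <- patient_ids(cfg)[i]
    ps <- sites[sites$patient_id == pid, ]
    coords <- as.matrix(ps[, c("x", "y", "z")])
    n_s <- nrow(ps)
    presence_tr <- matrix(TRUE, nrow = p$n_truncal, ncol = n_s)
    presence_sub <- front_sides(n_sub, coords, T_half)
    presence <- rbind(presence_tr, presence_sub)
    af_mean <- c(clamp(stats::rnorm(p$n_truncal, p$truncal_af_mean, p$truncal_af_sd),
                       0.15, 0.9),
                 clamp(stats::rnorm(n_sub, p$private_af_mean, p$private_af_sd),
                       0.12, 0.5))
    rows <- list()
    for (m in seq_len(nrow(presence))) {
      in_samples <- which(presence[m, ])
      if (length(in_samples) == 0) next
      af <- clamp(stats::rnorm(length(in_samples), af_mean[m], p$af_sample_sd),
                  0.11, 0.95)
      n_alt <- clamp(round(af * p$read_depth), 11, p$read_depth - 10)
      n_ref <- p$read_depth - n_alt
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, sample_id = ps$sample_id[in_samples],
        chrom = sprintf("chr%d", (m %% 20) + 1), pos = 10000L + m * 100L,
        ref = "A", alt = "T", gene = sprintf("GENE%04d", m),
        region_class = "exonic",
        func_class = if (m %% 7 == 0) "stopgain" else "nonsynonymous SNV",
        ref_reads = n_ref, alt_reads = n_alt,
        alt_freq = n_alt / p$read_depth,
        intended_pass = TRUE)
    }
    calls <- dplyr::bind_rows(rows)
    # decoys: each violates exactly one retention criterion
    n_decoy <- round(p$decoy_fraction * nrow(calls))
    if (n_decoy > 0) {
      which_crit <- (seq_len(n_decoy) - 1L) %% 5L + 1L
      dsample <- sample(ps$sample_id, n_decoy, replace = TRUE)
      decoys <- tibble::tibble(
        patient_id = pid, sample_id = dsample,
        chrom = "chr21", pos = 900000L + seq_len(n_decoy) * 10L,
        ref = "G", alt = "C", gene = "DECOY",
        region_class = ifelse(which_crit == 1L, "intronic", "exonic"),
        func_class = ifelse(which_crit == 2L, "synonymous SNV",
                            "nonsynonymous SNV"),
        ref_reads = c(50L, 50L, 5L, 40L, 92L)[which_crit],
        alt_reads = c(20L, 20L, 20L, 5L, 8L)[which_crit],
        intended_pass = FALSE)
      decoys$alt_freq <- decoys$alt_reads / (decoys$ref_reads + decoys$alt_reads)
      calls <- dplyr::bind_rows(calls, decoys)
    }
    out[[i]] <- calls
  }
  dplyr::bind_rows(out)
}

#' Simulate CNV segment profiles
#'
#' Per patient: a baseline segmentation (`n_segments` fixed-width bins over
#' `n_chrom` chromosomes) with log2 ratios N(0, `base_log2_sd`). Subclonal
#' copy-number switches of magnitude uniform on [`switch_min`, `switch_max`]
#' are placed on planar fronts; fronts are budgeted until the summed Canberra
#' term weights reach `4 * T * target_slope`, so the expected Canberra
#' distance between two samples grows as `target_slope` per mm. Occasional
#' sample-private breakpoints split one segment in half (same log2) to
#' exercise breakpoint unification.
#'
#' @param cfg A [simulation_config()].
#' @param sites Site tibble from [simulate_coordinates()].
#' @return Segment tibble `patient_id, sample_id, chrom, start, end, log2`.
#' @export
simulate_cnv <- function(cfg, sites) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- cfg$cnv
  T_half <- slab_halfwidth(cfg)
  budget <- 4 * T_half * p$target_slope
  per_chrom <- ceiling(p$n_segments / p$n_chrom)
  layout <- tibble::tibble(
    chrom = sprintf("chr%d", rep(seq_len(p$n_chrom), each = per_chrom)[seq_len(p$n_segments)]),
    start = rep((seq_len(per_chrom) - 1) * p$segment_length, p$n_chrom)[seq_len(p$n_segments)],
    end = rep(seq_len(per_chrom) * p$segment_length, p$n_chrom)[seq_len(p$n_segments)])
  out <- list()
  for (i in seq_len(cfg$n_patients)) {
    set.seed(child_seed(cfg$seed, i * 10L + 3L))
    pid <- patient_ids(cfg)[i]
    ps <- sites[sites$patient_id == pid, ]
    coords <- as.matrix(ps[, c("x", "y", "z")])
    n_e <- p$n_segments
    base <- stats::rnorm(n_e, 0, p$base_log2_sd)
    delta <- sample(c(-1, 1), n_e, replace = TRUE) *
      stats::runif(n_e, p$switch_min, p$switch_max)
    w <- abs(delta) / (abs(base) + abs(base + delta)) # Canberra term if switched
    cum <- cumsum(w)
    n_front <- if (budget <= 0) 0L else which(cum >= budget)[1]
    if (is.na(n_front)) {
      stop_spatgeno(sprintf(
        "CNV front budget %.1f unreachable with %d segments (sum of weights %.1f); increase n_segments",
        budget, n_e, cum[n_e]), class = "spatgeno_invalid_input")
    }
    switched <- matrix(FALSE, nrow = n_e, ncol = nrow(ps))
    switched[seq_len(n_front), ] <- front_sides(n_front, coords, T_half)
    log2m <- matrix(base, nrow = n_e, ncol = nrow(ps)) +
      matrix(delta, nrow = n_e, ncol = nrow(ps)) * switched
    if (p$noise_sd > 0) {
      log2m <- log2m + matrix(stats::rnorm(n_e * nrow(ps), 0, p$noise_sd),
                              nrow = n_e)
    }
    for (s in seq_len(nrow(ps))) {
      seg <- tibble::tibble(patient_id = pid, sample_id = ps$sample_id[s],
                            chrom = layout$chrom, start = layout$start,
                            end = layout$end, log2 = log2m[, s])
      if (stats::runif(1) < p$extra_breakpoint_prob) {
        k <- sample(nrow(seg), 1)
        mid <- floor((seg$start[k] + seg$end[k]) / 2)
        split <- seg[c(k, k), ]
        split$end[1] <- mid
        split$start[2] <- mid
        seg <- dplyr::bind_rows(seg[-k, ], split)
      }
      out[[length(out) + 1L]] <- seg
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a methylation beta matrix
#'
#' Probes have bimodal baseline betas (hyper/hypo-methylated). A fixed panel
#' of `n_informative` mid-range probes carries subclonal methylation switches
#' on planar fronts, with beta-scale switch weights scaled so the expected
#' top-`n_informative` L1 distance grows as `target_slope` per mm. All probes
#' receive N(0, `noise_sd_beta`) measurement noise (clamped to \[0, 1\]) and
#' `missing_rate` missing values.
#'
#' @param cfg A [simulation_config()].
#' @param sites Site tibble from [simulate_coordinates()].
#' @return Beta matrix (probes x samples).
#' @export
simulate_methylation <- function(cfg, sites) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- cfg$methylation
  T_half <- slab_halfwidth(cfg)
  probe_ids <- sprintf("cg%06d", seq_len(p$n_probes))
  informative <- seq_len(p$n_informative)
  cols <- list()
  for (i in seq_len(cfg$n_patients)) {
    set.seed(child_seed(cfg$seed, i * 10L + 4L))
    pid <- patient_ids(cfg)[i]
    ps <- sites[sites$patient_id == pid, ]
    coords <- as.matrix(ps[, c("x", "y", "z")])
    n_s <- nrow(ps)
    base_logit <- ifelse(stats::runif(p$n_probes) < 0.5,
                         stats::rnorm(p$n_probes, -2.5, 0.5),
                         stats::rnorm(p$n_probes, 2.5, 0.5))
    base <- stats::plogis(base_logit)
    base[informative] <- stats::runif(p$n_informative, 0.3, 0.6)
    w_raw <- stats::runif(p$n_informative, 0.5, 1.5)
    # Weight budget sums to 4 T slope after two analytic corrections: a
    # switched probe displaces its measurement-noise baseline E|e_a - e_b| =
    # 2 sd / sqrt(pi), and probes with a missing value within a patient drop
    # out of the variance selection (retention (1 - mr)^E[samples/patient]).
    noise_floor <- 2 * p$noise_sd_beta / sqrt(pi)
    retain <- (1 - p$missing_rate)^expected_samples_per_patient(cfg)
    budget <- (4 * T_half * p$target_slope) / retain +
      p$n_informative * noise_floor
    w <- w_raw * budget / sum(w_raw)
    side <- front_sides(p$n_informative, coords, T_half)
    beta <- matrix(base, nrow = p$n_probes, ncol = n_s,
                   dimnames = list(probe_ids, ps$sample_id))
    beta[informative, ] <- beta[informative, ] + side * w
    beta <- clamp(beta + matrix(stats::rnorm(p$n_probes * n_s, 0, p$noise_sd_beta),
                                nrow = p$n_probes), 0, 1)
    if (p$missing_rate > 0) {
      beta[stats::runif(length(beta)) < p$missing_rate] <- NA_real_
    }
    cols[[i]] <- beta
  }
  do.call(cbind, cols)
}

#' Simulate sample metadata (patient mapping and molecular subgroup labels)
#'
#' @param cfg A [simulation_config()].
#' @param sites Site tibble from [simulate_coordinates()].
#' @return Tibble `sample_id, patient_id, idh_status, codeletion_1p19q`
#'   (labels constant within a patient).
#' @export
simulate_sample_meta <- function(cfg, sites) {
  meta <- sites[, c("sample_id", "patient_id")]
  pids <- patient_ids(cfg)
  set.seed(child_seed(cfg$seed, 7L))
  idh <- sample(c("mutant", "wildtype"), length(pids), replace = TRUE)
  codel <- ifelse(idh == "mutant" & stats::runif(length(pids)) < 0.5,
                  "codeleted", "intact")
  meta$idh_status <- idh[match(meta$patient_id, pids)]
  meta$codeletion_1p19q <- codel[match(meta$patient_id, pids)]
  meta
}

#' Directly simulate (Euclidean, genomic) distance pairs from a linear model
#'
#' Draws `x` uniform on `x_range` and `y = a + b x + N(0, sd)`, truncated at 0
#' so y stays a valid distance. Used for slope/intercept recovery checks with
#' known ground truth.
#'
#' @param a Intercept (genomic units). @param b Slope (units per mm).
#' @param sd Gaussian noise standard deviation.
#' @param n Number of pairs (>= 3).
#' @param x_range Length-2 range of Euclidean distances in mm (default
#'   c(7, 25), the span over which multi-site biopsy pairs are typically
#'   observed).
#' @param seed Optional seed.
#' @return Tibble `euclidean_mm, genomic_distance`.
#' @export
simulate_distance_pairs <- function(a, b, sd, n, x_range = c(7, 25),
                                    seed = NULL) {
  if (n < 3) stop_spatgeno("need n >= 3 pairs", class = "spatgeno_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- pmax(0, a + b * x + stats::rnorm(n, 0, sd))
  tibble::tibble(euclidean_mm = x, genomic_distance = y)
}

#' Simulate a complete cohort
#'
#' @param cfg A [simulation_config()].
#' @return List with `sites`, `calls`, `segments`, `beta`, `sample_meta` and a
#'   `truth` block (target slopes and bookkeeping).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  sites <- simulate_coordinates(cfg)
  list(
    sites = sites,
    calls = simulate_mutations(cfg, sites),
    segments = simulate_cnv(cfg, sites),
    beta = simulate_methylation(cfg, sites),
    sample_meta = simulate_sample_meta(cfg, sites),
    truth = list(
      seed = cfg$seed,
      target_slopes = list(mutation = cfg$mutation$target_slope,
                           cnv = cfg$cnv$target_slope,
                           methylation = cfg$methylation$target_slope),
      slab_halfwidth_mm = slab_halfwidth(cfg)
    )
  )
}

#' Write a simulated cohort as pipeline input files
#'
#' Writes `coordinates.tsv`, `variants.tsv`, per-sample `.cns` segment files
#' with a `cns_manifest.tsv`, `beta.csv`, `sample_meta.tsv` and `truth.json`
#' under `dir`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coords <- sim$sites
  names(coords)[names(coords) %in% c("x", "y", "z")] <- c("x_mm", "y_mm", "z_mm")
  readr::write_tsv(coords[, c("patient_id", "sample_id", "x_mm", "y_mm", "z_mm",
                              "instrument", "depth_label", "source_site_id")],
                   file.path(dir, "coordinates.tsv"), progress = FALSE)
  readr::write_tsv(sim$calls, file.path(dir, "variants.tsv"), progress = FALSE)
  cns_dir <- file.path(dir, "cns")
  dir.create(cns_dir, showWarnings = FALSE)
  manifest <- list()
  for (sid in unique(sim$segments$sample_id)) {
    seg <- sim$segments[sim$segments$sample_id == sid, ]
    path <- file.path(cns_dir, paste0(sid, ".cns"))
    readr::write_tsv(tibble::tibble(chromosome = seg$chrom, start = seg$start,
                                    end = seg$end, log2 = seg$log2),
                     path, progress = FALSE)
    manifest[[sid]] <- tibble::tibble(patient_id = seg$patient_id[1],
                                      sample_id = sid, path = path)
  }
  readr::write_tsv(dplyr::bind_rows(manifest),
                   file.path(dir, "cns_manifest.tsv"), progress = FALSE)
  beta_df <- tibble::as_tibble(sim$beta, rownames = "probe_id")
  readr::write_csv(beta_df, file.path(dir, "beta.csv"), progress = FALSE)
  readr::write_tsv(sim$sample_meta, file.path(dir, "sample_meta.tsv"),
                   progress = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
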