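# Methylation distances: beta-matrix QC, variable-probe selection (cohort MAD
# and within-patient variance), and the L1 distance between sample pairs.

#' Read a beta-value matrix
#'
#' Probes as rows, samples as columns, first column the probe id. All
#' non-missing values must lie in \[0, 1\].
#'
#' @param path CSV/TSV path (delimiter inferred from extension).
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(raw[[1]])
  validate_beta(m)
  m
}

validate_beta <- function(m) {
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop_spatgeno("probe and sample ids must be unique",
                  class = "spatgeno_invalid_input")
  }
  vals <- m[!is.na(m)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    stop_spatgeno("beta values must lie in [0, 1]",
                  class = "spatgeno_invalid_input")
  }
  invisible(m)
}

#' Compute beta values from intensity pairs
#'
#' \eqn{\beta = M / (M + U)}: methylated signal over total signal.
#'
#' @param meth,unmeth Non-negative intensity matrices of identical shape.
#' @return Beta matrix; cells with zero total signal are `NA`.
#' @export
beta_from_intensities <- function(meth, unmeth) {
  if (!identical(dim(meth), dim(unmeth))) {
    stop_spatgeno("intensity matrices must have identical dimensions",
                  class = "spatgeno_invalid_input")
  }
  total <- meth + unmeth
  out <- ifelse(total > 0, meth / total, NA_real_)
  dimnames(out) <- dimnames(meth)
  out
}

#' Quality-filter a beta matrix
#'
#' First drops samples with more than `max_sample_missing` (default 10%) of
#' values missing, then drops probes with more than `max_probe_missing`
#' (default 3) missing values among the remaining samples. Both thresholds are
#' strict inequalities. Re-running on the result is a no-op.
#'
#' @param m Beta matrix (probes x samples).
#' @param max_sample_missing Maximum tolerated missing fraction per sample.
#' @param max_probe_missing Maximum tolerated missing count per probe.
#' @return The filtered matrix with a QC report in `attr(, "qc")`: dropped
#'   sample/probe ids and their missing fractions/counts.
#' @export
qc_filter <- function(m, max_sample_missing = 0.10, max_probe_missing = 3) {
  validate_beta(m)
  sample_missing <- colMeans(is.na(m))
  drop_samples <- sample_missing > max_sample_missing
  if (all(drop_samples)) {
    stop_spatgeno("all samples exceed the missingness threshold",
                  class = "spatgeno_invalid_input")
  }
  kept <- m[, !drop_samples, drop = FALSE]
  probe_missing <- rowSums(is.na(kept))
  drop_probes <- probe_missing > max_probe_missing
  out <- kept[!drop_probes, , drop = FALSE]
  attr(out, "qc") <- list(
    dropped_samples = tibble::tibble(sample_id = colnames(m)[drop_samples],
                                     missing_fraction = unname(sample_missing[drop_samples])),
    dropped_probes = tibble::tibble(probe_id = rownames(kept)[drop_probes],
                                    n_missing = unname(probe_missing[drop_probes])),
    n_samples_kept = ncol(out), n_probes_kept = nrow(out)
  )
  out
}

#' Select the probes with highest median absolute deviation
#'
#' Ranks probes by the MAD of their beta values across all samples,
#' `median(|beta - median(beta)|)` (unscaled), after removing probes with any
#' missing value. Ties break lexicographically by probe id.
#'
#' @param m Beta matrix (probes x samples).
#' @param k Number of probes to return (commonly 200 or 500).
#' @return Character vector of `k` probe ids, highest MAD first.
#' @export
select_top_mad_probes <- function(m, k) {
  validate_beta(m)
  complete <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  if (k > nrow(complete)) {
    stop_spatgeno(sprintf("k = %d exceeds the %d probes with complete data",
                          k, nrow(complete)),
                  class = "spatgeno_invalid_input")
  }
  mads <- apply(complete, 1, stats::mad, constant = 1)
  ord <- order(-mads, rownames(complete))
  rownames(complete)[ord][seq_len(k)]
}

#' Select the most variable probes within one patient
#'
#' Ranks probes by the sample variance of beta across one patient's samples
#' (unbiased, n-1 denominator by default), over probes complete within the
#' patient. If fewer than `k` probes are eligible, all are returned with a
#' warning. Ties break lexicographically by probe id.
#'
#' @param m Beta matrix restricted to one patient's samples (>= 2 columns).
#' @param k Number of probes (default 500).
#' @param unbiased Use the n-1 denominator (default TRUE); FALSE divides by n.
#' @return Character vector of probe ids, highest variance first.
#' @export
select_top_variance_probes <- function(m, k = 500, unbiased = TRUE) {
  validate_beta(m)
  if (ncol(m) < 2) {
    stop_spatgeno("variance probe selection needs >= 2 samples",
                  class = "spatgeno_invalid_input")
  }
  complete <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  v <- apply(complete, 1, stats::var)
  if (!unbiased) v <- v * (ncol(m) - 1) / ncol(m)
  ord <- order(-v, rownames(complete))
  if (k > length(v)) {
    rlang::warn(sprintf("only %d eligible probes (< k = %d); returning all",
                        length(v), k))
    k <- length(v)
  }
  rownames(complete)[ord][seq_len(k)]
}

#' L1 distance between beta-value vectors
#'
#' \eqn{d = \sum_i |P_i - Q_i|}: the total variation in methylation level over
#' the selected probes. Bounded by the vector length.
#'
#' @param p,q Numeric vectors of equal length with entries in \[0, 1\].
#' @return Non-negative distance.
#' @export
l1_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop_spatgeno("l1_distance(): vectors differ in length",
                  class = "spatgeno_invalid_input")
  }
  sum(abs(p - q))
}

#' Pairwise methylation distances per patient
#'
#' For each patient with >= 2 post-QC samples, selects the top-`k` most
#' variable probes within that patient and computes the L1 distance between
#' every sample pair. Probe selection is per patient, so distances are
#' comparable across patients only through the common `k`.
#'
#' @param m QC-filtered beta matrix.
#' @param sample_meta Tibble mapping `sample_id` to `patient_id` (extra
#'   columns such as an IDH label are ignored here).
#' @param k Probes per patient (default 500).
#' @param unbiased Variance denominator choice, see
#'   [select_top_variance_probes()].
#' @return Tibble `patient_id, sample_a, sample_b, l1_distance,
#'   n_probes_used`.
#' @export
methylation_pair_distances <- function(m, sample_meta, k = 500, unbiased = TRUE) {
  validate_beta(m)
  meta <- sample_meta[sample_meta$sample_id %in% colnames(m), ]
  out <- list()
  for (pid in unique(meta$patient_id)) {
    ids <- meta$sample_id[meta$patient_id == pid]
    if (length(ids) < 2) next
    sub <- m[, ids, drop = FALSE]
    probes <- suppressWarnings(select_top_variance_probes(sub, k, unbiased))
    sel <- sub[probes, , drop = FALSE]
    combos <- utils::combn(ids, 2)
    rows <- apply(combos, 2, function(pr) {
      cp <- canonical_pair(pr[1], pr[2])
      tibble::tibble(patient_id = pid, sample_a = cp$a, sample_b = cp$b,
                     l1_distance = l1_distance(sel[, pr[1]], sel[, pr[2]]),
                     n_probes_used = length(probes))
    })
    out[[pid]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(patient_id = character(), sample_a = character(),
                          sample_b = character(), l1_distance = double(),
                          n_probes_used = integer())
  }
  res
}
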