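# Spatial-genomic association: pooled Pearson correlation, OLS best-fit line,
# and the derived per-10-mm / mm-per-unit equivalence constants.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between pooled Euclidean and genomic distances;
#' the p-value comes from the t transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}
#' on n-2 degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop_spatgeno("pearson_correlation(): vectors differ in length",
                  class = "spatgeno_invalid_input")
  }
  if (length(x) < 3) {
    stop_spatgeno("pearson_correlation(): need n >= 3 for a defined p-value",
                  class = "spatgeno_invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_spatgeno("degenerate input: zero variance", class = "spatgeno_invalid_input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ordinary least-squares fit of genomic on Euclidean distance
#'
#' @param x Euclidean distances (mm); at least two distinct values.
#' @param y Genomic distances.
#' @return List with `slope` (genomic units per mm), `intercept`
#'   (genomic units), `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_spatgeno("ols_fit(): need equal-length vectors with n >= 2",
                  class = "spatgeno_invalid_input")
  }
  if (length(unique(x)) < 2) {
    stop_spatgeno("ols_fit(): constant x, slope undefined",
                  class = "spatgeno_invalid_input")
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # suppress the "essentially perfect fit" warning for noiseless inputs
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(slope = unname(co[2]), intercept = unname(co[1]), n = length(x),
       slope_se = se)
}

#' Spatial-equivalence constants from a fitted slope
#'
#' `per_10mm = 10 * slope` is the expected increase in genomic distance over
#' 10 mm of additional physical separation; `mm_per_unit = 1 / slope` is the
#' physical separation equivalent to one genomic-distance unit.
#'
#' @param slope Fitted slope (genomic units per mm) or the list returned by
#'   [ols_fit()].
#' @param digits Decimal places for the rounded values (default 1; `NA` keeps
#'   raw values).
#' @return List with raw `per_10mm` and `mm_per_unit` plus rounded
#'   `per_10mm_rounded`, `mm_per_unit_rounded`. A zero slope yields
#'   `mm_per_unit = NA` (undefined).
#' @export
derived_equivalences <- function(slope, digits = 1) {
  if (is.list(slope)) slope <- slope$slope
  assert_scalar_number(slope, "slope")
  per_10mm <- 10 * slope
  mm_per_unit <- if (slope == 0) NA_real_ else 1 / slope
  rnd <- function(v) if (is.na(digits)) v else round(v, digits)
  list(per_10mm = per_10mm, mm_per_unit = mm_per_unit,
       per_10mm_rounded = rnd(per_10mm), mm_per_unit_rounded = rnd(mm_per_unit))
}

#' Join spatial pairs with per-modality genomic distances
#'
#' Inner join on (patient_id, sample_a, sample_b) between the pair table and
#' each supplied distance table; unmatched rows are dropped and counted in
#' `attr(, "n_unmatched")`. Optional per-sample stratification labels (e.g.
#' IDH status) are carried through when `sample_meta` provides them.
#'
#' @param pairs Pair table from [enumerate_pairs()].
#' @param mutation,cnv,methylation Optional distance tables from
#'   [mutation_pair_distances()], [cnv_pair_distances()],
#'   [methylation_pair_distances()].
#' @param mutation_measure Which mutation column feeds the association:
#'   `"count"` (union minus shared, the mutation-count genetic distance;
#'   default) or `"jaccard"`.
#' @param sample_meta Optional tibble `sample_id, patient_id[, idh_status,
#'   codeletion_1p19q]` for subgroup labels.
#' @param exclude_same_site_forceps Drop same-location forceps shallow/deep
#'   pairs (default FALSE).
#' @return Tibble `patient_id, sample_a, sample_b, euclidean_mm, pair_kind,
#'   modality, genomic_distance[, subgroup columns]`.
#' @export
assemble_records <- function(pairs, mutation = NULL, cnv = NULL,
                             methylation = NULL,
                             mutation_measure = c("count", "jaccard"),
                             sample_meta = NULL,
                             exclude_same_site_forceps = FALSE) {
  mutation_measure <- match.arg(mutation_measure)
  if (exclude_same_site_forceps) {
    pairs <- pairs[pairs$pair_kind != "same_site_forceps", ]
  }
  keys <- c("patient_id", "sample_a", "sample_b")
  if (anyDuplicated(pairs[, keys])) {
    stop_spatgeno("duplicate pair keys in pair table",
                  class = "spatgeno_invalid_input")
  }
  n_unmatched <- 0L
  one <- function(tab, modality, col) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    if (anyDuplicated(tab[, keys])) {
      stop_spatgeno(sprintf("duplicate pair keys in %s distance table", modality),
                    class = "spatgeno_invalid_input")
    }
    joined <- dplyr::inner_join(pairs, tab, by = keys)
    n_unmatched <<- n_unmatched + (nrow(tab) - nrow(joined)) +
      (nrow(pairs) - nrow(joined))
    tibble::tibble(patient_id = joined$patient_id, sample_a = joined$sample_a,
                   sample_b = joined$sample_b,
                   euclidean_mm = joined$euclidean_mm,
                   pair_kind = joined$pair_kind, modality = modality,
                   genomic_distance = joined[[col]])
  }
  mut_col <- if (mutation_measure == "count") "count_distance" else "jaccard_distance"
  records <- dplyr::bind_rows(
    one(mutation, "mutation", mut_col),
    one(cnv, "cnv", "canberra_distance"),
    one(methylation, "methylation", "l1_distance")
  )
  if (is.null(records) || nrow(records) == 0) {
    records <- tibble::tibble(patient_id = character(), sample_a = character(),
                              sample_b = character(), euclidean_mm = double(),
                              pair_kind = character(), modality = character(),
                              genomic_distance = double())
  }
  if (!is.null(sample_meta)) {
    for (col in intersect(c("idh_status", "codeletion_1p19q"), names(sample_meta))) {
      a <- sample_meta[[col]][match(records$sample_a, sample_meta$sample_id)]
      b <- sample_meta[[col]][match(records$sample_b, sample_meta$sample_id)]
      records[[paste0(col, "_concordant")]] <- !is.na(a) & !is.na(b) & a == b
      records[[paste0(col, "_pair")]] <- ifelse(!is.na(a) & !is.na(b) & a == b,
                                                a, NA_character_)
    }
  }
  attr(records, "n_unmatched") <- n_unmatched
  records
}

#' Quantify the spatial-genomic relationship per modality
#'
#' Pools all intra-patient pairs of each modality and reports Pearson r with
#' two-sided p, the OLS best-fit line, and the derived equivalence constants.
#' Pairs within one patient are not statistically independent; the pooled
#' analysis treats them as such (documented caveat), and an optional
#' within-patient permutation p-value is available as a robustness extension.
#'
#' @param records Record tibble from [assemble_records()].
#' @param digits Rounding for reported equivalences (default 1).
#' @param permutation Also compute a permutation p-value for r obtained by
#'   shuffling genomic distances within patients (default FALSE).
#' @param n_perm Number of permutations (default 999).
#' @return Named list (one element per modality present) of association
#'   results: `modality, n_pairs, pearson_r, p_value, slope, intercept,
#'   per_10mm, mm_per_unit, per_10mm_rounded, mm_per_unit_rounded`
#'   (+ `perm_p_value`); modalities with fewer than 3 pairs yield
#'   `insufficient_n = TRUE` with null statistics.
#' @export
associate <- function(records, digits = 1, permutation = FALSE, n_perm = 999) {
  out <- list()
  for (mod in unique(records$modality)) {
    rec <- records[records$modality == mod, ]
    if (nrow(rec) < 3 || length(unique(rec$euclidean_mm)) < 2 ||
        stats::sd(rec$genomic_distance) == 0) {
      out[[mod]] <- list(modality = mod, n_pairs = nrow(rec),
                         insufficient_n = TRUE,
                         pearson_r = NA_real_, p_value = NA_real_,
                         slope = NA_real_, intercept = NA_real_,
                         per_10mm = NA_real_, mm_per_unit = NA_real_)
      next
    }
    pc <- pearson_correlation(rec$euclidean_mm, rec$genomic_distance)
    fit <- ols_fit(rec$euclidean_mm, rec$genomic_distance)
    eq <- derived_equivalences(fit$slope, digits)
    res <- list(modality = mod, n_pairs = nrow(rec), insufficient_n = FALSE,
                pearson_r = pc$r, p_value = pc$p_value,
                slope = fit$slope, intercept = fit$intercept,
                slope_se = fit$slope_se,
                per_10mm = eq$per_10mm, mm_per_unit = eq$mm_per_unit,
                per_10mm_rounded = eq$per_10mm_rounded,
                mm_per_unit_rounded = eq$mm_per_unit_rounded)
    if (permutation) {
      obs <- abs(pc$r)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        shuffled <- stats::ave(rec$genomic_distance, rec$patient_id,
                               FUN = function(v) v[sample.int(length(v))])
        if (abs(stats::cor(rec$euclidean_mm, shuffled)) >= obs - 1e-12) {
          hits <- hits + 1L
        }
      }
      res$perm_p_value <- (hits + 1) / (n_perm + 1)
    }
    out[[mod]] <- res
  }
  out
}
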