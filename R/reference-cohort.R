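# Reference cohort layout: 23 glioma patients, 66 methylation-evaluable
# samples, 77 intra-patient biopsy pairs. Used for cohort accounting checks.

#' Reference 23-patient cohort layout
#'
#' Builds a site table with the per-patient sample counts of the multiregion
#' glioma cohort the package's synthetic defaults emulate: 23 patients, 66
#' samples, yielding 77 unique intra-patient biopsy pairs. Coordinates are
#' synthetic placeholders (the study coordinates are not public); they only
#' serve pair enumeration and distance plumbing, not reproduction of the
#' published distances.
#'
#' @return Site tibble in the [read_coordinates()] schema.
#' @export
reference_cohort_sites <- function() {
  # samples contributing pairs, per patient (patient 4 has one sample excluded
  # upstream by quality control, hence 5 effective of 6 collected)
  n_samples <- c(3L, 2L, 2L, 5L, 4L, 2L, 4L, 4L, 4L, 3L, 2L, 3L,
                 2L, 6L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 4L)
  rows <- list()
  for (p in seq_along(n_samples)) {
    pid <- sprintf("P%02d", p)
    for (s in seq_len(n_samples[p])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, sample_id = sprintf("%sS%d", pid, s),
        x = 7 * s, y = 3 * (s %% 2), z = 0,
        instrument = "needle", depth_label = "whole",
        source_site_id = sprintf("%s_T%d", pid, s))
    }
  }
  sites <- dplyr::bind_rows(rows)
  sites$has_coordinates <- TRUE
  sites
}
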