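# Biopsy cohort geometry: site tables, Euclidean distances, intra-patient
# pair enumeration with the shallow/deep needle-split convention.

#' Euclidean distance between two biopsy coordinates
#'
#' Straight-line distance in millimetres between two 3D stereotactic
#' coordinates \eqn{d_{ij} = \sqrt{(x_i-x_j)^2 + (y_i-y_j)^2 + (z_i-z_j)^2}}.
#'
#' @param a,b Numeric vectors of length 3 (x, y, z) in mm.
#' @return Distance in mm (non-negative scalar).
#' @examples
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != 3L || length(b) != 3L) {
    stop_spatgeno("coordinates must be length-3 (x, y, z) vectors",
                  class = "spatgeno_invalid_input")
  }
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop_spatgeno("non-finite coordinate in euclidean_distance()",
                  class = "spatgeno_invalid_input")
  }
  sqrt(sum((a - b)^2))
}

#' Read a biopsy coordinate table
#'
#' Reads a delimited table of biopsy sites (one row per physical sample).
#' Mandatory columns: patient, sample, x, y, z; optional: instrument
#' (`needle`/`forceps`), depth label (`shallow`/`deep`/`whole`) and the id of
#' the physical needle track shared by a shallow/deep split. Rows whose
#' coordinate triple is incomplete are kept but flagged
#' (`has_coordinates = FALSE`) and excluded from coordinate-based pairs.
#'
#' @param path Path to a TSV/CSV file (delimiter inferred from extension;
#'   `.csv` means comma, anything else tab).
#' @param col_map Named character vector overriding default column names, e.g.
#'   `c(x = "coord_x")`. Defaults:
#'   `patient_id, sample_id, x_mm, y_mm, z_mm, instrument, depth_label,
#'   source_site_id`.
#' @return A tibble of biopsy sites with columns `patient_id, sample_id, x, y,
#'   z, instrument, depth_label, source_site_id, has_coordinates`.
#' @export
read_coordinates <- function(path, col_map = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  defaults <- c(patient_id = "patient_id", sample_id = "sample_id",
                x = "x_mm", y = "y_mm", z = "z_mm",
                instrument = "instrument", depth_label = "depth_label",
                source_site_id = "source_site_id")
  if (!is.null(col_map)) defaults[names(col_map)] <- col_map
  for (key in c("patient_id", "sample_id", "x", "y", "z")) {
    if (!defaults[[key]] %in% names(raw)) {
      stop_spatgeno(sprintf("mandatory column `%s` missing from %s",
                            defaults[[key]], path),
                    class = "spatgeno_parse_error")
    }
  }
  parse_num <- function(col) {
    v <- raw[[defaults[[col]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad)) {
      stop_spatgeno(sprintf("unparsable numeric value '%s' in column `%s`, row %d",
                            v[bad[1]], defaults[[col]], bad[1]),
                    class = "spatgeno_parse_error")
    }
    out
  }
  opt <- function(col, fill) {
    nm <- defaults[[col]]
    if (nm %in% names(raw)) raw[[nm]] else rep(fill, nrow(raw))
  }
  sites <- tibble::tibble(
    patient_id = as.character(raw[[defaults[["patient_id"]]]]),
    sample_id = as.character(raw[[defaults[["sample_id"]]]]),
    x = parse_num("x"), y = parse_num("y"), z = parse_num("z"),
    instrument = as.character(opt("instrument", NA_character_)),
    depth_label = as.character(opt("depth_label", "whole")),
    source_site_id = as.character(opt("source_site_id", NA_character_))
  )
  sites$depth_label[is.na(sites$depth_label)] <- "whole"
  sites$has_coordinates <- is.finite(sites$x) & is.finite(sites$y) & is.finite(sites$z)
  validate_sites(sites)
  n_flagged <- sum(!sites$has_coordinates)
  if (n_flagged > 0) {
    rlang::inform(sprintf("%d site(s) lack a complete coordinate triple and are flagged",
                          n_flagged))
  }
  sites
}

validate_sites <- function(sites) {
  dup <- duplicated(sites[, c("patient_id", "sample_id")])
  if (any(dup)) {
    d <- sites[dup, ][1, ]
    stop_spatgeno(sprintf("duplicate sample_id `%s` within patient `%s`",
                          d$sample_id, d$patient_id),
                  class = "spatgeno_invalid_input")
  }
  bad_depth <- !sites$depth_label %in% c("shallow", "deep", "whole")
  if (any(bad_depth)) {
    stop_spatgeno(sprintf("unknown depth_label `%s` (expected shallow/deep/whole)",
                          sites$depth_label[bad_depth][1]),
                  class = "spatgeno_invalid_input")
  }
  invisible(sites)
}

#' Enumerate intra-patient biopsy pairs with distances
#'
#' Emits every unordered pair of distinct samples within each patient (never
#' across patients). Shallow/deep sub-samples of one needle track are assigned
#' the fixed needle-geometry offset (`shallow_deep_mm`, default 5 mm) instead
#' of a coordinate distance; shallow/deep forceps samples taken at one spatial
#' location get `same_site_forceps_mm` (default 0 mm, the only value consistent
#' with identical coordinates). All other pairs use the Euclidean distance of
#' their coordinates; samples lacking coordinates are excluded from
#' coordinate-based pairs and counted in the `excluded` attribute.
#'
#' @param sites Tibble of biopsy sites as returned by [read_coordinates()].
#' @param shallow_deep_mm Distance assigned to a needle shallow/deep split
#'   (mm, default 5).
#' @param same_site_forceps_mm Distance assigned to a same-location forceps
#'   shallow/deep pair (mm, default 0).
#' @return Tibble with columns `patient_id, sample_a, sample_b, euclidean_mm,
#'   pair_kind` (`coordinate`, `shallow_deep_needle`, `same_site_forceps`),
#'   sample ids canonically ordered within each pair. The number of
#'   coordinate-less samples skipped is stored in `attr(, "n_excluded")`.
#' @export
enumerate_pairs <- function(sites, shallow_deep_mm = 5, same_site_forceps_mm = 0) {
  assert_scalar_number(shallow_deep_mm, "shallow_deep_mm", min = 0)
  assert_scalar_number(same_site_forceps_mm, "same_site_forceps_mm", min = 0)
  if (!"has_coordinates" %in% names(sites)) {
    sites$has_coordinates <- is.finite(sites$x) & is.finite(sites$y) & is.finite(sites$z)
  }
  if (!"source_site_id" %in% names(sites)) sites$source_site_id <- NA_character_
  if (!"instrument" %in% names(sites)) sites$instrument <- NA_character_
  if (!"depth_label" %in% names(sites)) sites$depth_label <- "whole"
  validate_sites(sites)

  out <- vector("list", length(unique(sites$patient_id)))
  n_excluded <- 0L
  for (pi in seq_along(out)) {
    pid <- unique(sites$patient_id)[pi]
    ps <- sites[sites$patient_id == pid, ]
    n <- nrow(ps)
    if (n < 2) next
    rows <- list()
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        a <- ps[i, ]; b <- ps[j, ]
        split_pair <- !is.na(a$source_site_id) && !is.na(b$source_site_id) &&
          a$source_site_id == b$source_site_id &&
          a$depth_label != b$depth_label &&
          all(c(a$depth_label, b$depth_label) %in% c("shallow", "deep"))
        if (split_pair) {
          forceps <- identical(a$instrument, "forceps") && identical(b$instrument, "forceps")
          d <- if (forceps) same_site_forceps_mm else shallow_deep_mm
          kind <- if (forceps) "same_site_forceps" else "shallow_deep_needle"
        } else {
          if (!a$has_coordinates || !b$has_coordinates) {
            n_excluded <- n_excluded + 1L
            next
          }
          d <- euclidean_distance(c(a$x, a$y, a$z), c(b$x, b$y, b$z))
          kind <- "coordinate"
        }
        cp <- canonical_pair(a$sample_id, b$sample_id)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = pid, sample_a = cp$a, sample_b = cp$b,
          euclidean_mm = d, pair_kind = kind)
      }
    }
    if (length(rows)) out[[pi]] <- dplyr::bind_rows(rows)
  }
  pairs <- dplyr::bind_rows(out)
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(patient_id = character(), sample_a = character(),
                            sample_b = character(), euclidean_mm = double(),
                            pair_kind = character())
  }
  attr(pairs, "n_excluded") <- n_excluded
  pairs
}

#' Write a pair table to TSV
#' @param pairs Tibble from [enumerate_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}
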