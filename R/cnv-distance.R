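# Copy-number distances: breakpoint union across a patient's samples, the
# event-by-sample log2 matrix, and the Canberra distance between sample pairs.

#' Read a CNVkit-style segment file
#'
#' Accepts a `.cns`-style TSV with at least columns `chromosome, start, end,
#' log2` (extra columns ignored). Coordinates are 0-based half-open.
#'
#' @param path Segment TSV path.
#' @param patient_id,sample_id Identifiers attached to every segment.
#' @return Tibble `patient_id, sample_id, chrom, start, end, log2`.
#' @export
read_cns <- function(path, patient_id, sample_id) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("chromosome", "start", "end", "log2")
  missing <- setdiff(needed, names(seg))
  if (length(missing)) {
    stop_spatgeno(sprintf("segment file %s lacks column(s): %s",
                          path, paste(missing, collapse = ", ")),
                  class = "spatgeno_parse_error")
  }
  out <- tibble::tibble(patient_id = patient_id, sample_id = sample_id,
                        chrom = as.character(seg$chromosome),
                        start = as.numeric(seg$start), end = as.numeric(seg$end),
                        log2 = as.numeric(seg$log2))
  validate_segments(out)
  out
}

validate_segments <- function(segments) {
  if (any(segments$start >= segments$end)) {
    bad <- segments[segments$start >= segments$end, ][1, ]
    stop_spatgeno(sprintf("segment with start >= end: %s:%s-%s (sample %s)",
                          bad$chrom, bad$start, bad$end, bad$sample_id),
                  class = "spatgeno_invalid_input")
  }
  if (any(!is.finite(segments$log2))) {
    stop_spatgeno("non-finite log2 ratio in segments",
                  class = "spatgeno_invalid_input")
  }
  # non-overlap within each (sample, chromosome)
  key <- paste(segments$sample_id, segments$chrom)
  for (k in unique(key)) {
    s <- segments[key == k, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      i <- which(s$start[-1] < s$end[-nrow(s)])[1]
      stop_spatgeno(sprintf(
        "overlapping segments in sample %s on %s near [%s, %s)",
        s$sample_id[1], s$chrom[1], s$start[i + 1], s$end[i]),
        class = "spatgeno_invalid_input")
    }
  }
  invisible(segments)
}

#' Union of segment breakpoints across samples
#'
#' Per chromosome, the sorted union of every sample's start/end positions
#' defines maximal intervals; the returned events are those intervals covered
#' by at least one sample's segmentation. No event straddles any input
#' breakpoint, so each event inherits a unique log2 value from any covering
#' segment.
#'
#' @param segments Tibble of one patient's segments (see [read_cns()]);
#'   samples may also span several patients when a cohort-wide event list is
#'   wanted (`per_patient = FALSE` semantics are up to the caller).
#' @param drop_sex_chroms Drop chrX/chrY (and X/Y) events (default FALSE).
#' @return Tibble `chrom, start, end` sorted by (chrom, start).
#' @export
union_breakpoints <- function(segments, drop_sex_chroms = FALSE) {
  validate_segments(segments)
  if (drop_sex_chroms) {
    segments <- segments[!segments$chrom %in% c("chrX", "chrY", "X", "Y"), ]
  }
  out <- lapply(split(segments, segments$chrom), function(s) {
    bp <- sort(unique(c(s$start, s$end)))
    if (length(bp) < 2) return(NULL)
    ev <- tibble::tibble(chrom = s$chrom[1], start = bp[-length(bp)], end = bp[-1])
    covered <- rep(FALSE, nrow(ev))
    for (sid in unique(s$sample_id)) {
      seg <- s[s$sample_id == sid, ]
      seg <- seg[order(seg$start), ]
      idx <- findInterval(ev$start, seg$start)
      hit <- idx > 0 & seg$end[pmax(idx, 1)] >= ev$end
      covered <- covered | hit
    }
    ev[covered, ]
  })
  events <- dplyr::bind_rows(out)
  if (nrow(events) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  events[order(events$chrom, events$start), ]
}

#' Event-by-sample log2 matrix
#'
#' Assigns each (event, sample) cell the log2 ratio of the unique segment of
#' that sample containing the event; cells with no covering segment are marked
#' absent in the `present` mask (no interpolation or imputation).
#'
#' @param events Event tibble from [union_breakpoints()].
#' @param segments The same segments the events were derived from.
#' @return Object of class `cnv_event_matrix`: list with `events`, `log2`
#'   (events x samples matrix), `present` (logical mask), `patient_id`.
#' @export
build_event_matrix <- function(events, segments) {
  samples <- sort(unique(segments$sample_id))
  n_e <- nrow(events)
  log2m <- matrix(NA_real_, nrow = n_e, ncol = length(samples),
                  dimnames = list(paste0(events$chrom, ":", events$start, "-",
                                         events$end), samples))
  for (s in samples) {
    seg_all <- segments[segments$sample_id == s, ]
    for (ch in unique(events$chrom)) {
      ei <- which(events$chrom == ch)
      seg <- seg_all[seg_all$chrom == ch, ]
      if (nrow(seg) == 0 || length(ei) == 0) next
      seg <- seg[order(seg$start), ]
      idx <- findInterval(events$start[ei], seg$start)
      full <- idx > 0 & seg$end[pmax(idx, 1)] >= events$end[ei]
      partial <- idx > 0 & !full & seg$end[pmax(idx, 1)] > events$start[ei]
      if (any(partial)) {
        stop_spatgeno(sprintf("event %s partially covered in sample %s",
                              rownames(log2m)[ei][partial][1], s),
                      class = "spatgeno_internal_error")
      }
      log2m[ei[full], s] <- seg$log2[idx[full]]
    }
  }
  structure(list(events = events, log2 = log2m, present = !is.na(log2m),
                 patient_id = unique(segments$patient_id)[1]),
            class = "cnv_event_matrix")
}

#' Canberra distance between log2 copy-ratio vectors
#'
#' \deqn{d = \sum_i |P_i - Q_i| / (|P_i| + |Q_i|)} over the events present in
#' both samples, with a term defined as 0 when \eqn{|P_i| + |Q_i| = 0} (both
#' ratios exactly neutral), so the distance between a sample and itself is 0.
#' Each term lies in \[0, 1\], so the total is bounded by the number of shared
#' events. Note the denominator uses absolute values: log2 ratios are signed,
#' and the magnitude sum is the standard Canberra form that keeps every term
#' non-negative (for non-negative inputs it coincides with \eqn{P_i + Q_i}).
#'
#' @param p,q Numeric vectors of equal length.
#' @param mask Optional logical vector marking events present in both samples
#'   (default all TRUE).
#' @return Non-negative distance.
#' @export
canberra_distance <- function(p, q, mask = NULL) {
  if (length(p) != length(q)) {
    stop_spatgeno("canberra_distance(): vectors differ in length",
                  class = "spatgeno_invalid_input")
  }
  mask <- mask %||% rep(TRUE, length(p))
  if (length(mask) != length(p)) {
    stop_spatgeno("canberra_distance(): mask length mismatch",
                  class = "spatgeno_invalid_input")
  }
  p <- p[mask]; q <- q[mask]
  denom <- abs(p) + abs(q)
  terms <- ifelse(denom == 0, 0, abs(p - q) / denom)
  sum(terms)
}

#' Pairwise CNV distances for one patient
#'
#' @param em A `cnv_event_matrix` from [build_event_matrix()].
#' @param impute_neutral Treat events missing from a sample's segmentation as
#'   neutral (log2 = 0) instead of excluding them pairwise (default FALSE).
#' @return Tibble `patient_id, sample_a, sample_b, canberra_distance,
#'   n_events_shared`.
#' @export
cnv_pair_distances <- function(em, impute_neutral = FALSE) {
  stopifnot(inherits(em, "cnv_event_matrix"))
  samples <- colnames(em$log2)
  if (length(samples) < 2) {
    return(tibble::tibble(patient_id = character(), sample_a = character(),
                          sample_b = character(), canberra_distance = double(),
                          n_events_shared = integer()))
  }
  log2m <- em$log2
  present <- em$present
  if (impute_neutral) {
    log2m[!present] <- 0
    present[] <- TRUE
  }
  combos <- utils::combn(samples, 2)
  rows <- apply(combos, 2, function(pr) {
    mask <- present[, pr[1]] & present[, pr[2]]
    cp <- canonical_pair(pr[1], pr[2])
    tibble::tibble(patient_id = em$patient_id, sample_a = cp$a, sample_b = cp$b,
                   canberra_distance = canberra_distance(log2m[, pr[1]],
                                                         log2m[, pr[2]], mask),
                   n_events_shared = as.integer(sum(mask)))
  })
  dplyr::bind_rows(rows)
}
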