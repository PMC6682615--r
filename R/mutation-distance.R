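# Somatic mutation distances: five-criteria variant filtering, per-patient
# allele-frequency matrices, the continuous Jaccard (Tanimoto) distance,
# hypermutation flagging and a shared/private mutation sharing tree.

#' Variant filter configuration
#'
#' The five retention criteria applied to annotated somatic calls:
#' (1) located in an allowed region class (default exonic only);
#' (2) function class among the protein-altering set (frameshift
#' insertion/deletion, nonsynonymous SNV, stopgain, stoploss);
#' (3) reference read count at least `min_ref_reads` (default 10);
#' (4) alternate read count at least `min_alt_reads` (default 8);
#' (5) alternate read frequency at least `min_alt_freq` (default 0.1).
#'
#' @param allowed_regions Character vector of allowed `region_class` values.
#' @param allowed_functions Character vector of allowed `func_class` values.
#' @param min_ref_reads,min_alt_reads Non-negative integer thresholds.
#' @param min_alt_freq Minimum alternate allele frequency in \[0, 1\].
#' @return A list of class `mutation_filter_config`.
#' @export
mutation_filter_config <- function(allowed_regions = "exonic",
                                   allowed_functions = c("frameshift deletion",
                                                         "frameshift insertion",
                                                         "nonsynonymous SNV",
                                                         "stopgain", "stoploss"),
                                   min_ref_reads = 10L,
                                   min_alt_reads = 8L,
                                   min_alt_freq = 0.1) {
  assert_scalar_number(min_ref_reads, "min_ref_reads", min = 0)
  assert_scalar_number(min_alt_reads, "min_alt_reads", min = 0)
  assert_scalar_number(min_alt_freq, "min_alt_freq", min = 0, max = 1)
  structure(list(allowed_regions = allowed_regions,
                 allowed_functions = allowed_functions,
                 min_ref_reads = min_ref_reads,
                 min_alt_reads = min_alt_reads,
                 min_alt_freq = min_alt_freq),
            class = "mutation_filter_config")
}

#' Read a long-format annotated variant table
#'
#' Expects columns `patient_id, sample_id, chrom, pos, ref, alt, region_class,
#' func_class, ref_reads, alt_reads` and optionally `gene` and `alt_freq`
#' (ANNOVAR-style region/function vocabulary). When `alt_freq` is absent it is
#' computed as `alt_reads / (ref_reads + alt_reads)`; when both are present and
#' disagree beyond 1e-6 the provided value wins with a warning.
#'
#' @param path TSV path (CSV accepted for `.csv` extension).
#' @return A tibble of variant calls.
#' @export
read_variant_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  calls <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  needed <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt",
              "region_class", "func_class", "ref_reads", "alt_reads")
  missing <- setdiff(needed, names(calls))
  if (length(missing)) {
    stop_spatgeno(sprintf("variant table %s lacks column(s): %s",
                          path, paste(missing, collapse = ", ")),
                  class = "spatgeno_parse_error")
  }
  if (!"gene" %in% names(calls)) calls$gene <- NA_character_
  normalize_calls(tibble::as_tibble(calls))
}

normalize_calls <- function(calls) {
  if (any(calls$pos < 1)) {
    stop_spatgeno("variant positions must be 1-based (pos >= 1)",
                  class = "spatgeno_invalid_input")
  }
  if (any(calls$ref == calls$alt)) {
    stop_spatgeno("ref and alt alleles must differ",
                  class = "spatgeno_invalid_input")
  }
  if (any(calls$ref_reads < 0) || any(calls$alt_reads < 0)) {
    stop_spatgeno("read counts must be non-negative",
                  class = "spatgeno_invalid_input")
  }
  depth <- calls$ref_reads + calls$alt_reads
  computed <- ifelse(depth > 0, calls$alt_reads / depth, NA_real_)
  if (!"alt_freq" %in% names(calls) || all(is.na(calls$alt_freq))) {
    calls$alt_freq <- computed
  } else {
    fill <- is.na(calls$alt_freq)
    calls$alt_freq[fill] <- computed[fill]
    clash <- !is.na(calls$alt_freq) & !is.na(computed) &
      abs(calls$alt_freq - computed) > 1e-6
    if (any(clash)) {
      rlang::warn(sprintf(
        "%d call(s) have alt_freq inconsistent with read counts; provided alt_freq kept",
        sum(clash)))
    }
  }
  calls
}

#' Filter variant calls by the five retention criteria
#'
#' Returns exactly the calls that pass all five criteria of `cfg`, preserving
#' input order. A per-criterion rejection tally is attached as
#' `attr(, "rejections")`.
#'
#' @param calls Variant-call tibble (see [read_variant_table()]).
#' @param cfg A [mutation_filter_config()].
#' @return Filtered tibble (possibly empty).
#' @export
filter_variants <- function(calls, cfg = mutation_filter_config()) {
  stopifnot(inherits(cfg, "mutation_filter_config"))
  calls <- normalize_calls(calls)
  af <- calls$alt_freq
  af[is.na(af)] <- -Inf
  pass <- cbind(
    region = calls$region_class %in% cfg$allowed_regions,
    func = calls$func_class %in% cfg$allowed_functions,
    ref_reads = calls$ref_reads >= cfg$min_ref_reads,
    alt_reads = calls$alt_reads >= cfg$min_alt_reads,
    alt_freq = af >= cfg$min_alt_freq
  )
  keep <- rowSums(pass) == ncol(pass)
  out <- calls[keep, , drop = FALSE]
  attr(out, "rejections") <- colSums(!pass)
  out
}

mutation_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Build a per-patient mutation-by-sample allele-frequency matrix
#'
#' Rows are the union over the patient's samples of mutation identities
#' (chrom:pos:ref:alt); columns are samples. Entries hold the alternate allele
#' frequency, 0 where a sample lacks the call.
#'
#' @param calls Filtered variant calls for a single patient.
#' @param sample_ids Optional character vector fixing the column set/order
#'   (samples with no calls get an all-zero column).
#' @return Numeric matrix with rownames = mutation keys, colnames = sample
#'   ids, and the patient id in `attr(, "patient_id")`.
#' @export
build_af_matrix <- function(calls, sample_ids = NULL) {
  pid <- unique(calls$patient_id)
  if (length(pid) > 1) {
    stop_spatgeno("build_af_matrix() expects calls from a single patient",
                  class = "spatgeno_invalid_input")
  }
  calls <- normalize_calls(calls)
  keys <- mutation_key(calls)
  dup <- duplicated(paste(keys, calls$sample_id))
  if (any(dup)) {
    stop_spatgeno(sprintf("duplicate call for mutation %s in sample %s",
                          keys[dup][1], calls$sample_id[dup][1]),
                  class = "spatgeno_invalid_input")
  }
  ukeys <- sort(unique(keys))
  usamples <- sample_ids %||% sort(unique(calls$sample_id))
  if (!all(calls$sample_id %in% usamples)) {
    stop_spatgeno("calls contain sample ids not listed in `sample_ids`",
                  class = "spatgeno_invalid_input")
  }
  af <- matrix(0, nrow = length(ukeys), ncol = length(usamples),
               dimnames = list(ukeys, usamples))
  af[cbind(match(keys, ukeys), match(calls$sample_id, usamples))] <- calls$alt_freq
  attr(af, "patient_id") <- if (length(pid)) pid else NA_character_
  af
}

#' Continuous Jaccard (Tanimoto) distance between allele-frequency vectors
#'
#' \deqn{d = \frac{\sum_i (P_i - Q_i)^2}{\sum_i P_i^2 + \sum_i Q_i^2 - \sum_i P_i Q_i}}
#'
#' Zero when the profiles are identical; one when the mutation supports are
#' disjoint (and at least one vector is nonzero). On binary vectors it reduces
#' to the set Jaccard distance \eqn{1 - |A \cap B| / |A \cup B|}. The
#' degenerate all-zero/all-zero case (0/0) is defined as 0 with a warning.
#'
#' @param p,q Numeric vectors of equal length with entries in \[0, 1\].
#' @return Distance in \[0, 1\].
#' @export
jaccard_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop_spatgeno("jaccard_distance(): vectors differ in length",
                  class = "spatgeno_invalid_input")
  }
  denom <- sum(p^2) + sum(q^2) - sum(p * q)
  if (denom == 0) {
    rlang::warn("both allele-frequency profiles are all-zero; distance defined as 0")
    return(0)
  }
  sum((p - q)^2) / denom
}

#' Pairwise mutation distances for one patient
#'
#' @param af Allele-frequency matrix from [build_af_matrix()].
#' @return Tibble `patient_id, sample_a, sample_b, jaccard_distance,
#'   count_distance, n_union_mutations, n_shared`. `count_distance` is the
#'   number of mutations private to one of the two samples
#'   (union minus shared), the mutation-count genetic distance used in the
#'   regression against physical distance.
#' @export
mutation_pair_distances <- function(af) {
  samples <- colnames(af)
  if (length(samples) < 2) {
    return(tibble::tibble(patient_id = character(), sample_a = character(),
                          sample_b = character(), jaccard_distance = double(),
                          count_distance = double(),
                          n_union_mutations = integer(), n_shared = integer()))
  }
  combos <- utils::combn(samples, 2)
  rows <- apply(combos, 2, function(pr) {
    p <- af[, pr[1]]; q <- af[, pr[2]]
    present_p <- p > 0; present_q <- q > 0
    n_union <- sum(present_p | present_q)
    n_shared <- sum(present_p & present_q)
    cp <- canonical_pair(pr[1], pr[2])
    tibble::tibble(patient_id = attr(af, "patient_id"),
                   sample_a = cp$a, sample_b = cp$b,
                   jaccard_distance = jaccard_distance(p, q),
                   count_distance = as.double(n_union - n_shared),
                   n_union_mutations = as.integer(n_union),
                   n_shared = as.integer(n_shared))
  })
  dplyr::bind_rows(rows)
}

#' Flag hypermutated samples
#'
#' A sample is flagged when its filtered mutation count exceeds
#' `max(absolute_threshold, fold_threshold * cohort median)`. Flags are
#' advisory: callers exclude flagged samples only via an explicit switch.
#' The literature-derived reference burden, `rate_per_mb * exome_mb`
#' (default 1/Mb over a 30 Mb exome = 30 mutations), is reported alongside.
#'
#' @param counts Named numeric vector of filtered mutation counts per sample.
#' @param absolute_threshold Absolute count floor for flagging (default 300).
#' @param fold_threshold Multiple of the cohort median (default 10).
#' @param rate_per_mb,exome_mb Background mutation rate and exome size for the
#'   reference burden.
#' @return List with `flags` (tibble `sample_id, n_mutations, flagged`),
#'   `cohort_median`, `threshold`, and `reference_count`.
#' @export
flag_hypermutation <- function(counts, absolute_threshold = 300,
                               fold_threshold = 10,
                               rate_per_mb = 1, exome_mb = 30) {
  med <- stats::median(counts)
  threshold <- max(absolute_threshold, fold_threshold * med)
  list(
    flags = tibble::tibble(sample_id = names(counts) %||% as.character(seq_along(counts)),
                           n_mutations = as.numeric(counts),
                           flagged = counts > threshold),
    cohort_median = med,
    threshold = threshold,
    reference_count = rate_per_mb * exome_mb
  )
}

#' Shared/private mutation structure as a rooted tree
#'
#' Partitions a patient's mutations by their presence pattern (alt frequency
#' > 0) across samples, then builds a tree rooted at "N" (normal tissue, zero
#' mutations): the pattern covering all samples forms the trunk; remaining
#' patterns attach greedily in order of decreasing size beneath the deepest
#' already-placed pattern that is a strict superset. Branch lengths equal the
#' number of mutations per pattern; every sample appears as a leaf (with a
#' zero-length private branch if it has no private mutations). Patterns that
#' overlap an already-placed sibling without nesting are attached to the
#' deepest compatible ancestor and listed in `incompatible`.
#'
#' @param af Allele-frequency matrix from [build_af_matrix()].
#' @return List with `patterns` (tibble `pattern, samples, n_mutations,
#'   mean_af`), `newick` (string with branch lengths), and `incompatible`
#'   (character vector of pattern labels that violated nesting).
#' @export
mutation_sharing_tree <- function(af) {
  if (nrow(af) == 0 || ncol(af) == 0) {
    stop_spatgeno("mutation_sharing_tree() requires a nonempty matrix",
                  class = "spatgeno_invalid_input")
  }
  samples <- colnames(af)
  presence <- af > 0
  pat_str <- apply(presence, 1, function(r) paste(samples[r], collapse = "+"))
  keep <- pat_str != ""
  pat_str <- pat_str[keep]
  af_kept <- af[keep, , drop = FALSE]
  patterns <- tibble::tibble(pattern = pat_str, af_mean = rowSums(af_kept) /
                               pmax(rowSums(presence[keep, , drop = FALSE]), 1)) |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(n_mutations = dplyr::n(), mean_af = mean(.data$af_mean),
                     .groups = "drop")
  pattern_sets <- lapply(strsplit(patterns$pattern, "+", fixed = TRUE), unique)
  patterns$samples <- vapply(pattern_sets, length, 1L)
  ord <- order(-patterns$samples, patterns$pattern)
  patterns <- patterns[ord, ]
  pattern_sets <- pattern_sets[ord]

  # Nodes: 1 = root N. Each placed pattern becomes an internal node (or leaf).
  nodes <- list(list(set = samples, parent = 0L, length = 0, label = "N"))
  incompatible <- character()
  for (k in seq_along(pattern_sets)) {
    set <- pattern_sets[[k]]
    # deepest placed node whose set is a superset of this pattern; on equal
    # set size the later (deeper) node wins, so equal patterns chain
    anc <- 1L
    anc_size <- length(samples) + 1L
    for (ni in seq_along(nodes)) {
      nset <- nodes[[ni]]$set
      if (all(set %in% nset) && length(nset) <= anc_size) {
        anc <- ni; anc_size <- length(nset)
      }
    }
    # flag overlap with a sibling already under the same ancestor
    for (ni in seq_along(nodes)) {
      if (nodes[[ni]]$parent == anc) {
        ov <- intersect(nodes[[ni]]$set, set)
        if (length(ov) > 0 && !all(set %in% nodes[[ni]]$set)) {
          incompatible <- c(incompatible, patterns$pattern[k])
        }
      }
    }
    nodes[[length(nodes) + 1L]] <- list(set = set, parent = anc,
                                        length = patterns$n_mutations[k],
                                        label = patterns$pattern[k])
  }
  # ensure every sample terminates in a singleton leaf (zero-length private
  # branch when the sample has no private mutations)
  for (s in samples) {
    anc <- 1L; anc_size <- length(samples) + 1L
    for (ni in seq_along(nodes)) {
      if (s %in% nodes[[ni]]$set && length(nodes[[ni]]$set) <= anc_size) {
        anc <- ni; anc_size <- length(nodes[[ni]]$set)
      }
    }
    if (length(nodes[[anc]]$set) > 1L) {
      nodes[[length(nodes) + 1L]] <- list(set = s, parent = anc,
                                          length = 0, label = s)
    }
  }
  newick_of <- function(ni) {
    children <- which(vapply(nodes, function(n) n$parent, 0L) == ni)
    node <- nodes[[ni]]
    lab <- if (ni == 1L) "N" else if (length(node$set) == 1L) node$set else ""
    body <- if (length(children)) {
      paste0("(", paste(vapply(children, newick_of, ""), collapse = ","), ")", lab)
    } else {
      lab
    }
    if (ni == 1L) paste0(body, ";") else paste0(body, ":", format(node$length))
  }
  patterns <- patterns[, c("pattern", "samples", "n_mutations", "mean_af")]
  list(patterns = patterns, newick = newick_of(1L),
       incompatible = unique(incompatible))
}
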