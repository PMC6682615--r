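# End-to-end orchestration: ingest -> pair enumeration -> per-modality
# distance tables -> association report, with file outputs and a provenance
# block.

#' Run configuration for the full pipeline
#'
#' @param coordinates Path to the biopsy coordinate table (required).
#' @param variants Optional path to a long-format variant table.
#' @param cns_manifest Optional path to a TSV `patient_id, sample_id, path`
#'   pointing at per-sample `.cns` segment files.
#' @param beta Optional path to a beta-value matrix (CSV/TSV).
#' @param sample_meta Optional path to a sample metadata TSV (`sample_id,
#'   patient_id[, idh_status, codeletion_1p19q]`); required with `beta`.
#' @param outdir Output directory.
#' @param shallow_deep_mm,same_site_forceps_mm Pairing distances, see
#'   [enumerate_pairs()].
#' @param exclude_same_site_forceps Drop same-location forceps pairs from the
#'   association (default FALSE).
#' @param filter_config A [mutation_filter_config()].
#' @param exclude_hypermutated Exclude samples flagged by
#'   [flag_hypermutation()] from mutation distances (default FALSE; flags are
#'   always reported).
#' @param impute_neutral,drop_sex_chroms CNV options, see
#'   [cnv_pair_distances()] and [union_breakpoints()].
#' @param k_probes Probes per patient for methylation distances (default 500).
#' @param mutation_measure `"count"` or `"jaccard"`, see [assemble_records()].
#' @param digits Rounding for reported equivalences.
#' @param permutation,n_perm Optional within-patient permutation p-value.
#' @param seed Seed recorded in provenance and used for the permutation
#'   extension.
#' @return A list of class `run_config`.
#' @export
run_config <- function(coordinates, variants = NULL, cns_manifest = NULL,
                       beta = NULL, sample_meta = NULL, outdir = tempfile("spatgeno_run_"),
                       shallow_deep_mm = 5, same_site_forceps_mm = 0,
                       exclude_same_site_forceps = FALSE,
                       filter_config = mutation_filter_config(),
                       exclude_hypermutated = FALSE,
                       impute_neutral = FALSE, drop_sex_chroms = FALSE,
                       k_probes = 500, mutation_measure = "count",
                       digits = 1, permutation = FALSE, n_perm = 999,
                       seed = 1L) {
  for (pth in c(coordinates, variants, cns_manifest, beta, sample_meta)) {
    if (!is.null(pth) && !file.exists(pth)) {
      stop_spatgeno(sprintf("input path does not exist: %s", pth),
                    class = "spatgeno_invalid_input")
    }
  }
  if (is.null(variants) && is.null(cns_manifest) && is.null(beta)) {
    stop_spatgeno("no molecular inputs: need at least one of variants, cns_manifest, beta",
                  class = "spatgeno_invalid_input")
  }
  assert_scalar_number(k_probes, "k_probes", min = 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full spatial-genomic distance pipeline
#'
#' Executes every stage for which inputs exist: pair enumeration, mutation /
#' CNV / methylation distance tables, pooled association per modality.
#' Writes `pairs.tsv`, `<modality>_distances.tsv`, `records.tsv`,
#' `association.json` (including a provenance block) and per-patient Newick
#' mutation trees under `outdir`. Modalities with fewer than 3 pairs yield
#' distances but a null association flagged `insufficient_n`.
#'
#' @param cfg A [run_config()].
#' @return The run report (invisibly written as JSON): list with `pairs`,
#'   per-modality distance tables, `records`, `association`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  sites <- read_coordinates(cfg$coordinates)
  pairs <- enumerate_pairs(sites, cfg$shallow_deep_mm, cfg$same_site_forceps_mm)
  log$n_sites <- nrow(sites)
  log$n_pairs <- nrow(pairs)
  log$n_pairs_excluded_no_coordinates <- attr(pairs, "n_excluded")
  single <- table(sites$patient_id)
  log$patients_single_sample <- names(single)[single < 2]
  write_pairs(pairs, file.path(cfg$outdir, "pairs.tsv"))

  mut_tab <- cnv_tab <- meth_tab <- NULL

  if (!is.null(cfg$variants)) {
    calls <- read_variant_table(cfg$variants)
    filtered <- filter_variants(calls, cfg$filter_config)
    log$mutation_rejections <- as.list(attr(filtered, "rejections"))
    counts_tbl <- table(factor(filtered$sample_id,
                               levels = unique(sites$sample_id)))
    counts <- as.numeric(counts_tbl)
    names(counts) <- names(counts_tbl)
    hyper <- flag_hypermutation(counts)
    log$hypermutation <- list(
      flagged = hyper$flags$sample_id[hyper$flags$flagged],
      cohort_median = hyper$cohort_median, threshold = hyper$threshold,
      reference_count = hyper$reference_count)
    bad <- character()
    if (cfg$exclude_hypermutated) {
      bad <- hyper$flags$sample_id[hyper$flags$flagged]
      filtered <- filtered[!filtered$sample_id %in% bad, ]
    }
    readr::write_tsv(filtered, file.path(cfg$outdir, "filtered_calls.tsv"),
                     progress = FALSE)
    tabs <- list()
    for (pid in unique(filtered$patient_id)) {
      pc <- filtered[filtered$patient_id == pid, ]
      samps <- setdiff(sort(unique(sites$sample_id[sites$patient_id == pid])),
                       bad)
      if (nrow(pc) == 0 || length(samps) == 0) next
      af <- build_af_matrix(pc, sample_ids = samps)
      tabs[[pid]] <- mutation_pair_distances(af)
      tree <- mutation_sharing_tree(af)
      writeLines(tree$newick,
                 file.path(cfg$outdir, sprintf("tree_%s.nwk", pid)))
    }
    mut_tab <- dplyr::bind_rows(tabs)
    readr::write_tsv(mut_tab, file.path(cfg$outdir, "mutation_distances.tsv"),
                     progress = FALSE)
  }

  if (!is.null(cfg$cns_manifest)) {
    manifest <- readr::read_tsv(cfg$cns_manifest, show_col_types = FALSE,
                                progress = FALSE)
    tabs <- list()
    for (pid in unique(manifest$patient_id)) {
      rows <- manifest[manifest$patient_id == pid, ]
      segs <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
        read_cns(rows$path[i], pid, rows$sample_id[i])
      }))
      events <- union_breakpoints(segs, drop_sex_chroms = cfg$drop_sex_chroms)
      em <- build_event_matrix(events, segs)
      tabs[[pid]] <- cnv_pair_distances(em, impute_neutral = cfg$impute_neutral)
    }
    cnv_tab <- dplyr::bind_rows(tabs)
    readr::write_tsv(cnv_tab, file.path(cfg$outdir, "cnv_distances.tsv"),
                     progress = FALSE)
  }

  meta <- NULL
  if (!is.null(cfg$sample_meta)) {
    meta <- readr::read_tsv(cfg$sample_meta, show_col_types = FALSE,
                            progress = FALSE)
  }
  if (!is.null(cfg$beta)) {
    if (is.null(meta)) {
      stop_spatgeno("beta matrix supplied without sample_meta",
                    class = "spatgeno_invalid_input")
    }
    m <- read_beta_matrix(cfg$beta)
    m <- qc_filter(m)
    log$methylation_qc <- attr(m, "qc")[c("n_samples_kept", "n_probes_kept")]
    log$methylation_dropped_samples <- attr(m, "qc")$dropped_samples$sample_id
    meth_tab <- methylation_pair_distances(m, meta, k = cfg$k_probes)
    readr::write_tsv(meth_tab,
                     file.path(cfg$outdir, "methylation_distances.tsv"),
                     progress = FALSE)
  }

  records <- assemble_records(pairs, mutation = mut_tab, cnv = cnv_tab,
                              methylation = meth_tab,
                              mutation_measure = cfg$mutation_measure,
                              sample_meta = meta,
                              exclude_same_site_forceps = cfg$exclude_same_site_forceps)
  log$n_records <- nrow(records)
  log$n_records_unmatched <- attr(records, "n_unmatched")
  readr::write_tsv(records, file.path(cfg$outdir, "records.tsv"),
                   progress = FALSE)

  set.seed(cfg$seed)
  assoc <- associate(records, digits = cfg$digits,
                     permutation = cfg$permutation, n_perm = cfg$n_perm)

  report <- list(
    schema_version = "1.0",
    provenance = list(package_version = as.character(utils::packageVersion("spatgeno")),
                      seed = cfg$seed,
                      timestamp = format(Sys.time(), tz = "UTC"),
                      inputs = cfg[c("coordinates", "variants", "cns_manifest",
                                     "beta", "sample_meta")]),
    association = assoc,
    log = log
  )
  jsonlite::write_json(report, file.path(cfg$outdir, "association.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(pairs = pairs, mutation = mut_tab, cnv = cnv_tab,
                 methylation = meth_tab, records = records,
                 association = assoc, log = log, outdir = cfg$outdir))
}
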