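# Optional VCF ingestion for single-sample annotated somatic calls.

#' Read variant calls from a single-sample VCF
#'
#' Accepts an uncompressed or bgzipped single-sample VCF with ANNOVAR-style
#' annotations in INFO (`Func.refGene` -> region class,
#' `ExonicFunc.refGene` -> function class, `Gene.refGene` -> gene) and
#' per-allele depths in the `AD` FORMAT field. Multi-allelic records must be
#' pre-split (one ALT per row); records with several ALT alleles are rejected.
#' Positions are 1-based (VCF convention). Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @param patient_id,sample_id Identifiers attached to every call.
#' @return Variant-call tibble compatible with [filter_variants()].
#' @export
read_variant_vcf <- function(path, patient_id, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_spatgeno("read_variant_vcf() requires the vcfR package",
                  class = "spatgeno_missing_dependency")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.null(dim(fix))) t(fix) else fix
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop_spatgeno("multi-allelic VCF records found; pre-split to one ALT per row",
                  class = "spatgeno_invalid_input")
  }
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) {
    stop_spatgeno("VCF lacks the AD (allelic depth) FORMAT field",
                  class = "spatgeno_parse_error")
  }
  ad_parts <- strsplit(ad[, 1], ",", fixed = TRUE)
  ref_reads <- vapply(ad_parts, function(p) as.integer(p[1]), 1L)
  alt_reads <- vapply(ad_parts, function(p) as.integer(p[2]), 1L)
  normalize_calls(tibble::tibble(
    patient_id = patient_id, sample_id = sample_id,
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt,
    gene = info_field("Gene.refGene"),
    region_class = info_field("Func.refGene"),
    func_class = info_field("ExonicFunc.refGene"),
    ref_reads = ref_reads, alt_reads = alt_reads))
}
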