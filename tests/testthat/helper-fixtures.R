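# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / closed forms) and never call the implementation they check.

toy_sites <- function() {
  tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    sample_id = c("P1S1", "P1S2", "P1S3", "P2S1", "P2S2"),
    x = c(0, 3, 1, 0, 0), y = c(0, 4, 2, 0, 3), z = c(0, 0, 3, 0, 4),
    instrument = "needle", depth_label = "whole",
    source_site_id = c("P1_T1", "P1_T2", "P1_T3", "P2_T1", "P2_T2"),
    has_coordinates = TRUE)
}

# One violation of each retention criterion plus clean calls.
toy_variant_table <- function() {
  clean <- tibble::tibble(
    patient_id = "P1", sample_id = "P1S1",
    chrom = "chr1", pos = 100L + 1:5, ref = "A", alt = "T",
    gene = paste0("G", 1:5), region_class = "exonic",
    func_class = "nonsynonymous SNV", ref_reads = 50L, alt_reads = 10L)
  viol <- clean[rep(1, 5), ]
  viol$pos <- 200L + 1:5
  viol$region_class[1] <- "intronic"
  viol$func_class[2] <- "synonymous SNV"
  viol$ref_reads[3] <- 5L; viol$alt_reads[3] <- 20L
  viol$ref_reads[4] <- 40L; viol$alt_reads[4] <- 5L
  viol$ref_reads[5] <- 92L; viol$alt_reads[5] <- 8L
  dplyr::bind_rows(clean, viol)
}

# Brute-force continuous Jaccard straight from its definition.
oracle_jaccard <- function(p, q) {
  num <- 0; sp <- 0; sq <- 0; spq <- 0
  for (i in seq_along(p)) {
    num <- num + (p[i] - q[i])^2
    sp <- sp + p[i]^2; sq <- sq + q[i]^2; spq <- spq + p[i] * q[i]
  }
  unname(if (sp + sq - spq == 0) 0 else num / (sp + sq - spq))
}

# Set Jaccard distance for binary vectors (empty/empty defined as 0).
oracle_set_jaccard <- function(a, b) {
  un <- sum(a | b)
  if (un == 0) 0 else 1 - sum(a & b) / un
}

# Term-by-term Canberra with magnitude denominators.
oracle_canberra <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    d <- abs(p[i]) + abs(q[i])
    if (d > 0) s <- s + abs(p[i] - q[i]) / d
  }
  s
}

# Closed-form normal equations and the t transform for Pearson's p.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- (sy - b * sx) / n
  c(intercept = a, slope = b)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  c(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Random valid per-sample segmentation of [0, L) with k breakpoints.
random_segmentation <- function(patient_id, sample_id, L = 1000, max_k = 6) {
  k <- sample(0:max_k, 1)
  bp <- sort(unique(c(0, L, sample(seq(10, L - 10, by = 10), k))))
  tibble::tibble(patient_id = patient_id, sample_id = sample_id, chrom = "chr1",
                 start = bp[-length(bp)], end = bp[-1],
                 log2 = round(stats::rnorm(length(bp) - 1, 0, 0.8), 3))
}
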