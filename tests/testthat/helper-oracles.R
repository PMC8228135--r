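# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately written as naive scalar code, separate from the
# package's vectorized implementations.

# build a genotype_dataset from a dosage matrix with minimal metadata
make_ds <- function(geno, positions = NULL, chromosome = "1",
                    groups = NULL, a1 = "A", a2 = "B") {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  chromosome <- rep_len(chromosome, m)
  if (is.null(groups)) groups <- rep("g1", nrow(geno))
  genotype_dataset(
    geno,
    markers = data.frame(marker_id = paste0("m", seq_len(m)),
                         chromosome = chromosome, position = positions,
                         a1 = rep_len(a1, m), a2 = rep_len(a2, m),
                         stringsAsFactors = FALSE),
    samples = data.frame(sample_id = paste0("s", seq_len(nrow(geno))),
                         group = groups, stringsAsFactors = FALSE))
}

# exhaustive ROH scan for a single sample on one chromosome: every maximal
# homozygous sub-run (split at het/missing and oversized gaps), filtered by
# the length / count / density rules
brute_force_roh <- function(genotypes, positions, min_length_bp, max_gap_bp,
                            min_snps, min_density_bp_per_snp) {
  m <- length(genotypes)
  hom <- !is.na(genotypes) & genotypes != 1L
  gap_ok <- c(diff(positions) <= max_gap_bp, TRUE)  # gap after SNP i fits
  runs <- list()
  for (s in seq_len(m)) for (e in s:m) {
    if (!all(hom[s:e])) next
    if (e > s && !all(gap_ok[s:(e - 1)])) next
    # maximality: cannot extend left or right
    if (s > 1 && hom[s - 1] && gap_ok[s - 1]) next
    if (e < m && hom[e + 1] && gap_ok[e]) next
    len <- positions[e] - positions[s] + 1
    n <- e - s + 1
    if (len >= min_length_bp && n >= min_snps &&
        len / n <= min_density_bp_per_snp)
      runs[[length(runs) + 1]] <- c(start = positions[s], end = positions[e],
                                    n_snps = n)
  }
  if (!length(runs)) return(matrix(numeric(0), ncol = 3,
                                   dimnames = list(NULL, c("start", "end", "n_snps"))))
  do.call(rbind, runs)
}

# literal scalar transcription of the Weir & Cockerham (1984) two-population
# variance components, locus by locus
wc_theta_oracle <- function(g1, g2) {
  suma <- 0; sumall <- 0
  for (j in seq_len(ncol(g1))) {
    x1 <- g1[, j]; x1 <- x1[!is.na(x1)]
    x2 <- g2[, j]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 == 0 || n2 == 0 || n1 + n2 <= 2) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar == 0 || pbar == 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    suma <- suma + a
    sumall <- sumall + a + b + cc
  }
  suma / sumall
}

# naive interval membership: marker-by-marker, gene-by-gene double loop
brute_force_gene_map <- function(markers, panel) {
  out <- list()
  for (i in seq_len(nrow(markers))) for (j in seq_len(nrow(panel))) {
    if (markers$chromosome[i] == panel$chromosome[j] &&
        markers$position[i] >= panel$start_bp[j] &&
        markers$position[i] <= panel$end_bp[j])
      out[[length(out) + 1]] <- data.frame(marker_id = markers$marker_id[i],
                                           gene = panel$gene[j],
                                           stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(marker_id = character(),
                                      gene = character()))
  do.call(rbind, out)
}

# frequency table from Table-3-style printed matrices used in summaries
published_nei_gw_row <- c(0.169, 0.214, 0.215, 0.189)
published_fst_gw_col <- c(0.319, 0.346, 0.357, 0.294)
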