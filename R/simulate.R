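#' Simulation configuration
#'
#' Describes a Balding-Nichols divergence scenario: K populations drifted
#' from a shared ancestral allele-frequency pool, genotyped at biallelic
#' SNPs laid out on a dog-like genome.
#'
#' @param n_populations number of populations K.
#' @param fst per-population divergence parameter F in (0, 1), recycled to
#'   length K.
#' @param n_loci number of SNPs.
#' @param n_per_population samples per population, recycled to length K.
#' @param ancestral_range range of the uniform ancestral-frequency draw
#'   (default c(0.05, 0.95)).
#' @param n_chromosomes,chromosome_length_bp genome geometry; defaults are a
#'   scaled-down dog autosome set (38 chromosomes x 60 Mbp).
#' @param missing_rate per-genotype missingness probability in [0, 1).
#' @param seed integer seed (mandatory; every generator is reproducible).
#' @param pop_labels optional population labels (default "pop1", ...).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_populations = 5, fst = 0.2, n_loci = 2000,
                       n_per_population = 30,
                       ancestral_range = c(0.05, 0.95),
                       n_chromosomes = 38, chromosome_length_bp = 60e6,
                       missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  fst <- rep_len(fst, n_populations)
  n_per_population <- rep_len(as.integer(n_per_population), n_populations)
  stopifnot(all(fst >= 0), all(fst < 1), missing_rate >= 0, missing_rate < 1,
            n_loci >= 1, n_populations >= 1)
  structure(list(n_populations = n_populations, fst = fst, n_loci = n_loci,
                 n_per_population = n_per_population,
                 ancestral_range = ancestral_range,
                 n_chromosomes = n_chromosomes,
                 chromosome_length_bp = chromosome_length_bp,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 pop_labels = paste0("pop", seq_len(n_populations))),
            class = "sim_config")
}

# uniform-sorted marker positions along n_chromosomes of equal length
simulate_marker_map <- function(n_loci, n_chromosomes, chrom_len) {
  chr <- sort(sample.int(n_chromosomes, n_loci, replace = TRUE))
  pos <- integer(n_loci)
  for (c_ in unique(chr)) {
    i <- chr == c_
    pos[i] <- sort(sample.int(chrom_len, sum(i)))
  }
  data.frame(marker_id = sprintf("snp%06d", seq_len(n_loci)),
             chromosome = as.character(chr), position = pos,
             a1 = "A", a2 = "B", stringsAsFactors = FALSE)
}

#' Simulate divergent populations under the Balding-Nichols model
#'
#' Ancestral frequencies p are drawn uniformly from
#' \code{config$ancestral_range}; each population's frequency at a locus is
#' drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance
#' F p (1-p); genotypes are Binomial(2, freq). F = 0 is handled as the
#' no-drift limit (population frequencies equal the ancestral ones).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{dataset} (a \code{\link{genotype_dataset}}) and
#'   \code{truth}: ancestral frequencies (\code{ancestral_p}), the
#'   populations-by-loci frequency matrix (\code{pop_freqs}) and the true
#'   population label per sample (\code{labels}).
#' @export
simulate_balding_nichols <- function(config) {
  set.seed(config$seed)
  L <- config$n_loci; K <- config$n_populations
  p <- stats::runif(L, config$ancestral_range[1], config$ancestral_range[2])
  freqs <- matrix(0, nrow = K, ncol = L,
                  dimnames = list(config$pop_labels, NULL))
  for (k in seq_len(K)) {
    F <- config$fst[k]
    freqs[k, ] <- if (F == 0) p else
      stats::rbeta(L, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  n <- config$n_per_population
  labels <- rep(config$pop_labels, n)
  geno <- matrix(NA_integer_, nrow = sum(n), ncol = L)
  row0 <- 0L
  for (k in seq_len(K)) {
    geno[row0 + seq_len(n[k]), ] <-
      matrix(stats::rbinom(n[k] * L, 2L, rep(freqs[k, ], each = n[k])),
             nrow = n[k])
    row0 <- row0 + n[k]
  }
  markers <- simulate_marker_map(L, config$n_chromosomes,
                                 config$chromosome_length_bp)
  samples <- data.frame(sample_id = sprintf("s%04d", seq_len(sum(n))),
                        group = labels, stringsAsFactors = FALSE)
  ds <- genotype_dataset(geno, markers, samples, sort_markers = FALSE)
  if (config$missing_rate > 0)
    ds <- add_missingness(ds, config$missing_rate,
                          seed = config$seed + 1L)
  list(dataset = ds,
       truth = list(ancestral_p = p, pop_freqs = freqs, labels = labels))
}

#' Simulate admixed individuals between two allele-frequency profiles
#'
#' Each sample i with ancestry fraction q_i has genotypes
#' Binomial(2, q_i * f_a + (1 - q_i) * f_b) per locus.
#'
#' @param pop_a_freqs,pop_b_freqs allele-frequency vectors of equal length.
#' @param q_values ancestry fraction toward population A, one per sample,
#'   each in [0, 1].
#' @param seed integer seed.
#' @param markers optional marker map data.frame (as in
#'   \code{\link{genotype_dataset}}); generated if omitted.
#' @param group group label for the simulated samples (default "admixed").
#' @return list with \code{dataset} and \code{truth} (the true Q matrix with
#'   columns popA, popB).
#' @export
simulate_admixed <- function(pop_a_freqs, pop_b_freqs, q_values, seed,
                             markers = NULL, group = "admixed") {
  if (length(pop_a_freqs) != length(pop_b_freqs))
    stop("frequency vectors of unequal length")
  stopifnot(all(q_values >= 0), all(q_values <= 1))
  set.seed(as.integer(seed))
  L <- length(pop_a_freqs); n <- length(q_values)
  pi_ <- outer(q_values, pop_a_freqs) + outer(1 - q_values, pop_b_freqs)
  geno <- matrix(stats::rbinom(n * L, 2L, pi_), nrow = n)
  if (is.null(markers)) markers <- simulate_marker_map(L, 38, 60e6)
  samples <- data.frame(sample_id = sprintf("adm%04d", seq_len(n)),
                        group = group, stringsAsFactors = FALSE)
  ds <- genotype_dataset(geno, markers, samples, sort_markers = FALSE)
  truth_q <- cbind(popA = q_values, popB = 1 - q_values)
  rownames(truth_q) <- samples$sample_id
  list(dataset = ds, truth = list(Q = truth_q))
}

#' Implant autozygous tracts with a target genomic inbreeding level
#'
#' Per sample, tract lengths are drawn from an exponential distribution with
#' the given mean, truncated below at \code{min_tract_mbp}, and placed
#' uniformly on the genome without overlap until the realized F_ROH (summed
#' tract length over the SNP-covered genome span) reaches \code{target_froh}.
#' Every SNP inside a tract is set homozygous, for the allele drawn once per
#' locus with its population frequency; the tract intervals are recorded as
#' truth.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param target_froh target fraction of the genome in autozygous tracts.
#' @param mean_tract_mbp,min_tract_mbp tract length distribution (Mbp).
#' @param seed integer seed.
#' @param max_attempts placement attempts per tract before giving up.
#' @return list with \code{dataset} and \code{truth}: \code{tracts} (sample,
#'   chromosome, start/end bp) and \code{realized_froh} per sample.
#' @export
implant_roh <- function(ds, target_froh, mean_tract_mbp = 8,
                        min_tract_mbp = 1, seed, max_attempts = 200) {
  stopifnot(target_froh >= 0, target_froh < 1)
  set.seed(as.integer(seed))
  if (target_froh == 0)
    return(list(dataset = ds,
                truth = list(tracts = data.frame(), realized_froh =
                  stats::setNames(rep(0, n_samples(ds)), ds$samples$sample_id))))
  span <- genome_span(ds)
  genome_bp <- span$total_bp
  chrs <- split(seq_len(n_markers(ds)), ds$markers$chromosome)
  chr_tab <- span$per_chromosome
  chr_tab <- chr_tab[chr_tab$span_bp > 0, ]
  # per-locus homozygous allele probability from pooled frequency
  pool <- colMeans(ds$genotypes, na.rm = TRUE) / 2
  pool[is.na(pool)] <- 0.5
  g <- ds$genotypes
  all_tracts <- list()
  froh <- numeric(n_samples(ds))
  for (i in seq_len(n_samples(ds))) {
    placed <- lapply(chr_tab$chromosome, function(x) matrix(0, 0, 2))
    names(placed) <- chr_tab$chromosome
    tot <- 0
    attempts <- 0L
    while (tot / genome_bp < target_froh) {
      len <- max(stats::rexp(1, 1 / (mean_tract_mbp * 1e6)), min_tract_mbp * 1e6)
      ci <- sample.int(nrow(chr_tab), 1, prob = chr_tab$span_bp)
      chrom <- chr_tab$chromosome[ci]
      lo <- min(ds$markers$position[chrs[[chrom]]])
      hi <- max(ds$markers$position[chrs[[chrom]]])
      if (len >= hi - lo) len <- hi - lo
      start <- lo + floor(stats::runif(1, 0, hi - lo - len))
      end <- start + len
      ov <- placed[[chrom]]
      if (nrow(ov) && any(start <= ov[, 2] & end >= ov[, 1])) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("cannot place tract without overlap after ", max_attempts,
               " attempts (sample ", ds$samples$sample_id[i], ")")
        next
      }
      placed[[chrom]] <- rbind(ov, c(start, end))
      tot <- tot + len
      idx <- chrs[[chrom]]
      inside <- idx[ds$markers$position[idx] >= start &
                    ds$markers$position[idx] <= end]
      if (length(inside)) {
        hom <- stats::rbinom(length(inside), 1L, pool[inside]) * 2L
        g[i, inside] <- hom
      }
      all_tracts[[length(all_tracts) + 1L]] <-
        data.frame(sample_id = ds$samples$sample_id[i], chromosome = chrom,
                   start_bp = start, end_bp = end, length_bp = len,
                   stringsAsFactors = FALSE)
    }
    froh[i] <- tot / genome_bp
  }
  tracts <- do.call(rbind, all_tracts)
  out <- genotype_dataset(g, ds$markers, ds$samples, sort_markers = FALSE)
  list(dataset = out,
       truth = list(tracts = tracts,
                    realized_froh = stats::setNames(froh, ds$samples$sample_id)))
}

#' Sprinkle missing genotypes at a fixed rate
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param rate per-genotype missingness probability in [0, 1).
#' @param seed integer seed.
#' @return A \code{genotype_dataset} with genotypes independently set
#'   missing with probability \code{rate}.
#' @export
add_missingness <- function(ds, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(ds)
  set.seed(as.integer(seed))
  g <- ds$genotypes
  g[stats::runif(length(g)) < rate] <- NA_integer_
  genotype_dataset(g, ds$markers, ds$samples, sort_markers = FALSE)
}
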