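#' Minimum SNP count for a run of homozygosity
#'
#' The false-positive control of Lencz et al.:
#' \deqn{l = \ln(\alpha / (n_s n_i)) / \ln(1 - \bar{het})}
#' where alpha is the tolerated proportion of chance ROH, n_s the number of
#' SNPs, n_i the number of animals, and mean_het the average heterozygosity
#' across SNPs and animals. The real value is floored (and never below 1);
#' use the \code{min_snps} override in \code{\link{roh_params}} to force a
#' fixed count such as 65.
#'
#' @param alpha false-positive proportion in (0, 1); conventionally 0.05.
#' @param n_snps,n_samples dataset dimensions.
#' @param mean_het mean heterozygosity in (0, 1).
#' @return integer minimum SNP count.
#' @export
lencz_min_snps <- function(alpha, n_snps, n_samples, mean_het) {
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1, n_samples >= 1)
  if (mean_het <= 0 || mean_het >= 1)
    stop("mean_het must be in (0,1)")
  l <- log(alpha / (n_snps * n_samples)) / log(1 - mean_het)
  max(1L, as.integer(floor(l)))
}

#' Observed mean heterozygosity of a dataset
#'
#' Fraction of non-missing genotype calls that are heterozygous, pooled over
#' all SNPs and samples.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @return fraction in [0, 1].
#' @export
mean_heterozygosity <- function(ds) {
  g <- ds$genotypes
  mean(g[!is.na(g)] == 1L)
}

#' ROH detection parameters
#'
#' Defaults reproduce the strict consecutive-runs setting: runs of
#' homozygous genotypes at least 500 kb long, broken by any heterozygous or
#' missing call and by inter-SNP gaps over 1000 kb, with on average at least
#' one SNP per 5000 kb, and a minimum SNP count taken from
#' \code{\link{lencz_min_snps}} at detection time unless \code{min_snps} is
#' given.
#'
#' @param min_length_bp minimum run length (bp).
#' @param max_gap_bp maximum allowed gap between consecutive SNPs (bp).
#' @param max_het,max_missing allowed heterozygous/missing calls inside a
#'   run; only 0 is supported (runs split at any such call).
#' @param min_density_bp_per_snp maximum average bp per SNP inside a run.
#' @param min_snps minimum SNP count, or NULL to compute it from
#'   \code{\link{lencz_min_snps}} on the dataset at hand.
#' @param alpha false-positive proportion for the Lencz formula.
#' @return A \code{roh_params} list.
#' @export
roh_params <- function(min_length_bp = 500000, max_gap_bp = 1000000,
                       max_het = 0, max_missing = 0,
                       min_density_bp_per_snp = 5000000,
                       min_snps = NULL, alpha = 0.05) {
  if (max_het != 0 || max_missing != 0)
    stop("only max_het = max_missing = 0 is supported (runs split at any ",
         "heterozygous or missing call)")
  stopifnot(min_length_bp > 0, max_gap_bp > 0, min_density_bp_per_snp > 0,
            alpha > 0, alpha < 1, is.null(min_snps) || min_snps >= 1)
  structure(list(min_length_bp = min_length_bp, max_gap_bp = max_gap_bp,
                 max_het = max_het, max_missing = max_missing,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 min_snps = if (is.null(min_snps)) NULL else as.integer(min_snps),
                 alpha = alpha),
            class = "roh_params")
}

#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Per sample and chromosome, every maximal run of consecutive homozygous
#' genotypes — split at any heterozygous or missing call and at any
#' inter-SNP gap larger than \code{max_gap_bp} — is reported iff its length
#' (closed interval over the first and last SNP of the run) is at least
#' \code{min_length_bp}, it contains at least \code{min_snps} SNPs, and its
#' average SNP spacing length/n_snps does not exceed
#' \code{min_density_bp_per_snp}.
#'
#' @param ds a \code{\link{genotype_dataset}}; markers must be sorted by
#'   (chromosome, position).
#' @param params a \code{\link{roh_params}}. When \code{params$min_snps} is
#'   NULL it is computed via \code{\link{lencz_min_snps}} from the dataset's
#'   dimensions and observed mean heterozygosity.
#' @return data.frame of segments: sample_id, chromosome, start_bp, end_bp,
#'   n_snps, length_bp (= end - start + 1). Attribute \code{min_snps} holds
#'   the threshold used.
#' @export
detect_roh <- function(ds, params = roh_params()) {
  mk <- ds$markers
  o <- order(chrom_order(mk$chromosome), mk$position)
  if (!identical(o, seq_len(nrow(mk))))
    stop("markers are not sorted by (chromosome, position)")
  min_snps <- params$min_snps
  if (is.null(min_snps)) {
    het <- mean_heterozygosity(ds)
    if (is.nan(het) || het <= 0 || het >= 1)
      stop("cannot compute Lencz minimum SNP count: mean heterozygosity ",
           "outside (0,1); supply params$min_snps")
    min_snps <- lencz_min_snps(params$alpha, n_markers(ds), n_samples(ds), het)
  }
  chr_idx <- split(seq_len(nrow(mk)), mk$chromosome)
  out <- vector("list", 0)
  for (chrom in names(chr_idx)) {
    idx <- chr_idx[[chrom]]
    pos <- mk$position[idx]
    gap_break <- c(FALSE, diff(pos) > params$max_gap_bp)
    for (i in seq_len(n_samples(ds))) {
      g <- ds$genotypes[i, idx]
      hom <- !is.na(g) & g != 1L
      # run ids: increment at every non-hom call or oversized gap
      brk <- !hom | gap_break
      run_id <- cumsum(brk)
      keep <- which(hom)
      if (!length(keep)) next
      for (r in split(keep, run_id[keep])) {
        n <- length(r)
        len <- pos[r[n]] - pos[r[1]] + 1
        if (len >= params$min_length_bp && n >= min_snps &&
            len / n <= params$min_density_bp_per_snp) {
          out[[length(out) + 1L]] <- data.frame(
            sample_id = ds$samples$sample_id[i], chromosome = chrom,
            start_bp = pos[r[1]], end_bp = pos[r[n]], n_snps = n,
            length_bp = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  segs <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), chromosome = character(),
               start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), length_bp = numeric(),
               stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  attr(segs, "min_snps") <- min_snps
  segs
}

#' Length-class scheme for ROH
#'
#' @param bounds_mbp upper bounds of the classes in Mbp, default
#'   c(2, 4, 8, 16): classes (0-2], (2-4], (4-8], (8-16], >16 Mbp.
#' @return A \code{length_class_scheme} with breaks and labels.
#' @export
length_class_scheme <- function(bounds_mbp = c(2, 4, 8, 16)) {
  stopifnot(all(diff(bounds_mbp) > 0), all(bounds_mbp > 0))
  breaks <- c(0, bounds_mbp, Inf)
  labels <- c(paste0(breaks[-length(breaks)][-length(bounds_mbp) - 1],
                     "-", bounds_mbp),
              paste0(">", bounds_mbp[length(bounds_mbp)]))
  structure(list(breaks_mbp = breaks, labels = labels),
            class = "length_class_scheme")
}

#' Classify ROH segments by length and summarise per group
#'
#' Adds a length-class label to each segment and tabulates, per group and
#' class: segment count, mean length (Mbp), and the within-group
#' distribution percentage (100 x class count / total count in the group).
#'
#' @param segments data.frame from \code{\link{detect_roh}}.
#' @param groups named character vector mapping sample_id to group, or NULL
#'   to treat all samples as one group.
#' @param scheme a \code{\link{length_class_scheme}}.
#' @return list with \code{segments} (input plus \code{class} column) and
#'   \code{summary} (group, class, n_roh, mean_length_mbp, distribution_pct).
#' @export
classify_roh <- function(segments, groups = NULL,
                         scheme = length_class_scheme()) {
  if (nrow(segments) == 0)
    return(list(segments = segments,
                summary = data.frame(group = character(), class = character(),
                                     n_roh = integer(),
                                     mean_length_mbp = numeric(),
                                     distribution_pct = numeric())))
  len_mbp <- segments$length_bp / 1e6
  cls <- cut(len_mbp, breaks = scheme$breaks_mbp, labels = scheme$labels,
             right = TRUE, include.lowest = TRUE)
  segments$class <- as.character(cls)
  grp <- if (is.null(groups)) rep("all", nrow(segments)) else {
    g <- unname(groups[segments$sample_id])
    if (anyNA(g)) stop("segments with sample_id missing from groups")
    g
  }
  parts <- split(seq_len(nrow(segments)), grp)
  summ <- do.call(rbind, lapply(names(parts), function(gname) {
    i <- parts[[gname]]
    total <- length(i)
    per <- lapply(scheme$labels, function(cl) {
      j <- i[segments$class[i] == cl]
      data.frame(group = gname, class = cl, n_roh = length(j),
                 mean_length_mbp = if (length(j)) mean(len_mbp[j]) else NA_real_,
                 distribution_pct = 100 * length(j) / total,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  }))
  rownames(summ) <- NULL
  list(segments = segments, summary = summ)
}

#' Genomic inbreeding coefficients from ROH
#'
#' For each sample, F_ROH at threshold X is the summed length of its ROH
#' with length >= X Mbp divided by the SNP-covered autosomal genome length
#' ("cumulative" mode, the default). The literal "per-class" mode instead
#' sums only segments whose length falls inside each class. Group summaries
#' report the arithmetic mean and the n-1 standard deviation, either over
#' all animals of the group (default) or only over animals carrying at
#' least one qualifying segment (\code{carriers_only}).
#'
#' @param segments data.frame from \code{\link{detect_roh}}.
#' @param genome_length_bp SNP-covered genome length (see
#'   \code{\link{genome_span}}).
#' @param sample_ids all sample ids to report (samples with no segments get
#'   F_ROH 0); defaults to the ids present in \code{segments}.
#' @param scheme a \code{\link{length_class_scheme}}; its bounds plus the
#'   0.5 Mbp detection floor define the thresholds.
#' @param mode \code{"cumulative"} (F_ROH >= X) or \code{"per_class"}.
#' @param groups optional named group vector for the group summary.
#' @param carriers_only average class F_ROH only over samples with >= 1
#'   segment qualifying for that threshold/class? Default FALSE.
#' @param min_length_mbp detection floor used for the first cumulative
#'   threshold (default 0.5).
#' @return list with \code{per_sample} (sample_id, froh_total and one column
#'   per threshold/class) and, when \code{groups} is given,
#'   \code{per_group} (group, statistic rows of mean and sd).
#' @export
froh <- function(segments, genome_length_bp, sample_ids = NULL,
                 scheme = length_class_scheme(),
                 mode = c("cumulative", "per_class"), groups = NULL,
                 carriers_only = FALSE, min_length_mbp = 0.5) {
  mode <- match.arg(mode)
  stopifnot(genome_length_bp > 0)
  if (is.null(sample_ids))
    sample_ids <- unique(segments$sample_id)
  bounds <- scheme$breaks_mbp[-length(scheme$breaks_mbp)]
  bounds[1] <- min_length_mbp
  if (mode == "cumulative") {
    cols <- paste0("froh_ge_", bounds)
    val <- sapply(bounds, function(b) {
      sel <- segments$length_bp >= b * 1e6
      v <- tapply(segments$length_bp[sel], segments$sample_id[sel], sum)
      out <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
      out[names(v)] <- v
      out / genome_length_bp
    })
  } else {
    cols <- paste0("froh_class_", scheme$labels)
    len_mbp <- segments$length_bp / 1e6
    cls <- as.character(cut(len_mbp, breaks = scheme$breaks_mbp,
                            labels = scheme$labels, right = TRUE,
                            include.lowest = TRUE))
    val <- sapply(scheme$labels, function(cl) {
      sel <- cls == cl
      v <- tapply(segments$length_bp[sel], segments$sample_id[sel], sum)
      out <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
      out[names(v)] <- v
      out / genome_length_bp
    })
  }
  val <- matrix(val, nrow = length(sample_ids),
                dimnames = list(sample_ids, cols))
  total <- if (mode == "cumulative") val[, 1] else rowSums(val)
  per_sample <- data.frame(sample_id = sample_ids,
                           froh_total = total, val,
                           row.names = NULL, stringsAsFactors = FALSE)
  res <- list(per_sample = per_sample)
  if (!is.null(groups)) {
    g <- unname(groups[per_sample$sample_id])
    if (anyNA(g)) stop("sample ids missing from groups")
    stats_rows <- do.call(rbind, lapply(split(seq_len(nrow(per_sample)), g),
      function(i) {
        m <- vapply(cols, function(cn) {
          x <- per_sample[[cn]][i]
          if (carriers_only) x <- x[x > 0]
          if (!length(x)) return(c(NA_real_, NA_real_))
          c(mean(x), stats::sd(x))
        }, numeric(2))
        data.frame(group = unique(g[match(i, seq_along(g))])[1],
                   statistic = c("mean", "sd"), m,
                   stringsAsFactors = FALSE, check.names = FALSE)
      }))
    rownames(stats_rows) <- NULL
    res$per_group <- stats_rows
  }
  res
}
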