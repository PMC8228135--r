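#' Per-group allele frequencies
#'
#' A1 frequency per group and marker, with missing genotypes excluded;
#' groups with no genotyped sample at a marker get \code{NA} there.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param groups named character vector mapping sample_id to group; defaults
#'   to the dataset's own sample table.
#' @return list with \code{freq} (groups x markers matrix of A1
#'   frequencies) and \code{n_alleles} (matching matrix of non-missing
#'   allele counts, 2 x genotyped samples).
#' @export
allele_freqs <- function(ds, groups = NULL) {
  g <- resolve_groups(ds, groups)
  lev <- unique(g)
  geno <- ds$genotypes
  freq <- matrix(NA_real_, nrow = length(lev), ncol = ncol(geno),
                 dimnames = list(lev, colnames(geno)))
  cnt <- matrix(0L, nrow = length(lev), ncol = ncol(geno),
                dimnames = list(lev, colnames(geno)))
  for (k in seq_along(lev)) {
    gg <- geno[g == lev[k], , drop = FALSE]
    n_ok <- colSums(!is.na(gg))
    cnt[k, ] <- 2L * n_ok
    s <- colSums(gg, na.rm = TRUE)
    freq[k, ] <- ifelse(n_ok > 0, s / (2 * n_ok), NA_real_)
  }
  list(freq = freq, n_alleles = cnt)
}

resolve_groups <- function(ds, groups) {
  if (is.null(groups))
    return(ds$samples$group)
  g <- unname(groups[ds$samples$sample_id])
  if (anyNA(g)) stop("unknown group label for some samples")
  g
}

#' Nei genetic distances between allele-frequency profiles
#'
#' Two variants over biallelic loci with frequencies x, y per unit:
#' \itemize{
#' \item \code{nei1972} standard distance: D = -ln I with the normalized
#'   identity I pooled over loci, I = sum_l (x y + (1-x)(1-y)) /
#'   sqrt(sum_l (x^2 + (1-x)^2) * sum_l (y^2 + (1-y)^2)).
#' \item \code{nei1983} D_A: 1 - (1/L) sum_l (sqrt(x y) +
#'   sqrt((1-x)(1-y))).
#' }
#' Loci with a missing frequency in either unit are skipped (L adjusted).
#' A zero identity under nei1972 (fully fixed for opposite alleles) would be
#' infinite and is returned as the flagged large value 1e6.
#'
#' @param freqs result of \code{\link{allele_freqs}}, or a units-by-loci
#'   frequency matrix.
#' @param method \code{"nei1972"} (default; the standard distance) or
#'   \code{"nei1983"}.
#' @return A \code{dist_matrix}: list with \code{labels}, symmetric
#'   \code{matrix} (zero diagonal) and \code{method}.
#' @export
nei_distance <- function(freqs, method = c("nei1972", "nei1983")) {
  method <- match.arg(method)
  f <- if (is.list(freqs)) freqs$freq else freqs
  if (nrow(f) < 2) stop("need at least 2 units")
  n <- nrow(f)
  d <- matrix(0, n, n, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- f[i, ]; y <- f[j, ]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (!length(x)) { d[i, j] <- d[j, i] <- NA_real_; next }
    if (method == "nei1972") {
      jxy <- sum(x * y + (1 - x) * (1 - y))
      jx <- sum(x^2 + (1 - x)^2)
      jy <- sum(y^2 + (1 - y)^2)
      I <- jxy / sqrt(jx * jy)
      d[i, j] <- d[j, i] <- if (I <= 0) 1e6 else -log(I)
    } else {
      d[i, j] <- d[j, i] <-
        1 - mean(sqrt(x * y) + sqrt((1 - x) * (1 - y)))
    }
  }
  dist_matrix(d, method)
}

#' Symmetric distance matrix container
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param method one of \code{"fst_wc"}, \code{"nei1972"}, \code{"nei1983"},
#'   \code{"ibs"}, \code{"pi_hat"}.
#' @param extra optional list of diagnostics (e.g. unclipped values,
#'   bootstrap CIs).
#' @return A \code{dist_matrix} object.
#' @export
dist_matrix <- function(m, method, extra = list()) {
  stopifnot(nrow(m) == ncol(m))
  structure(list(labels = rownames(m), matrix = m, method = method,
                 extra = extra),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", x$method, "), ", length(x$labels), " units\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Pairwise Weir-Cockerham F_ST between groups
#'
#' The Weir & Cockerham (1984) theta estimator in its two-population
#' biallelic form: per locus the variance components a (among populations),
#' b (among individuals within populations) and c (within individuals) are
#' computed from per-group sample sizes, allele frequencies and observed
#' heterozygosity, and theta for a pair is sum(a) / sum(a + b + c) over
#' loci. Loci monomorphic across the pair, or with a group entirely
#' ungenotyped, are skipped. Negative estimates are clipped to 0 in the
#' headline matrix; the unclipped values are kept in
#' \code{$extra$unclipped}. Optional bootstrap over loci gives percentile
#' CIs in \code{$extra$boot_ci}.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param groups optional named sample_id -> group vector.
#' @param n_bootstrap bootstrap replicates over loci (0 = none).
#' @param seed seed for the bootstrap.
#' @return A \code{\link{dist_matrix}} with method \code{"fst_wc"}.
#' @export
wc_fst_pairwise <- function(ds, groups = NULL, n_bootstrap = 0, seed = 1) {
  g <- resolve_groups(ds, groups)
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) stop("each group needs >= 2 samples")
  n <- length(lev)
  m <- matrix(0, n, n, dimnames = list(lev, lev))
  raw <- m
  boot_ci <- NULL
  if (n_bootstrap > 0) {
    set.seed(as.integer(seed))
    boot_ci <- array(NA_real_, dim = c(n, n, 2),
                     dimnames = list(lev, lev, c("lo", "hi")))
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- wc_components_pair(ds$genotypes[g == lev[i], , drop = FALSE],
                               ds$genotypes[g == lev[j], , drop = FALSE])
    denom <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
    if (denom == 0 || all(is.na(comp$a))) {
      raw[i, j] <- raw[j, i] <- NA_real_
      m[i, j] <- m[j, i] <- NA_real_
      warning("theta undefined for pair ", lev[i], "/", lev[j],
              " (monomorphic everywhere)")
      next
    }
    th <- sum(comp$a, na.rm = TRUE) / denom
    raw[i, j] <- raw[j, i] <- th
    m[i, j] <- m[j, i] <- min(max(th, 0), 1)
    if (n_bootstrap > 0) {
      ok <- which(!is.na(comp$a))
      reps <- vapply(seq_len(n_bootstrap), function(b) {
        s <- sample(ok, length(ok), replace = TRUE)
        sum(comp$a[s]) / sum(comp$a[s] + comp$b[s] + comp$c[s])
      }, 0)
      ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE)
      boot_ci[i, j, ] <- boot_ci[j, i, ] <- ci
    }
  }
  dist_matrix(m, "fst_wc",
              extra = c(list(unclipped = raw),
                        if (!is.null(boot_ci)) list(boot_ci = boot_ci)))
}

# Per-locus W&C (1984) variance components for one pair of populations,
# vectorized across loci. Loci monomorphic in the pooled sample, or with a
# population entirely missing, get NA components.
wc_components_pair <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, colSums(g1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(g2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(g1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(g2 == 1L, na.rm = TRUE) / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 == 0 | n2 == 0 | n1 + n2 <= 2 | pbar %in% c(0, 1) | is.na(pbar)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Mean and SD of one unit's distances to all others
#'
#' @param dm a \code{\link{dist_matrix}}.
#' @param focal unit label.
#' @return list with \code{mean}, \code{sd} (n-1 denominator), \code{n}
#'   partners.
#' @export
summarize_vs_group <- function(dm, focal) {
  i <- match(focal, dm$labels)
  if (is.na(i)) stop("unknown unit: ", focal)
  vals <- dm$matrix[i, -i]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) stop("need >= 2 partners for a summary")
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Combined distance table in two-triangle layout
#'
#' One matrix carrying one method below the diagonal and another above it,
#' in the conventional publication layout.
#'
#' @param lower,upper \code{\link{dist_matrix}} objects over the same
#'   labels.
#' @return matrix with \code{lower}'s values under the diagonal and
#'   \code{upper}'s above; attribute \code{methods} records which is which.
#' @export
combined_distance_table <- function(lower, upper) {
  if (!identical(lower$labels, upper$labels))
    stop("label sets differ")
  m <- lower$matrix
  m[upper.tri(m)] <- upper$matrix[upper.tri(m)]
  diag(m) <- NA_real_
  attr(m, "methods") <- c(lower = lower$method, upper = upper$method)
  m
}
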