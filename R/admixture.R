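#' Log-likelihood of the admixture model
#'
#' Under the K-cluster admixture model with uncorrelated cluster allele
#' frequencies, each genotype g_ij (dosage of A1 at locus j in individual i)
#' is Binomial(2, pi_ij) with pi_ij = sum_k q_ik f_kj. The log-likelihood is
#' sum over non-missing genotypes of
#' g ln(pi) + (2 - g) ln(1 - pi) + ln C(2, g).
#' pi is clamped to [1e-6, 1 - 1e-6] with a warning if it strays outside.
#'
#' @param ds a \code{\link{genotype_dataset}} or dosage matrix.
#' @param Q samples x K ancestry fractions (rows sum to 1).
#' @param P K x markers cluster allele frequencies.
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(ds, Q, P) {
  g <- if (inherits(ds, "genotype_dataset")) ds$genotypes else ds
  if (nrow(Q) != nrow(g) || ncol(Q) != nrow(P) || ncol(P) != ncol(g))
    stop("dimension mismatch between genotypes, Q and P")
  eps <- 1e-6
  pi_ <- Q %*% P
  if (any(pi_ < 0 | pi_ > 1, na.rm = TRUE))
    warning("mixture frequencies outside [0,1]; clamped")
  pi_ <- pmin(pmax(pi_, eps), 1 - eps)
  ok <- !is.na(g)
  gl <- g[ok] * log(pi_[ok]) + (2 - g[ok]) * log(1 - pi_[ok]) +
    log(choose(2, g[ok]))
  sum(gl)
}

#' Fit the admixture model by expectation-maximization
#'
#' Maximum-likelihood point estimation of the K-cluster admixture model:
#' from a seeded random start, alternate the expected per-cluster allele
#' counts (E step) with closed-form updates of the cluster frequencies P
#' and ancestry fractions Q (M step) until the log-likelihood gain drops
#' below \code{tol} or \code{max_iter} is reached. The log-likelihood trace
#' is non-decreasing (an EM guarantee, asserted per iteration). K = 1 has
#' the closed-form solution Q = 1, P = pooled frequencies.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param K number of ancestral clusters (>= 1).
#' @param seed integer seed for the random start.
#' @param max_iter iteration cap (default 2000).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return An \code{admixture_run}: K, seed, Q, P, \code{loglik} (final),
#'   \code{trace}, \code{converged}, \code{n_iter}.
#' @export
fit_admixture <- function(ds, K, seed = 1, max_iter = 2000, tol = 1e-6) {
  stopifnot(K >= 1)
  g <- ds$genotypes
  storage.mode(g) <- "double"
  n <- nrow(g); L <- ncol(g)
  miss <- is.na(g)
  g0 <- g; g0[miss] <- 0               # dosage with missing zeroed
  w <- 1 - miss                        # observation mask
  n_obs <- 2 * rowSums(w)              # observed allele count per sample
  eps <- 1e-6
  if (K == 1) {
    cs <- colSums(g0); cn <- 2 * colSums(w)
    P <- matrix(pmin(pmax(ifelse(cn > 0, cs / cn, 0.5), eps), 1 - eps),
                nrow = 1)
    Q <- matrix(1, nrow = n, ncol = 1)
    ll <- admixture_loglik(g, Q, P)
    return(structure(list(K = 1L, seed = as.integer(seed), Q = Q, P = P,
                          loglik = ll, trace = ll, converged = TRUE,
                          n_iter = 0L),
                     class = "admixture_run"))
  }
  set.seed(as.integer(seed))
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pi_ <- pmin(pmax(Q %*% P, eps), 1 - eps)
    # E step: expected ancestry-specific allele counts
    #   A1 alleles from cluster k at (i,j): g_ij * q_ik f_kj / pi_ij
    #   A2 alleles from cluster k:      (2-g_ij) * q_ik (1-f_kj) / (1-pi_ij)
    Ga <- (g0 * w) / pi_               # g / pi, missing contribute 0
    Gb <- ((2 - g0) * w) / (1 - pi_)
    Anum <- matrix(0, K, L)            # sum_i a_ijk
    Qnew <- matrix(0, n, K)
    for (k in seq_len(K)) {
      ak <- (Ga * outer(Q[, k], P[k, ]))          # n x L
      bk <- (Gb * outer(Q[, k], 1 - P[k, ]))
      Anum[k, ] <- colSums(ak)
      Qnew[, k] <- rowSums(ak) + rowSums(bk)
      P[k, ] <- Anum[k, ] / (Anum[k, ] + colSums(bk))
    }
    P[is.na(P)] <- 0.5
    P <- pmin(pmax(P, eps), 1 - eps)
    Q <- Qnew / n_obs
    Q <- Q / rowSums(Q)                # guard against numeric drift
    ll <- admixture_loglik(g, Q, P)
    if (!is.finite(ll))
      stop("non-finite log-likelihood at iteration ", it,
           " (K=", K, ", seed=", seed, ")")
    if (ll < ll_old - 1e-6)
      stop("log-likelihood decreased at iteration ", it,
           " (", ll_old, " -> ", ll, ")")
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(K = as.integer(K), seed = as.integer(seed), Q = Q, P = P,
                 loglik = trace[length(trace)], trace = trace,
                 converged = converged, n_iter = it),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("admixture_run: K =", x$K, " loglik =", round(x$loglik, 2),
      if (x$converged) "(converged" else "(not converged",
      "after", x$n_iter, "iterations)\n")
  invisible(x)
}

#' Replicate admixture runs over a range of K
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param k_range integer vector of K values (default 1:10).
#' @param n_replicates runs per K from different seeds (default 10).
#' @param seed base seed; replicate r of K uses seed
#'   \code{seed + 1000 * K + r}.
#' @param ... passed to \code{\link{fit_admixture}}.
#' @return list of \code{admixture_run} objects.
#' @export
admixture_scan <- function(ds, k_range = 1:10, n_replicates = 10, seed = 1,
                           ...) {
  runs <- list()
  for (K in k_range) for (r in seq_len(n_replicates))
    runs[[length(runs) + 1L]] <-
      fit_admixture(ds, K, seed = seed + 1000L * K + r, ...)
  runs
}

#' Evanno delta-K model selection
#'
#' From replicate log-likelihoods L(K): with mean over replicates
#' \eqn{\bar L(K)},
#' \deqn{\Delta K = |\bar L(K+1) - 2 \bar L(K) + \bar L(K-1)| / SD(L(K))}
#' computed for interior K; the selected K maximizes delta-K. A zero
#' replicate SD gives an infinite (flagged) delta-K.
#'
#' @param runs list of \code{admixture_run} objects covering >= 3
#'   consecutive K values with >= 2 replicates each.
#' @return list with \code{table} (K, mean_loglik, sd_loglik, l_prime,
#'   l_second, delta_k) and \code{selected_k}.
#' @export
evanno_delta_k <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, 0L)
  ll <- vapply(runs, function(r) r$loglik, 0)
  ks <- sort(unique(Ks))
  if (length(ks) < 3 || any(diff(ks) != 1))
    stop("need >= 3 consecutive K values")
  reps <- table(Ks)
  if (any(reps < 2))
    stop("need >= 2 replicates per K for the SD")
  mean_ll <- tapply(ll, Ks, mean)[as.character(ks)]
  sd_ll <- tapply(ll, Ks, stats::sd)[as.character(ks)]
  l_prime <- c(NA, diff(mean_ll))
  l_second <- rep(NA_real_, length(ks))
  delta_k <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1)) {
    l_second[i] <- abs(mean_ll[i + 1] - 2 * mean_ll[i] + mean_ll[i - 1])
    delta_k[i] <- if (sd_ll[i] == 0) Inf else l_second[i] / sd_ll[i]
  }
  tab <- data.frame(K = ks, mean_loglik = as.numeric(mean_ll),
                    sd_loglik = as.numeric(sd_ll),
                    l_prime = as.numeric(l_prime), l_second = l_second,
                    delta_k = delta_k)
  sel <- tab$K[which.max(tab$delta_k)]
  list(table = tab, selected_k = sel)
}

#' Group-mean ancestry fractions
#'
#' Averages the Q matrix within predefined groups and labels clusters by
#' the group with the largest mean membership (ties broken by group order;
#' a cluster claimed by no group, or a group claimed twice, keeps a
#' numbered suffix with a warning).
#'
#' @param Q samples x K ancestry matrix (or an \code{admixture_run}).
#' @param groups group label per sample.
#' @return groups x K matrix of mean ancestry fractions, columns named by
#'   majority group; rows sum to 1.
#' @export
admixture_by_group <- function(Q, groups) {
  if (inherits(Q, "admixture_run")) Q <- Q$Q
  if (nrow(Q) != length(groups)) stop("Q and groups are not aligned")
  lev <- unique(groups)
  M <- do.call(rbind, lapply(lev, function(g_)
    colMeans(Q[groups == g_, , drop = FALSE])))
  rownames(M) <- lev
  owner <- lev[apply(M, 2, which.max)]
  if (anyDuplicated(owner)) {
    warning("multiple clusters claim the same group; suffixing labels")
    owner <- make.unique(owner)
  }
  colnames(M) <- owner
  M
}

#' Align cluster columns to reference labels by greedy matching
#'
#' Resolves admixture label switching: permutes the columns of Q so that
#' each cluster maps to the reference column with which it shares the
#' largest total membership, matched greedily.
#'
#' @param Q estimated samples x K ancestry matrix.
#' @param ref reference samples x K matrix (e.g. a truth Q or indicator
#'   matrix of true labels).
#' @return Q with columns permuted to match \code{ref}.
#' @export
align_clusters <- function(Q, ref) {
  if (!all(dim(Q) == dim(ref))) stop("Q and ref dimensions differ")
  K <- ncol(Q)
  sim <- crossprod(ref, Q)             # ref-cluster x est-cluster overlap
  perm <- integer(K)
  for (step in seq_len(K)) {
    best <- arrayInd(which.max(sim), dim(sim))
    perm[best[1]] <- best[2]
    sim[best[1], ] <- -Inf
    sim[, best[2]] <- -Inf
  }
  Q[, perm, drop = FALSE]
}
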