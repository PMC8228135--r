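#' Principal component analysis of genotype dosages
#'
#' Missing dosages are imputed to the marker mean, columns are centered and
#' optionally scaled, and the sample covariance matrix is
#' eigendecomposed (via SVD). Signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param ds a \code{\link{genotype_dataset}} or a numeric samples x
#'   variables matrix.
#' @param n_components number of PCs to return (default: all with positive
#'   eigenvalue); silently truncated at the matrix rank, with a warning when
#'   the request exceeds it.
#' @param scale \code{"none"} (default), \code{"unit"} (unit variance), or
#'   \code{"allele_freq"} (divide by sqrt(p(1-p)), the drift-scaled
#'   standardization with p the imputed mean dosage / 2).
#' @return A \code{pca_result}: scores, loadings, eigenvalues, explained
#'   variance fractions, center/scale vectors.
#' @export
pca <- function(ds, n_components = NULL,
                scale = c("none", "unit", "allele_freq")) {
  scale <- match.arg(scale)
  x <- if (inherits(ds, "genotype_dataset")) ds$genotypes else as.matrix(ds)
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in which(colSums(is.na(x)) > 0))
    x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, mu)
  sc <- rep(1, ncol(x))
  if (scale == "unit") {
    sc <- apply(x, 2, stats::sd)
  } else if (scale == "allele_freq") {
    p <- mu / 2
    sc <- sqrt(p * (1 - p))
  }
  sc[!is.finite(sc) | sc == 0] <- 1
  x <- sweep(x, 2, sc, "/")
  sv <- svd(x)
  eig <- sv$d^2 / (nrow(x) - 1)
  pos <- eig > max(eig) * 1e-12
  rank_ <- sum(pos)
  if (is.null(n_components)) n_components <- rank_
  if (n_components > rank_) {
    warning("n_components (", n_components, ") exceeds rank (", rank_,
            "); truncated")
    n_components <- rank_
  }
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (c_ in seq_len(ncol(loadings))) {
    piv <- which.max(abs(loadings[, c_]))
    if (loadings[piv, c_] < 0) {
      loadings[, c_] <- -loadings[, c_]
      sv$u[, k[c_]] <- -sv$u[, k[c_]]
    }
  }
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  dimnames(scores) <- list(rownames(x), paste0("PC", k))
  dimnames(loadings) <- list(colnames(x), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eig[k],
                 explained = eig[k] / sum(eig),
                 all_eigenvalues = eig[seq_len(rank_)],
                 center = mu, scale = sc),
            class = "pca_result")
}

#' Number of PCs covering a target variance fraction
#'
#' @param p a \code{pca_result}.
#' @param target cumulative explained-variance fraction (default 0.95).
#' @return smallest number of PCs whose cumulative explained variance
#'   reaches \code{target}.
#' @export
n_pcs_for_variance <- function(p, target = 0.95) {
  cum <- cumsum(p$all_eigenvalues) / sum(p$all_eigenvalues)
  which(cum >= target)[1]
}

#' Alpha-score for choosing the number of retained PCs
#'
#' For each candidate number of PCs, a DAPC is fitted and the alpha-score is
#' the observed proportion of correctly reassigned samples minus the mean
#' proportion obtained when group labels are permuted, averaged over groups.
#' It rewards discrimination but penalizes the overfitting that inflates
#' reassignment as the number of PCs approaches the sample count.
#'
#' @param ds dataset or matrix (passed to \code{\link{pca}}).
#' @param groups character vector of group labels, one per sample.
#' @param candidate_n_pcs integer vector of candidate PC counts.
#' @param n_permutations label permutations per candidate (default 25).
#' @param seed integer seed.
#' @return list with \code{table} (n_pcs, alpha_score) and
#'   \code{recommended} n_pcs (the maximizer).
#' @export
a_score <- function(ds, groups, candidate_n_pcs, n_permutations = 25,
                    seed = 1) {
  if (n_permutations < 1) stop("need at least 1 permutation")
  n <- if (inherits(ds, "genotype_dataset")) n_samples(ds) else nrow(ds)
  stopifnot(all(candidate_n_pcs >= 1), all(candidate_n_pcs < n))
  set.seed(as.integer(seed))
  p_full <- pca(ds)
  score_one <- function(np, lab) {
    fit <- dapc_fit(p_full, lab, n_pcs = np)
    pred <- fit$assigned
    mean(vapply(unique(lab), function(g_)
      mean(pred[lab == g_] == g_), 0))
  }
  alpha <- vapply(candidate_n_pcs, function(np) {
    np <- min(np, ncol(p_full$scores))
    obs <- score_one(np, groups)
    perm <- vapply(seq_len(n_permutations), function(b)
      score_one(np, sample(groups)), 0)
    obs - mean(perm)
  }, 0)
  tab <- data.frame(n_pcs = candidate_n_pcs, alpha_score = alpha)
  list(table = tab, recommended = candidate_n_pcs[which.max(alpha)])
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on the retained PC scores: the within-group
#' covariance is whitened (ridge-regularized by 1e-8 on its diagonal when
#' singular) and the between-group covariance eigendecomposed in the
#' whitened space, giving at most n_groups - 1 discriminant functions.
#' Posterior group memberships come from a Gaussian model with shared
#' identity covariance in the whitened discriminant space and uniform
#' priors.
#'
#' @param p a \code{pca_result} from \code{\link{pca}} (or a
#'   \code{genotype_dataset}, in which case the PCA is run first).
#' @param groups group label per sample (>= 2 groups).
#' @param n_pcs number of leading PCs to retain.
#' @param n_df number of discriminant functions (default
#'   \code{n_groups - 1}).
#' @return A \code{dapc_result}: \code{df_coord} (samples x DFs),
#'   \code{df_loadings} (PCs x DFs), \code{posterior} (rows sum to 1),
#'   \code{assigned} labels, \code{var_represented} (explained variance of
#'   retained PCs times the discriminated share), group centroids, and the
#'   inputs used.
#' @export
dapc_fit <- function(p, groups, n_pcs, n_df = NULL) {
  if (inherits(p, "genotype_dataset")) p <- pca(p)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups for a discriminant analysis")
  if (n_pcs > ncol(p$scores)) stop("n_pcs exceeds available PCs")
  max_df <- length(lev) - 1L
  if (is.null(n_df)) n_df <- max_df
  if (n_df > max_df) stop("n_df cannot exceed n_groups - 1")
  x <- p$scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(x)
  # pooled within-group covariance
  W <- matrix(0, n_pcs, n_pcs)
  centroids <- matrix(0, length(lev), n_pcs, dimnames = list(lev, NULL))
  for (g_ in lev) {
    xi <- x[groups == g_, , drop = FALSE]
    centroids[g_, ] <- colMeans(xi)
    if (nrow(xi) > 1)
      W <- W + crossprod(sweep(xi, 2, centroids[g_, ])) ## (n_g - 1) * cov
  }
  W <- W / (n - length(lev))
  ridge <- 0
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-10) {
    ridge <- 1e-8
    W <- W + diag(ridge, n_pcs)
    ew <- eigen(W, symmetric = TRUE)
  }
  Wm12 <- ew$vectors %*% diag(1 / sqrt(ew$values), n_pcs) %*% t(ew$vectors)
  # between-group covariance in whitened space
  mu <- colMeans(x)
  Bh <- matrix(0, n_pcs, n_pcs)
  for (g_ in lev) {
    d_ <- Wm12 %*% (centroids[g_, ] - mu)
    Bh <- Bh + sum(groups == g_) * tcrossprod(d_)
  }
  Bh <- Bh / n
  eb <- eigen(Bh, symmetric = TRUE)
  k <- seq_len(n_df)
  df_loadings <- Wm12 %*% eb$vectors[, k, drop = FALSE]
  # deterministic sign convention as in pca()
  for (c_ in k) {
    piv <- which.max(abs(df_loadings[, c_]))
    if (df_loadings[piv, c_] < 0) df_loadings[, c_] <- -df_loadings[, c_]
  }
  df_coord <- x %*% df_loadings
  colnames(df_coord) <- paste0("DF", k)
  cent_df <- centroids %*% df_loadings
  # Gaussian memberships: in the whitened metric along DFs the pooled
  # within covariance is identity, so squared Euclidean distance suffices
  d2 <- outer(rep(1, n), rep(0, length(lev)))
  for (g_ in seq_along(lev))
    d2[, g_] <- rowSums(sweep(df_coord, 2, cent_df[g_, ])^2)
  logp <- -d2 / 2
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp) / rowSums(exp(logp))
  colnames(post) <- lev
  rownames(post) <- rownames(x)
  assigned <- lev[max.col(post, ties.method = "first")]
  disc_share <- sum(eb$values[k]) / sum(pmax(eb$values, 0))
  var_repr <- sum(p$explained[seq_len(n_pcs)]) * disc_share
  structure(list(n_pcs = n_pcs, n_df = n_df, df_loadings = df_loadings,
                 df_coord = df_coord, posterior = post, assigned = assigned,
                 groups = groups, centroids_df = cent_df,
                 eigenvalues = eb$values[k], var_represented = var_repr,
                 ridge = ridge),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat("DAPC:", x$n_pcs, "PCs,", x$n_df, "discriminant functions\n")
  cat("variance represented:", sprintf("%.1f%%", 100 * x$var_represented), "\n")
  cat("correct reassignment:",
      sprintf("%.1f%%", 100 * mean(x$assigned == x$groups)), "\n")
  invisible(x)
}
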