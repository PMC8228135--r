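#' Pairwise identity-by-state (or PI_HAT) distance matrix
#'
#' Default: per pair of samples, IBS similarity is the mean over loci
#' genotyped in both of (2 - |g_a - g_b|) / 2 and the distance is
#' 1 - similarity. \code{method = "pi_hat"} instead estimates PLINK-style
#' identity-by-descent by the method of moments: the observed IBS 0/1/2
#' counts are compared with their expectations under Hardy-Weinberg
#' proportions at the sample allele frequencies (with PLINK's finite-sample
#' correction factors) to give P(IBD = 0/1/2), PI_HAT = P(IBD=1)/2 +
#' P(IBD=2), and distance 1 - PI_HAT.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param method \code{"ibs"} (default) or \code{"pi_hat"}.
#' @return A \code{\link{dist_matrix}}. Pairs sharing no genotyped locus
#'   get \code{NA} with a warning.
#' @export
ibs_distance_matrix <- function(ds, method = c("ibs", "pi_hat")) {
  method <- match.arg(method)
  g <- ds$genotypes
  if (nrow(g) < 2) stop("need at least 2 samples")
  # indicator matrices give all pairwise genotype-combination counts as
  # cross products: N[g=x][g=y] etc.
  I0 <- (!is.na(g) & g == 0L) * 1
  I1 <- (!is.na(g) & g == 1L) * 1
  I2 <- (!is.na(g) & g == 2L) * 1
  n00 <- tcrossprod(I0); n11 <- tcrossprod(I1); n22 <- tcrossprod(I2)
  n01 <- tcrossprod(I0, I1); n02 <- tcrossprod(I0, I2)
  n12 <- tcrossprod(I1, I2)
  ibs2 <- n00 + n11 + n22
  ibs1 <- n01 + t(n01) + n12 + t(n12)
  ibs0 <- n02 + t(n02)
  shared <- ibs0 + ibs1 + ibs2
  if (method == "ibs") {
    sim <- (2 * ibs2 + ibs1) / (2 * shared)
    d <- 1 - sim
  } else {
    p <- pi_hat_matrix(ds)
    d <- 1 - p
  }
  diag(d) <- 0
  if (any(shared[upper.tri(shared)] == 0)) {
    warning("sample pair(s) share no genotyped locus; distance set NA")
    d[shared == 0] <- NA_real_
    diag(d) <- 0
  }
  dimnames(d) <- list(ds$samples$sample_id, ds$samples$sample_id)
  dist_matrix(d, if (method == "ibs") "ibs" else "pi_hat")
}

# Method-of-moments P(IBD=0/1/2) from pairwise IBS counts under
# Hardy-Weinberg proportions at the sample allele frequencies.  Per-locus
# IBS-state probabilities conditional on the IBD state are summed over
# polymorphic loci and the observed counts peeled in order:
# P(Z=0) = N0 / E[N0|Z=0], then P(Z=1), then P(Z=2); estimates are
# truncated into the simplex.  (A simplified PLINK --genome: the
# finite-sample correction factors are omitted.)
pi_hat_matrix <- function(ds) {
  g <- ds$genotypes
  n_typed <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(n_typed, 1))
  valid <- n_typed >= 2 & p > 0 & p < 1
  p <- p[valid]; q <- 1 - p
  if (!length(p)) stop("no polymorphic locus available for PI_HAT")
  # expected counts per IBD state, summed over loci
  E00 <- sum(2 * p^2 * q^2)                  # E[N_IBS0 | Z=0]
  E10 <- sum(4 * p^3 * q + 4 * p * q^3)      # E[N_IBS1 | Z=0]
  E11 <- sum(2 * p^2 * q + 2 * p * q^2)      # E[N_IBS1 | Z=1]
  L <- length(p)
  # restrict observed counts to the same loci: recompute on the valid subset
  sub <- subset_dataset(ds, markers = which(valid))
  gs <- sub$genotypes
  I0 <- (!is.na(gs) & gs == 0L) * 1
  I1 <- (!is.na(gs) & gs == 1L) * 1
  I2 <- (!is.na(gs) & gs == 2L) * 1
  n01 <- tcrossprod(I0, I1); n12 <- tcrossprod(I1, I2)
  N2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  N1 <- n01 + t(n01) + n12 + t(n12)
  N0 <- tcrossprod(I0, I2); N0 <- N0 + t(N0)
  P0 <- N0 / E00
  P1 <- (N1 - P0 * E10) / E11
  P2 <- (N2 - P0 * (L - E00 - E10) - P1 * (L - E11)) / L
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- pmax(P0 + P1 + P2, .Machine$double.eps)
  P1 <- P1 / tot; P2 <- P2 / tot
  pi_hat <- P1 / 2 + P2
  diag(pi_hat) <- 1
  pi_hat
}

#' Mutual (or union) k-nearest-neighbour network
#'
#' From a symmetric distance matrix, each sample's k nearest neighbours are
#' found (ties at the k-th distance broken deterministically by sample-id
#' order); under the \code{"mutual"} rule an edge (a, b) is kept iff each is
#' among the other's k nearest, under \code{"union"} if either is. This is
#' the input graph of fine-scale network clustering of SNP relatedness.
#'
#' @param dm a \code{\link{dist_matrix}} over samples.
#' @param k neighbourhood size, 1 <= k < n.
#' @param rule \code{"mutual"} (default) or \code{"union"}.
#' @param groups optional named sample_id -> group vector stored as a node
#'   attribute.
#' @return list with \code{edges} (data.frame from, to, distance),
#'   \code{graph} (an igraph object with \code{group} vertex attribute),
#'   and \code{k}.
#' @export
knn_network <- function(dm, k, rule = c("mutual", "union"), groups = NULL) {
  rule <- match.arg(rule)
  m <- dm$matrix
  n <- nrow(m)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  ids <- dm$labels
  neigh <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    o <- order(m[i, -i], ids[-i])      # ties by sample-id order
    neigh[i, (seq_len(n)[-i])[o[seq_len(k)]]] <- TRUE
  }
  adj <- if (rule == "mutual") neigh & t(neigh) else neigh | t(neigh)
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      distance = m[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  gr <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  if (!is.null(groups))
    igraph::V(gr)$group <- unname(groups[ids])
  list(edges = edges, graph = gr, k = k, rule = rule)
}

#' Write a k-NN network as edge list TSV and GraphML
#'
#' @param net result of \code{\link{knn_network}}.
#' @param prefix output path prefix (writes \code{<prefix>_edges.tsv} and
#'   \code{<prefix>.graphml}).
#' @return \code{prefix}, invisibly.
#' @export
write_network <- function(net, prefix) {
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(net$graph, paste0(prefix, ".graphml"),
                      format = "graphml")
  invisible(prefix)
}
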