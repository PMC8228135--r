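#' Read a gene panel table
#'
#' BED-like TSV with columns chromosome, start_bp, end_bp, gene, category.
#' Categories follow the four phenotype groups used for breed
#' stratification: ATO (aerobic trainability), BM (behaviour and
#' motivation), CC (coat colour), SE (strength and endurance); other labels
#' are accepted.
#'
#' @param path TSV file path.
#' @return data.frame with the five columns, validated (start <= end).
#' @export
read_gene_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character"))
  req <- c("chromosome", "start_bp", "end_bp", "gene", "category")
  if (!all(req %in% names(tab)))
    stop("panel file must have columns: ", paste(req, collapse = ", "))
  if (any(tab$start_bp > tab$end_bp)) stop("gene with start > end")
  tab
}

#' Path of the packaged synthetic example panel
#'
#' The four phenotype categories with their candidate-gene symbols, on
#' synthetic placeholder coordinates matching the generator's default
#' 38 x 60 Mbp genome. Real-genome coordinates must be supplied by the user
#' for real data.
#'
#' @return file path of the installed panel TSV.
#' @export
example_gene_panel <- function() {
  system.file("extdata", "gene_panel_synthetic.tsv", package = "canid",
              mustWork = TRUE)
}

#' Map SNPs to candidate genes
#'
#' A SNP belongs to a gene iff the chromosome matches and
#' start_bp <= position <= end_bp (closed interval). SNPs inside
#' overlapping genes are assigned to all of them and flagged. Interval
#' overlap is resolved with IRanges.
#'
#' @param markers marker map data.frame (as in
#'   \code{\link{genotype_dataset}}).
#' @param panel gene panel data.frame (see \code{\link{read_gene_panel}}).
#' @return list with \code{assignments} (marker_id, gene, category,
#'   multi_gene flag) and \code{by_category} (named list of marker_id
#'   vectors, one per category; empty categories are dropped with a
#'   warning).
#' @export
map_snps_to_genes <- function(markers, panel) {
  hits <- list()
  for (chrom in unique(panel$chromosome)) {
    mi <- which(markers$chromosome == chrom)
    pi_ <- which(panel$chromosome == chrom)
    if (!length(mi) || !length(pi_)) next
    q <- IRanges::IRanges(start = markers$position[mi], width = 1L)
    s <- IRanges::IRanges(start = panel$start_bp[pi_],
                          end = panel$end_bp[pi_])
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    hits[[chrom]] <- data.frame(
      marker_id = markers$marker_id[mi[S4Vectors::from(ov)]],
      gene = panel$gene[pi_[S4Vectors::to(ov)]],
      category = panel$category[pi_[S4Vectors::to(ov)]],
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(hits)) do.call(rbind, hits) else
    data.frame(marker_id = character(), gene = character(),
               category = character(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  dup <- assignments$marker_id %in%
    assignments$marker_id[duplicated(assignments$marker_id)]
  assignments$multi_gene <- dup
  cats <- unique(panel$category)
  by_category <- lapply(cats, function(cc)
    unique(assignments$marker_id[assignments$category == cc]))
  names(by_category) <- cats
  empty <- lengths(by_category) == 0
  if (any(empty)) {
    warning("no SNPs in categor", if (sum(empty) > 1) "ies " else "y ",
            paste(cats[empty], collapse = ", "), "; skipped")
    by_category <- by_category[!empty]
  }
  list(assignments = assignments, by_category = by_category)
}

#' PCA restricted to a panel's SNPs
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param subset marker ids (or indices) of the panel.
#' @param ... passed to \code{\link{pca}}.
#' @return A \code{pca_result} computed only on the subset columns.
#' @export
panel_pca <- function(ds, subset, ...) {
  if (length(subset) == 0) stop("empty marker subset")
  pca(subset_dataset(ds, markers = subset), ...)
}

#' Principal-axis factor analysis of panel SNPs
#'
#' Factoring of the marker (or gene-aggregated) correlation matrix by
#' iterated principal axes: communalities start at the squared multiple
#' correlations, the reduced correlation matrix is eigendecomposed, and the
#' first \code{n_factors} axes are iterated until the communalities
#' stabilise (max 100 iterations). Optional varimax rotation. With
#' \code{aggregate = "gene"}, dosages are first averaged within each gene so
#' that each gene enters as one variable — the "each gene as a factor"
#' stratification view; \code{n_factors} then defaults to the number of
#' genes.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param assignments marker-to-gene assignment data.frame from
#'   \code{\link{map_snps_to_genes}} (possibly filtered to one category).
#' @param n_factors number of factors; default: number of genes.
#' @param rotation \code{"none"} or \code{"varimax"}.
#' @param aggregate \code{"marker"} (one variable per SNP) or \code{"gene"}
#'   (gene-mean dosage).
#' @param max_iter communality iteration cap.
#' @param tol communality convergence tolerance.
#' @return A \code{factor_result}: loadings, per-sample scores (regression
#'   method), communalities, rotation tag.
#' @export
factor_analysis <- function(ds, assignments, n_factors = NULL,
                            rotation = c("none", "varimax"),
                            aggregate = c("marker", "gene"),
                            max_iter = 100, tol = 1e-3) {
  rotation <- match.arg(rotation)
  aggregate <- match.arg(aggregate)
  genes <- unique(assignments$gene)
  if (is.null(n_factors)) n_factors <- length(genes)
  keep <- assignments$marker_id[assignments$marker_id %in%
                                  ds$markers$marker_id]
  if (!length(keep)) stop("no panel markers present in the dataset")
  sub <- subset_dataset(ds, markers = unique(keep))
  x <- sub$genotypes
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  if (aggregate == "gene") {
    gmap <- assignments$gene[match(colnames(x), assignments$marker_id)]
    x <- sapply(genes, function(g_) {
      cols <- which(gmap == g_)
      if (!length(cols)) return(rep(NA_real_, nrow(x)))
      rowMeans(x[, cols, drop = FALSE])
    })
    x <- x[, colSums(is.na(x)) == 0, drop = FALSE]
  }
  # drop constant variables (zero variance breaks the correlation matrix)
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) < 2) stop("need >= 2 variable columns for factor analysis")
  n_factors <- min(n_factors, ncol(x) - 1)
  R <- stats::cor(x)
  # initial communalities: squared multiple correlations
  h2 <- tryCatch({
    Ri <- solve(R)
    1 - 1 / diag(Ri)
  }, error = function(e) rep(0.5, ncol(R)))
  h2 <- pmin(pmax(h2, 0.01), 0.99)
  conv <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    k <- seq_len(n_factors)
    lam <- e$vectors[, k, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[k], 0)), n_factors)
    h2_new <- pmin(rowSums(lam^2), 0.995)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) { conv <- TRUE; break }
  }
  if (!conv)
    stop("communalities did not converge after ", max_iter,
         " iterations; last max change ", signif(delta, 3))
  rownames(lam) <- colnames(x)
  colnames(lam) <- paste0("F", seq_len(n_factors))
  if (rotation == "varimax" && n_factors > 1) {
    rot <- stats::varimax(lam)
    lam <- lam %*% rot$rotmat
    dimnames(lam) <- list(colnames(x), paste0("F", seq_len(n_factors)))
  }
  # regression-method factor scores
  scores <- scale(x) %*% solve(R, lam)
  colnames(scores) <- colnames(lam)
  structure(list(loadings = lam, scores = scores, communalities = h2,
                 rotation = rotation, aggregate = aggregate,
                 n_factors = n_factors, variables = colnames(x)),
            class = "factor_result")
}
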