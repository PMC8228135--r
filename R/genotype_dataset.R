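#' Construct a genotype dataset
#'
#' The central container of the package: a samples-by-markers matrix of
#' counted-allele dosages together with a marker map and a sample table.
#' Dosages count copies of the A1 allele, so values are 0, 1, 2 or \code{NA}
#' (missing). Markers are kept sorted by (chromosome, position); positions
#' are 1-based as in PLINK MAP/BIM files.
#'
#' @param genotypes integer matrix, one row per sample, one column per
#'   marker, values in \{0, 1, 2, NA\}.
#' @param markers data.frame with columns \code{marker_id}, \code{chromosome}
#'   (character), \code{position} (base pairs), \code{a1}, \code{a2}
#'   (allele codes; \code{a1} is the counted allele).
#' @param samples data.frame with columns \code{sample_id} and \code{group}.
#' @param sort_markers sort columns by (chromosome, position)? Default TRUE.
#'
#' @return An object of class \code{genotype_dataset}: a list with elements
#'   \code{genotypes}, \code{markers}, \code{samples}.
#' @export
genotype_dataset <- function(genotypes, markers, samples, sort_markers = TRUE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req_m <- c("marker_id", "chromosome", "position", "a1", "a2")
  if (!all(req_m %in% names(markers)))
    stop("markers must have columns: ", paste(req_m, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples must have columns: sample_id, group")
  markers$chromosome <- as.character(markers$chromosome)
  markers$position <- as.integer(markers$position)
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (nrow(genotypes) != nrow(samples))
    stop("genotype rows (", nrow(genotypes), ") != samples (", nrow(samples), ")")
  if (ncol(genotypes) != nrow(markers))
    stop("genotype columns (", ncol(genotypes), ") != markers (", nrow(markers), ")")
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker_ids")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_ids")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- markers$marker_id
  if (sort_markers) {
    ord <- order(chrom_order(markers$chromosome), markers$position)
    markers <- markers[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
  }
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  structure(list(genotypes = genotypes, markers = markers, samples = samples),
            class = "genotype_dataset")
}

# numeric chromosome labels sort numerically, others after, alphabetically
chrom_order <- function(chr) {
  u <- unique(chr)
  num <- suppressWarnings(as.numeric(u))
  u <- u[order(ifelse(is.na(num), Inf, num), u)]
  match(chr, u)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "markers\n")
  grp <- table(x$samples$group)
  cat("groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("chromosomes:", length(unique(x$markers$chromosome)),
      " missing rate:", signif(mean(is.na(x$genotypes)), 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

n_samples <- function(ds) nrow(ds$genotypes)
n_markers <- function(ds) ncol(ds$genotypes)

#' Subset a genotype dataset
#'
#' @param ds a \code{genotype_dataset}.
#' @param samples sample indices, logical mask, or sample_ids to keep.
#' @param markers marker indices, logical mask, or marker_ids to keep.
#' @return A \code{genotype_dataset} restricted to the selection.
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  si <- resolve_index(samples, ds$samples$sample_id)
  mi <- resolve_index(markers, ds$markers$marker_id)
  genotype_dataset(ds$genotypes[si, mi, drop = FALSE],
                   ds$markers[mi, , drop = FALSE],
                   ds$samples[si, , drop = FALSE],
                   sort_markers = FALSE)
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.logical(idx)) return(which(idx))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ids: ", paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  as.integer(idx)
}

#' Restrict a dataset to autosomes
#'
#' @param ds a \code{genotype_dataset}.
#' @param autosomes character vector of chromosome labels to keep
#'   (default \code{"1"}--\code{"38"}, the dog autosomes).
#' @return Filtered \code{genotype_dataset}.
#' @export
filter_autosomes <- function(ds, autosomes = as.character(1:38)) {
  keep <- ds$markers$chromosome %in% autosomes
  if (!any(keep)) stop("no autosomal markers left")
  subset_dataset(ds, markers = keep)
}

#' Total autosomal genome span covered by the markers
#'
#' Per chromosome the span is max(position) - min(position); the total is the
#' sum over chromosomes. A chromosome represented by fewer than two markers
#' contributes a span of 0 with a warning.
#'
#' @param ds a \code{genotype_dataset}.
#' @return list with \code{total_bp} and a per-chromosome data.frame
#'   \code{per_chromosome} (chromosome, n_markers, span_bp).
#' @export
genome_span <- function(ds) {
  sp <- lapply(split(ds$markers$position, ds$markers$chromosome), function(p) {
    c(n = length(p), span = if (length(p) >= 2) max(p) - min(p) else 0)
  })
  chrs <- names(sp)
  tab <- data.frame(chromosome = chrs,
                    n_markers = vapply(sp, `[[`, 0, "n"),
                    span_bp = vapply(sp, `[[`, 0, "span"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(tab$n_markers < 2))
    warning("chromosome(s) with <2 markers have span 0: ",
            paste(tab$chromosome[tab$n_markers < 2], collapse = ", "))
  tab <- tab[order(chrom_order(tab$chromosome)), ]
  rownames(tab) <- NULL
  list(total_bp = sum(tab$span_bp), per_chromosome = tab)
}
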