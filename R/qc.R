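#' Intersect marker sets and merge datasets
#'
#' Keeps exactly the markers present in every input, harmonizes counted
#' alleles to the first dataset's A1/A2 (complementing dosages d -> 2 - d
#' where A1/A2 are reversed), and concatenates samples. Markers whose allele
#' pairs cannot be reconciled — including strand-ambiguous A/T and C/G pairs
#' when the codes differ — are dropped and counted.
#'
#' @param datasets list of \code{\link{genotype_dataset}} objects (>= 2).
#' @return list with \code{dataset} (merged \code{genotype_dataset}) and
#'   \code{report} (a \code{\link{qc_report}}).
#' @export
intersect_and_merge <- function(datasets) {
  if (length(datasets) < 2) stop("need at least 2 datasets")
  ids <- Reduce(intersect, lapply(datasets, function(d) d$markers$marker_id))
  if (length(ids) == 0) stop("empty marker intersection")
  ref <- datasets[[1]]
  ref_idx <- match(ids, ref$markers$marker_id)
  a1 <- ref$markers$a1[ref_idx]; a2 <- ref$markers$a2[ref_idx]
  keep <- rep(TRUE, length(ids))
  genolist <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    mi <- match(ids, d$markers$marker_id)
    g <- d$genotypes[, mi, drop = FALSE]
    if (k > 1) {
      b1 <- d$markers$a1[mi]; b2 <- d$markers$a2[mi]
      same <- allele_match(a1, a2, b1, b2)
      flip <- allele_match(a1, a2, b2, b1)
      g[, flip & !same] <- 2L - g[, flip & !same, drop = FALSE]
      keep <- keep & (same | flip)
    }
    genolist[[k]] <- g
  }
  n_conflict <- sum(!keep)
  geno <- do.call(rbind, lapply(genolist, function(g) g[, keep, drop = FALSE]))
  markers <- ref$markers[ref_idx, , drop = FALSE][keep, , drop = FALSE]
  samples <- do.call(rbind, lapply(datasets, function(d) d$samples))
  out <- genotype_dataset(geno, markers, samples)
  total_in <- vapply(datasets, n_markers, 0L)
  report <- qc_report(
    n_markers_in = length(ids), n_markers_out = sum(keep),
    n_samples_in = nrow(samples), n_samples_out = nrow(samples),
    removed = list(allele_conflict = n_conflict),
    thresholds = list(),
    notes = sprintf("marker intersection of %s input sets (sizes %s) -> %d common",
                    length(datasets), paste(total_in, collapse = "/"),
                    length(ids)))
  list(dataset = out, report = report)
}

# do (a1,a2) and (b1,b2) denote the same allele pair in the same orientation?
# "0" (unknown allele, monomorphic marker) matches anything.
allele_match <- function(a1, a2, b1, b2) {
  (a1 == b1 | a1 == "0" | b1 == "0") & (a2 == b2 | a2 == "0" | b2 == "0")
}

#' Missingness quality control
#'
#' Removes samples whose missing-genotype fraction exceeds
#' \code{max_sample_missing}, then markers whose missing fraction (computed
#' on the surviving samples) exceeds \code{max_marker_missing}. Strictly
#' greater-than removes; equality retains (the PLINK \code{--mind}/
#' \code{--geno} convention). The order is configurable.
#'
#' @param ds a \code{\link{genotype_dataset}}.
#' @param max_sample_missing,max_marker_missing fractions in [0, 1];
#'   default 0.10 each.
#' @param order \code{"samples_first"} (default) or \code{"markers_first"}.
#' @return list with \code{dataset} and \code{report}
#'   (a \code{\link{qc_report}}).
#' @export
filter_missingness <- function(ds, max_sample_missing = 0.10,
                               max_marker_missing = 0.10,
                               order = c("samples_first", "markers_first")) {
  order <- match.arg(order)
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1,
            max_marker_missing >= 0, max_marker_missing <= 1)
  n_in <- n_samples(ds); m_in <- n_markers(ds)
  pass1 <- function(d, axis) {
    miss <- is.na(d$genotypes)
    if (axis == "samples") {
      frac <- rowMeans(miss)
      keep <- frac <= max_sample_missing
      if (!any(keep)) stop("all samples removed by missingness filter")
      list(ds = subset_dataset(d, samples = keep), removed = sum(!keep))
    } else {
      frac <- colMeans(miss)
      keep <- frac <= max_marker_missing
      if (!any(keep)) stop("all markers removed by missingness filter")
      list(ds = subset_dataset(d, markers = keep), removed = sum(!keep))
    }
  }
  axes <- if (order == "samples_first") c("samples", "markers")
          else c("markers", "samples")
  removed <- c(samples = 0L, markers = 0L)
  for (ax in axes) {
    step <- pass1(ds, ax)
    ds <- step$ds
    removed[[ax]] <- step$removed
  }
  report <- qc_report(
    n_markers_in = m_in, n_markers_out = n_markers(ds),
    n_samples_in = n_in, n_samples_out = n_samples(ds),
    removed = list(samples_missingness = unname(removed["samples"]),
                   markers_missingness = unname(removed["markers"])),
    thresholds = list(max_sample_missing = max_sample_missing,
                      max_marker_missing = max_marker_missing,
                      order = order))
  list(dataset = ds, report = report)
}

#' QC accounting record
#'
#' @param n_markers_in,n_markers_out,n_samples_in,n_samples_out counts.
#' @param removed named list of per-filter removal counts.
#' @param thresholds named list of thresholds used.
#' @param notes optional free-text note.
#' @return A \code{qc_report} object; its counts always reconcile
#'   (in = out + removed per axis), enforced at construction.
#' @export
qc_report <- function(n_markers_in, n_markers_out, n_samples_in,
                      n_samples_out, removed = list(), thresholds = list(),
                      notes = NULL) {
  x <- structure(list(n_markers_in = as.integer(n_markers_in),
                      n_markers_out = as.integer(n_markers_out),
                      n_samples_in = as.integer(n_samples_in),
                      n_samples_out = as.integer(n_samples_out),
                      removed = removed, thresholds = thresholds,
                      notes = notes),
                 class = "qc_report")
  rs <- sum(unlist(removed[grepl("sample", names(removed))]))
  rm_ <- sum(unlist(removed[grepl("marker|allele", names(removed))]))
  if (x$n_samples_in - rs != x$n_samples_out)
    stop("qc_report sample counts do not reconcile")
  if (x$n_markers_in - rm_ != x$n_markers_out)
    stop("qc_report marker counts do not reconcile")
  x
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  markers: %d in -> %d out\n", x$n_markers_in, x$n_markers_out))
  cat(sprintf("  samples: %d in -> %d out\n", x$n_samples_in, x$n_samples_out))
  for (nm in names(x$removed))
    cat(sprintf("  removed [%s]: %d\n", nm, x$removed[[nm]]))
  if (!is.null(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

#' Write a QC report as TSV and JSON
#'
#' @param report a \code{\link{qc_report}}.
#' @param prefix output path prefix (writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}).
#' @return \code{prefix}, invisibly.
#' @export
write_qc_report <- function(report, prefix) {
  flat <- data.frame(
    field = c("n_markers_in", "n_markers_out", "n_samples_in", "n_samples_out",
              paste0("removed_", names(report$removed))),
    value = c(report$n_markers_in, report$n_markers_out, report$n_samples_in,
              report$n_samples_out, unlist(report$removed, use.names = FALSE)))
  utils::write.table(flat, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), paste0(prefix, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(prefix)
}
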