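#' Pipeline run configuration
#'
#' Bundles every stage's parameters with the input specification and the
#' seed. Defaults reproduce the standard analysis settings: ROH runs of at
#' least 500 kb with gaps up to 1000 kb and alpha 0.05; pairwise
#' Weir-Cockerham F_ST plus Nei distances; DAPC with automatic alpha-score
#' PC choice; admixture over K = 1..10 with 10 replicate runs; a mutual
#' k-NN network at k = 15. Unknown keys are rejected.
#'
#' @param input either a \code{\link{genotype_dataset}} or a list
#'   \code{list(prefix =, dialect =)} for \code{\link{read_plink}}.
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory for report files (created if needed), or
#'   NULL to skip file output.
#' @param qc list(max_sample_missing, max_marker_missing).
#' @param roh list overriding \code{\link{roh_params}} arguments.
#' @param nei_method \code{"nei1972"} or \code{"nei1983"}.
#' @param dapc list(n_pcs = "auto" or integer, candidate_n_pcs,
#'   n_permutations).
#' @param admixture list(k_range, n_replicates, max_iter, tol).
#' @param network list(k, rule, method).
#' @param panel optional gene panel data.frame or TSV path.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(input, seed, out_dir = NULL,
                       qc = list(), roh = list(), nei_method = "nei1972",
                       dapc = list(), admixture = list(), network = list(),
                       panel = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  merge_block <- function(defaults, user, name) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown ", name, " config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    input = input, seed = as.integer(seed), out_dir = out_dir,
    qc = merge_block(list(max_sample_missing = 0.10,
                          max_marker_missing = 0.10), qc, "qc"),
    roh = merge_block(list(min_length_bp = 500000, max_gap_bp = 1000000,
                           min_density_bp_per_snp = 5000000,
                           min_snps = NULL, alpha = 0.05), roh, "roh"),
    nei_method = match.arg(nei_method, c("nei1972", "nei1983")),
    dapc = merge_block(list(n_pcs = "auto", candidate_n_pcs = NULL,
                            n_permutations = 25), dapc, "dapc"),
    admixture = merge_block(list(k_range = 1:10, n_replicates = 10,
                                 max_iter = 2000, tol = 1e-6),
                            admixture, "admixture"),
    network = merge_block(list(k = 15, rule = "mutual", method = "ibs"),
                          network, "network"),
    panel = panel)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes QC, ROH detection and F_ROH, pairwise F_ST and Nei distances
#' (combined two-triangle table), DAPC, the admixture scan with Evanno
#' delta-K, the k-NN network, and (when a panel is configured) the
#' gene-panel analyses. Deterministic given the config seed. When
#' \code{config$out_dir} is set, each table is written as TSV alongside a
#' provenance JSON recording parameters, seed and input checksum. The input
#' dataset is never mutated.
#'
#' @param config a \code{\link{run_config}}.
#' @return A report bundle (list): \code{qc_report}, \code{roh}
#'   (segments, class summary, froh), \code{distances} (fst, nei,
#'   combined), \code{dapc}, \code{admixture} (runs table, delta_k,
#'   by_group), \code{network}, optional \code{panels}, and
#'   \code{provenance}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds0 <- if (inherits(config$input, "genotype_dataset")) config$input
         else read_plink(config$input$prefix, config$input$dialect)
  input_checksum <- dataset_checksum(ds0)

  qc <- filter_missingness(ds0, config$qc$max_sample_missing,
                           config$qc$max_marker_missing)
  ds <- qc$dataset
  groups <- stats::setNames(ds$samples$group, ds$samples$sample_id)

  rp <- do.call(roh_params, config$roh)
  segs <- detect_roh(ds, rp)
  span <- genome_span(ds)
  cls <- classify_roh(segs, groups = groups)
  fr <- froh(segs, span$total_bp, sample_ids = ds$samples$sample_id,
             groups = groups)

  fst <- wc_fst_pairwise(ds, seed = config$seed)
  nei <- nei_distance(allele_freqs(ds), method = config$nei_method)
  combined <- combined_distance_table(fst, nei)

  p <- pca(ds)
  lev <- unique(ds$samples$group)
  npc <- config$dapc$n_pcs
  ascore <- NULL
  if (identical(npc, "auto")) {
    cand <- config$dapc$candidate_n_pcs
    if (is.null(cand)) {
      top <- min(n_pcs_for_variance(p, 0.95), ncol(p$scores),
                 n_samples(ds) - 2)
      cand <- unique(pmax(1, round(seq(2, top, length.out = min(8, top)))))
    }
    ascore <- a_score(ds, ds$samples$group, cand,
                      n_permutations = config$dapc$n_permutations,
                      seed = config$seed)
    npc <- ascore$recommended
  }
  dap <- dapc_fit(p, ds$samples$group, n_pcs = npc)

  runs <- admixture_scan(ds, k_range = config$admixture$k_range,
                         n_replicates = config$admixture$n_replicates,
                         seed = config$seed,
                         max_iter = config$admixture$max_iter,
                         tol = config$admixture$tol)
  dk <- if (length(unique(vapply(runs, `[[`, 0L, "K"))) >= 3)
    evanno_delta_k(runs) else NULL
  best_k <- if (!is.null(dk)) dk$selected_k else max(vapply(runs, `[[`, 0L, "K"))
  cand_runs <- Filter(function(r) r$K == best_k, runs)
  best_run <- cand_runs[[which.max(vapply(cand_runs, `[[`, 0, "loglik"))]]
  by_group <- admixture_by_group(best_run$Q, ds$samples$group)

  dm <- ibs_distance_matrix(ds, method = config$network$method)
  k_used <- min(config$network$k, n_samples(ds) - 1)
  net <- knn_network(dm, k = k_used, rule = config$network$rule,
                     groups = groups)

  panels <- NULL
  if (!is.null(config$panel)) {
    panel <- if (is.character(config$panel)) read_gene_panel(config$panel)
             else config$panel
    mp <- map_snps_to_genes(ds$markers, panel)
    panels <- list(mapping = mp, pca = list(), fa = list())
    for (cc in names(mp$by_category)) {
      sub <- mp$by_category[[cc]]
      panels$pca[[cc]] <- panel_pca(ds, sub)
      asg <- mp$assignments[mp$assignments$category == cc, , drop = FALSE]
      panels$fa[[cc]] <- tryCatch(
        factor_analysis(ds, asg, rotation = "varimax", aggregate = "gene"),
        error = function(e) e)
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("canid")),
    seed = config$seed, input_checksum = input_checksum,
    n_samples = n_samples(ds), n_markers = n_markers(ds),
    parameters = config[c("qc", "roh", "nei_method", "dapc", "admixture",
                          "network")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  bundle <- list(qc_report = qc$report,
                 roh = list(segments = cls$segments, summary = cls$summary,
                            froh = fr, genome_span_bp = span$total_bp,
                            min_snps = attr(segs, "min_snps")),
                 distances = list(fst = fst, nei = nei, combined = combined),
                 dapc = list(fit = dap, a_score = ascore, n_pcs = npc),
                 admixture = list(delta_k = dk, best_k = best_k,
                                  best_run = best_run, by_group = by_group,
                                  logliks = data.frame(
                                    K = vapply(runs, `[[`, 0L, "K"),
                                    seed = vapply(runs, `[[`, 0L, "seed"),
                                    loglik = vapply(runs, `[[`, 0, "loglik"))),
                 network = net, panels = panels, provenance = provenance)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

dataset_checksum <- function(ds) {
  g <- ds$genotypes
  g[is.na(g)] <- 3L
  sprintf("%.0f", sum(as.numeric(g) * (seq_along(g) %% 97 + 1)))
}

# write the six report artifacts as TSV plus a provenance JSON
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(bundle$roh$summary, "roh_class_summary.tsv")
  w(bundle$roh$segments, "roh_segments.tsv")
  w(bundle$roh$froh$per_sample, "froh_per_sample.tsv")
  if (!is.null(bundle$roh$froh$per_group))
    w(bundle$roh$froh$per_group, "froh_per_group.tsv")
  comb <- bundle$distances$combined
  w(cbind(unit = rownames(comb), as.data.frame(comb)),
    "distance_table_fst_below_nei_above.tsv")
  w(cbind(sample_id = rownames(bundle$dapc$fit$df_coord),
          as.data.frame(bundle$dapc$fit$df_coord),
          assigned = bundle$dapc$fit$assigned),
    "dapc_coordinates.tsv")
  if (!is.null(bundle$admixture$delta_k))
    w(bundle$admixture$delta_k$table, "evanno_delta_k.tsv")
  w(cbind(group = rownames(bundle$admixture$by_group),
          as.data.frame(bundle$admixture$by_group)),
    "admixture_by_group.tsv")
  qm <- bundle$admixture$best_run$Q
  w(data.frame(sample_id = rownames(bundle$dapc$fit$posterior), qm),
    "admixture_q_matrix.tsv")
  w(bundle$network$edges, "network_edges.tsv")
  write_qc_report(bundle$qc_report, file.path(out_dir, "qc_report"))
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}
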