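#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the synthetic cohort (or a
#' directory written by [write_cohort()]), significance levels, filter
#' thresholds, the PCSF grid and an output directory.
#'
#' @param cohort a [cohort_config()] (the cohort is generated), a
#'   `cohort_bundle`, or a directory path readable by [read_cohort()].
#' @param alpha expression ANOVA significance level.
#' @param phospho_alpha phosphosite significance level.
#' @param min_targets TF terminal gate.
#' @param expr_thresh expression filter threshold.
#' @param hub_deg_thresh,hub_sd_mult hub-removal parameters.
#' @param grid list of [pcsf_params()].
#' @param hub_degree degree cutoff for "hub" counting during grid selection.
#' @param ss_floor separation floor for the sensitivity regression.
#' @param out_dir optional directory; when given, per-condition artifacts
#'   and summary tables are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), alpha = 0.05,
                            phospho_alpha = 0.05, min_targets = 3,
                            expr_thresh = 2.0, hub_deg_thresh = 900,
                            hub_sd_mult = 10, grid = default_pcsf_grid(),
                            hub_degree = 100, ss_floor = -0.45,
                            out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, phospho_alpha > 0, phospho_alpha < 1,
            expr_thresh >= 0, length(grid) > 0)
  structure(list(cohort = cohort, alpha = alpha, phospho_alpha = phospho_alpha,
                 min_targets = min_targets, expr_thresh = expr_thresh,
                 hub_deg_thresh = hub_deg_thresh, hub_sd_mult = hub_sd_mult,
                 grid = grid, hub_degree = hub_degree, ss_floor = ss_floor,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full reconstruction-and-comparison pipeline
#'
#' Fixed stage order: cohort -> terminal sets -> condition-specific
#' interactome refinement (hub removal, expression filter, link prediction,
#' localization filter, augmentation) -> PCSF grid reconstruction ->
#' separation matrix -> pathway enrichment -> MoA benchmark, combination
#' rating and sensitivity association. Conditions whose terminal sets are
#' infeasible (no omics-derived terminal) are skipped and reported, as are
#' conditions where every grid point is infeasible.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_result` manifest: the bundle, per-condition terminal
#'   sets and networks, the separation matrix, enrichments, evaluation
#'   results and the dropped-condition log.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  bundle <- cfg$cohort
  if (inherits(bundle, "cohort_config")) bundle <- generate_cohort(bundle)
  else if (is.character(bundle)) bundle <- read_cohort(bundle)
  stopifnot(inherits(bundle, "cohort_bundle"))

  ref <- bundle$interactome
  hub <- remove_hubs(ref, deg_thresh = cfg$hub_deg_thresh,
                     sd_mult = cfg$hub_sd_mult)

  terminals <- list(); networks <- list(); dropped <- list()
  for (key in names(bundle$panels)) {
    cond <- bundle$panels[[key]]$condition
    ts <- tryCatch(
      build_terminal_set(bundle, cond[["cell_line"]], cond[["drug"]],
                         alpha = cfg$alpha, phospho_alpha = cfg$phospho_alpha,
                         min_targets = cfg$min_targets),
      error = function(e) e)
    if (inherits(ts, "error")) {
      dropped[[key]] <- paste("terminals:", conditionMessage(ts))
      next
    }
    expr <- rowMeans(bundle$panels[[key]]$treated)
    prep <- prepare_interactome(hub$graph, expr, bundle$localization,
                                expr_thresh = cfg$expr_thresh,
                                deg_thresh = Inf)  # hubs already removed once
    net <- tryCatch(
      grid_reconstruct(prep$graph, ts, grid = cfg$grid,
                       hub_degree = cfg$hub_degree),
      error = function(e) e)
    if (inherits(net, "error")) {
      dropped[[key]] <- paste("pcsf:", conditionMessage(net))
      next
    }
    if (nrow(net$nodes) == 0) {
      dropped[[key]] <- "pcsf: empty merged network"
      next
    }
    terminals[[key]] <- ts
    networks[[key]] <- net
  }
  if (length(networks) < 2)
    stop("pipeline aborted at comparison stage: fewer than 2 reconstructed networks")

  sep <- separation_matrix(networks, ref, moa = bundle$moa_labels)
  gsc <- gene_set_collection(bundle$gene_sets, universe = igraph::V(ref)$name)
  enrichments <- lapply(networks, function(net) enrich(network_nodes(net), gsc))

  sweep <- sweep_thresholds(sep, bundle$moa_labels)
  combos <- predict_combinations(networks, enrichments, sep,
                                 drivers = bundle$driver_genes,
                                 signaling_filter = NULL)
  sens <- tryCatch(sensitivity_association(sep, bundle$sensitivity,
                                           ss_floor = cfg$ss_floor),
                   error = function(e) conditionMessage(e))

  res <- structure(list(config = cfg, bundle = bundle,
                        removed_hubs = hub$removed,
                        terminals = terminals, networks = networks,
                        separation = sep, enrichments = enrichments,
                        moa_sweep = sweep, combinations = combos,
                        sensitivity = sens, dropped = dropped),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result: ", length(x$networks), " reconstructed networks (",
      length(x$dropped), " condition(s) dropped)\n", sep = "")
  cat("  MoA benchmark: AUC", round(x$moa_sweep$auc, 3),
      "| best threshold", round(x$moa_sweep$best$threshold, 3),
      "| MCC", round(x$moa_sweep$best$mcc, 3), "\n")
  if (is.list(x$sensitivity))
    cat("  Sensitivity regression: R =", round(x$sensitivity$R, 3),
        "(p =", format(x$sensitivity$p_value, digits = 3),
        ", n =", x$sensitivity$n, ")\n")
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$separation$scores,
                   file.path(out_dir, "separation_matrix.csv"))
  utils::write.table(res$separation$details,
                     file.path(out_dir, "separation_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$moa_sweep$curve,
                     file.path(out_dir, "moa_threshold_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$combinations))
    utils::write.table(res$combinations,
                       file.path(out_dir, "combination_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(res$networks)) {
    slug <- gsub("::", "__", key, fixed = TRUE)
    utils::write.table(res$networks[[key]]$edges,
                       file.path(out_dir, paste0("network_", slug, "_edges.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$networks[[key]]$nodes,
                       file.path(out_dir, paste0("network_", slug, "_nodes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
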