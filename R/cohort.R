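#' Configuration of a synthetic drug-perturbation cohort
#'
#' The generator emulates the statistical structure of a small-molecule
#' perturbation study: a confidence-weighted scale-free interactome with
#' planted pathway modules, replicate fluorescence-scale expression panels
#' (drug vs DMSO control), phosphoprotein fold-change tables, a TF-to-target
#' regulatory network, drug-target and localization annotations, MoA class
#' labels, cancer-driver genes and drug-sensitivity z-scores.
#'
#' Pathway modules are laid out on a ring with cross-talk bridges between
#' adjacent modules; each MoA class owns a contiguous block of modules, every
#' drug perturbs its class's modules, and a cell line's sensitivity to a drug
#' decays with the ring distance between the drug's modules and the cell
#' line's driver module.
#'
#' @param n_proteins number of proteins in the interactome.
#' @param n_pathway_modules number of planted pathway modules.
#' @param module_size proteins per module.
#' @param n_tfs number of transcription factors.
#' @param n_drugs number of drugs.
#' @param n_cell_lines number of cell lines.
#' @param n_moa_classes number of mechanism-of-action classes.
#' @param n_replicates replicates per arm per condition.
#' @param effect_size expression shift (log2-scale fluorescence units) applied
#'   to genes of a drug's planted modules.
#' @param noise_sd replicate noise standard deviation.
#' @param baseline_range interval of baseline expression values; the scale on
#'   which the expression filter threshold (2.0) is interpreted.
#' @param frac_phospho fraction of a drug's module proteins carrying phospho
#'   read-outs.
#' @param n_compartments number of subcellular compartments.
#' @param frac_unlocalized fraction of proteins left without localization.
#' @param seed RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_proteins = 300, n_pathway_modules = 8,
                          module_size = 15, n_tfs = 32, n_drugs = 8,
                          n_cell_lines = 2, n_moa_classes = 4,
                          n_replicates = 3, effect_size = 3.0, noise_sd = 1.0,
                          baseline_range = c(0, 15), frac_phospho = 0.4,
                          n_compartments = 4, frac_unlocalized = 0.15,
                          seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_pathway_modules = as.integer(n_pathway_modules),
              module_size = as.integer(module_size),
              n_tfs = as.integer(n_tfs), n_drugs = as.integer(n_drugs),
              n_cell_lines = as.integer(n_cell_lines),
              n_moa_classes = as.integer(n_moa_classes),
              n_replicates = as.integer(n_replicates),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_range = baseline_range, frac_phospho = frac_phospho,
              n_compartments = as.integer(n_compartments),
              frac_unlocalized = frac_unlocalized, seed = as.integer(seed))
  counts <- c("n_proteins", "n_pathway_modules", "module_size", "n_tfs",
              "n_drugs", "n_cell_lines", "n_moa_classes", "n_replicates",
              "n_compartments")
  if (any(vapply(cfg[counts], function(x) x < 1L, logical(1))))
    stop("all counts must be positive")
  if (cfg$module_size * cfg$n_pathway_modules > cfg$n_proteins)
    stop("infeasible config: module_size * n_pathway_modules exceeds n_proteins")
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$frac_phospho < 0 || cfg$frac_phospho > 1 ||
      cfg$frac_unlocalized < 0 || cfg$frac_unlocalized > 1)
    stop("fractions must lie in [0, 1]")
  if (cfg$n_moa_classes > cfg$n_drugs)
    stop("n_moa_classes cannot exceed n_drugs")
  if (cfg$n_moa_classes > cfg$n_pathway_modules)
    stop("n_moa_classes cannot exceed n_pathway_modules")
  structure(cfg, class = "cohort_config")
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Generate a synthetic weighted interactome with planted modules
#'
#' A preferential-attachment backbone gives the heavy-tailed degree
#' distribution typical of curated interactomes; each planted pathway module
#' is densified into a high-confidence subgraph, and adjacent modules on the
#' module ring receive a few cross-talk bridge edges. Edge weights
#' (confidences) lie in `(0, 1]`: module edges are high-confidence, backbone
#' edges intermediate.
#'
#' @param config a [cohort_config()].
#' @return list with `graph` (igraph interactome), `gene_sets` (named list of
#'   module member vectors) and `universe` (all protein ids).
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  vn <- protein_ids(n)
  g0 <- igraph::sample_pa(n, power = 1, m = 2, directed = FALSE)
  igraph::V(g0)$name <- vn
  e0 <- igraph::as_data_frame(g0, what = "edges")
  edges <- data.frame(node_a = e0$from, node_b = e0$to,
                      weight = stats::runif(nrow(e0), 0.3, 0.9),
                      stringsAsFactors = FALSE)
  # plant modules on randomly chosen disjoint member sets
  nm <- config$n_pathway_modules
  ms <- config$module_size
  members <- sample(vn, nm * ms)
  gene_sets <- split(members, rep(seq_len(nm), each = ms))
  names(gene_sets) <- sprintf("module_%02d", seq_len(nm))
  dens <- lapply(gene_sets, function(gs) {
    pr <- utils::combn(sort(gs), 2)
    pick <- stats::runif(ncol(pr)) < 0.35
    data.frame(node_a = pr[1, pick], node_b = pr[2, pick],
               weight = stats::runif(sum(pick), 0.75, 1),
               stringsAsFactors = FALSE)
  })
  # ring cross-talk: a few bridges between adjacent modules
  bridges <- lapply(seq_len(nm), function(i) {
    j <- if (i == nm) 1L else i + 1L
    if (nm < 2 || (nm == 2 && i == 2)) return(NULL)
    data.frame(node_a = sample(gene_sets[[i]], 3),
               node_b = sample(gene_sets[[j]], 3),
               weight = stats::runif(3, 0.5, 0.9), stringsAsFactors = FALSE)
  })
  edges <- rbind(edges, do.call(rbind, dens), do.call(rbind, c(bridges, list(NULL))))
  g <- make_interactome(edges)
  list(graph = g, gene_sets = gene_sets, universe = vn)
}

ring_distance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

#' Generate a full synthetic cohort
#'
#' Builds the interactome plus, for each (cell line, drug) condition:
#' replicate expression panels (control = baseline + noise; genes of the
#' drug's planted modules shifted by `effect_size` in the treated arm),
#' phosphoprotein fold-change/p-value tables with elevated signal on a
#' fraction of module proteins, TF regulatory wiring (each TF is a module
#' member regulating several module genes), drug-target and localization
#' annotations, MoA labels, driver genes and sensitivity z-scores.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_bundle`; see fields in the source.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ic <- generate_interactome(config)   # seeds the RNG stream
  g <- ic$graph
  gene_sets <- ic$gene_sets
  vn <- ic$universe
  n <- config$n_proteins
  nm <- config$n_pathway_modules
  nd <- config$n_drugs
  nc <- config$n_moa_classes
  nl <- config$n_cell_lines
  nr <- config$n_replicates

  drugs <- sprintf("drug_%02d", seq_len(nd))
  cells <- sprintf("CL%d", seq_len(nl))
  moa_classes <- sprintf("moa_%d", seq_len(nc))
  moa_labels <- stats::setNames(moa_classes[(seq_len(nd) - 1L) %% nc + 1L], drugs)

  # each MoA class owns a contiguous block of modules on the ring
  mpc <- nm %/% nc
  class_modules <- lapply(seq_len(nc), function(c) ((c - 1L) * mpc + 1L):(c * mpc))
  truth <- lapply(drugs, function(d) class_modules[[match(moa_labels[[d]], moa_classes)]])
  names(truth) <- drugs

  # transcription factors: module members wired to >=3 genes of their module
  tfs <- character(0)
  reg <- list()
  for (j in seq_len(config$n_tfs)) {
    m <- (j - 1L) %% nm + 1L
    gs <- gene_sets[[m]]
    tf <- gs[(j - 1L) %/% nm %% length(gs) + 1L]
    if (tf %in% tfs) next
    tfs <- c(tfs, tf)
    targets <- sample(setdiff(gs, tf), min(6L, length(gs) - 1L))
    extra <- sample(setdiff(vn, gs), 2L)
    reg[[tf]] <- c(targets, extra)
  }
  regnet <- data.frame(
    tf = rep(names(reg), lengths(reg)),
    target = unlist(reg, use.names = FALSE), stringsAsFactors = FALSE)

  # drug targets: members of the drug's first planted module
  drug_targets <- lapply(drugs, function(d) {
    gs <- gene_sets[[truth[[d]][1]]]
    sort(gs)[1:2]
  })
  names(drug_targets) <- drugs

  # localization: each module lives in one compartment (plus occasional
  # second), background proteins get 1-2 random compartments, a fraction of
  # proteins stays unannotated
  comps <- sprintf("compartment_%d", seq_len(config$n_compartments))
  loc <- stats::setNames(vector("list", n), vn)
  for (v in vn) loc[[v]] <- sample(comps, sample(1:2, 1))
  for (m in seq_len(nm)) {
    cm <- comps[(m - 1L) %% length(comps) + 1L]
    for (v in gene_sets[[m]])
      loc[[v]] <- unique(c(cm, if (stats::runif(1) < 0.3) sample(comps, 1)))
  }
  unloc <- sample(vn, round(config$frac_unlocalized * n))
  for (v in unloc) loc[[v]] <- character(0)

  baseline <- stats::setNames(
    stats::runif(n, config$baseline_range[1], config$baseline_range[2]), vn)
  shift_sign <- stats::setNames(sample(c(-1, 1), n, replace = TRUE), vn)

  clamp <- function(x) pmin(pmax(x, config$baseline_range[1]),
                            config$baseline_range[2])

  panels <- list()
  phospho_tables <- list()
  sens <- data.frame(cell_line = character(), drug = character(), z = numeric(),
                     stringsAsFactors = FALSE)
  driver_module <- stats::setNames(
    vapply(seq_len(nl), function(l) class_modules[[(l - 1L) %% nc + 1L]][1],
           integer(1)), cells)
  sem <- config$noise_sd / sqrt(nr)

  for (cl in cells) {
    for (d in drugs) {
      key <- paste(cl, d, sep = "::")
      shifted <- unlist(gene_sets[truth[[d]]], use.names = FALSE)
      mu_t <- baseline
      mu_t[shifted] <- baseline[shifted] + config$effect_size * shift_sign[shifted]
      treated <- clamp(matrix(stats::rnorm(n * nr, mean = mu_t, sd = config$noise_sd),
                              nrow = n, dimnames = list(vn, paste0("T", seq_len(nr)))))
      control <- clamp(matrix(stats::rnorm(n * nr, mean = baseline, sd = config$noise_sd),
                              nrow = n, dimnames = list(vn, paste0("C", seq_len(nr)))))
      panels[[key]] <- list(genes = vn, treated = treated, control = control,
                            condition = c(cell_line = cl, drug = d))
      # phospho read-outs: fraction of module proteins perturbed + matched
      # background proteins; p from a z-test of the observed fold change
      on <- sample(shifted, round(config$frac_phospho * length(shifted)))
      off <- sample(setdiff(vn, shifted), length(on))
      mu_fc <- c(stats::setNames(rep(config$effect_size * 0.6, length(on)), on) *
                   shift_sign[on],
                 stats::setNames(rep(0, length(off)), off))
      fc <- mu_fc + stats::rnorm(length(mu_fc), sd = sem)
      pv <- 2 * stats::pnorm(-abs(fc) / sem)
      phospho_tables[[key]] <- data.frame(protein = names(mu_fc),
                                          fold_change = as.numeric(fc),
                                          p_value = as.numeric(pv),
                                          stringsAsFactors = FALSE)
      rd <- min(ring_distance(truth[[d]], driver_module[[cl]], nm))
      z <- -2.5 + 1.2 * rd + stats::rnorm(1, sd = 0.3)
      sens <- rbind(sens, data.frame(cell_line = cl, drug = d, z = z,
                                     stringsAsFactors = FALSE))
    }
  }

  driver_genes <- sort(unique(unlist(gene_sets[unique(driver_module)],
                                     use.names = FALSE)))

  structure(list(config = config, interactome = g, gene_sets = gene_sets,
                 universe = vn, panels = panels,
                 phospho_tables = phospho_tables, regnet = regnet,
                 drug_targets = drug_targets, localization = loc,
                 moa_labels = moa_labels, driver_genes = driver_genes,
                 sensitivity = sens, truth = truth,
                 cell_lines = cells, drugs = drugs),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic drug-perturbation cohort\n")
  cat("  interactome:", igraph::vcount(x$interactome), "proteins,",
      igraph::ecount(x$interactome), "edges\n")
  cat("  conditions :", length(x$panels), sprintf("(%d cell lines x %d drugs)\n",
      length(x$cell_lines), length(x$drugs)))
  cat("  modules    :", length(x$gene_sets), "planted;",
      length(unique(x$moa_labels)), "MoA classes\n")
  invisible(x)
}

#' Write a cohort bundle to plain-text files
#'
#' Emits the interactome TSV, one GCT-like expression TSV per condition
#' (condition header line, gene rows, replicate columns), phospho TSVs, the
#' regulatory network, localization and label tables, and the planted gene
#' sets in GMT format (`set_name<TAB>description<TAB>gene1<TAB>...`).
#'
#' @param bundle a `cohort_bundle`.
#' @param directory output directory (created if missing).
#' @return data frame manifest (`kind`, `path`), invisibly.
#' @export
write_cohort <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    path <- file.path(directory, f)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  manifest <- data.frame(kind = character(), path = character(),
                         stringsAsFactors = FALSE)
  add <- function(kind, path) {
    manifest <<- rbind(manifest, data.frame(kind = kind, path = path,
                                            stringsAsFactors = FALSE))
  }
  add("interactome", {
    p <- file.path(directory, "interactome.tsv"); write_interactome(bundle$interactome, p); p
  })
  for (key in names(bundle$panels)) {
    pn <- bundle$panels[[key]]
    slug <- gsub("::", "__", key, fixed = TRUE)
    path <- file.path(directory, paste0("expr_", slug, ".tsv"))
    con <- file(path, "w")
    writeLines(paste("#condition", pn$condition[["cell_line"]],
                     pn$condition[["drug"]], sep = "\t"), con)
    df <- data.frame(gene = pn$genes,
                     signif(pn$treated, 6), signif(pn$control, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    add("expression", path)
    add("phospho", wt(data.frame(
      bundle$phospho_tables[[key]][1],
      signif(bundle$phospho_tables[[key]][-1], 6)),
      paste0("phospho_", slug, ".tsv")))
  }
  add("regnet", wt(bundle$regnet, "regnet.tsv"))
  tg <- bundle$drug_targets
  add("drug_targets", wt(data.frame(drug = rep(names(tg), lengths(tg)),
                                    target = unlist(tg, use.names = FALSE)),
                         "drug_targets.tsv"))
  lc <- bundle$localization[lengths(bundle$localization) > 0]
  add("localization", wt(data.frame(protein = rep(names(lc), lengths(lc)),
                                    location = unlist(lc, use.names = FALSE)),
                         "localization.tsv"))
  gmt_path <- file.path(directory, "gene_sets.gmt")
  write_gmt(bundle$gene_sets, gmt_path, description = "planted pathway module")
  add("gene_sets", gmt_path)
  add("moa_labels", wt(data.frame(drug = names(bundle$moa_labels),
                                  moa = unname(bundle$moa_labels)),
                       "moa_labels.tsv"))
  add("driver_genes", wt(data.frame(gene = bundle$driver_genes), "driver_genes.tsv"))
  add("sensitivity", wt(data.frame(bundle$sensitivity[1:2],
                                   z = signif(bundle$sensitivity$z, 6)),
                        "sensitivity.tsv"))
  tr <- bundle$truth
  add("truth", wt(data.frame(drug = rep(names(tr), lengths(tr)),
                             module = unlist(tr, use.names = FALSE)), "truth.tsv"))
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param directory directory containing the manifest and data files.
#' @return a `cohort_bundle` (without the generating `config`).
#' @export
read_cohort <- function(directory) {
  manifest <- utils::read.delim(file.path(directory, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  pick <- function(kind) manifest$path[manifest$kind == kind]
  g <- read_interactome(pick("interactome"))
  panels <- list()
  for (path in pick("expression")) {
    hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
    df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$gene
    tc <- grepl("^T", colnames(mat))
    key <- paste(hdr[2], hdr[3], sep = "::")
    panels[[key]] <- list(genes = df$gene,
                          treated = mat[, tc, drop = FALSE],
                          control = mat[, !tc, drop = FALSE],
                          condition = c(cell_line = hdr[2], drug = hdr[3]))
  }
  phospho <- list()
  for (path in pick("phospho")) {
    slug <- sub("^phospho_", "", sub("\\.tsv$", "", basename(path)))
    key <- gsub("__", "::", slug, fixed = TRUE)
    phospho[[key]] <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  regnet <- utils::read.delim(pick("regnet"), stringsAsFactors = FALSE)
  tgt <- utils::read.delim(pick("drug_targets"), stringsAsFactors = FALSE)
  drug_targets <- split(tgt$target, tgt$drug)
  lc <- utils::read.delim(pick("localization"), stringsAsFactors = FALSE)
  loc <- stats::setNames(vector("list", igraph::vcount(g)), igraph::V(g)$name)
  sp <- split(lc$location, lc$protein)
  loc[names(sp)] <- sp
  loc[vapply(loc, is.null, logical(1))] <- list(character(0))
  gene_sets <- read_gmt(pick("gene_sets"))
  moa <- utils::read.delim(pick("moa_labels"), stringsAsFactors = FALSE)
  moa_labels <- stats::setNames(moa$moa, moa$drug)
  drivers <- utils::read.delim(pick("driver_genes"), stringsAsFactors = FALSE)$gene
  sens <- utils::read.delim(pick("sensitivity"), stringsAsFactors = FALSE)
  tr <- utils::read.delim(pick("truth"), stringsAsFactors = FALSE)
  truth <- split(tr$module, tr$drug)
  conds <- do.call(rbind, lapply(panels, function(p) p$condition))
  structure(list(config = NULL, interactome = g, gene_sets = gene_sets,
                 universe = igraph::V(g)$name, panels = panels,
                 phospho_tables = phospho, regnet = regnet,
                 drug_targets = drug_targets, localization = loc,
                 moa_labels = moa_labels, driver_genes = drivers,
                 sensitivity = sens, truth = truth,
                 cell_lines = unique(unname(conds[, "cell_line"])),
                 drugs = unique(unname(conds[, "drug"]))),
            class = "cohort_bundle")
}
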