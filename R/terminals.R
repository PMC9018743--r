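#' Per-gene differential expression by one-way ANOVA
#'
#' Compares the treated and control replicate values of each gene with a
#' one-way ANOVA (two groups, so the F statistic is the squared pooled-
#' variance two-sample t). The log2 fold change is computed on the arm means:
#' `log2(mean treated) - log2(mean control)`.
#'
#' Degenerate genes (zero within-group variance in both arms) get `p = 1`
#' when the arm means agree and `p = 0` (flagged) when they differ.
#'
#' @param panel list with `genes`, `treated` and `control` replicate value
#'   matrices (genes in rows) and a `condition` tag.
#' @param alpha significance level for the "significantly transcribed genes"
#'   flag (default 0.05).
#' @return data frame with `gene`, `p_value`, `log2fc`, `significant`,
#'   `degenerate`.
#' @export
differential_expression <- function(panel, alpha = 0.05) {
  tr <- as.matrix(panel$treated)
  co <- as.matrix(panel$control)
  if (ncol(tr) < 2 || ncol(co) < 2)
    stop("at least 2 replicates per arm are required")
  if (!all(is.finite(tr)) || !all(is.finite(co)))
    stop("replicate values must be finite")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  nt <- ncol(tr); nc <- ncol(co); ntot <- nt + nc
  mt <- rowMeans(tr); mc <- rowMeans(co)
  ssw <- rowSums((tr - mt)^2) + rowSums((co - mc)^2)
  ssb <- (nt * nc / ntot) * (mt - mc)^2
  msw <- ssw / (ntot - 2)
  f <- ssb / msw
  p <- stats::pf(f, 1, ntot - 2, lower.tail = FALSE)
  degen <- ssw == 0
  p[degen & ssb == 0] <- 1
  p[degen & ssb > 0] <- 0
  if (any(degen & ssb > 0))
    warning("zero within-group variance with different means for ",
            sum(degen & ssb > 0), " gene(s); p set to 0")
  eps <- 1e-9
  log2fc <- log2(pmax(mt, eps)) - log2(pmax(mc, eps))
  data.frame(gene = panel$genes, p_value = as.numeric(p),
             log2fc = as.numeric(log2fc), significant = p < alpha,
             degenerate = degen & ssb > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

terminal_set_frame <- function(protein, prize, source) {
  data.frame(protein = protein, prize = prize, source = source,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcription-factor terminals from differential expression
#'
#' A transcription factor becomes a terminal iff it regulates at least
#' `min_targets` significantly transcribed genes; its prize is the mean of
#' the absolute log2 fold changes of those significant regulated genes
#' (absolute values keep prizes non-negative, which the prize function
#' requires).
#'
#' @param diffexpr result of [differential_expression()].
#' @param regnet data frame with columns `tf`, `target`.
#' @param min_targets minimum number of significant regulated genes
#'   (default 3).
#' @return partial terminal-set data frame (`source = "tf"`).
#' @export
select_tf_terminals <- function(diffexpr, regnet, min_targets = 3) {
  stopifnot(nrow(regnet) > 0, all(c("tf", "target") %in% names(regnet)))
  sig <- diffexpr[diffexpr$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(terminal_set_frame(character(), numeric(), character()))
  hits <- regnet[regnet$target %in% sig$gene, , drop = FALSE]
  if (nrow(hits) == 0)
    return(terminal_set_frame(character(), numeric(), character()))
  fc <- stats::setNames(abs(sig$log2fc), sig$gene)
  by_tf <- split(hits$target, hits$tf)
  by_tf <- lapply(by_tf, unique)
  keep <- lengths(by_tf) >= min_targets
  prize <- vapply(by_tf[keep], function(tg) mean(fc[tg]), numeric(1))
  out <- terminal_set_frame(names(prize), unname(prize),
                            rep("tf", length(prize)))
  out[order(out$protein), , drop = FALSE]
}

#' Phosphoprotein terminals
#'
#' Proteins with at least one phosphosite passing `p < alpha` become
#' terminals; multiple significant sites on one protein collapse to the
#' maximum absolute fold change, which is the prize.
#'
#' @param phospho data frame with `protein`, `fold_change`, `p_value`
#'   (one row per site).
#' @param alpha site-level significance threshold (default 0.05).
#' @return partial terminal-set data frame (`source = "phospho"`).
#' @export
select_phospho_terminals <- function(phospho, alpha = 0.05) {
  if (is.null(phospho) || nrow(phospho) == 0)
    return(terminal_set_frame(character(), numeric(), character()))
  stopifnot(all(is.finite(phospho$fold_change)), all(is.finite(phospho$p_value)))
  sig <- phospho[phospho$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0)
    return(terminal_set_frame(character(), numeric(), character()))
  prize <- vapply(split(abs(sig$fold_change), sig$protein), max, numeric(1))
  out <- terminal_set_frame(names(prize), unname(prize),
                            rep("phospho", length(prize)))
  out[order(out$protein), , drop = FALSE]
}

#' Assemble the terminal set of one condition
#'
#' Merges the TF and phosphoprotein terminal lists (phosphoproteomic
#' evidence takes precedence on conflicts) and appends every drug target
#' with a uniform prize equal to the mean prize of the non-target entries
#' (1.0 when there are none). A condition with no omics-derived terminal at
#' all is infeasible for network reconstruction and raises an error, which
#' the orchestrator records as a dropped condition.
#'
#' @param tf_part,phospho_part partial terminal sets from
#'   [select_tf_terminals()] / [select_phospho_terminals()].
#' @param targets character vector of drug-target proteins.
#' @param condition optional condition id attached as an attribute.
#' @return a `terminal_set` data frame (`protein`, `prize`, `source`).
#' @export
assemble_terminal_set <- function(tf_part, phospho_part, targets = character(0),
                                  condition = NULL) {
  if (nrow(tf_part) == 0 && nrow(phospho_part) == 0)
    stop("infeasible condition: no omics-derived terminals")
  omics <- rbind(phospho_part, tf_part[!tf_part$protein %in% phospho_part$protein, ,
                                       drop = FALSE])
  targets <- setdiff(unique(targets), omics$protein)
  uniform <- if (nrow(omics) > 0) mean(omics$prize) else 1.0
  out <- rbind(omics, terminal_set_frame(targets,
                                         rep(uniform, length(targets)),
                                         rep("drug_target", length(targets))))
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$protein), all(out$prize >= 0))
  structure(out, class = c("terminal_set", "data.frame"), condition = condition)
}

#' Build the terminal set of a condition straight from a cohort bundle
#'
#' Convenience wrapper running differential expression, TF selection,
#' phospho selection and assembly for one (cell line, drug) condition.
#'
#' @param bundle a `cohort_bundle`.
#' @param cell_line,drug condition identifiers.
#' @param alpha expression significance level (default 0.05).
#' @param phospho_alpha phosphosite significance level (default 0.05).
#' @param min_targets TF gate (default 3).
#' @return a `terminal_set`.
#' @export
build_terminal_set <- function(bundle, cell_line, drug, alpha = 0.05,
                               phospho_alpha = 0.05, min_targets = 3) {
  key <- paste(cell_line, drug, sep = "::")
  panel <- bundle$panels[[key]]
  if (is.null(panel)) stop("no panel for condition ", key)
  de <- differential_expression(panel, alpha = alpha)
  tf <- select_tf_terminals(de, bundle$regnet, min_targets = min_targets)
  ph <- select_phospho_terminals(bundle$phospho_tables[[key]],
                                 alpha = phospho_alpha)
  assemble_terminal_set(tf, ph, targets = bundle$drug_targets[[drug]],
                        condition = key)
}
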