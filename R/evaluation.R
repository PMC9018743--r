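#' Confusion-matrix classification metrics
#'
#' Metrics for the MoA benchmark in which a pair of drug networks is
#' predicted "similar" when its separation score falls below a threshold:
#' TP = same MoA & similar, FP = different MoA & similar, FN = same MoA &
#' separated, TN = different MoA & separated. MCC is defined as 0 whenever
#' a marginal is empty; precision is 0 (flagged) when nothing is predicted
#' positive.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @param threshold separation-score cutoff recorded with the metrics.
#' @return one-row data frame with the counts and `precision`, `recall`,
#'   `accuracy`, `sensitivity`, `specificity`, `tpr`, `fpr`, `f1`, `mcc`,
#'   `threshold`, `degenerate`.
#' @export
classification_metrics <- function(tp, fp, fn, tn, threshold = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  degenerate <- (tp + fp) == 0
  precision <- if (degenerate) 0 else tp / (tp + fp)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  total <- tp + fp + fn + tn
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, recall = recall,
             accuracy = (tp + tn) / total,
             sensitivity = recall, specificity = specificity,
             tpr = recall, fpr = 1 - specificity,
             f1 = f1, mcc = mcc, threshold = threshold,
             degenerate = degenerate)
}

moa_pair_table <- function(m, moa, pairs = c("same_cell_line", "all")) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(m, "separation_matrix"))
  det <- m$details
  pa <- condition_parts(det$cond_a)
  pb <- condition_parts(det$cond_b)
  if (pairs == "same_cell_line") {
    keep <- pa$cell_line == pb$cell_line
    det <- det[keep, , drop = FALSE]
    pa <- pa[keep, , drop = FALSE]; pb <- pb[keep, , drop = FALSE]
  }
  if (!all(c(pa$drug, pb$drug) %in% names(moa)))
    stop("every drug must carry a MoA label")
  data.frame(s_ab = det$s_ab,
             same_moa = unname(moa[pa$drug] == moa[pb$drug]),
             cond_a = det$cond_a, cond_b = det$cond_b,
             stringsAsFactors = FALSE)
}

#' Classify condition pairs by MoA at a separation threshold
#'
#' A pair is predicted "similar" iff `s_ab < threshold` (strict). By
#' default only pairs within the same cell line are pooled, matching the
#' benchmark design where drugs are compared within each cellular context.
#'
#' @param m a `separation_matrix`.
#' @param moa named vector drug -> MoA class.
#' @param threshold separation-score cutoff.
#' @param pairs `"same_cell_line"` (default) or `"all"`.
#' @return one-row metrics data frame (see [classification_metrics()]).
#' @export
classify_pairs <- function(m, moa, threshold, pairs = "same_cell_line") {
  tab <- moa_pair_table(m, moa, pairs)
  similar <- tab$s_ab < threshold
  classification_metrics(tp = sum(tab$same_moa & similar),
                         fp = sum(!tab$same_moa & similar),
                         fn = sum(tab$same_moa & !similar),
                         tn = sum(!tab$same_moa & !similar),
                         threshold = threshold)
}

#' Threshold sweep: ROC / precision-recall curves and best MCC threshold
#'
#' Computes the full metrics table over a threshold grid, the trapezoidal
#' ROC AUC, and the best-performing threshold by Matthews correlation
#' coefficient (ties resolve to the smaller threshold, i.e. the more
#' conservative similarity call).
#'
#' @param m a `separation_matrix`.
#' @param moa named vector drug -> MoA class.
#' @param thresholds numeric grid; defaults to the midpoints between sorted
#'   observed scores plus flanking values.
#' @param pairs `"same_cell_line"` (default) or `"all"`.
#' @return list with `curve` (metrics per threshold), `best` (one-row
#'   metrics), `auc`, `degenerate` (TRUE when only one class is present).
#' @export
sweep_thresholds <- function(m, moa, thresholds = NULL, pairs = "same_cell_line") {
  tab <- moa_pair_table(m, moa, pairs)
  if (is.null(thresholds)) {
    s <- sort(unique(tab$s_ab))
    thresholds <- c(s[1] - 1e-6, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-6)
  }
  if (!length(thresholds)) stop("need at least one threshold")
  thresholds <- sort(thresholds)
  curve <- do.call(rbind, lapply(thresholds, function(th)
    classify_pairs(m, moa, th, pairs)))
  degenerate <- length(unique(tab$same_moa)) < 2
  if (degenerate) warning("only one MoA pair class present; ROC is degenerate")
  best <- curve[which.max(curve$mcc), , drop = FALSE]  # which.max -> smallest index/threshold
  fpr <- c(0, curve$fpr, 1); tpr <- c(0, curve$tpr, 1)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  list(curve = curve, best = best, auc = auc, degenerate = degenerate)
}

#' Tanimoto similarity of binary fingerprints
#'
#' `|A intersect B| / |A union B|` on the sets of on-bits of two binary
#' chemical fingerprints; the associated distance is `1 - similarity`.
#'
#' @param fp_a,fp_b character or integer vectors of on-bit identifiers.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  fp_a <- unique(fp_a); fp_b <- unique(fp_b)
  u <- length(union(fp_a, fp_b))
  if (u == 0) stop("both fingerprints are empty")
  length(intersect(fp_a, fp_b)) / u
}

#' Rate condition pairs as candidate drug combinations
#'
#' Complementary-exposure rating: a pair of drug networks is a combination
#' candidate (`passes_rating`) when the networks are separated
#' (`s_ab > 0`), share fewer than `max_shared` significantly enriched
#' signaling pathways, both exceed `min_nodes` nodes and at least one
#' exceeds `large_nodes` nodes. The driver rule (`passes_driver_rule`)
#' additionally marks separated pairs sharing at least one cancer driver
#' protein. Candidates are ranked by decreasing separation.
#'
#' @param networks named list of `reconstructed_network` (names =
#'   condition ids).
#' @param enrichments named list of [enrich()] results aligned with
#'   `networks`.
#' @param m a `separation_matrix` over the same conditions.
#' @param drivers character vector of cancer driver proteins.
#' @param signaling_filter passed to [shared_pathways()].
#' @param min_nodes,large_nodes,max_shared rule parameters (defaults 40,
#'   100, 2).
#' @param pairs `"same_cell_line"` (default) or `"all"`.
#' @return data frame of candidates with rule fields and flags.
#' @export
predict_combinations <- function(networks, enrichments, m, drivers,
                                 signaling_filter = "signaling",
                                 min_nodes = 40, large_nodes = 100,
                                 max_shared = 2, pairs = "same_cell_line") {
  det <- m$details
  if (pairs == "same_cell_line") {
    pa <- condition_parts(det$cond_a); pb <- condition_parts(det$cond_b)
    det <- det[pa$cell_line == pb$cell_line, , drop = FALSE]
  }
  out <- list()
  for (r in seq_len(nrow(det))) {
    ca <- det$cond_a[r]; cb <- det$cond_b[r]
    if (is.null(enrichments[[ca]]) || is.null(enrichments[[cb]])) {
      warning("missing enrichment for pair ", ca, " / ", cb, "; skipped")
      next
    }
    na <- length(network_nodes(networks[[ca]]))
    nb <- length(network_nodes(networks[[cb]]))
    shared <- length(shared_pathways(enrichments[[ca]], enrichments[[cb]],
                                     signaling_filter))
    shared_driver <- length(intersect(
      intersect(network_nodes(networks[[ca]]), network_nodes(networks[[cb]])),
      drivers))
    s <- det$s_ab[r]
    out[[length(out) + 1]] <- data.frame(
      cond_a = ca, cond_b = cb, s_ab = s, shared_pathways = shared,
      nodes_a = na, nodes_b = nb, shared_drivers = shared_driver,
      passes_rating = s > 0 && shared < max_shared &&
        min(na, nb) > min_nodes && max(na, nb) > large_nodes,
      passes_driver_rule = s > 0 && shared_driver >= 1,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(-res$s_ab), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Association between network separation and drug-sensitivity differences
#'
#' Keeps condition pairs in which one drug has a negative sensitivity
#' z-score on its cell line (sensitive) and the other a positive one, and
#' whose separation score exceeds `ss_floor`; then reports the Pearson
#' correlation between `s_ab` and the absolute z-score difference with its
#' two-sided p-value.
#'
#' @param m a `separation_matrix`.
#' @param sens data frame with `cell_line`, `drug`, `z`.
#' @param ss_floor separation-score floor (default -0.45).
#' @return list with `R`, `p_value`, `n` (pairs used).
#' @export
sensitivity_association <- function(m, sens, ss_floor = -0.45) {
  det <- m$details
  key <- function(cl, d) paste(cl, d, sep = "::")
  z <- stats::setNames(sens$z, key(sens$cell_line, sens$drug))
  za <- z[det$cond_a]; zb <- z[det$cond_b]
  keep <- !is.na(za) & !is.na(zb) & (za * zb < 0) & det$s_ab > ss_floor
  if (sum(keep) < 3) stop("insufficient data: fewer than 3 pairs after filtering")
  ct <- stats::cor.test(det$s_ab[keep], abs(za - zb)[keep], method = "pearson")
  list(R = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}
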