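#' Build a weighted interactome from an edge table
#'
#' The interactome is an undirected protein--protein interaction graph whose
#' edge weights are interaction confidences in `(0, 1]`. The edge *cost* used
#' by the network reconstruction is `c(e) = 1 - w(e)`, so high-confidence
#' interactions are cheap to include. Each edge carries an `origin` flag,
#' either `"reference"` (curated interaction) or `"predicted"` (added by link
#' prediction; see [augment_interactome()]).
#'
#' @param edges data frame with columns `node_a`, `node_b`, `weight` and
#'   optionally `origin`.
#' @return an `igraph` object with `weight` and `origin` edge attributes.
#' @details Self-loops are rejected, duplicate edges are collapsed keeping the
#'   highest-confidence record, and weights must lie in `(0, 1]`.
#' @export
make_interactome <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("node_a", "node_b", "weight") %in% names(edges)))
  if (any(edges$node_a == edges$node_b))
    stop("self-loops are not allowed in the interactome")
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0) || any(edges$weight > 1))
    stop("edge weights must lie in (0, 1]")
  if (is.null(edges$origin)) edges$origin <- "reference"
  # collapse duplicate unordered pairs, keeping the highest confidence
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$weight)
  keep <- ord[!duplicated(key[ord])]
  df <- data.frame(from = a[keep], to = b[keep],
                   weight = edges$weight[keep], origin = edges$origin[keep],
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Read / write an interactome edge list (TSV)
#'
#' Plain tab-separated edge list with columns `node_a`, `node_b`, `weight`
#' and `origin`.
#'
#' @param path file path.
#' @return [read_interactome()] returns an `igraph`; [write_interactome()]
#'   returns `path` invisibly.
#' @export
read_interactome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  make_interactome(df)
}

#' @rdname read_interactome
#' @param g interactome graph.
#' @export
write_interactome <- function(g, path) {
  df <- interactome_edges(g)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge table of an interactome
#'
#' @param g interactome graph.
#' @return data frame with `node_a`, `node_b`, `weight`, `origin`.
#' @export
interactome_edges <- function(g) {
  if (igraph::ecount(g) == 0)
    return(data.frame(node_a = character(), node_b = character(),
                      weight = numeric(), origin = character()))
  e <- igraph::as_data_frame(g, what = "edges")
  if (is.null(e$origin)) e$origin <- "reference"
  data.frame(node_a = pmin(e$from, e$to), node_b = pmax(e$from, e$to),
             weight = e$weight, origin = e$origin, stringsAsFactors = FALSE)
}

#' Edge costs of an interactome
#'
#' Cost of including an edge in a reconstruction: `c(e) = 1 - w(e)`.
#'
#' @param g interactome graph.
#' @return numeric vector aligned with `igraph::E(g)`.
#' @export
edge_costs <- function(g) 1 - igraph::E(g)$weight

#' Remove hub proteins from the interactome
#'
#' Drops every edge incident to a hub, where a hub satisfies *both* clauses:
#' degree greater than `deg_thresh` and degree more than `sd_mult` standard
#' deviations above the mean degree (mean/SD taken over all nodes of `g`).
#' Extremely promiscuous proteins (ubiquitin-like, chaperones) otherwise
#' short-circuit link prediction and path finding. Any self-loops are dropped
#' as well.
#'
#' @param g interactome graph.
#' @param deg_thresh absolute degree cutoff (default 900).
#' @param sd_mult standard-deviation multiplier (default 10).
#' @return list with `graph` (hub edges removed; nodes kept) and `removed`
#'   (character vector of hub node ids).
#' @export
remove_hubs <- function(g, deg_thresh = 900, sd_mult = 10) {
  stopifnot(igraph::vcount(g) > 0)
  g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  cut <- mean(deg) + sd_mult * stats::sd(deg)
  hubs <- names(deg)[deg > deg_thresh & deg > cut]
  if (length(hubs)) {
    eid <- unlist(igraph::incident_edges(g, hubs))
    g <- igraph::delete_edges(g, unique(eid))
  }
  list(graph = g, removed = hubs)
}

#' Expression-filter the interactome for one condition
#'
#' Edges with at least one endpoint whose recorded expression value falls
#' below `thresh` are excluded; endpoints with no recorded value are treated
#' as unknown and kept. Expression values are on the fluorescence scale of
#' the panels (roughly 0--15), so the default cutoff 2.0 removes edges
#' touching essentially unexpressed proteins.
#'
#' @param g interactome graph.
#' @param expr named numeric vector, protein -> expression value.
#' @param thresh expression cutoff (default 2.0).
#' @return filtered interactome graph.
#' @export
expression_filter <- function(g, expr, thresh = 2.0) {
  if (igraph::ecount(g) == 0) return(g)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  low <- names(expr)[!is.na(expr) & expr < thresh]
  bad <- ends[, 1] %in% low | ends[, 2] %in% low
  igraph::delete_edges(g, which(bad))
}

#' Adamic/Adar link prediction scores
#'
#' Scores every non-adjacent node pair that shares at least one neighbor:
#' `Score(x, y) = sum over common neighbors w of 1 / ln(degree(w))`, which
#' up-weights rare shared partners. The natural logarithm is used. The
#' `top_k` highest-scoring pairs are returned, ties broken lexicographically
#' on the pair id so results are deterministic.
#'
#' @param g processed interactome (hub- and expression-filtered).
#' @param top_k number of predictions to keep; defaults to the number of
#'   edges of `g`.
#' @return data frame with `node_a`, `node_b`, `aa_score`, ordered by
#'   decreasing score.
#' @export
adamic_adar_scores <- function(g, top_k = igraph::ecount(g)) {
  vn <- igraph::V(g)$name
  n <- length(vn)
  empty <- data.frame(node_a = character(), node_b = character(),
                      aa_score = numeric(), stringsAsFactors = FALSE)
  if (n < 3 || igraph::ecount(g) == 0 || top_k <= 0) return(empty)
  adj <- igraph::as_adj_list(g, mode = "all")
  deg <- igraph::degree(g)
  keys <- vector("list", n)
  vals <- vector("list", n)
  for (w in seq_len(n)) {
    nb <- sort(as.integer(adj[[w]]))
    nb <- unique(nb)
    if (length(nb) < 2) next
    pr <- utils::combn(nb, 2)
    keys[[w]] <- (pr[1, ] - 1) * n + pr[2, ]   # i < j encoded as one number
    vals[[w]] <- rep_len(1 / log(deg[w]), ncol(pr))
  }
  key <- unlist(keys, use.names = FALSE)
  if (is.null(key) || !length(key)) return(empty)
  val <- unlist(vals, use.names = FALSE)
  agg <- rowsum(val, group = key)
  k <- as.numeric(rownames(agg))
  i <- (k - 1) %/% n + 1
  j <- (k - 1) %% n + 1
  # drop pairs that are already edges of g
  eid <- igraph::get_edge_ids(g, rbind(i, j))
  keep <- eid == 0
  df <- data.frame(node_a = vn[i[keep]], node_b = vn[j[keep]],
                   aa_score = agg[keep, 1], stringsAsFactors = FALSE)
  swap <- df$node_a > df$node_b
  tmp <- df$node_a[swap]; df$node_a[swap] <- df$node_b[swap]; df$node_b[swap] <- tmp
  df <- df[order(-df$aa_score, df$node_a, df$node_b), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}

#' Subcellular-localization filter for predicted edges
#'
#' A predicted interaction is plausible only if the two proteins can meet:
#' keep a prediction iff the proteins share at least one annotated
#' compartment, or at least one of them has no localization record (unknown
#' localization is not evidence of absence).
#'
#' @param preds data frame of predictions (`node_a`, `node_b`, `aa_score`).
#' @param loc named list, protein -> character vector of compartments.
#'   Proteins absent from the list (or with an empty vector) are unannotated.
#' @return the surviving rows of `preds`.
#' @export
localization_filter <- function(preds, loc) {
  if (nrow(preds) == 0) return(preds)
  keep <- vapply(seq_len(nrow(preds)), function(r) {
    la <- loc[[preds$node_a[r]]]
    lb <- loc[[preds$node_b[r]]]
    if (is.null(la) || !length(la) || is.null(lb) || !length(lb)) return(TRUE)
    length(intersect(la, lb)) > 0
  }, logical(1))
  out <- preds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Append predicted edges to the interactome
#'
#' Surviving Adamic/Adar scores are min--max scaled onto `[0, 0.5]` and
#' appended as edges with `origin = "predicted"`; their weight never reaches
#' the reference-edge range, so the solver treats predictions as expensive
#' (cost in `[0.5, 1]`). If all surviving scores are equal (including a
#' single survivor) they map to 0.5.
#'
#' @param g interactome graph.
#' @param preds data frame of surviving predictions.
#' @return augmented interactome graph.
#' @export
augment_interactome <- function(g, preds) {
  if (is.null(preds) || nrow(preds) == 0) return(g)
  eid <- igraph::get_edge_ids(g, rbind(preds$node_a, preds$node_b))
  if (any(eid != 0)) {
    warning(sum(eid != 0), " predicted edge(s) duplicate existing edges; skipped")
    preds <- preds[eid == 0, , drop = FALSE]
    if (nrow(preds) == 0) return(g)
  }
  rng <- range(preds$aa_score)
  w <- if (diff(rng) == 0) rep(0.5, nrow(preds)) else
    0.5 * (preds$aa_score - rng[1]) / (rng[2] - rng[1])
  igraph::add_edges(g, rbind(preds$node_a, preds$node_b),
                    attr = list(weight = w, origin = rep("predicted", nrow(preds))))
}

#' Condition-specific interactome preparation
#'
#' Fixed refinement order: hub removal, expression filter, Adamic/Adar
#' scoring on the processed graph, localization filter, augmentation.
#'
#' @param g reference interactome.
#' @param expr named expression vector for the condition.
#' @param loc localization list (protein -> compartments).
#' @param expr_thresh expression cutoff (default 2.0).
#' @param deg_thresh,sd_mult hub-removal parameters (see [remove_hubs()]).
#' @param top_k predictions to keep before the localization filter;
#'   defaults to the processed edge count.
#' @return list with `graph` (augmented condition interactome), `removed_hubs`
#'   and `n_predicted` (edges actually appended).
#' @export
prepare_interactome <- function(g, expr, loc, expr_thresh = 2.0,
                                deg_thresh = 900, sd_mult = 10, top_k = NULL) {
  hr <- remove_hubs(g, deg_thresh = deg_thresh, sd_mult = sd_mult)
  gp <- expression_filter(hr$graph, expr, thresh = expr_thresh)
  if (is.null(top_k)) top_k <- igraph::ecount(gp)
  preds <- adamic_adar_scores(gp, top_k = top_k)
  preds <- localization_filter(preds, loc)
  ga <- augment_interactome(gp, preds)
  list(graph = ga, removed_hubs = hr$removed, n_predicted = nrow(preds))
}
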