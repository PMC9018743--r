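#' Topological separation score of two protein sets
#'
#' The network-medicine separation score
#' `s_AB = <d_AB> - (<d_AA> + <d_BB>)/2`, where distances are unweighted
#' shortest-path hop counts on the reference interactome. `<d_AB>` averages,
#' over every node of A its distance to the nearest node of B and over every
#' node of B its distance to the nearest node of A; a protein common to both
#' sets contributes 0. `<d_AA>` averages each node's distance to the nearest
#' *other* node of A (0 for a singleton set). Negative `s_AB` means the two
#' sets overlap topologically; positive means they occupy separated
#' neighborhoods. Nodes unreachable from the other set are dropped from the
#' mean with a warning.
#'
#' @param set_a,set_b nonempty character vectors of proteins (must be nodes
#'   of `ref`).
#' @param ref reference interactome graph.
#' @return object of class `separation_score`: list with `s_ab`, `d_ab`,
#'   `d_aa`, `d_bb`, `n_common`.
#' @export
separation_score <- function(set_a, set_b, ref) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) stop("both protein sets must be nonempty")
  vn <- igraph::V(ref)$name
  if (!all(set_a %in% vn) || !all(set_b %in% vn))
    stop("all proteins must be nodes of the reference interactome")
  finite_mean <- function(x, what) {
    bad <- !is.finite(x)
    if (any(bad)) {
      warning(sum(bad), " node(s) unreachable in ", what, "; dropped from the mean")
      x <- x[!bad]
    }
    if (!length(x)) stop("no reachable node pairs for ", what)
    mean(x)
  }
  dmat <- igraph::distances(ref, v = set_a, to = set_b, weights = NA)
  d_ab <- finite_mean(c(apply(dmat, 1, min), apply(dmat, 2, min)), "d_AB")
  within <- function(s) {
    if (length(s) == 1) return(0)
    dm <- igraph::distances(ref, v = s, to = s, weights = NA)
    diag(dm) <- Inf
    finite_mean(apply(dm, 1, min), "within-set distances")
  }
  d_aa <- within(set_a)
  d_bb <- within(set_b)
  structure(list(s_ab = d_ab - (d_aa + d_bb) / 2, d_ab = d_ab,
                 d_aa = d_aa, d_bb = d_bb,
                 n_common = length(intersect(set_a, set_b))),
            class = "separation_score")
}

condition_parts <- function(ids) {
  parts <- strsplit(ids, "::", fixed = TRUE)
  data.frame(condition = ids,
             cell_line = vapply(parts, `[`, character(1), 1),
             drug = vapply(parts, function(p) paste(p[-1], collapse = "::"),
                           character(1)),
             stringsAsFactors = FALSE)
}

#' All-pairs separation score matrix
#'
#' Scores every unordered pair of reconstructed networks on the reference
#' interactome and annotates each pair with its comparison class:
#' T1 same cell line / same MoA, T2 same cell line / different MoA,
#' T3 different cell line / same MoA, T4 different cell line / different MoA.
#'
#' @param networks list of `reconstructed_network` objects (or named list of
#'   protein-id vectors); names or `condition` fields must be
#'   `"cellline::drug"` ids.
#' @param ref reference interactome graph.
#' @param moa optional named vector drug -> MoA class for pair-class
#'   annotation.
#' @return object of class `separation_matrix`: list with `scores` (symmetric
#'   matrix, diagonal 0 set to the self-separation, always <= 0), `classes`
#'   (character matrix or NULL), `conditions` (data frame), `details`
#'   (long-form per-pair data frame).
#' @export
separation_matrix <- function(networks, ref, moa = NULL) {
  stopifnot(length(networks) >= 2)
  sets <- lapply(networks, function(x)
    if (inherits(x, "reconstructed_network")) network_nodes(x) else x)
  ids <- names(networks)
  if (is.null(ids))
    ids <- vapply(networks, function(x) x$condition %||% NA_character_,
                  character(1))
  if (anyNA(ids) || anyDuplicated(ids)) stop("networks must carry unique condition ids")
  names(sets) <- ids
  k <- length(sets)
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(m) <- 0
  conds <- condition_parts(ids)
  cls <- matrix(NA_character_, k, k, dimnames = list(ids, ids))
  det <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sc <- tryCatch(separation_score(sets[[i]], sets[[j]], ref),
                     error = function(e) NULL)
      if (is.null(sc)) next   # recorded as missing
      m[i, j] <- m[j, i] <- sc$s_ab
      pc <- if (!is.null(moa)) {
        same_cl <- conds$cell_line[i] == conds$cell_line[j]
        same_moa <- moa[[conds$drug[i]]] == moa[[conds$drug[j]]]
        paste0("T", 1L + 2L * (!same_cl) + (!same_moa))
      } else NA_character_
      cls[i, j] <- cls[j, i] <- pc
      det[[length(det) + 1]] <- data.frame(
        cond_a = ids[i], cond_b = ids[j], s_ab = sc$s_ab, d_ab = sc$d_ab,
        d_aa = sc$d_aa, d_bb = sc$d_bb, n_common = sc$n_common,
        class = pc, stringsAsFactors = FALSE)
    }
  }
  diag(m) <- vapply(seq_len(k), function(i) {
    sc <- separation_score(sets[[i]], sets[[i]], ref)
    sc$s_ab
  }, numeric(1))
  structure(list(scores = m, classes = if (is.null(moa)) NULL else cls,
                 conditions = conds, details = do.call(rbind, det)),
            class = "separation_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.separation_matrix <- function(x, ...) {
  cat("Separation matrix over", nrow(x$scores), "conditions;",
      sum(!is.na(x$scores[upper.tri(x$scores)])), "scored pairs\n")
  invisible(x)
}

#' Hypergeometric significance of a network overlap
#'
#' Upper-tail (inclusive) hypergeometric test of observing at least `x`
#' shared proteins when the smaller network's nodes are drawn from an
#' interactome of `N` proteins of which `M` belong to the larger network:
#' `p = P(X >= x)`.
#'
#' @param net_a,net_b reconstructed networks or protein-id vectors.
#' @param ref reference interactome graph.
#' @return data frame with `x`, `M`, `n`, `N`, `p_value`.
#' @export
overlap_significance <- function(net_a, net_b, ref) {
  a <- unique(if (inherits(net_a, "reconstructed_network")) network_nodes(net_a) else net_a)
  b <- unique(if (inherits(net_b, "reconstructed_network")) network_nodes(net_b) else net_b)
  vn <- igraph::V(ref)$name
  if (!all(a %in% vn) || !all(b %in% vn))
    stop("network nodes must belong to the reference interactome")
  x <- length(intersect(a, b))
  M <- max(length(a), length(b))
  nn <- min(length(a), length(b))
  N <- length(vn)
  if (x > nn) stop("overlap larger than the smaller network")
  data.frame(x = x, M = M, n = nn, N = N,
             p_value = stats::phyper(x - 1, M, N - M, nn, lower.tail = FALSE))
}

#' Topological summary of a reconstructed network
#'
#' Node/edge counts, average degree, density, and -- on the largest
#' connected component when the network is disconnected (flagged) --
#' average shortest path length and diameter, all in unweighted hops.
#'
#' @param net a `reconstructed_network` (or igraph).
#' @return data frame with `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_shortest_path`, `density`, `diameter`, `connected`.
#' @export
topology_summary <- function(net) {
  g <- if (inherits(net, "reconstructed_network")) {
    igraph::graph_from_data_frame(net$edges[, c("from", "to")], directed = FALSE,
                                  vertices = net$nodes$protein)
  } else net
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  e <- igraph::ecount(g)
  comp <- igraph::components(g)
  connected <- comp$no == 1
  gl <- if (connected) g else {
    big <- which.max(comp$csize)
    igraph::induced_subgraph(g, which(comp$membership == big))
  }
  data.frame(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
             avg_shortest_path = igraph::mean_distance(gl, weights = NA),
             density = igraph::edge_density(g),
             diameter = igraph::diameter(gl, weights = NA),
             connected = connected)
}

#' Hierarchical clustering of a separation matrix
#'
#' Agglomerative average-linkage clustering on Euclidean distances between
#' the rows of the score matrix. Missing entries are imputed as the matrix
#' maximum (most separated) with a warning.
#'
#' @param m a `separation_matrix` (or plain numeric matrix).
#' @return an `hclust` object; leaf order in `$order`, labels in `$labels`.
#' @export
cluster_matrix <- function(m) {
  sc <- if (inherits(m, "separation_matrix")) m$scores else m
  if (nrow(sc) < 2) stop("need at least 2 conditions to cluster")
  if (anyNA(sc)) {
    warning("missing separation scores imputed as the matrix maximum")
    sc[is.na(sc)] <- max(sc, na.rm = TRUE)
  }
  stats::hclust(stats::dist(sc, method = "euclidean"), method = "average")
}

#' Export a clustering as Newick text
#'
#' @param hc an `hclust` from [cluster_matrix()].
#' @return single Newick string (requires the `ape` package).
#' @export
linkage_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc))
}
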