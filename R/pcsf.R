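#' Prize-collecting Steiner forest parameters
#'
#' `beta` scales terminal prizes (larger beta pulls more terminals into the
#' solution), `mu` penalizes high-degree nodes through the generalized prize
#' `p'(v) = beta * p(v) - mu * degree(v)`, `omega` is the cost of opening a
#' tree (the edge to the virtual root), and `depth` bounds the hop distance
#' of any node from the root.
#'
#' @param beta terminal scaling, > 0.
#' @param mu hub penalty, >= 0 (0 disables hub correction).
#' @param omega per-tree cost, > 0.
#' @param depth maximum path length from the virtual root, >= 1.
#' @return object of class `pcsf_params`.
#' @export
pcsf_params <- function(beta = 1, mu = 0, omega = 1, depth = 10) {
  stopifnot(is.finite(beta), beta > 0, is.finite(mu), mu >= 0,
            is.finite(omega), omega > 0, depth >= 1)
  structure(list(beta = beta, mu = mu, omega = omega, depth = as.integer(depth)),
            class = "pcsf_params")
}

#' Default reduced parameter grid
#'
#' A desk-scale subset of the full tuning grid (mu in \{0, 0.01, 0.1\},
#' beta in \{2, 5, 10\}, omega in \{1, 2, 3\}, depth 10). The full-resolution
#' mu grid is available by passing explicit vectors.
#'
#' @param mu,beta,omega,depth parameter values to cross.
#' @return list of `pcsf_params`, one per grid point.
#' @export
default_pcsf_grid <- function(mu = c(0, 0.01, 0.1), beta = c(2, 5, 10),
                              omega = c(1, 2, 3), depth = 10) {
  grid <- expand.grid(mu = mu, beta = beta, omega = omega, depth = depth)
  lapply(seq_len(nrow(grid)), function(i)
    pcsf_params(beta = grid$beta[i], mu = grid$mu[i], omega = grid$omega[i],
                depth = grid$depth[i]))
}

terminal_prizes <- function(terminals) {
  if (inherits(terminals, "data.frame"))
    stats::setNames(terminals$prize, terminals$protein)
  else terminals  # already a named vector
}

#' Adjusted prizes p'(v) = beta * p(v) - mu * degree(v)
#'
#' Terminals carry their assembled prize `p(v)`; every other node has
#' `p(v) = 0`, so with `mu > 0` non-terminals get negative adjusted prizes
#' proportional to their interactome degree, discouraging hub inclusion.
#' Terminals absent from the graph are dropped with a warning.
#'
#' @param terminals a `terminal_set` (or named prize vector).
#' @param g interactome graph.
#' @param params a [pcsf_params()].
#' @return named numeric vector over all nodes of `g`.
#' @export
adjust_prizes <- function(terminals, g, params) {
  p <- terminal_prizes(terminals)
  vn <- igraph::V(g)$name
  missing <- setdiff(names(p), vn)
  if (length(missing)) {
    warning(length(missing), " terminal(s) absent from the interactome; dropped")
    p <- p[names(p) %in% vn]
  }
  base <- stats::setNames(numeric(length(vn)), vn)
  base[names(p)] <- p
  params$beta * base - params$mu * igraph::degree(g)[vn]
}

new_forest <- function(nodes, edges, kappa, objective) {
  structure(list(nodes = nodes, edges = edges, kappa = kappa,
                 objective = objective),
            class = "pcsf_forest")
}

empty_forest <- function(objective) {
  new_forest(character(0),
             data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE), 0L, objective)
}

#' @export
print.pcsf_forest <- function(x, ...) {
  cat("PCSF forest:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      x$kappa, "tree(s); objective", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Objective value of a forest
#'
#' Evaluates `f'(F)`: the positive adjusted prizes of excluded nodes, plus
#' the hub penalties `max(-p'(v), 0)` of included nodes, plus included edge
#' costs, plus `omega * kappa`. This is the paper's objective up to an
#' additive constant over fixed inputs (the all-excluded negative-prize mass),
#' so it has the same minimizers while staying non-negative.
#'
#' @param forest a `pcsf_forest` (or list with `nodes`, `edges`, `kappa`).
#' @param g interactome graph the forest lives in.
#' @param terminals terminal set.
#' @param params a [pcsf_params()].
#' @return numeric objective value.
#' @export
pcsf_objective <- function(forest, g, terminals, params) {
  pr <- suppressWarnings(adjust_prizes(terminals, g, params))
  vn <- names(pr)
  if (!all(forest$nodes %in% vn)) stop("forest contains nodes not in g")
  if (nrow(forest$edges) > 0) {
    eid <- igraph::get_edge_ids(g, rbind(forest$edges$from, forest$edges$to))
    if (any(eid == 0)) stop("forest contains an edge not present in g")
    ecost <- sum(edge_costs(g)[eid])
  } else ecost <- 0
  excluded <- setdiff(vn, forest$nodes)
  sum(pmax(pr[excluded], 0)) + sum(pmax(-pr[forest$nodes], 0)) +
    ecost + params$omega * forest$kappa
}

#' Heuristic prize-collecting Steiner forest solver
#'
#' Deterministic root-attached cheapest-path heuristic: a virtual root is
#' attached to every positive-prize terminal at cost `omega`; terminals are
#' processed in a fixed order and either attached to the growing forest
#' along the cheapest cost-plus-hub-penalty path, opened as a new tree, or
#' skipped; the depth of any node from the root is bounded by
#' `params$depth`. Each tree is then strong-pruned (subtrees whose
#' collected prize cannot pay their connection cost are removed, and trees
#' that cannot pay their `omega` are closed). Because greedy growth is
#' order-sensitive, several deterministic terminal orderings are tried
#' (descending and ascending adjusted prize, plus rotations that seed the
#' forest from each of the top `restarts` terminals) and the best-scoring
#' forest is returned. The result never scores worse than the empty forest.
#'
#' @param g interactome graph.
#' @param terminals terminal set.
#' @param params a [pcsf_params()].
#' @param restarts number of leading terminals additionally tried as the
#'   seed of the first tree (default 3).
#' @return a `pcsf_forest`.
#' @export
solve_pcsf <- function(g, terminals, params, restarts = 3) {
  pr <- adjust_prizes(terminals, g, params)
  vn <- names(pr)
  pos <- vn[pr > 0]
  obj_empty <- sum(pmax(pr, 0))
  if (length(pos) == 0) stop("infeasible condition: no terminal with positive adjusted prize")
  base <- pos[order(-pr[pos], pos)]
  nodecost <- pmax(-pr, 0)
  cost <- pmax(edge_costs(g), 0)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  # effective weights: edge cost plus half the hub penalty of each endpoint
  ew <- pmax(cost + (nodecost[ends[, 1]] + nodecost[ends[, 2]]) / 2, 1e-12)

  orders <- c(list(base, rev(base)),
              lapply(seq_len(min(restarts, length(base))), function(i)
                c(base[i], base[-i])))
  orders <- unique(orders)
  best <- empty_forest(obj_empty)
  for (ord in orders) {
    f <- pcsf_greedy_pass(g, ord, pr, nodecost, cost, ew, params)
    if (is.null(f)) next
    f$objective <- pcsf_objective(f, g, terminals, params)
    if (f$objective < best$objective) best <- f
  }
  best
}

# One greedy grow-and-prune pass over a fixed terminal ordering; returns a
# pcsf_forest without objective (NULL when everything is pruned away).
pcsf_greedy_pass <- function(g, ord, pr, nodecost, cost, ew, params) {
  depth <- integer(0)     # named by node: hops from virtual root
  parent <- character(0)  # named by node
  troot <- character(0)   # named by node: id of its tree root

  for (t in ord) {
    if (t %in% names(depth)) next
    attach <- NULL
    fn <- names(depth)
    if (length(fn)) {
      d <- stats::setNames(igraph::distances(g, v = t, to = fn, weights = ew)[1, ], fn)
      if (any(is.finite(d))) {
        a <- fn[order(d, fn)][1]
        if (is.finite(d[[a]])) {
          sp <- igraph::shortest_paths(g, from = t, to = a, weights = ew)$vpath[[1]]
          vp <- names(sp)                      # t ... a
          k <- which(vp %in% fn)[1]            # truncate at first forest node
          vp <- vp[seq_len(k)]
          anchor <- vp[k]
          newn <- vp[-k]
          eid <- igraph::get_edge_ids(g, rbind(vp[-length(vp)], vp[-1]))
          inc <- sum(cost[eid]) + sum(nodecost[newn]) -
            sum(pmax(pr[setdiff(newn, t)], 0))
          if (depth[[anchor]] + (length(vp) - 1) <= params$depth)
            attach <- list(cost = inc, path = rev(vp))  # anchor ... t
        }
      }
    }
    if (!is.null(attach) && attach$cost < params$omega) {
      vp <- attach$path
      for (i in 2:length(vp)) {
        v <- vp[i]
        if (!(v %in% names(depth))) {
          depth[[v]] <- depth[[vp[i - 1]]] + 1L
          parent[[v]] <- vp[i - 1]
          troot[[v]] <- troot[[vp[1]]]
        }
      }
    } else if (pr[[t]] > params$omega) {
      depth[[t]] <- 1L
      parent[[t]] <- NA_character_
      troot[[t]] <- t
    }
  }

  if (!length(depth)) return(NULL)

  # strong pruning, per tree, children before parents (by decreasing depth)
  keep <- stats::setNames(rep(TRUE, length(depth)), names(depth))
  val <- stats::setNames(pmax(pr[names(depth)], 0) - nodecost[names(depth)],
                         names(depth))
  for (v in names(depth)[order(-depth)]) {
    if (!keep[[v]]) next
    pa <- parent[[v]]
    if (is.na(pa)) next
    eid <- igraph::get_edge_ids(g, c(pa, v))
    gain <- val[[v]] - cost[eid]
    if (gain > 0) val[[pa]] <- val[[pa]] + gain
    else {
      # prune v and its whole subtree
      drop <- v
      frontier <- v
      while (length(frontier)) {
        kids <- names(parent)[!is.na(parent) & parent %in% frontier & keep[names(parent)]]
        kids <- setdiff(kids, drop)
        drop <- c(drop, kids)
        frontier <- kids
      }
      keep[drop] <- FALSE
    }
  }
  roots <- names(depth)[is.na(parent[names(depth)])]
  for (r in roots) {
    if (val[[r]] <= params$omega) {  # tree cannot pay its opening cost
      drop <- names(depth)[keep[names(depth)] & troot[names(depth)] == r]
      keep[drop] <- FALSE
    }
  }
  nodes <- names(depth)[keep[names(depth)]]
  if (!length(nodes)) return(NULL)
  ef <- parent[nodes]
  has_edge <- !is.na(ef)
  edges <- data.frame(from = unname(ef[has_edge]), to = nodes[has_edge],
                      stringsAsFactors = FALSE)
  kappa <- sum(is.na(parent[nodes]))
  new_forest(nodes, edges, as.integer(kappa), NA_real_)
}

#' Exact PCSF oracle by exhaustive enumeration
#'
#' Enumerates every node subset (graphs up to 12 nodes); for a fixed subset
#' the cheapest forest spanning it is the minimum spanning forest of the
#' induced subgraph with every MST edge costing more than `omega` removed
#' (each removal trades one edge for one extra tree). Ties are broken by
#' fewer edges, then by the lexicographically smallest node set.
#'
#' @inheritParams solve_pcsf
#' @return the optimal `pcsf_forest`.
#' @export
brute_force_pcsf <- function(g, terminals, params) {
  n <- igraph::vcount(g)
  if (n > 12) stop("brute_force_pcsf refuses instances with more than 12 nodes")
  pr <- suppressWarnings(adjust_prizes(terminals, g, params))
  vn <- names(pr)
  pos <- pmax(pr, 0)
  ncost <- pmax(-pr, 0)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  ecost <- pmax(edge_costs(g), 0)
  tol <- 1e-9

  best <- empty_forest(sum(pos))
  best_key <- ""
  for (mask in seq_len(2^n - 1)) {
    inb <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    vin <- which(inb)
    base <- sum(pos[!inb]) + sum(ncost[inb])
    if (base - tol > best$objective) next
    # Kruskal over edges inside the subset
    esub <- which(inb[ends[, 1]] & inb[ends[, 2]])
    esub <- esub[order(ecost[esub])]
    comp <- seq_len(n)          # union-find over vertex indices
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    mst <- integer(0)
    for (e in esub) {
      a <- find(ends[e, 1]); b <- find(ends[e, 2])
      if (a != b) { comp[a] <- b; mst <- c(mst, e) }
    }
    # drop MST edges that cost at least omega: trading the edge for an extra
    # tree is never worse, and ties resolve toward fewer edges
    kept <- mst[ecost[mst] < params$omega]
    kappa <- length(vin) - length(kept)
    objective <- base + sum(ecost[kept]) + params$omega * kappa
    key <- paste(vn[vin], collapse = ",")
    better <- objective < best$objective - tol ||
      (abs(objective - best$objective) <= tol &&
         (length(kept) < nrow(best$edges) ||
            (length(kept) == nrow(best$edges) && best_key != "" && key < best_key)))
    if (better) {
      edges <- if (length(kept))
        data.frame(from = vn[ends[kept, 1]], to = vn[ends[kept, 2]],
                   stringsAsFactors = FALSE)
      else data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
      best <- new_forest(vn[vin], edges, as.integer(kappa), objective)
      best_key <- key
    }
  }
  best
}

network_roles <- function(nodes, terminals) {
  src <- stats::setNames(terminals$source, terminals$protein)
  role <- rep("steiner", length(nodes))
  m <- match(nodes, names(src))
  hit <- !is.na(m)
  role[hit] <- c(tf = "terminal_tf", phospho = "terminal_phospho",
                 drug_target = "drug_target")[src[m[hit]]]
  role
}

#' Grid reconstruction: solve, select, merge
#'
#' Solves the PCSF instance at every grid point, scores each solution by
#' (number of terminals included, minus the number of included hub nodes,
#' i.e. nodes with interactome degree above `hub_degree`), keeps all
#' solutions tied at the lexicographic maximum, and merges their nodes and
#' edges into the final condition network with role and edge-origin
#' annotation.
#'
#' @param g condition interactome (possibly augmented with predicted edges).
#' @param terminals terminal set.
#' @param grid list of [pcsf_params()] (default [default_pcsf_grid()]).
#' @param hub_degree degree cutoff defining a "hub" for selection
#'   (default 100).
#' @return object of class `reconstructed_network` with `condition`, `nodes`
#'   (protein, role, prize), `edges` (from, to, weight, origin), `provenance`
#'   (selected parameter sets) and `n_solutions`.
#' @export
grid_reconstruct <- function(g, terminals, grid = default_pcsf_grid(),
                             hub_degree = 100) {
  stopifnot(length(grid) > 0)
  deg <- igraph::degree(g)
  sols <- list()
  for (i in seq_along(grid)) {
    f <- tryCatch(solve_pcsf(g, terminals, grid[[i]]),
                  error = function(e) NULL)
    if (is.null(f)) next
    sols[[length(sols) + 1]] <- list(params = grid[[i]], forest = f,
                                     n_term = sum(f$nodes %in% terminals$protein),
                                     n_hub = sum(deg[f$nodes] > hub_degree))
  }
  if (!length(sols)) stop("all grid points infeasible")
  nt <- vapply(sols, `[[`, numeric(1), "n_term")
  nh <- vapply(sols, `[[`, numeric(1), "n_hub")
  sel <- which(nt == max(nt))
  sel <- sel[nh[sel] == min(nh[sel])]
  nodes <- sort(unique(unlist(lapply(sols[sel], function(s) s$forest$nodes))))
  edges <- do.call(rbind, lapply(sols[sel], function(s) s$forest$edges))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), origin = character(),
                        stringsAsFactors = FALSE)
  } else {
    a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
    dup <- duplicated(paste(a, b, sep = "\r"))
    edges <- data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
    eid <- igraph::get_edge_ids(g, rbind(edges$from, edges$to))
    edges$weight <- igraph::E(g)$weight[eid]
    eo <- igraph::E(g)$origin
    edges$origin <- if (is.null(eo)) "reference" else eo[eid]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  prize <- stats::setNames(terminals$prize, terminals$protein)
  ndf <- data.frame(protein = nodes,
                    role = network_roles(nodes, terminals),
                    prize = ifelse(nodes %in% names(prize), prize[nodes], 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(condition = attr(terminals, "condition"),
                 nodes = ndf, edges = edges,
                 provenance = lapply(sols[sel], `[[`, "params"),
                 n_solutions = length(sel)),
            class = "reconstructed_network")
}

#' @export
print.reconstructed_network <- function(x, ...) {
  cat("Reconstructed network", if (!is.null(x$condition)) paste0("[", x$condition, "]"),
      ":", nrow(x$nodes), "nodes,", nrow(x$edges), "edges;",
      sum(x$nodes$role != "steiner"), "terminals,",
      sum(x$nodes$role == "steiner"), "Steiner nodes;",
      x$n_solutions, "merged solution(s)\n")
  invisible(x)
}

#' Node set of a reconstructed network
#' @param net a `reconstructed_network`.
#' @return character vector of protein ids.
#' @export
network_nodes <- function(net) net$nodes$protein
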