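# Shared fixtures and independent oracles. Toy solver graphs set the weight
# attribute directly (weight ~ 0 gives edge cost ~ 1 exactly where a test
# needs unit costs).

toy_graph <- function(from, to, weight = 1e-12) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::E(g)$weight <- rep_len(weight, igraph::ecount(g))
  igraph::E(g)$origin <- "reference"
  g
}

toy_terminals <- function(protein, prize, source = "phospho", condition = NULL) {
  structure(data.frame(protein = protein, prize = prize,
                       source = rep_len(source, length(protein)),
                       stringsAsFactors = FALSE),
            class = c("terminal_set", "data.frame"), condition = condition)
}

# random connected-ish weighted graph + prized terminals, for oracle trials
random_pcsf_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:8, 1)
  repeat {
    m <- matrix(stats::runif(n * n) < 0.4, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) >= n - 1) break
  }
  vn <- sprintf("v%d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = vn[idx[, 1]], to = vn[idx[, 2]]),
    directed = FALSE, vertices = vn)
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.05, 0.99)
  nt <- sample(2:4, 1)
  ts <- toy_terminals(sample(vn, nt), stats::runif(nt, 0.2, 3))
  params <- pcsf_params(beta = sample(c(1, 2), 1), mu = sample(c(0, 0.1), 1),
                        omega = sample(c(0.5, 1, 2), 1), depth = 10)
  list(g = g, terminals = ts, params = params)
}

random_weighted_graph <- function(seed, n_min = 4, n_max = 8, p = 0.45) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  m <- matrix(stats::runif(n * n) < p, n, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  idx <- which(m, arr.ind = TRUE)
  vn <- sprintf("n%d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = vn[pmin(idx[, 1], idx[, 2])],
               to = vn[pmax(idx[, 1], idx[, 2])]),
    directed = FALSE, vertices = vn)
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 1)
  g
}

# independent Adamic/Adar oracle: double loop over all node pairs
aa_brute_force <- function(g) {
  vn <- igraph::V(g)$name
  deg <- igraph::degree(g)
  out <- list()
  if (length(vn) < 2) return(NULL)
  for (i in seq_along(vn)[-length(vn)]) {
    for (j in (i + 1):length(vn)) {
      if (igraph::are_adjacent(g, vn[i], vn[j])) next
      cm <- intersect(names(igraph::neighbors(g, vn[i])),
                      names(igraph::neighbors(g, vn[j])))
      if (!length(cm)) next
      out[[length(out) + 1]] <- data.frame(
        node_a = min(vn[i], vn[j]), node_b = max(vn[i], vn[j]),
        aa_score = sum(1 / log(deg[cm])), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  df[order(-df$aa_score, df$node_a, df$node_b), , drop = FALSE]
}

# independent hypergeometric upper-tail oracle by direct summation
hyper_tail_oracle <- function(x, M, N, n) {
  k <- x:min(M, n)
  sum(choose(M, k) * choose(N - M, n - k)) / choose(N, n)
}

# cached default cohort / pipeline result (expensive; built once per run)
.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- generate_cohort(cohort_config())
  .fixture_cache$bundle
}

default_pipeline_result <- function() {
  if (is.null(.fixture_cache$pipeline))
    .fixture_cache$pipeline <- run_pipeline(pipeline_config())
  .fixture_cache$pipeline
}
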