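test_that("interactome construction validates weights and loops", {
  expect_error(make_interactome(data.frame(node_a = "a", node_b = "a", weight = 0.5)),
               "self-loop")
  expect_error(make_interactome(data.frame(node_a = "a", node_b = "b", weight = 0)),
               "weights")
  g <- make_interactome(data.frame(node_a = c("a", "b", "a"),
                                   node_b = c("b", "a", "c"),
                                   weight = c(0.4, 0.9, 0.2)))
  expect_equal(igraph::ecount(g), 2)        # duplicate collapsed
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(g)$weight[eid], 0.9)    # highest confidence kept
  expect_equal(edge_costs(g)[eid], 0.1)
})

test_that("hub removal requires both degree clauses and strips self-loops", {
  # star on 10 nodes: center degree 9; mean degree 1.8, SD ~ 2.4
  star <- toy_graph(rep("hub", 9), paste0("leaf", 1:9), weight = 0.5)
  deg <- igraph::degree(star)
  expect_equal(mean(deg), 1.8)
  res <- remove_hubs(star, deg_thresh = 3, sd_mult = 1)
  expect_identical(res$removed, "hub")
  expect_equal(igraph::ecount(res$graph), 0)
  # thresholds not met: graph unchanged
  res2 <- remove_hubs(star)   # defaults 900 / 10 SD
  expect_identical(res2$removed, character(0))
  expect_equal(igraph::ecount(res2$graph), 9)
  # self-loops go regardless of degree
  gl <- igraph::add_edges(star, c("leaf1", "leaf1"), attr = list(weight = 0.5))
  res3 <- remove_hubs(gl)
  expect_false(igraph::any_loop(res3$graph))
})

test_that("expression filter drops edges with a low-expressed endpoint", {
  g <- toy_graph(c("a", "b", "c"), c("b", "c", "d"), weight = 0.5)
  expr <- c(a = 1.5, b = 2.5, c = 3)            # d unmeasured
  gf <- expression_filter(g, expr)
  expect_equal(igraph::ecount(gf), 2)       # a-b removed
  expect_identical(igraph::get_edge_ids(gf, c("a", "b")), 0)
  expect_gt(igraph::get_edge_ids(gf, c("c", "d")), 0)  # unknown endpoint kept
  expect_equal(igraph::ecount(expression_filter(g, expr, thresh = 0)), 3)
})

test_that("Adamic/Adar matches hand case, brute force and igraph", {
  # square a-c, c-b, a-d, d-b: Score(a,b) = 2/ln 2
  sq <- toy_graph(c("a", "c", "a", "d"), c("c", "b", "d", "b"), weight = 0.5)
  sc <- adamic_adar_scores(sq, top_k = 10)
  expect_equal(sc$aa_score[sc$node_a == "a" & sc$node_b == "b"],
               2 / log(2), tolerance = 1e-12)
  # never emits existing edges and never introduces pairs without common
  # neighbors
  for (seed in 1:25) {
    g <- random_weighted_graph(seed)
    got <- adamic_adar_scores(g, top_k = igraph::vcount(g)^2)
    oracle <- aa_brute_force(g)
    if (is.null(oracle)) {
      expect_identical(nrow(got), 0L)
      next
    }
    expect_equal(got[c("node_a", "node_b")], oracle[c("node_a", "node_b")],
                 ignore_attr = TRUE)
    expect_equal(got$aa_score, oracle$aa_score, tolerance = 1e-10)
    eid <- igraph::get_edge_ids(g, rbind(got$node_a, got$node_b))
    expect_true(all(eid == 0))
    # cross-check scores against igraph's inverse-log-weighted similarity
    sim <- igraph::similarity(g, method = "invlogweighted")
    rownames(sim) <- colnames(sim) <- igraph::V(g)$name
    expect_equal(got$aa_score, sim[cbind(got$node_a, got$node_b)],
                 tolerance = 1e-10)
  }
})

test_that("top_k selection is bounded and deterministically tie-broken", {
  sq <- toy_graph(c("a", "c", "a", "d"), c("c", "b", "d", "b"), weight = 0.5)
  all_sc <- adamic_adar_scores(sq, top_k = 100)
  expect_identical(adamic_adar_scores(sq), utils::head(all_sc, igraph::ecount(sq)))
  one <- adamic_adar_scores(sq, top_k = 1)
  expect_identical(nrow(one), 1L)
  # equal scores for (a,b) and (c,d): lexicographic pair id wins
  expect_identical(one$node_a, "a")
})

test_that("localization filter keeps shared or unknown compartments", {
  preds <- data.frame(node_a = c("p", "p", "p"), node_b = c("q", "r", "s"),
                      aa_score = c(3, 2, 1))
  loc <- list(p = "nucleus", q = c("nucleus", "cytosol"), r = "membrane")
  out <- localization_filter(preds, loc)     # s unannotated -> kept
  expect_setequal(out$node_b, c("q", "s"))
})

test_that("augmentation scales surviving scores onto [0, 0.5]", {
  g <- toy_graph(c("a", "b", "c", "d"), c("b", "c", "d", "e"), weight = 0.8)
  preds <- data.frame(node_a = c("a", "a", "b"), node_b = c("c", "d", "e"),
                      aa_score = c(2, 4, 6))
  ga <- augment_interactome(g, preds)
  w <- igraph::E(ga)$weight[igraph::E(ga)$origin == "predicted"]
  expect_equal(sort(w), c(0, 0.25, 0.5))
  expect_equal(igraph::vcount(ga), igraph::vcount(g))  # no new nodes
  # degenerate scaling: all equal -> all 0.5
  ga2 <- augment_interactome(g, data.frame(node_a = "a", node_b = "c",
                                           aa_score = 7))
  expect_equal(igraph::E(ga2)$weight[igraph::E(ga2)$origin == "predicted"], 0.5)
  # empty predictions leave the graph unchanged
  expect_equal(igraph::ecount(augment_interactome(g, preds[0, ])),
                   igraph::ecount(g))
  # duplicates of existing edges are skipped with a warning
  expect_warning(ga3 <- augment_interactome(g, data.frame(
    node_a = c("a", "a"), node_b = c("b", "d"), aa_score = c(1, 2))),
    "duplicate")
  expect_equal(igraph::ecount(ga3), igraph::ecount(g) + 1)
})

test_that("prepared condition interactome respects the fixed stage order", {
  b <- default_bundle()
  key <- names(b$panels)[1]
  expr <- rowMeans(b$panels[[key]]$treated)
  prep <- prepare_interactome(b$interactome, expr, b$localization)
  expect_true(all(igraph::E(prep$graph)$weight > 0 |
                    igraph::E(prep$graph)$origin == "predicted"))
  no <- table(igraph::E(prep$graph)$origin)
  expect_lte(prep$n_predicted,
             igraph::ecount(prep$graph) - prep$n_predicted)  # |pred| <= |E(processed)|
  # predicted edges introduce no new nodes by construction
  expect_true(all(igraph::V(prep$graph)$name %in% igraph::V(b$interactome)$name))
})
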