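test_that("adjusted prizes implement beta*p - mu*degree", {
  g <- toy_graph(c("v", "v", "w"), c("a", "b", "a"), weight = 0.5)
  ts <- toy_terminals("v", 2)
  pr <- adjust_prizes(ts, g, pcsf_params(beta = 3, mu = 0.1))
  expect_equal(unname(pr["v"]), 3 * 2 - 0.1 * 2)
  # mu = 0: p' = beta * p, non-terminals at 0
  pr0 <- adjust_prizes(ts, g, pcsf_params(beta = 3, mu = 0))
  expect_equal(unname(pr0["v"]), 6)
  expect_equal(unname(pr0["a"]), 0)
  # non-terminal with mu > 0 goes negative by mu * degree
  pr2 <- adjust_prizes(ts, g, pcsf_params(beta = 1, mu = 0.5))
  expect_equal(unname(pr2["a"]), -1)   # degree 2
  expect_warning(adjust_prizes(toy_terminals(c("v", "zz"), c(1, 1)), g,
                               pcsf_params()), "absent")
})

test_that("objective evaluates excluded prizes, edge costs and tree penalty", {
  g <- toy_graph(c("t1", "s"), c("s", "t2"))        # edge costs ~ 1
  ts <- toy_terminals(c("t1", "t2"), c(5, 5))
  pp <- pcsf_params(beta = 1, mu = 0, omega = 1)
  path_forest <- list(nodes = c("t1", "s", "t2"),
                      edges = data.frame(from = c("t1", "s"), to = c("s", "t2")),
                      kappa = 1L)
  expect_equal(pcsf_objective(path_forest, g, ts, pp), 3, tolerance = 1e-6)
  two_singletons <- list(nodes = c("t1", "t2"),
                         edges = data.frame(from = character(), to = character()),
                         kappa = 2L)
  expect_equal(pcsf_objective(two_singletons, g, ts, pp), 2)
  empty <- list(nodes = character(),
                edges = data.frame(from = character(), to = character()),
                kappa = 0L)
  expect_equal(pcsf_objective(empty, g, ts, pp), 10)
  bad <- list(nodes = c("t1", "t2"),
              edges = data.frame(from = "t1", to = "t2"), kappa = 1L)
  expect_error(pcsf_objective(bad, g, ts, pp), "not present")
})

test_that("brute force reproduces hand-enumerated optima", {
  pp <- pcsf_params(beta = 1, mu = 0, omega = 1)
  # two singletons beat the connected path (2 < 3)
  g <- toy_graph(c("t1", "s"), c("s", "t2"))
  ts <- toy_terminals(c("t1", "t2"), c(5, 5))
  bf <- brute_force_pcsf(g, ts, pp)
  expect_equal(bf$objective, 2)
  expect_identical(bf$kappa, 2L)
  # single terminal: singleton forest, f' = omega
  g1 <- toy_graph("t", "x")
  bf1 <- brute_force_pcsf(g1, toy_terminals("t", 5), pp)
  expect_equal(bf1$objective, 1)
  expect_identical(bf1$nodes, "t")
  # all prizes zero: empty forest optimal at 0 (solver would refuse)
  bf0 <- brute_force_pcsf(g1, toy_terminals("t", 0), pp)
  expect_equal(bf0$objective, 0)
  expect_length(bf0$nodes, 0)
  # triangle of terminals, unit costs: one tree with 2 edges, f' = 3
  g3 <- toy_graph(c("a", "b", "c"), c("b", "c", "a"))
  bf3 <- brute_force_pcsf(g3, toy_terminals(c("a", "b", "c"), c(10, 10, 10)), pp)
  expect_equal(bf3$objective, 3, tolerance = 1e-6)
  expect_identical(nrow(bf3$edges), 2L)
  expect_identical(bf3$kappa, 1L)
  expect_error(brute_force_pcsf(toy_graph(letters[1:13], c(letters[2:13], "a")),
                                toy_terminals("a", 1), pp), "12")
})

test_that("heuristic keeps profitable isolated terminals and drops weak ones", {
  pp <- pcsf_params(beta = 1, mu = 0, omega = 1)
  g <- toy_graph(c("t1", "s", "iso"), c("s", "t2", "far"))
  # isolated component terminal with p' = 5 > omega: kept as singleton
  ts <- toy_terminals(c("t1", "t2", "iso"), c(5, 5, 5))
  f <- solve_pcsf(g, ts, pp)
  expect_true("iso" %in% f$nodes)
  # p' = 0.5 < omega: excluded entirely
  ts2 <- toy_terminals("iso", 0.5)
  f2 <- solve_pcsf(g, ts2, pp)
  expect_length(f2$nodes, 0)
  expect_error(solve_pcsf(g, toy_terminals("t1", 0), pp), "infeasible")
})

test_that("heuristic is admissible against the exact oracle", {
  eq <- 0
  for (seed in 1:100) {
    ins <- random_pcsf_instance(seed)
    bf <- brute_force_pcsf(ins$g, ins$terminals, ins$params)
    hf <- solve_pcsf(ins$g, ins$terminals, ins$params)
    expect_gte(hf$objective, bf$objective - 1e-9)
    pr <- adjust_prizes(ins$terminals, ins$g, ins$params)
    expect_lte(hf$objective, sum(pmax(pr, 0)) + 1e-9)
    if (abs(hf$objective - bf$objective) <= 1e-9) eq <- eq + 1
    # structural invariants: acyclic forest, every tree holds a terminal
    if (length(hf$nodes)) {
      fg <- igraph::graph_from_data_frame(hf$edges, directed = FALSE,
                                          vertices = hf$nodes)
      comp <- igraph::components(fg)
      # |E| = |V| - kappa together with kappa components <=> acyclic forest
      expect_equal(igraph::ecount(fg), length(hf$nodes) - hf$kappa)
      expect_equal(comp$no, hf$kappa)
      for (cid in seq_len(comp$no)) {
        members <- names(comp$membership)[comp$membership == cid]
        expect_gt(length(intersect(members, ins$terminals$protein)), 0)
      }
    }
  }
  expect_gte(eq, 80)
})

test_that("solver output is deterministic", {
  ins <- random_pcsf_instance(11)
  a <- solve_pcsf(ins$g, ins$terminals, ins$params)
  b <- solve_pcsf(ins$g, ins$terminals, ins$params)
  expect_identical(a, b)
})

test_that("raising mu never adds hub nodes on oracle instances", {
  for (seed in 1:20) {
    ins <- random_pcsf_instance(seed + 500)
    deg <- igraph::degree(ins$g)
    thresh <- stats::quantile(deg, 0.75)
    counts <- vapply(c(0, 0.05, 0.15, 0.4), function(mu) {
      pp <- pcsf_params(beta = ins$params$beta, mu = mu,
                        omega = ins$params$omega)
      bf <- brute_force_pcsf(ins$g, ins$terminals, pp)
      sum(deg[bf$nodes] > thresh)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("grid reconstruction selects by terminals then hub count and merges ties", {
  g <- toy_graph(c("t1", "s", "t3"), c("s", "t2", "t2"), weight = 0.9)
  ts <- toy_terminals(c("t1", "t2", "t3"), c(2, 2, 1), source = "tf",
                      condition = "CL::drug")
  net1 <- grid_reconstruct(g, ts, grid = list(pcsf_params(beta = 5, omega = 1)))
  expect_s3_class(net1, "reconstructed_network")
  expect_identical(net1$n_solutions, 1L)
  expect_identical(net1$condition, "CL::drug")
  # a grid with a dominating high-beta point: that solution's terminals win
  net2 <- grid_reconstruct(g, ts, grid = list(pcsf_params(beta = 0.1, omega = 1),
                                              pcsf_params(beta = 5, omega = 1)))
  n_term <- function(net) sum(net$nodes$role != "steiner")
  expect_gte(n_term(net2), n_term(net1))
  # union rule: merged network contains every tied solution's nodes
  nets <- grid_reconstruct(g, ts, grid = list(pcsf_params(beta = 5, omega = 1),
                                              pcsf_params(beta = 5, omega = 1.5)))
  expect_true(all(net1$nodes$protein %in% nets$nodes$protein))
  # roles annotated from the terminal set
  expect_true(all(net1$nodes$role[net1$nodes$protein %in% ts$protein] ==
                    "terminal_tf"))
})
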