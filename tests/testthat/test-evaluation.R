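test_that("classification metrics handle perfect and degenerate cases", {
  perfect <- classification_metrics(10, 0, 0, 20)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  nothing <- classification_metrics(0, 0, 5, 10, threshold = -99)
  expect_true(nothing$degenerate)
  expect_equal(nothing$precision, 0)
  expect_equal(nothing$mcc, 0)    # zero-denominator convention
})

test_that("MCC is invariant under class swap with prediction complementation", {
  # swapping positive/negative labels together with the prediction direction
  # maps (tp, fp, fn, tn) -> (tn, fn, fp, tp) and must preserve MCC; checked
  # against a brute-force enumeration of small confusion tables
  for (tp in 0:3) for (fp in 0:3) for (fn in 0:3) for (tn in 0:3) {
    a <- classification_metrics(tp, fp, fn, tn)
    b <- classification_metrics(tn, fn, fp, tp)
    mcc_oracle <- function(tp, fp, fn, tn) {
      d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
    }
    expect_equal(a$mcc, mcc_oracle(tp, fp, fn, tn))
    expect_equal(a$mcc, b$mcc)
  }
})

toy_sepmat <- function() {
  # 2 cell lines x 2 drugs; same-MoA pairs score low, cross-MoA high
  nets <- list("CL1::d1" = "x", "CL1::d2" = "x", "CL2::d1" = "x", "CL2::d2" = "x")
  scores <- c("CL1::d1|CL1::d2" = -0.5, "CL1::d1|CL2::d1" = -0.6,
              "CL1::d1|CL2::d2" = 0.4, "CL1::d2|CL2::d1" = 0.5,
              "CL1::d2|CL2::d2" = -0.4, "CL2::d1|CL2::d2" = 0.6)
  ids <- names(nets)
  det <- do.call(rbind, lapply(names(scores), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(cond_a = p[1], cond_b = p[2], s_ab = scores[[k]], d_ab = NA,
               d_aa = NA, d_bb = NA, n_common = 0L, class = NA_character_)
  }))
  structure(list(scores = NULL, classes = NULL,
                 conditions = condition_parts_for_test(ids), details = det),
            class = "separation_matrix")
}
condition_parts_for_test <- function(ids)
  getFromNamespace("condition_parts", "drugnetstrat")(ids)

test_that("pair classification pools within cell lines by default", {
  m <- toy_sepmat()
  moa <- c(d1 = "m1", d2 = "m2")
  got <- classify_pairs(m, moa, threshold = 0)
  # same-cell-line pairs: (CL1::d1, CL1::d2) s=-0.5 and (CL2::d1, CL2::d2)
  # s=0.6; both are different-MoA -> one FP, one TN
  expect_equal(got$tp, 0); expect_equal(got$fp, 1)
  expect_equal(got$fn, 0); expect_equal(got$tn, 1)
  all_pairs <- classify_pairs(m, moa, threshold = 0, pairs = "all")
  expect_equal(all_pairs$tp + all_pairs$fp + all_pairs$fn + all_pairs$tn, 6)
  expect_equal(all_pairs$tp, 2)   # the two same-MoA cross-cell-line pairs
  expect_error(classify_pairs(m, c(d1 = "m1"), 0), "MoA label")
})

test_that("threshold sweep finds the MCC-best cutoff with monotone ROC", {
  m <- toy_sepmat()
  moa <- c(d1 = "m1", d2 = "m2")
  sw <- sweep_thresholds(m, moa, pairs = "all")
  expect_true(all(diff(sw$curve$tpr) >= 0))
  expect_true(all(diff(sw$curve$fpr) >= 0))
  # rank-based oracle: positives {-0.6, -0.4}, negatives {-0.5, 0.4, 0.5,
  # 0.6}; 7 of the 8 cross pairs rank the positive lower
  expect_equal(sw$auc, 7 / 8)
  # best cut sits between -0.4 and 0.4: tp=2 fp=1 fn=0 tn=3
  expect_equal(sw$best$mcc, 6 / sqrt(72))
  expect_gt(sw$best$threshold, -0.4)
  expect_lt(sw$best$threshold, 0.4)
  # independent AUC cross-check (pROC ranks by the same score direction)
  if (requireNamespace("pROC", quietly = TRUE)) {
    tab <- drugnetstrat:::moa_pair_table(m, moa, "all")
    roc <- pROC::roc(response = tab$same_moa, predictor = tab$s_ab,
                     direction = ">", quiet = TRUE)
    expect_equal(sw$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-9)
  }
  # a one-point grid returns that point
  one <- sweep_thresholds(m, moa, thresholds = 0.1, pairs = "all")
  expect_equal(one$best$threshold, 0.1)
  # degenerate single-class labels are flagged
  expect_warning(sw2 <- sweep_thresholds(m, c(d1 = "m1", d2 = "m1"),
                                         pairs = "all"), "degenerate")
  expect_true(sw2$degenerate)
})

test_that("tanimoto similarity follows the set definition", {
  expect_equal(tanimoto(c("b1", "b2"), c("b1", "b2")), 1)
  expect_equal(tanimoto("b1", "b2"), 0)
  expect_equal(tanimoto(c("b1", "b2", "b3"), c("b2", "b3", "b4")), 0.5)
  expect_error(tanimoto(character(0), character(0)), "empty")
})

test_that("combination rating applies the complementary-exposure rules", {
  mk_net <- function(n, cond) {
    nodes <- sprintf("%s_n%03d", cond, seq_len(n))
    nodes[1] <- "BRAF"   # shared driver candidate
    structure(list(condition = cond,
                   nodes = data.frame(protein = nodes, role = "steiner",
                                      prize = 0),
                   edges = data.frame(from = character(), to = character())),
              class = "reconstructed_network")
  }
  nets <- list("CL1::dA" = mk_net(120, "CL1::dA"), "CL1::dB" = mk_net(60, "CL1::dB"),
               "CL1::dC" = mk_net(35, "CL1::dC"))
  enr <- function(sig) data.frame(set = "Jak-STAT signaling pathway",
                                  significant = sig)
  enrichments <- list("CL1::dA" = enr(FALSE), "CL1::dB" = enr(FALSE),
                      "CL1::dC" = enr(FALSE))
  det <- data.frame(cond_a = c("CL1::dA", "CL1::dA", "CL1::dB"),
                    cond_b = c("CL1::dB", "CL1::dC", "CL1::dC"),
                    s_ab = c(0.69, -0.2, 0.5), d_ab = NA, d_aa = NA, d_bb = NA,
                    n_common = 1L, class = NA_character_)
  m <- structure(list(details = det), class = "separation_matrix")
  cand <- predict_combinations(nets, enrichments, m, drivers = "BRAF")
  expect_equal(cand$s_ab, sort(cand$s_ab, decreasing = TRUE))
  top <- cand[cand$cond_a == "CL1::dA" & cand$cond_b == "CL1::dB", ]
  expect_true(top$passes_rating)        # 0.69, 0 shared, sizes 120/60
  expect_true(top$passes_driver_rule)   # BRAF shared, separated
  neg <- cand[cand$s_ab < 0, ]
  expect_false(any(neg$passes_rating) || any(neg$passes_driver_rule))
  small <- cand[cand$cond_b == "CL1::dC" & cand$cond_a == "CL1::dB", ]
  expect_false(small$passes_rating)     # 35-node network too small
  # flags are pure functions of the recorded fields
  with(cand, expect_identical(passes_rating,
    s_ab > 0 & shared_pathways < 2 & pmin(nodes_a, nodes_b) > 40 &
      pmax(nodes_a, nodes_b) > 100))
  # missing enrichment: candidate skipped with warning
  w <- testthat::capture_warnings(
    cand2 <- predict_combinations(nets, enrichments[-2], m, drivers = "BRAF"))
  expect_match(w, "missing enrichment", all = FALSE)
  expect_equal(nrow(cand2), 1)
})

test_that("sensitivity association filters signs and the separation floor", {
  det <- data.frame(cond_a = sprintf("CL1::d%d", 1:6),
                    cond_b = sprintf("CL2::d%d", 1:6),
                    s_ab = c(0.1, 0.4, 0.8, -0.6, 0.2, 0.6),
                    d_ab = NA, d_aa = NA, d_bb = NA, n_common = 0L,
                    class = NA_character_)
  m <- structure(list(details = det), class = "separation_matrix")
  sens <- data.frame(
    cell_line = rep(c("CL1", "CL2"), each = 6),
    drug = rep(sprintf("d%d", 1:6), 2),
    z = c(-1, -2, -3, -1, 1, -2.5,    # CL1 side
          2, 1, 3, 2, 2, 1.5))        # CL2 side
  res <- sensitivity_association(m, sens)
  # pair 4 fails the floor (-0.6 <= -0.45), pair 5 has two non-negative z
  expect_equal(res$n, 4L)
  expect_true(res$R >= -1 && res$R <= 1)
  # perfectly linear filtered data gives R = 1
  det2 <- det; det2$s_ab <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  sens2 <- sens; sens2$z <- c(-(1:6) / 2, rep(1, 6))
  m2 <- structure(list(details = det2), class = "separation_matrix")
  expect_equal(sensitivity_association(m2, sens2)$R, 1, tolerance = 1e-9)
  # both z negative everywhere -> no usable pairs
  sens3 <- sens; sens3$z <- -abs(sens3$z)
  expect_error(sensitivity_association(m, sens3), "insufficient")
})
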