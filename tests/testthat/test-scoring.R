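# a small calibrated model shared by the scoring tests
local_params <- function(gu = TRUE) {
  d <- make_duplex(12, seed = 41, gu_frac = if (gu) 0.25 else 0)
  h <- make_hairpin(6, 4, seed = 42, gu_frac = if (gu) 0.25 else 0)
  cssr_calibrate(list(d$structure, h$structure), list(d$truth, h$truth))
}

test_that("candidate enumeration follows the compatibility and separation rules", {
  # G:G is never canonical
  g4 <- make_hairpin(2, 4, seed = 43)
  x <- g4$structure
  x$chains[[1]]$bases <- rep("G", 8)
  expect_equal(nrow(candidate_pairs(x)), 0L)
  # GAAAC with min_separation 4: exactly the (1, 5) terminal pair
  h <- make_hairpin(2, 4, seed = 44)
  x2 <- h$structure
  x2$chains[[1]]$bases <- c("G", "A", "A", "A", "C", "A", "A", "A")
  cand <- candidate_pairs(x2)
  expect_true(any(cand$i == 1 & cand$j == 5))
  x3 <- x2
  x3$chains[[1]]$bases <- c("G", "A", "A", "A", "C", "C", "C", "C")[1:8]
  # restrict to 5 residues to mirror the minimal example
  ch <- x3$chains[[1]]
  x3 <- new_rna_structure_for_test(list(new_rna_chain_for_test(
    "A", c("G", "A", "A", "A", "C"),
    lapply(ch$xyz, function(m) m[1:5, , drop = FALSE]))))
  cand3 <- candidate_pairs(x3)
  expect_equal(nrow(cand3), 1L)
  expect_equal(c(cand3$i, cand3$j), c(1L, 5L))
  expect_identical(cand3$class, "WC")
})

test_that("candidate sets equal the brute-force oracle on random chains", {
  for (seed in 45:48) {
    fx <- make_hairpin(8, 6, seed = seed, gu_frac = 0.3)
    x <- add_noise(fx$structure, 0.4, seed = seed)
    got <- candidate_pairs(x)
    want <- o_candidates(x)
    expect_equal(got[order(got$i, got$j), , drop = FALSE]$i, want$i)
    expect_equal(got[order(got$i, got$j), , drop = FALSE]$j, want$j)
  }
  # inter-chain flag
  d <- make_duplex(6, seed = 49)
  expect_equal(nrow(candidate_pairs(d$structure)),
               nrow(o_candidates(d$structure)))
  expect_equal(nrow(candidate_pairs(d$structure, inter_chain = TRUE)),
               nrow(o_candidates(d$structure, inter_chain = TRUE)))
})

test_that("term values handle chain boundaries and match hand computation", {
  fx <- make_hairpin(6, 4, seed = 50)
  x <- fx$structure
  # 5' terminal stem pair (1, 16): no i-1, so dist_down and dih_j absent
  expect_true(is.na(term_value(x, 1, 16, "P", "dist_down")))
  expect_true(is.na(term_value(x, 1, 16, "P", "dih_j")))
  expect_false(is.na(term_value(x, 1, 16, "P", "dist0")))
  # interior pair: all 7 P sub-terms present and equal to scalar recomputation
  res <- o_residues(x)
  for (k in cssr_term_kinds()) {
    v <- term_value(x, 3, 14, "P", k)
    expect_false(is.na(v))
    expect_equal(v, o_term(res, 3, 14, "P", k), tolerance = 1e-10)
  }
})

test_that("score is 1 at the calibrated means and follows the half-max rule", {
  p <- local_params()
  fx <- make_hairpin(6, 4, seed = 51)
  sc <- cssr_score_pairs(fx$structure, p)
  truth_keys <- paste(fx$truth$pairs[, 1], fx$truth$pairs[, 2])
  sc_truth <- sc[paste(sc$i, sc$j) %in% truth_keys, ]
  expect_equal(sc_truth$score, rep(1, nrow(sc_truth)), tolerance = 1e-9)

  # single-term model: a deviation of sigma * sqrt(2 log 2) scores exactly 0.5
  tab <- data.frame(class = "WC", atom = "P", kind = "dist0",
                    mean = 18, sigma = 0.5, n_obs = 10)
  p1 <- cssr:::new_cssr_params(tab, 1e-2, "single cell")
  delta <- 0.5 * sqrt(2 * log(2))
  mk <- function(d) {
    xyz <- list(P = rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0),
                          c(18 + d, 0, 0)))
    new_rna_structure_for_test(list(new_rna_chain_for_test(
      "A", c("G", "A", "A", "A", "C"), xyz)))
  }
  s <- cssr_score_pairs(mk(delta), p1)
  expect_equal(s$score, 0.5, tolerance = 1e-12)
  expect_equal(s$n_terms, 1L)
  expect_equal(cssr_score_pairs(mk(0), p1)$score, 1, tolerance = 1e-12)
})

test_that("score is symmetric, bounded, and decays monotonically", {
  p <- local_params()
  set.seed(52)
  fx <- make_hairpin(7, 5, gu_frac = 0.3)
  x <- add_noise(fx$structure, 0.6)
  sc <- cssr_score_pairs(x, p)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  for (r in sample(nrow(sc), 5)) {
    s_ij <- cssr_score(x, sc$i[r], sc$j[r], p)
    s_ji <- cssr_score(x, sc$j[r], sc$i[r], p)
    expect_identical(s_ij$score, s_ji$score)
  }
  # monotone decay in a one-term model
  tab <- data.frame(class = "WC", atom = "P", kind = "dist0",
                    mean = 18, sigma = 0.5, n_obs = 10)
  p1 <- cssr:::new_cssr_params(tab, 1e-2, "single cell")
  deltas <- seq(0, 3, by = 0.25)
  scores <- vapply(deltas, function(d) {
    xyz <- list(P = rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0),
                          c(18 + d, 0, 0)))
    x1 <- new_rna_structure_for_test(list(new_rna_chain_for_test(
      "A", c("G", "A", "A", "A", "C"), xyz)))
    cssr_score_pairs(x1, p1)$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("missing atoms shrink the denominator, never the other terms", {
  p <- local_params()
  fx <- make_hairpin(6, 4, seed = 53)
  x <- add_noise(fx$structure, 0.3, seed = 53)
  sc_p <- cssr_score_pairs(x, p, atoms = "P")
  expect_true(all(sc_p$n_terms <= 7))
  # ablating the structure equals restricting the scored atom set
  xp <- subset_atoms(x, "P")
  sc_p2 <- cssr_score_pairs(xp, p)
  expect_equal(sc_p$score, sc_p2$score, tolerance = 1e-12)
  # the P contributions are identical whether or not C4' also contributes
  res <- o_residues(x)
  pair <- c(sc_p$i[3], sc_p$j[3])
  both <- o_score(x, pair[1], pair[2], p, atoms = c("P", "C4'"))
  only_p <- o_score(x, pair[1], pair[2], p, atoms = "P")
  only_c4 <- o_score(x, pair[1], pair[2], p, atoms = "C4'")
  expect_equal(both$score * both$n_terms,
               only_p$score * only_p$n_terms +
                 only_c4$score * only_c4$n_terms, tolerance = 1e-12)
})

test_that("flat and nested averaging agree with the explicit-loop oracle", {
  p <- local_params()
  set.seed(54)
  fx <- make_hairpin(6, 5, gu_frac = 0.3)
  x <- add_noise(fx$structure, 0.5)
  # knock out some atoms so per-atom term counts differ between atom types
  x$chains[[1]]$xyz$P[c(2, 5, 9), ] <- NA_real_
  x$chains[[1]]$xyz$N[c(3, 11), ] <- NA_real_
  flat <- cssr_score_pairs(x, p)
  nested <- cssr_score_pairs(x, p, average = "nested")
  for (r in sample(nrow(flat), 8)) {
    o_f <- o_score(x, flat$i[r], flat$j[r], p)
    expect_equal(flat$score[r], o_f$score, tolerance = 1e-12)
    o_n <- o_score(x, nested$i[r], nested$j[r], p, nested = TRUE)
    expect_equal(nested$score[r], o_n$score, tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(flat$score, nested$score)))
})
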