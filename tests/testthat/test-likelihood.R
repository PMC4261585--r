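test_that("transition_probs: identity at nu = 0, 2-state ER closed form,
          stationary limit", {
  q <- calibrate_q(assemble_q(make_model_spec("ER", 2)))
  expect_equal(transition_probs(q, 0), diag(2))

  # calibrated 2-state ER: P_01(nu) = (1 - exp(-2 nu)) / 2
  for (nu in c(0.01, 0.1, log(2) / 2, 1, 3)) {
    expect_lt(abs(transition_probs(q, nu)[1, 2] - (1 - exp(-2 * nu)) / 2),
              1e-10)
  }
  expect_equal(transition_probs(q, log(2) / 2)[1, 2], 0.25)

  # very long branch: every row approaches the uniform stationary law
  q3 <- calibrate_q(assemble_q(make_model_spec("ER", 3)))
  p <- transition_probs(q3, 1e6)
  expect_lt(max(abs(p - 1 / 3)), 1e-8)

  expect_error(transition_probs(q, -1), "nonnegative")
  expect_error(transition_probs(q, Inf), "finite")
  # rows sum to 1 across regimes
  for (nu in c(1e-8, 1, 50)) {
    expect_lt(max(abs(rowSums(transition_probs(q3, nu)) - 1)), 1e-10)
  }
})

test_that("pattern_loglik degenerate cases on a zero-length tree", {
  tr <- parse_newick("(A:0,B:0);")
  cfg <- lik_config(make_model_spec("ER", 2), mu = 1)
  # P = I: only root state 0 contributes, weight pi_0 = 1/2
  expect_equal(pattern_loglik(tr, c(A = 0L, B = 0L), cfg), log(0.5))
  # impossible pattern under P = I
  expect_identical(pattern_loglik(tr, c(A = 0L, B = 1L), cfg), -Inf)
})

test_that("pruning equals exhaustive ancestral-state enumeration", {
  set.seed(21)
  newicks <- c(
    "((A:0.3,B:0.7):0.2,C:0.5);",
    "((A:0.3,B:0.7):0.2,(C:0.5,D:0.1):0.4);",
    "(((A:0.2,B:0.4):0.3,C:0.6):0.2,(D:0.5,E:0.1):0.7);")
  for (nw in newicks) {
    tr <- parse_newick(nw)
    ntip <- length(tr$tip.label)
    for (a in 2:3) {
      for (model in c("ER", "SYM", "ARD")) {
        spec <- make_model_spec(model, a)
        rel <- runif(spec$n_params, 0.3, 2.5)
        pi <- rgamma(a, 2); pi <- pi / sum(pi)
        cfg <- lik_config(spec, mu = runif(1, 0.3, 2), rel_rates = rel,
                          pi = pi)
        pat <- sample(0:(a - 1L), ntip, replace = TRUE)
        names(pat) <- tr$tip.label
        expect_equal(pattern_loglik(tr, pat, cfg),
                     enum_loglik(tr, unname(pat[tr$tip.label]), cfg),
                     tolerance = 1e-9, label = paste(nw, a, model))
      }
    }
  }
})

test_that("unobservable_loglik is the all-zero pattern likelihood", {
  # zero-length star tree, a = 2, uniform pi -> L_- = 1/2
  tr <- parse_newick("(A:0,B:0,C:0);")
  cfg <- lik_config(make_model_spec("ER", 2))
  expect_equal(unobservable_loglik(tr, cfg), log(0.5))

  # mu -> 0: no transitions occur, L_- -> pi_0
  tr2 <- parse_newick("((A:0.4,B:0.6):0.3,C:0.8);")
  pi <- c(0.7, 0.3)
  cfg2 <- lik_config(make_model_spec("SYM", 2), mu = 1e-8, pi = pi,
                     reversible = TRUE)
  expect_equal(unobservable_loglik(tr2, cfg2), log(0.7),
               tolerance = 1e-6)

  # matches enumeration
  cfg3 <- lik_config(make_model_spec("ER", 2), mu = 1.3)
  expect_equal(unobservable_loglik(tr2, cfg3),
               enum_loglik(tr2, c(0L, 0L, 0L), cfg3), tolerance = 1e-9)
})

test_that("total_loglik is the weighted pattern sum without gamma or
          correction", {
  tr <- random_tree(6, seed = 31)
  set.seed(32)
  m <- char_matrix(matrix(sample(0:1, 6 * 40, TRUE), nrow = 6,
                          dimnames = list(tr$tip.label, NULL)))
  cfg <- lik_config(make_model_spec("ER", 2), mu = 0.8)
  ps <- compress_patterns(m)
  per_pattern <- vapply(seq_len(ncol(ps$patterns)), function(j)
    pattern_loglik(tr, setNames(ps$patterns[, j], ps$taxa), cfg),
    numeric(1))
  expect_equal(total_loglik(tr, ps, cfg),
               sum(ps$weights * per_pattern), tolerance = 1e-9)
  # compression is transparent
  expect_equal(total_loglik(tr, m, cfg), total_loglik(tr, ps, cfg))
})

test_that("zero-correction defines a proper conditional distribution over
          observable patterns", {
  tr <- parse_newick("((A:0.4,B:0.6):0.3,C:0.8);")
  cfg <- lik_config(make_model_spec("ER", 2), mu = 1.2,
                    zerocorrection = TRUE)
  pats <- all_patterns(3, 2)
  observable <- pats[, colSums(pats) > 0, drop = FALSE]
  total <- 0
  for (j in seq_len(ncol(observable))) {
    m <- char_matrix(matrix(observable[, j], ncol = 1,
                            dimnames = list(tr$tip.label, NULL)),
                     nstates = 2)
    total <- total + exp(total_loglik(tr, m, cfg))
  }
  expect_lt(abs(total - 1), 1e-9)

  # corrected lnL exceeds uncorrected on data with no all-zero column
  set.seed(33)
  m <- char_matrix(matrix(sample(0:1, 3 * 30, TRUE, prob = c(0.3, 0.7)),
                          nrow = 3, dimnames = list(tr$tip.label, NULL)))
  cfg_plain <- lik_config(make_model_spec("ER", 2), mu = 1.2)
  expect_gt(total_loglik(tr, m, cfg), total_loglik(tr, m, cfg_plain))
})

test_that("gamma mixture: K = 1 and alpha -> infinity recover the
          homogeneous likelihood", {
  tr <- random_tree(5, seed = 41)
  set.seed(42)
  m <- char_matrix(matrix(sample(0:1, 5 * 25, TRUE), nrow = 5,
                          dimnames = list(tr$tip.label, NULL)))
  spec <- make_model_spec("ER", 2)
  base <- total_loglik(tr, m, lik_config(spec, mu = 1.4))
  expect_equal(total_loglik(tr, m, lik_config(spec, mu = 1.4,
                                              gamma = discrete_gamma(0.7, 1))),
               base, tolerance = 1e-12)
  expect_equal(total_loglik(tr, m, lik_config(spec, mu = 1.4,
                                              gamma = discrete_gamma(1e5, 4))),
               base, tolerance = 1e-4)
  # and a genuine mixture changes the likelihood
  expect_false(isTRUE(all.equal(
    total_loglik(tr, m, lik_config(spec, mu = 1.4,
                                   gamma = discrete_gamma(0.3, 4))),
    base, tolerance = 1e-6)))
})

test_that("pulley principle: reversible likelihood is invariant to the
          root position, irreversible is not", {
  set.seed(51)
  phy <- ape::rtree(6, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  tr <- as_rate_tree(phy)
  set.seed(52)
  m <- char_matrix(matrix(sample(0:2, 6 * 30, TRUE), nrow = 6,
                          dimnames = list(tr$tip.label, NULL)))
  rootings <- lapply(c("t1", "t3", "t5"), function(og)
    as_rate_tree(ape::root(phy, outgroup = og, resolve.root = TRUE)))

  spec <- make_model_spec("SYM", 3)
  rel <- runif(spec$n_params, 0.4, 2)
  pi <- c(0.5, 0.3, 0.2)
  cfg_rev <- lik_config(spec, mu = 0.9, rel_rates = rel, pi = pi,
                        reversible = TRUE)
  cfg_unif <- lik_config(spec, mu = 0.9, rel_rates = rel)
  ll_rev <- vapply(rootings, total_loglik, numeric(1),
                   patterns = compress_patterns(m), config = cfg_rev)
  ll_unif <- vapply(rootings, total_loglik, numeric(1),
                    patterns = compress_patterns(m), config = cfg_unif)
  expect_lt(max(ll_rev) - min(ll_rev), 1e-8)
  expect_lt(max(ll_unif) - min(ll_unif), 1e-8)

  cfg_ard <- lik_config(make_model_spec("ARD", 3), mu = 0.9,
                        rel_rates = runif(6, 0.3, 2.5))
  ll_ard <- vapply(rootings, total_loglik, numeric(1),
                   patterns = compress_patterns(m), config = cfg_ard)
  expect_gt(max(ll_ard) - min(ll_ard), 1e-6)
})

test_that("branch categories sharing one mu equal the single-category
          computation", {
  tr <- parse_rate_newick("((A$1:0.3,B$2:0.7)$1:0.2,C$2:0.5);")
  tr1 <- parse_newick("((A:0.3,B:0.7):0.2,C:0.5);")
  set.seed(61)
  m <- char_matrix(matrix(sample(0:1, 3 * 20, TRUE), nrow = 3,
                          dimnames = list(c("A", "B", "C"), NULL)))
  spec <- make_model_spec("ER", 2)
  expect_equal(
    total_loglik(tr, m, lik_config(spec, mu = c(1.3, 1.3))),
    total_loglik(tr1, m, lik_config(spec, mu = 1.3)))
  # and distinct mus really differ
  expect_false(isTRUE(all.equal(
    total_loglik(tr, m, lik_config(spec, mu = c(1.3, 0.2))),
    total_loglik(tr1, m, lik_config(spec, mu = 1.3)))))
})

test_that("taxa mismatches and state overflow are caught", {
  tr <- parse_newick("((A:0.3,B:0.7):0.2,C:0.5);")
  m <- char_matrix(matrix(0:1, nrow = 2, ncol = 4,
                          dimnames = list(c("A", "X"), NULL)))
  cfg <- lik_config(make_model_spec("ER", 2))
  expect_error(total_loglik(tr, m, cfg), "taxa mismatch")

  m3 <- char_matrix(matrix(c(0L, 1L, 2L), 3, 2,
                           dimnames = list(c("A", "B", "C"), NULL)))
  expect_error(total_loglik(tr, m3, cfg), "states")
})
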