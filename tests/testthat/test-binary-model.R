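test_that("transition probabilities have the stated closed form and limits", {
  P0 <- transition_probabilities(0.4, 0)
  expect_equal(unname(P0), diag(2))

  Pinf <- transition_probabilities(0.3, 1e6)
  expect_equal(unname(Pinf), matrix(c(0.7, 0.7, 0.3, 0.3), 2, 2), tolerance = 1e-12)

  # generic matrix-exponential oracle
  skip_if_not_installed("Matrix")
  for (pi1 in c(0.2, 0.5, 0.8)) {
    mu <- 1 / (2 * pi1 * (1 - pi1))
    Q <- mu * matrix(c(-pi1, pi1, 1 - pi1, -(1 - pi1)), 2, 2, byrow = TRUE)
    for (t in c(0.05, 0.3, 2)) {
      expect_equal(unname(transition_probabilities(pi1, t)),
                   unname(as.matrix(Matrix::expm(Q * t))), tolerance = 1e-10)
    }
  }
  expect_error(transition_probabilities(1.2, 0.1), class = "gcphylo_error")
  expect_error(transition_probabilities(0.5, -0.1), class = "gcphylo_error")
})

test_that("rows of the transition matrix sum to one for random inputs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      P <- transition_probabilities(runif(1, 0.01, 0.99), rexp(1), rate = rexp(1))
      expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-14)
    }
  })
})

test_that("pattern likelihood handles degenerate zero-length trees", {
  tr <- sample_tree(4, 0.1, seed = 1)
  tr$edge.length[] <- 0
  m <- binary_model_spec(pi1 = 0.35)
  all1 <- stats::setNames(rep(1L, 4), tr$tip.label)
  expect_equal(pattern_loglik(tr, all1, m), log(0.35), tolerance = 1e-12)
  mixed <- stats::setNames(c(1L, 0L, 1L, 1L), tr$tip.label)
  expect_identical(pattern_loglik(tr, mixed, m), -Inf)
})

test_that("pruning likelihood matches the internal-state enumeration oracle", {
  withr::with_seed(42, {
    for (n in c(3, 5, 8)) {
      tr <- sample_tree(n, 0.25, seed = 1000 + n)
      m <- binary_model_spec(pi1 = 0.4)
      for (i in 1:4) {
        pat <- sample(0:1, n, replace = TRUE)
        names(pat) <- tr$tip.label
        expect_equal(pattern_loglik(tr, pat, m),
                     log(enum_binary_pattern_prob(tr, pat[tr$tip.label], 0.4)),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("likelihood is invariant to root placement and to state relabelling", {
  tr <- sample_tree(6, 0.3, seed = 9)
  pat <- stats::setNames(c(1L, 0L, 1L, 1L, 0L, 0L), tr$tip.label)
  m <- binary_model_spec(pi1 = 0.3)
  base <- pattern_loglik(tr, pat, m)
  for (og in tr$tip.label[1:3]) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(pattern_loglik(rerooted, pat, m), base, tolerance = 1e-12)
  }
  # pi1 <-> pi0 with all states flipped
  flipped <- stats::setNames(1L - pat, names(pat))
  m_flip <- binary_model_spec(pi1 = 0.7)
  expect_equal(pattern_loglik(tr, flipped, m_flip), base, tolerance = 1e-12)
})

test_that("count distribution matches enumeration, normalises, and hits its limits", {
  tr <- sample_tree(5, 0.35, seed = 5)
  m <- binary_model_spec(pi1 = 0.4)
  cd <- count_distribution(tr, m)
  expect_equal(sum(cd), 1, tolerance = 1e-12)
  enum <- numeric(6)
  for (code in 0:31) {
    pat <- as.integer(intToBits(code))[1:5]
    enum[sum(pat) + 1] <- enum[sum(pat) + 1] + enum_binary_pattern_prob(tr, pat, 0.4)
  }
  expect_equal(cd, enum, tolerance = 1e-10)

  # zero-length limit
  tr0 <- tr; tr0$edge.length[] <- 0
  cd0 <- count_distribution(tr0, m)
  expect_equal(cd0, c(0.6, 0, 0, 0, 0, 0.4), tolerance = 1e-12)

  # independence limit: star tree, huge branches -> Binomial(N, pi1)
  star <- ape::read.tree(text = "(a:1e6,b:1e6,c:1e6,d:1e6,e:1e6);")
  cds <- count_distribution(star, m)
  expect_equal(cds, dbinom(0:5, 5, 0.4), tolerance = 1e-9)
})

test_that("corrected likelihood conditions exactly on the window", {
  tr <- sample_tree(4, 0.2, seed = 3)
  # single balanced character, window [2,2]: equals pattern prob over the
  # sum of all balanced-pattern probabilities, by enumeration
  pat <- c(1L, 1L, 0L, 0L)
  names(pat) <- tr$tip.label
  mat <- pa_matrix(matrix(pat, ncol = 1, dimnames = list(names(pat), "c1")),
                   window = c(2L, 2L))
  m <- binary_model_spec(pi1 = 0.45, window = c(2L, 2L))
  num <- enum_binary_pattern_prob(tr, pat[tr$tip.label], 0.45)
  den <- 0
  for (code in 0:15) {
    p <- as.integer(intToBits(code))[1:4]
    if (sum(p) == 2) den <- den + enum_binary_pattern_prob(tr, p, 0.45)
  }
  expect_equal(corrected_loglik(mat, tr, m), log(num / den), tolerance = 1e-10)

  # full window reduces to the unconditioned likelihood exactly
  m_full <- binary_model_spec(pi1 = 0.45, window = c(0L, 4L))
  mat2 <- mat; mat2$window <- NULL
  m_none <- binary_model_spec(pi1 = 0.45)
  expect_identical(corrected_loglik(mat2, tr, m_full),
                   corrected_loglik(mat2, tr, m_none))

  # window mismatch is an error
  m_bad <- binary_model_spec(pi1 = 0.45, window = c(1L, 3L))
  expect_error(corrected_loglik(mat, tr, m_bad), class = "gcphylo_error")
})

test_that("gamma category rates match quadrature and their limits", {
  expect_identical(gamma_category_rates(1.7, 1), 1)
  expect_equal(gamma_category_rates(1e6, 4), rep(1, 4), tolerance = 1e-3)
  r <- gamma_category_rates(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  oracle <- vapply(1:4, function(i) {
    lo <- qgamma((i - 1) / 4, 0.5, 0.5); hi <- qgamma(i / 4, 0.5, 0.5)
    stats::integrate(function(x) x * dgamma(x, 0.5, 0.5), lo, hi)$value * 4
  }, 1)
  expect_equal(r, oracle, tolerance = 1e-6)
  expect_error(gamma_category_rates(-1, 4), class = "gcphylo_error")
})

test_that("the C++ kernel agrees with the reference R implementation", {
  withr::with_seed(8, {
    for (i in 1:3) {
      tr <- sample_tree(7, 0.2, seed = 600 + i)
      mod_sim <- binary_model_spec(pi1 = 0.35)
      mat <- simulate_binary_matrix(tr, 400, mod_sim, seed = 700 + i)
      fm <- apply_observability_filter(mat)
      for (mod in list(binary_model_spec(0.35, window = c(2L, 5L)),
                       binary_model_spec(0.35, gamma_shape = 0.8, window = c(2L, 5L)))) {
        ut <- gcphylo:::as_utree(tr)
        trav <- gcphylo:::utree_traversal(ut)
        cmp <- gcphylo:::compress_patterns(fm$data[ut$tip_label, ])
        cpp <- gcphylo:::bin_corrected_loglik_cpp(cmp$patterns, cmp$weights, ncol(fm$data),
                                        trav$order, trav$parent, trav$pedge,
                                        trav$root, ut$length, 0.35, mod$rates,
                                        2L, 5L, TRUE)
        expect_equal(cpp, corrected_loglik(fm, tr, mod), tolerance = 1e-10)
      }
    }
  })
})

test_that("ML branch lengths are recovered under the corrected likelihood", {
  # conditioning on a narrow window leaves limited information per
  # character, so recovery is checked on the ratio averaged over replicates
  ratios <- vapply(1:3, function(i) {
    tr <- sample_tree(6, 0.15, seed = 20 + i)
    mod <- binary_model_spec(pi1 = 0.5, window = c(2L, 4L))
    mat <- simulate_binary_matrix(tr, 4000, binary_model_spec(0.5), seed = 50 + i)
    fm <- apply_observability_filter(mat)
    fit <- fit_branch_lengths(fm, tr, mod, corrected = TRUE)
    expect_equal(fit$convergence, 0)
    fit$tree_length / sum(tr$edge.length)
  }, 1)
  expect_equal(mean(ratios), 1, tolerance = 0.12)
})
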