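test_that("the model grid has exactly 24 distinct members", {
  grid <- morph_model_grid()
  expect_equal(nrow(grid), 24L)
  expect_equal(anyDuplicated(grid$model_id), 0L)
  expect_equal(length(unique(grid$ascertainment)), 2L)
  expect_equal(length(unique(grid$bl_prior)), 2L)
  expect_equal(length(unique(grid$rates)), 2L)
  expect_equal(length(unique(grid$freq_model)), 3L)
})

test_that("binary Mk reduces to the binary substitution model", {
  tr <- sample_tree(6, 0.3, seed = 4)
  pat <- stats::setNames(c(1L, 0L, 0L, 1L, 1L, 0L), tr$tip.label)
  expect_equal(mk_pattern_loglik(tr, pat, 2, c(0.5, 0.5)),
               pattern_loglik(tr, pat, binary_model_spec(0.5)), tolerance = 1e-12)
  expect_equal(mk_pattern_loglik(tr, pat, 2, c(0.65, 0.35)),
               pattern_loglik(tr, pat, binary_model_spec(0.35)), tolerance = 1e-12)
})

test_that("constant patterns on a zero-length tree have probability freqs[s]", {
  tr <- sample_tree(5, 0.1, seed = 2)
  tr$edge.length[] <- 0
  fr <- c(0.2, 0.3, 0.5)
  for (s in 0:2) {
    pat <- stats::setNames(rep(s, 5), tr$tip.label)
    expect_equal(mk_pattern_loglik(tr, pat, 3, fr), log(fr[s + 1]), tolerance = 1e-12)
  }
  expect_error(mk_pattern_loglik(tr, stats::setNames(c(3, 0, 0, 0, 0), tr$tip.label), 3, fr),
               class = "gcphylo_error")
})

test_that("Mk pruning matches the enumeration oracle for k = 3", {
  withr::with_seed(7, {
    for (i in 1:2) {
      tr <- sample_tree(4, 0.4, seed = 80 + i)
      fr <- c(0.25, 0.35, 0.4)
      for (j in 1:3) {
        pat <- sample(0:2, 4, replace = TRUE)
        names(pat) <- tr$tip.label
        expect_equal(mk_pattern_loglik(tr, pat, 3, fr),
                     log(enum_mk_pattern_prob(tr, pat[tr$tip.label], 3, fr)),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("Mk likelihood is invariant to state relabelling", {
  tr <- sample_tree(5, 0.3, seed = 13)
  pat <- stats::setNames(c(0L, 2L, 1L, 2L, 0L), tr$tip.label)
  base <- mk_pattern_loglik(tr, pat, 3)
  perm <- c(2L, 0L, 1L)  # relabel states under equal frequencies
  expect_equal(mk_pattern_loglik(tr, stats::setNames(perm[pat + 1L], names(pat)), 3),
               base, tolerance = 1e-12)
})

test_that("ascertainment probabilities match exhaustive enumeration", {
  tr <- sample_tree(5, 0.4, seed = 11)
  fr <- c(0.2, 0.3, 0.5)
  pats <- as.matrix(expand.grid(rep(list(0:2), 5)))
  pr <- apply(pats, 1, function(p) enum_mk_pattern_prob(tr, p, 3, fr))
  const <- apply(pats, 1, function(p) length(unique(p)) == 1)
  noninf <- apply(pats, 1, function(p) max(table(p)) >= 4)  # >= N-1 in one state
  expect_equal(ascertainment_probability(tr, 3, fr, 1, "variable_only"),
               1 - sum(pr[const]), tolerance = 1e-10)
  expect_equal(ascertainment_probability(tr, 3, fr, 1, "parsimony_informative_only"),
               1 - sum(pr[noninf]), tolerance = 1e-10)

  # binary variable-only reduces to the count distribution tails
  cd <- count_distribution(tr, binary_model_spec(0.35))
  expect_equal(ascertainment_probability(tr, 2, c(0.65, 0.35), 1, "variable_only"),
               1 - cd[1] - cd[6], tolerance = 1e-12)
})

test_that("parsimony-informative probability never exceeds variable-only", {
  withr::with_seed(3, {
    for (i in 1:5) {
      tr <- sample_tree(sample(4:8, 1), runif(1, 0.05, 0.5), seed = 400 + i)
      k <- sample(2:3, 1)
      fr <- if (k == 2) { p <- runif(1, 0.2, 0.8); c(1 - p, p) } else rep(1 / 3, 3)
      pv <- ascertainment_probability(tr, k, fr, 1, "variable_only")
      ppi <- ascertainment_probability(tr, k, fr, 1, "parsimony_informative_only")
      expect_lte(ppi, pv + 1e-12)
    }
  })
})

test_that("degenerate trees and taxon counts are rejected or surface errors", {
  tr <- sample_tree(5, 0.1, seed = 2)
  tr0 <- tr; tr0$edge.length[] <- 0
  expect_equal(ascertainment_probability(tr0, 2, c(0.5, 0.5), 1, "variable_only"), 0)
  tri <- sample_tree(3, 0.1, seed = 2)
  expect_error(ascertainment_probability(tri, 2, mode = "parsimony_informative_only"),
               class = "gcphylo_error")
})

test_that("symmetric mixture categories follow the beta quantile medians", {
  cats <- sym_mixture_categories(5, 1)
  expect_equal(cats$pi1, c(0.1, 0.3, 0.5, 0.7, 0.9), tolerance = 1e-12)
  expect_equal(cats$weight, rep(0.2, 5))
  c4 <- sym_mixture_categories(4, 0.5)
  expect_equal(c4$pi1, qbeta(c(0.125, 0.375, 0.625, 0.875), 0.5, 0.5), tolerance = 1e-9)
  expect_equal(c4$pi1, rev(1 - c4$pi1), tolerance = 1e-12)   # symmetry
  cbig <- sym_mixture_categories(4, 1e8)
  expect_equal(cbig$pi1, rep(0.5, 4), tolerance = 1e-3)
  expect_error(sym_mixture_categories(4, -2), class = "gcphylo_error")
  expect_error(sym_mixture_categories(3, 1), class = "gcphylo_error")
})

test_that("the morphology likelihood equals the binary corrected likelihood for k=2", {
  tr <- sample_tree(6, 0.25, seed = 17)
  sim <- simulate_binary_matrix(tr, 300, binary_model_spec(0.5), seed = 18)
  keep <- apply_observability_filter(sim, 1L, 5L)  # variable characters
  mm <- morph_matrix(matrix(as.character(keep$data), nrow(keep$data),
                            dimnames = dimnames(keep$data)))
  spec <- morph_model_spec("variable_only", "fixed_exponential", "equal", "homogeneous")
  bin_model <- binary_model_spec(0.5, window = c(1L, 5L))
  expect_equal(morph_loglik(mm, tr, spec),
               corrected_loglik(keep, tr, bin_model), tolerance = 1e-10)
})

test_that("the morphology likelihood matches per-character enumeration", {
  tr <- sample_tree(4, 0.3, seed = 23)
  spec3 <- morph_sim_spec(30, state_counts = c("2" = 0.5, "3" = 0.5),
                          mixture_beta = NULL, seed = 24)
  mm <- simulate_morphology(tr, spec3)
  mm <- filter_morph_characters(mm, "variable_only")
  spec <- morph_model_spec("variable_only", "fixed_exponential", "equal", "homogeneous")
  got <- morph_loglik(mm, tr, spec)
  # oracle: per character, enumeration likelihood / enumeration observability
  kvec <- morph_state_counts(mm)
  pats3 <- as.matrix(expand.grid(rep(list(0:2), 4)))
  pats2 <- as.matrix(expand.grid(rep(list(0:1), 4)))
  expected <- 0
  for (j in seq_len(ncol(mm$data))) {
    k <- kvec[j]
    fr <- rep(1 / k, k)
    pat <- as.integer(mm$data[gcphylo:::as_utree(tr)$tip_label, j])
    num <- enum_mk_pattern_prob(tr, pat, k, fr)
    pats <- if (k == 3) pats3 else pats2
    allp <- apply(pats, 1, function(p) enum_mk_pattern_prob(tr, p, k, fr))
    const <- apply(pats, 1, function(p) length(unique(p)) == 1)
    expected <- expected + log(num / (1 - sum(allp[const])))
  }
  expect_equal(got, unname(expected), tolerance = 1e-10)
})

test_that("characters violating the ascertainment assumption are rejected", {
  tr <- sample_tree(5, 0.2, seed = 31)
  m <- matrix("0", 5, 3, dimnames = list(tr$tip.label, NULL))
  m[1, 2] <- "1"; m[1:2, 3] <- "1"   # col1 constant, col2 autapomorphy, col3 informative
  mm <- morph_matrix(m)
  spec <- morph_model_spec("variable_only")
  expect_error(morph_loglik(mm, tr, spec), class = "gcphylo_error")
  kept_v <- filter_morph_characters(mm, "variable_only")
  expect_equal(ncol(kept_v$data), 2L)
  kept_pi <- filter_morph_characters(mm, "parsimony_informative_only")
  expect_equal(ncol(kept_pi$data), 1L)
  expect_silent(morph_loglik(kept_v, tr, spec))

  # an all-missing character is excluded with a warning
  m2 <- m[, 3, drop = FALSE]
  m2 <- cbind(m2, "?")
  mm2 <- morph_matrix(m2)
  expect_warning(ll <- morph_loglik(mm2, tr, spec), "all-missing")
  expect_equal(ll, morph_loglik(morph_matrix(m[, 3, drop = FALSE]), tr, spec))
})

test_that("gamma rates and mixtures enter the likelihood as averages", {
  tr <- sample_tree(5, 0.3, seed = 41)
  m <- matrix(c("0", "1", "1", "0", "1"), 5, 1, dimnames = list(tr$tip.label, "c1"))
  mm <- morph_matrix(m)
  spec <- morph_model_spec("variable_only", rates = "gamma", freq_model = "sym_mixture4")
  got <- morph_loglik(mm, tr, spec, alpha = 0.7, beta = 0.9)
  rates <- gamma_category_rates(0.7, 4)
  cats <- sym_mixture_categories(4, 0.9)
  ut <- gcphylo:::as_utree(tr)
  pat <- as.integer(m[ut$tip_label, 1])
  cond <- 0
  for (ci in 1:4) {
    fr <- c(cats$pi0[ci], cats$pi1[ci])
    num <- mean(vapply(rates, function(r) enum_mk_pattern_prob(tr, pat, 2, fr, r), 1))
    den <- ascertainment_probability(tr, 2, fr, rates, "variable_only")
    cond <- cond + cats$weight[ci] * num / den
  }
  expect_equal(got, log(cond), tolerance = 1e-10)
})
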