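test_that("chains are bit-reproducible under the same seed and config", {
  tr <- sample_tree(5, 0.2, seed = 1)
  mat <- apply_observability_filter(
    simulate_binary_matrix(tr, 300, binary_model_spec(0.5), seed = 2))
  cfg <- mcmc_config(generations = 100, sample_every = 10, replicates = 2, seed = 5)
  a <- run_mcmc(combined_model(binary_partition(mat)), cfg)
  b <- run_mcmc(combined_model(binary_partition(mat)), cfg)
  expect_identical(a[[1]]$trees, b[[1]]$trees)
  expect_identical(a[[2]]$stats, b[[2]]$stats)
  expect_false(identical(a[[1]]$trees, a[[2]]$trees))  # replicates differ
})

test_that("prior-only sampling reproduces the branch-length prior mean", {
  tr <- sample_tree(6, 0.2, seed = 3)
  mat <- apply_observability_filter(
    simulate_binary_matrix(tr, 100, binary_model_spec(0.5), seed = 4))
  cfg <- mcmc_config(generations = 8000, sample_every = 5, replicates = 2,
                     seed = 11, likelihood = FALSE)
  trcs <- run_mcmc(combined_model(binary_partition(mat), bl_prior_mean = 0.1), cfg)
  post <- dplyr::bind_rows(lapply(trcs, function(tr) {
    gcphylo:::post_burn_in(tr$stats, 0.25)
  }))
  # mean tree length = n_edges * prior mean
  expect_equal(mean(post$tree_length) / nrow(gcphylo:::as_utree(tr)$edge),
               0.1, tolerance = 0.02)
  # pi1 prior is uniform
  expect_equal(mean(post$pi1.1), 0.5, tolerance = 0.06)
})

test_that("a four-taxon posterior matches exhaustive quadrature", {
  # small-instance oracle: integrate the likelihood x prior over a coarse
  # branch-length grid for each of the three topologies
  tr <- sample_tree(4, 0.15, seed = 21)
  mod <- binary_model_spec(0.5)
  mat <- simulate_binary_matrix(tr, 150, mod, seed = 22)
  taxa <- sort(rownames(mat$data))
  topos <- c(
    sprintf("((%s,%s),%s,%s);", taxa[1], taxa[2], taxa[3], taxa[4]),
    sprintf("((%s,%s),%s,%s);", taxa[1], taxa[3], taxa[2], taxa[4]),
    sprintf("((%s,%s),%s,%s);", taxa[1], taxa[4], taxa[2], taxa[3]))
  # midpoint grid on each of the 5 branch lengths under Exp(0.1)
  qs <- stats::qexp((1:5 - 0.5) / 5, rate = 10)
  grid <- as.matrix(expand.grid(rep(list(qs), 5)))
  marg <- vapply(topos, function(nw) {
    phy0 <- ape::read.tree(text = nw)
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      phy0$edge.length <- grid[g, ]
      ut <- gcphylo:::as_utree(phy0)
      phy <- gcphylo:::utree_to_phylo(ut)
      ll <- corrected_loglik(mat, phy, mod)
      tot <- tot + exp(ll)   # equal prior mass per midpoint cell
    }
    tot
  }, 1)
  post_oracle <- marg / sum(marg)

  cfg <- mcmc_config(generations = 3000, sample_every = 5, replicates = 2, seed = 23)
  traces <- run_mcmc(combined_model(binary_partition(mat, sample_pi1 = FALSE),
                                    bl_prior_mean = 0.1), cfg)
  freqs <- bipartition_frequencies(traces, 0.25)
  topo_of <- function(nw) splits_of(ape::read.tree(text = nw))
  mcmc_post <- vapply(topos, function(nw) {
    key <- topo_of(nw)
    i <- match(key, freqs$split)
    if (is.na(i)) 0 else freqs$frequency[i]
  }, 1)
  expect_equal(unname(mcmc_post), unname(post_oracle), tolerance = 0.05)
})

test_that("four-taxon simulated data recover the generating topology", {
  tr <- sample_tree(4, 0.2, seed = 31)
  mat <- apply_observability_filter(
    simulate_binary_matrix(tr, 2000, binary_model_spec(0.5), seed = 32))
  cfg <- mcmc_config(generations = 1500, sample_every = 10, replicates = 2, seed = 33)
  traces <- run_mcmc(combined_model(binary_partition(mat)), cfg)
  cons <- majority_consensus(traces)
  expect_true(all(splits_of(tr) %in%
                  cons$splits$split[cons$splits$frequency > 0.5]))
})

test_that("a combined model with identical partitions equals the concatenation", {
  tr <- sample_tree(5, 0.2, seed = 41)
  half <- apply_observability_filter(
    simulate_binary_matrix(tr, 400, binary_model_spec(0.5), seed = 42))
  both <- half
  both$data <- cbind(half$data, half$data)
  colnames(both$data) <- make.unique(colnames(both$data))
  cfg <- mcmc_config(generations = 400, sample_every = 10, replicates = 1, seed = 43)
  # pi1 fixed so both models register the identical move list (and hence
  # consume the same random number stream)
  two_part <- run_mcmc(combined_model(binary_partition(half, sample_pi1 = FALSE),
                                      binary_partition(half, sample_pi1 = FALSE),
                                      sample_scalers = FALSE), cfg)[[1]]
  one_part <- run_mcmc(combined_model(binary_partition(both, sample_pi1 = FALSE)), cfg)[[1]]
  expect_equal(two_part$stats$log_likelihood, one_part$stats$log_likelihood,
               tolerance = 1e-8)
  expect_identical(two_part$trees, one_part$trees)
})

test_that("ESS matches its closed-form and errors on degenerate traces", {
  withr::with_seed(51, {
    x <- rnorm(1000)
    expect_equal(ess(x), 1000, tolerance = 0.25)
    # AR(1) with coefficient 0.9: ESS ~ n (1-phi)/(1+phi)
    n <- 20000
    ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
    expect_equal(ess(ar), n * 0.1 / 1.9, tolerance = 0.25)
  })
  expect_error(ess(1:5), class = "gcphylo_error")
  expect_error(ess(rep(1, 100)), class = "gcphylo_error")
})

test_that("maxdiff is zero for identical runs and one for disjoint runs", {
  t1 <- "((a:1,b:1):1,(c:1,d:1):1);"
  t2 <- "((a:1,c:1):1,(b:1,d:1):1);"
  trA <- make_trace(rep(t1, 10))
  expect_equal(compare_runs(list(trA, trA))$maxdiff, 0)
  trB <- make_trace(rep(t2, 10))
  expect_equal(compare_runs(list(trA, trB))$maxdiff, 1)
  mixed <- make_trace(c(rep(t1, 6), rep(t2, 4)))
  cr <- compare_runs(list(trA, mixed))
  expect_equal(cr$maxdiff, 0.4)
  trE <- make_trace(rep("((a:1,b:1):1,(c:1,e:1):1);", 5))
  expect_error(compare_runs(list(trA, trE)), class = "gcphylo_error")
})

test_that("acceptance statistics are recorded per move", {
  tr <- sample_tree(5, 0.2, seed = 61)
  mat <- apply_observability_filter(
    simulate_binary_matrix(tr, 200, binary_model_spec(0.5), seed = 62))
  cfg <- mcmc_config(generations = 200, sample_every = 20, replicates = 1, seed = 63)
  trc <- run_mcmc(combined_model(binary_partition(mat)), cfg)[[1]]
  expect_setequal(trc$acceptance$move, c("nni", "spr", "brlen", "pi1.1"))
  expect_true(all(trc$acceptance$attempts > 0))
  expect_true(all(trc$acceptance$accepts <= trc$acceptance$attempts))
})

test_that("tree samples round-trip through newick list files", {
  tr <- sample_tree(5, 0.2, seed = 71)
  mat <- apply_observability_filter(
    simulate_binary_matrix(tr, 100, binary_model_spec(0.5), seed = 72))
  cfg <- mcmc_config(generations = 100, sample_every = 10, replicates = 1, seed = 73)
  trc <- run_mcmc(combined_model(binary_partition(mat)), cfg)[[1]]
  path <- withr::local_tempfile(fileext = ".trees")
  write_tree_samples(trc, path)
  back <- read_tree_samples(path)
  expect_identical(back, trc$trees)
})
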