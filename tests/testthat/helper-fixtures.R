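# Shared fixture builders; everything is generated in code under fixed
# seeds.

# A minimal trace object around explicit newick samples (no MCMC needed).
make_trace <- function(newicks, burn_in_fraction = 0) {
  phys <- ape::read.tree(text = paste(newicks, collapse = "\n"))
  if (inherits(phys, "phylo")) phys <- list(phys)
  taxa <- sort(phys[[1L]]$tip.label)
  structure(list(
    trees = newicks,
    splits = lapply(phys, function(p) gcphylo:::utree_splits(gcphylo:::as_utree(p))),
    stats = tibble::tibble(iteration = seq_along(newicks),
                           log_likelihood = NA_real_),
    taxa = taxa, seed = 0L, replicate = 1L,
    config = list(burn_in_fraction = burn_in_fraction),
    acceptance = tibble::tibble(move = character(), attempts = numeric(),
                                accepts = numeric(), rate = numeric())
  ), class = "gc_trace")
}

# Brute-force pattern probability by summing over all internal-node state
# assignments (the enumeration oracle; independent of the pruning code).
enum_binary_pattern_prob <- function(tree, pattern, pi1, rate = 1) {
  ut <- gcphylo:::as_utree(tree)
  trav <- gcphylo:::utree_traversal(ut)
  n <- 2L * ut$n_tip - 2L
  nint <- n - ut$n_tip
  total <- 0
  for (code in 0:(2^nint - 1L)) {
    states <- integer(n)
    states[seq_len(ut$n_tip)] <- pattern
    states[(ut$n_tip + 1L):n] <- as.integer(intToBits(code))[seq_len(nint)]
    p <- if (states[trav$root] == 1L) pi1 else 1 - pi1
    for (v in trav$order) {
      if (v == trav$root) next
      P <- transition_probabilities(pi1, ut$length[trav$pedge[v]], rate)
      p <- p * P[states[trav$parent[v]] + 1L, states[v] + 1L]
    }
    total <- total + p
  }
  total
}

# k-state analogue over a supplied transition-matrix function.
enum_mk_pattern_prob <- function(tree, pattern, k, freqs, rate = 1) {
  ut <- gcphylo:::as_utree(tree)
  trav <- gcphylo:::utree_traversal(ut)
  beta <- 1 / (1 - sum(freqs^2))
  Pmat <- function(t) {
    ef <- exp(-beta * t * rate)
    ef * diag(k) + (1 - ef) * matrix(freqs, k, k, byrow = TRUE)
  }
  n <- 2L * ut$n_tip - 2L
  nint <- n - ut$n_tip
  grid <- expand.grid(rep(list(0:(k - 1L)), nint))
  total <- 0
  for (gi in seq_len(nrow(grid))) {
    states <- integer(n)
    states[seq_len(ut$n_tip)] <- pattern
    states[(ut$n_tip + 1L):n] <- as.integer(grid[gi, ])
    p <- freqs[states[trav$root] + 1L]
    for (v in trav$order) {
      if (v == trav$root) next
      p <- p * Pmat(ut$length[trav$pedge[v]])[states[trav$parent[v]] + 1L,
                                              states[v] + 1L]
    }
    total <- total + p
  }
  total
}

splits_of <- function(tree) {
  gcphylo:::utree_splits(gcphylo:::as_utree(tree))
}
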