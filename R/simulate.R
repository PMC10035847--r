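# Synthetic data generators: trees, binary characters, gene-family
# clusterings with orthogroup substructure, and multistate morphology.
# These define the study conditions the inference machinery is validated
# against; every generator is deterministic under its seed.

#' Simulate a random unrooted tree
#'
#' Uniformly distributed unrooted binary topology over `n_taxa` labelled
#' leaves, with branch lengths drawn i.i.d. from an exponential distribution
#' with the given mean (the same scale as the branch-length prior used in
#' inference: 0.1 expected changes per character per branch).
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param branch_length_mean Mean branch length in expected changes per
#'   character (default 0.1).
#' @param seed Integer seed.
#' @param tip_labels Optional explicit labels (default `t01, t02, ...`).
#' @return A `phylo` tree.
#' @export
sample_tree <- function(n_taxa, branch_length_mean = 0.1, seed,
                        tip_labels = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 3L) abort_gc("n_taxa must be >= 3", "invalid_spec")
  if (!is.numeric(branch_length_mean) || branch_length_mean <= 0) {
    abort_gc("branch_length_mean must be > 0", "invalid_spec")
  }
  labels <- tip_labels %||% sprintf("t%02d", seq_len(n_taxa))
  if (length(labels) != n_taxa) abort_gc("wrong number of tip labels", "invalid_spec")
  with_seed(seed, function() {
    phy <- ape::rtopology(n_taxa, rooted = FALSE, tip.label = labels)
    phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / branch_length_mean)
    phy
  })
}

# simulate one edge of binary evolution for a vector of characters
.bin_evolve_edge <- function(parent_state, pi1, len, rates) {
  ef <- exp(-(len * rates) / (2 * pi1 * (1 - pi1)))
  p1 <- ifelse(parent_state == 1L, pi1 + (1 - pi1) * ef, pi1 * (1 - ef))
  stats::rbinom(length(parent_state), 1L, p1)
}

# Simulate leaf states for n_chars binary characters down a utree, given
# root states (vector) and per-character rate multipliers.
.bin_simulate_down <- function(ut, root_states, pi1, rates, trav = utree_traversal(ut)) {
  n <- utree_n_nodes(ut)
  states <- matrix(NA_integer_, n, length(root_states))
  states[trav$root, ] <- root_states
  for (v in rev(trav$order)) {         # preorder
    if (v == trav$root) next
    p <- trav$parent[v]
    states[v, ] <- .bin_evolve_edge(states[p, ], pi1, ut$length[trav$pedge[v]], rates)
  }
  states[seq_len(ut$n_tip), , drop = FALSE]
}

#' Simulate a binary presence/absence matrix
#'
#' Evolves `n_chars` independent binary characters along the tree under the
#' reversible binary substitution model of [binary_model_spec()] (root state
#' drawn from the stationary distribution; per-character gamma rate category
#' drawn uniformly if the model has rate variation). The result is
#' unfiltered; apply [apply_observability_filter()] to emulate the
#' singleton/near-constant filter.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param n_chars Number of characters.
#' @param model A [binary_model_spec()].
#' @param seed Integer seed.
#' @return A [pa_matrix()] (level `"simulated"`).
#' @export
simulate_binary_matrix <- function(tree, n_chars, model, seed) {
  ut <- as_utree(tree)
  n_chars <- as.integer(n_chars)
  stopifnot(n_chars >= 1L)
  with_seed(seed, function() {
    rates <- model$rates[sample.int(length(model$rates), n_chars, replace = TRUE)]
    roots <- stats::rbinom(n_chars, 1L, model$pi1)
    tips <- .bin_simulate_down(ut, roots, model$pi1, rates)
    rownames(tips) <- ut$tip_label
    pa_matrix(tips, level = "simulated",
              provenance = list(n_chars = n_chars, pi1 = model$pi1, seed = seed))
  })
}

#' Gene-family simulation specification
#'
#' Parameters of the two-level gene-content generator: families originate
#' either at the root (presence evolving under the reversible binary model
#' from stationarity) or once on a uniformly chosen branch with reversible
#' loss/regain below it (a Dollo-like origination). Each family is split
#' into `1 + Poisson(g - 1)` orthogroups — `g` is the expected number of
#' orthogroups per family and emulates MCL inflation granularity — and each
#' orthogroup inherits the family's presence pattern thinned by independent
#' per-species losses.
#'
#' @param n_families Number of gene families to simulate.
#' @param origination_mode `"root_only"` or `"along_branches"`.
#' @param pi1 Stationary presence frequency in (0, 1).
#' @param g Expected orthogroups per family (>= 1); `g = 1` gives exactly
#'   one orthogroup per family.
#' @param per_orthogroup_loss Probability in `[0, 1)` that a species present
#'   in the family is absent from a given orthogroup.
#' @param seed Integer seed.
#' @return An object of class `gc_genefam_spec`.
#' @export
gene_family_sim_spec <- function(n_families, origination_mode = c("root_only", "along_branches"),
                                 pi1 = 0.5, g = 1, per_orthogroup_loss = 0, seed = 1L) {
  origination_mode <- match.arg(origination_mode)
  n_families <- as.integer(n_families)
  if (is.na(n_families) || n_families < 1L) abort_gc("n_families must be >= 1", "invalid_spec")
  check_prob(pi1, "pi1", open_left = TRUE, open_right = TRUE)
  if (!is.numeric(g) || g < 1) abort_gc("g must be >= 1", "invalid_spec")
  check_prob(per_orthogroup_loss, "per_orthogroup_loss", open_right = TRUE)
  structure(list(n_families = n_families, origination_mode = origination_mode,
                 pi1 = pi1, g = g, per_orthogroup_loss = per_orthogroup_loss,
                 seed = as.integer(seed)),
            class = "gc_genefam_spec")
}

# Family-level presence patterns (n_families x n_species logical matrix).
.sim_family_patterns <- function(ut, spec) {
  with_seed(derive_seed(spec$seed, "families"), function() {
    n <- spec$n_families
    if (spec$origination_mode == "root_only") {
      roots <- stats::rbinom(n, 1L, spec$pi1)
      tips <- .bin_simulate_down(ut, roots, spec$pi1, rep(1, n))
    } else {
      trav <- utree_traversal(ut)
      tips <- matrix(0L, ut$n_tip, n)
      origin <- sample.int(nrow(ut$edge), n, replace = TRUE)
      for (e in unique(origin)) {
        idx <- which(origin == e)
        # gain at the head (child end) of edge e; reversible evolution below
        head_node <- if (trav$parent[ut$edge[e, 1L]] == ut$edge[e, 2L]) {
          ut$edge[e, 1L]
        } else ut$edge[e, 2L]
        sub <- .subtree_tips_states(ut, trav, head_node, rep(1L, length(idx)), spec$pi1)
        tips[sub$tips, idx] <- sub$states
      }
    }
    m <- t(tips) == 1L
    colnames(m) <- ut$tip_label
    m
  })
}

# Evolve states from `node` downwards (away from the root) only; returns
# the tip indices below `node` (inclusive) and their states.
.subtree_tips_states <- function(ut, trav, node, start_states, pi1) {
  n <- utree_n_nodes(ut)
  below <- logical(n); below[node] <- TRUE
  states <- matrix(NA_integer_, n, length(start_states))
  states[node, ] <- start_states
  for (v in rev(trav$order)) {
    if (v == trav$root || v == node) next
    p <- trav$parent[v]
    if (!below[p]) next
    below[v] <- TRUE
    states[v, ] <- .bin_evolve_edge(states[p, ], pi1,
                                    ut$length[trav$pedge[v]], 1)
  }
  tips <- which(below[seq_len(ut$n_tip)])
  list(tips = tips, states = states[tips, , drop = FALSE])
}

# Split family patterns into orthogroups and emit gene identifiers; the
# seed is derived from the retained species set so ab-initio regeneration
# on a reduced taxon set is reproducible.
.emit_clusters <- function(patterns, species_keep, spec, provenance) {
  key <- paste(sort(species_keep), collapse = ",")
  with_seed(derive_seed(spec$seed, paste0("clusters:", key)), function() {
    families <- list()
    for (f in seq_len(nrow(patterns))) {
      present <- colnames(patterns)[patterns[f, ]]
      present <- intersect(present, species_keep)
      if (length(present) == 0L) next
      n_og <- 1L + stats::rpois(1L, spec$g - 1)
      fid <- sprintf("F%05d", f)
      fam <- list()
      for (o in seq_len(n_og)) {
        kept <- present[stats::runif(length(present)) >= spec$per_orthogroup_loss]
        if (length(kept) == 0L) next
        og <- stats::setNames(lapply(kept, function(sp) {
          paste0(sp, "|", fid, ".", o)
        }), kept)
        fam[[paste0(fid, ".", o)]] <- og
      }
      if (length(fam)) families[[fid]] <- fam
    }
    if (length(families) == 0L) abort_gc("no observable families simulated", "degenerate_simulation")
    cluster_set(families, sort(species_keep), provenance)
  })
}

#' Simulate a two-level gene-family clustering
#'
#' Generates gene families along the tree per the origination mode of the
#' spec, splits each family into orthogroups, applies per-orthogroup
#' species losses, and emits per-species gene identifiers
#' (`species|family.orthogroup`). Families left with no genes are
#' unobservable and omitted, as in real clusterings.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param spec A [gene_family_sim_spec()].
#' @return A [cluster_set()] whose `provenance$sim` records the generating
#'   tree and family-level truth (for ab-initio regeneration and recovery
#'   checks).
#' @export
simulate_gene_families <- function(tree, spec) {
  stopifnot(inherits(spec, "gc_genefam_spec"))
  ut <- as_utree(tree)
  patterns <- .sim_family_patterns(ut, spec)
  prov <- list(strategy = "full",
               sim = list(tree = utree_to_newick(ut), spec = spec,
                          patterns = patterns))
  .emit_clusters(patterns, ut$tip_label, spec, prov)
}

#' Regenerate a clustering ab initio on a reduced taxon set
#'
#' Emulates re-running the clustering pipeline de novo on a reduced taxon
#' sampling: the underlying family-level truth is kept, restricted to
#' `keep_species`, but orthogroup splitting and per-orthogroup losses are
#' re-drawn under a seed derived from the spec seed and the retained
#' species. Contrast with [prune_taxa()], which deletes rows from the full
#' matrix and re-filters.
#'
#' @param clusters A [simulate_gene_families()] result (carries the truth).
#' @param keep_species Non-empty subset of the simulated species.
#' @return A [cluster_set()] over `keep_species`.
#' @export
regenerate_clusters <- function(clusters, keep_species) {
  sim <- clusters$provenance$sim
  if (is.null(sim)) abort_gc("cluster set lacks simulation provenance", "invalid_clusters")
  keep_species <- as.character(keep_species)
  if (length(keep_species) == 0L) abort_gc("keep_species is empty", "invalid_spec")
  unknown <- setdiff(keep_species, clusters$species)
  if (length(unknown)) {
    abort_gc(paste0("unknown species: ", paste(unknown, collapse = ", ")),
             "invalid_spec")
  }
  prov <- clusters$provenance
  prov$strategy <- "ab_initio"
  .emit_clusters(sim$patterns, keep_species, sim$spec, prov)
}

#' Morphology simulation specification
#'
#' @param n_chars Number of characters.
#' @param state_counts Named probability vector over the number of states
#'   per character, e.g. `c("2" = 0.8, "3" = 0.2)`.
#' @param mixture_beta Concentration of the symmetric Beta distribution the
#'   per-character frequency of state 1 is drawn from (binary characters
#'   only); `NULL` for equal frequencies.
#' @param missing_prob Probability a cell is masked to `?`.
#' @param inapplicable_block_prob Probability a character is inapplicable
#'   (`-`) for the designated taxon block (a random clade of the tree).
#' @param seed Integer seed.
#' @return An object of class `gc_morphsim_spec`.
#' @export
morph_sim_spec <- function(n_chars, state_counts = c("2" = 0.8, "3" = 0.2),
                           mixture_beta = NULL, missing_prob = 0,
                           inapplicable_block_prob = 0, seed = 1L) {
  n_chars <- as.integer(n_chars)
  if (is.na(n_chars) || n_chars < 1L) abort_gc("n_chars must be >= 1", "invalid_spec")
  ks <- as.integer(names(state_counts))
  if (anyNA(ks) || any(ks < 2L)) abort_gc("state counts must be named by k >= 2", "invalid_spec")
  if (any(state_counts < 0) || sum(state_counts) <= 0) {
    abort_gc("state_counts must be a non-negative weight vector", "invalid_spec")
  }
  if (!is.null(mixture_beta) && mixture_beta <= 0) {
    abort_gc("mixture_beta must be > 0", "invalid_spec")
  }
  check_prob(missing_prob, "missing_prob")
  check_prob(inapplicable_block_prob, "inapplicable_block_prob")
  structure(list(n_chars = n_chars, state_counts = state_counts / sum(state_counts),
                 mixture_beta = mixture_beta, missing_prob = missing_prob,
                 inapplicable_block_prob = inapplicable_block_prob,
                 seed = as.integer(seed)),
            class = "gc_morphsim_spec")
}

# k-state Mk transition sampling down the tree for one character set with
# shared k and per-character stationary frequencies (k=2 mixture) or equal
# frequencies.
.mk_simulate_chars <- function(ut, k, freqs_per_char, trav = utree_traversal(ut)) {
  n <- utree_n_nodes(ut)
  nc <- ncol(freqs_per_char)
  states <- matrix(NA_integer_, n, nc)
  u <- stats::runif(nc)
  cf <- apply(freqs_per_char, 2L, cumsum)
  states[trav$root, ] <- colSums(cf < rep(u, each = k)) # root from stationarity
  for (v in rev(trav$order)) {
    if (v == trav$root) next
    p <- trav$parent[v]; len <- ut$length[trav$pedge[v]]
    states[v, ] <- .mk_evolve_edge(states[p, ], freqs_per_char, len)
  }
  states[seq_len(ut$n_tip), , drop = FALSE]
}

# F81-type k-state step: with prob 1 - exp(-beta t) redraw from frequencies.
.mk_evolve_edge <- function(parent_state, freqs, len) {
  k <- nrow(freqs); nc <- ncol(freqs)
  beta <- 1 / (1 - colSums(freqs^2))
  stay <- exp(-beta * len)
  redraw <- stats::runif(nc) >= stay
  out <- parent_state
  if (any(redraw)) {
    u <- stats::runif(sum(redraw))
    cf <- apply(freqs[, redraw, drop = FALSE], 2L, cumsum)
    out[redraw] <- colSums(cf < rep(u, each = k))
  }
  out
}

#' Simulate a morphological matrix
#'
#' Characters evolve under the Mk model with k states drawn from
#' `state_counts`; binary characters optionally draw their stationary
#' frequency per character from Beta(`mixture_beta`, `mixture_beta`).
#' Cells are then masked to `?` with `missing_prob`; characters flagged
#' inapplicable get `-` for a designated taxon block (a random clade).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param spec A [morph_sim_spec()].
#' @param coding_scheme Tag recorded on the result.
#' @return A [morph_matrix()].
#' @export
simulate_morphology <- function(tree, spec, coding_scheme = "non_additive") {
  stopifnot(inherits(spec, "gc_morphsim_spec"))
  ut <- as_utree(tree)
  with_seed(spec$seed, function() {
    trav <- utree_traversal(ut)
    ks <- as.integer(names(spec$state_counts))
    k_per_char <- if (length(ks) == 1L) rep(ks, spec$n_chars) else {
      sample(ks, spec$n_chars, replace = TRUE, prob = spec$state_counts)
    }
    m <- matrix(NA_integer_, ut$n_tip, spec$n_chars)
    for (k in unique(k_per_char)) {
      idx <- which(k_per_char == k)
      freqs <- if (k == 2L && !is.null(spec$mixture_beta)) {
        p1 <- stats::rbeta(length(idx), spec$mixture_beta, spec$mixture_beta)
        rbind(1 - p1, p1)
      } else {
        matrix(1 / k, k, length(idx))
      }
      m[, idx] <- .mk_simulate_chars(ut, k, freqs, trav)
    }
    out <- matrix(as.character(m), nrow(m), ncol(m))
    # inapplicable block: tips below a random internal edge
    if (spec$inapplicable_block_prob > 0 && ut$n_tip >= 4L) {
      ie <- utree_internal_edges(ut)
      eid <- ie[sample.int(length(ie), 1L)]
      child <- if (trav$parent[ut$edge[eid, 1L]] == ut$edge[eid, 2L]) {
        ut$edge[eid, 1L]
      } else ut$edge[eid, 2L]
      block <- .subtree_tips_states(ut, trav, child,
                                    rep(1L, 1L), 0.5)$tips
      flagged <- stats::runif(spec$n_chars) < spec$inapplicable_block_prob
      out[block, flagged] <- "-"
    }
    mask <- matrix(stats::runif(length(out)) < spec$missing_prob, nrow(out))
    out[mask] <- "?"
    rownames(out) <- ut$tip_label
    morph_matrix(out, coding_scheme = coding_scheme,
                 provenance = list(seed = spec$seed, n_chars = spec$n_chars))
  })
}
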