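# Mk-family likelihoods for multistate morphological matrices: equal
# exchangeabilities, optional unequal stationary frequencies (F81-type),
# ascertainment corrections for variable-only and parsimony-informative-only
# data, gamma rate variation, and symmetric beta frequency mixtures for
# binary characters.

#' Morphological model specification
#'
#' One member of the model grid: an ascertainment-bias correction
#' (`variable_only` assumes invariant characters were removed — the Mkv
#' model — while `parsimony_informative_only` additionally assumes
#' autapomorphic characters were removed), a branch-length prior (fixed
#' exponential with mean 0.1 changes/character, or hierarchical with an
#' exponential hyperprior on the mean), a rate-variation model (`equal` or
#' 4-category discrete gamma), and a transition/frequency model for binary
#' characters (`homogeneous`, or a symmetric beta mixture with 4 or 5
#' categories). Characters with three or more states always use equal
#' frequencies.
#'
#' @param ascertainment `"variable_only"` or `"parsimony_informative_only"`.
#' @param bl_prior `"fixed_exponential"` or `"hierarchical"`.
#' @param rates `"equal"` or `"gamma"` (four categories).
#' @param freq_model `"homogeneous"`, `"sym_mixture4"` or `"sym_mixture5"`.
#' @return An object of class `gc_morph_model`.
#' @export
morph_model_spec <- function(ascertainment = c("variable_only", "parsimony_informative_only"),
                             bl_prior = c("fixed_exponential", "hierarchical"),
                             rates = c("equal", "gamma"),
                             freq_model = c("homogeneous", "sym_mixture4", "sym_mixture5")) {
  structure(list(ascertainment = match.arg(ascertainment),
                 bl_prior = match.arg(bl_prior),
                 rates = match.arg(rates),
                 n_rate_categories = if (match.arg(rates) == "gamma") 4L else 1L,
                 freq_model = match.arg(freq_model),
                 mixture_categories = switch(match.arg(freq_model),
                                             homogeneous = 1L,
                                             sym_mixture4 = 4L,
                                             sym_mixture5 = 5L)),
            class = "gc_morph_model")
}

#' Enumerate the full morphological model grid
#'
#' The cross-product of 2 ascertainment corrections, 2 branch-length
#' priors, 2 rate-variation models and 3 frequency models: 24 model
#' specifications.
#'
#' @return A tibble with one row per model (columns for each dimension, a
#'   unique `model_id`, and a list-column `spec` of [morph_model_spec()]
#'   objects).
#' @export
morph_model_grid <- function() {
  grid <- expand.grid(
    ascertainment = c("variable_only", "parsimony_informative_only"),
    bl_prior = c("fixed_exponential", "hierarchical"),
    rates = c("equal", "gamma"),
    freq_model = c("homogeneous", "sym_mixture4", "sym_mixture5"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$model_id <- sprintf(
    "%s+%s+%s+%s",
    ifelse(grid$ascertainment == "variable_only", "Mkv", "Mkpi"),
    ifelse(grid$bl_prior == "fixed_exponential", "blfix", "blhyper"),
    ifelse(grid$rates == "equal", "req", "rgamma4"),
    c(homogeneous = "fhom", sym_mixture4 = "fmix4", sym_mixture5 = "fmix5")[grid$freq_model])
  grid$spec <- purrr::pmap(grid[, 1:4], function(ascertainment, bl_prior, rates, freq_model) {
    morph_model_spec(ascertainment, bl_prior, rates, freq_model)
  })
  tibble::as_tibble(grid)
}

#' Symmetric beta mixture categories for binary frequencies
#'
#' Frequencies of state 1 at the medians of C equal-probability bins of a
#' Beta(beta, beta) distribution, each category weighted 1/C. The set is
#' symmetric about 0.5 (and contains 0.5 when C is odd).
#'
#' @param C Number of categories (4 or 5).
#' @param beta Concentration of the symmetric beta distribution (> 0).
#' @return A tibble with columns `pi0`, `pi1`, `weight`.
#' @export
sym_mixture_categories <- function(C, beta) {
  C <- as.integer(C)
  if (!C %in% c(4L, 5L)) abort_gc("C must be 4 or 5", "invalid_spec")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort_gc("beta must be > 0", "invalid_spec")
  }
  p <- (seq_len(C) - 0.5) / C
  pi1 <- stats::qbeta(p, beta, beta)
  # enforce exact symmetry against qbeta rounding
  pi1 <- (pi1 + rev(1 - pi1)) / 2
  tibble::tibble(pi0 = 1 - pi1, pi1 = pi1, weight = 1 / C)
}

# Tip indicator partials for a k-state pattern bank: list over tips of
# k x P matrices (NA columns fully ambiguous).
.mk_tip_partials <- function(X, k) {
  lapply(seq_len(nrow(X)), function(v) {
    x <- X[v, ]
    m <- matrix(0, k, length(x))
    amb <- is.na(x)
    m[, amb] <- 1
    if (any(!amb)) m[cbind(x[!amb] + 1L, which(!amb))] <- 1
    m
  })
}

# F81-type k-state pruning over a bank of patterns.
# X: n_tip x P integer matrix, states 0..k-1, NA marginalised.
# Returns P x R matrix of per-rate-category log site likelihoods.
.mk_site_loglik <- function(ut, X, k, freqs, rates, trav = NULL, tipL = NULL) {
  trav <- trav %||% utree_traversal(ut)
  tipL <- tipL %||% .mk_tip_partials(X, k)
  n <- utree_n_nodes(ut)
  P <- ncol(X)
  beta_rate <- 1 / (1 - sum(freqs^2))
  out <- matrix(NA_real_, P, length(rates))
  for (r in seq_along(rates)) {
    ef <- exp(-beta_rate * ut$length * rates[r])
    part <- vector("list", n)
    logscale <- numeric(P)
    for (v in trav$order) {
      if (v <= ut$n_tip) next
      m <- 1
      for (w in trav$children[[v]]) {
        e <- trav$pedge[w]
        cw <- if (w <= ut$n_tip) tipL[[w]] else part[[w]]
        pooled <- colSums(freqs * cw)
        m <- m * (ef[e] * cw + (1 - ef[e]) * rep(pooled, each = k))
      }
      s <- m[1L, ]
      for (s_i in 2:k) s <- pmax(s, m[s_i, ])
      s[s == 0] <- 1
      logscale <- logscale + log(s)
      part[[v]] <- m / rep(s, each = k)
    }
    lik <- colSums(freqs * part[[trav$root]])
    out[, r] <- log(lik) + logscale
  }
  out
}

#' Log-likelihood of one multistate pattern under the Mk model
#'
#' Pruning likelihood under the k-state CTMC with equal exchangeabilities
#' and the given stationary frequencies, rate-normalised to one expected
#' change per unit branch length at stationarity; averaged over the given
#' rate multipliers with equal weights. `?` and `-` are marginalised.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param pattern Named character/integer vector over the tips (states
#'   `0..k-1`, `?`, `-` or NA).
#' @param k Number of states.
#' @param freqs Stationary frequencies (length k, default equal).
#' @param rates Rate multipliers (default 1).
#' @return Log-probability.
#' @export
mk_pattern_loglik <- function(tree, pattern, k, freqs = rep(1 / k, k), rates = 1) {
  ut <- as_utree(tree)
  k <- as.integer(k)
  if (k < 2L) abort_gc("k must be >= 2", "invalid_spec")
  if (length(freqs) != k || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8) {
    abort_gc("freqs must be k positive numbers summing to 1", "invalid_spec")
  }
  x <- morph_pattern_to_vector(pattern, ut$tip_label, k)
  ll <- .mk_site_loglik(ut, matrix(x, ncol = 1L), k, freqs, rates)
  mx <- max(ll)
  log(mean(exp(ll - mx))) + mx
}

morph_pattern_to_vector <- function(pattern, tip_label, k) {
  if (!is.null(names(pattern))) pattern <- pattern[tip_label]
  if (length(pattern) != length(tip_label)) {
    abort_gc("pattern length does not match number of tips", "invalid_pattern")
  }
  if (is.character(pattern)) pattern[pattern %in% c("?", "-")] <- NA
  x <- suppressWarnings(as.integer(pattern))
  bad <- !is.na(x) & (x < 0L | x >= k)
  if (any(bad)) abort_gc("pattern contains a state >= k", "invalid_state")
  x
}

#' Probability that a character is observable under an ascertainment mode
#'
#' For `variable_only`, the probability that a character is not constant:
#' `1 - sum_s P(all tips in state s)`. For `parsimony_informative_only`,
#' the probability that a character is parsimony-informative:
#' `1 - sum_s P(at least N-1 tips in state s)`, computed per background
#' state with a pruning dynamic program that tracks the number of
#' off-background tips (capped at two); each constant pattern is counted
#' exactly once. Probabilities are averaged over the given rate categories.
#'
#' @inheritParams mk_pattern_loglik
#' @param mode `"variable_only"` or `"parsimony_informative_only"`.
#' @return Probability in `[0, 1]`.
#' @export
ascertainment_probability <- function(tree, k, freqs = rep(1 / k, k), rates = 1,
                                      mode = c("variable_only", "parsimony_informative_only"),
                                      trav = NULL) {
  mode <- match.arg(mode)
  ut <- as_utree(tree)
  if (mode == "parsimony_informative_only" && ut$n_tip < 4L) {
    abort_gc("parsimony-informative correction needs at least 4 taxa", "invalid_spec")
  }
  trav <- trav %||% utree_traversal(ut)
  if (mode == "variable_only") {
    const <- matrix(rep(0:(k - 1L), each = ut$n_tip), ut$n_tip, k)
    ll <- .mk_site_loglik(ut, const, k, freqs, rates, trav = trav)  # k patterns x R
    p_const <- rowMeans(exp(ll))
    max(0, 1 - sum(p_const))
  } else {
    p_noninf <- mean(vapply(rates, function(r) {
      sum(vapply(0:(k - 1L), function(s) {
        .mk_offcount_probs(ut, k, freqs, r, s, trav = trav)
      }, numeric(2L)))
    }, 0))
    max(0, 1 - p_noninf)
  }
}

# P(0 off-background tips) and P(exactly 1 off-background tip) for
# background state s, one rate category: DP over (node state, capped count).
.mk_offcount_probs <- function(ut, k, freqs, rate, s, trav = NULL) {
  trav <- trav %||% utree_traversal(ut)
  n <- utree_n_nodes(ut)
  beta_rate <- 1 / (1 - sum(freqs^2))
  ef <- exp(-beta_rate * ut$length * rate)
  tip_tab <- matrix(0, k, 3L)
  tip_tab[s + 1L, 1L] <- 1           # tip in background state: count 0
  tip_tab[-(s + 1L), 2L] <- 1        # tip off background: count 1
  tab <- vector("list", n)   # k x 3 : P(count = 0, 1, >=2 | node state)
  for (v in trav$order) {
    if (v <= ut$n_tip) next
    acc <- NULL
    for (w in trav$children[[v]]) {
      e <- trav$pedge[w]
      cw <- if (w <= ut$n_tip) tip_tab else tab[[w]]   # k x 3 by child state
      pooled <- colSums(freqs * cw)
      a <- ef[e] * cw + (1 - ef[e]) * rep(pooled, each = k)
      acc <- if (is.null(acc)) a else .conv_capped(acc, a)
    }
    tab[[v]] <- acc
  }
  rootm <- tab[[trav$root]]
  p <- colSums(freqs * rootm)
  p[1:2]
}

# capped-at-2 convolution of two k x 3 count tables, state-wise
.conv_capped <- function(a, b) {
  out <- matrix(0, nrow(a), 3L)
  out[, 1L] <- a[, 1L] * b[, 1L]
  out[, 2L] <- a[, 1L] * b[, 2L] + a[, 2L] * b[, 1L]
  out[, 3L] <- pmax(rowSums(a) * rowSums(b) - out[, 1L] - out[, 2L], 0)
  out
}

#' Filter morphological characters to the observable set
#'
#' Removes characters that are empty (all `?`/`-`), constant, and — under
#' the parsimony-informative correction — autapomorphic, so the data are
#' consistent with the model's ascertainment assumption.
#'
#' @param x A [morph_matrix()].
#' @param ascertainment `"variable_only"` or `"parsimony_informative_only"`.
#' @return A filtered `gc_morphmatrix`.
#' @export
filter_morph_characters <- function(x, ascertainment = c("variable_only",
                                                         "parsimony_informative_only")) {
  ascertainment <- match.arg(ascertainment)
  keep <- apply(x$data, 2L, function(col) {
    obs <- col[!col %in% c("?", "-")]
    if (length(obs) == 0L) return(FALSE)
    tb <- table(obs)
    if (length(tb) < 2L) return(FALSE)                    # constant
    if (ascertainment == "parsimony_informative_only") {
      return(sum(tb) - max(tb) >= 2L)                     # >1 off-background tip
    }
    TRUE
  })
  out <- x
  out$data <- x$data[, keep, drop = FALSE]
  out$provenance$ascertainment_filter <- ascertainment
  out
}

# Internal: precompute pattern banks and mixture structure for a morphology
# matrix under a model spec; reused by morph_loglik and the MCMC kernel.
.morph_prep <- function(x, spec, tip_label) {
  dat <- x$data[tip_label, , drop = FALSE]
  obs <- matrix(!(dat %in% c("?", "-")), nrow(dat))
  empty <- colSums(obs) == 0L
  if (any(empty)) {
    warning(sum(empty), " all-missing character(s) excluded", call. = FALSE)
    dat <- dat[, !empty, drop = FALSE]
  }
  kvec <- apply(dat, 2L, function(col) {
    obs <- suppressWarnings(as.integer(col[!col %in% c("?", "-")]))
    max(2L, max(obs) + 1L)
  })
  # reject characters the ascertainment assumption says cannot be observed
  bad <- apply(dat, 2L, function(col) {
    obs <- col[!col %in% c("?", "-")]
    tb <- table(obs)
    length(tb) < 2L ||
      (spec$ascertainment == "parsimony_informative_only" && sum(tb) - max(tb) < 2L)
  })
  if (any(bad)) {
    abort_gc(paste0(sum(bad), " character(s) violate the '", spec$ascertainment,
                    "' ascertainment assumption; drop them with ",
                    "filter_morph_characters()"), "unobservable_character")
  }
  groups <- lapply(sort(unique(kvec)), function(k) {
    sub <- dat[, kvec == k, drop = FALSE]
    num <- matrix(suppressWarnings(as.integer(ifelse(sub %in% c("?", "-"), NA, sub))),
                  nrow(sub), ncol(sub))
    cmp <- compress_patterns(num)
    list(k = k, patterns = cmp$patterns, weights = cmp$weights,
         n_chars = ncol(sub), tipL = .mk_tip_partials(cmp$patterns, k))
  })
  list(groups = groups, spec = spec)
}

# Internal: morphology log-likelihood from a prep object.
# params: list(alpha = gamma shape or NULL, beta = mixture concentration or NULL)
.morph_loglik_prep <- function(prep, ut, params, trav = NULL) {
  trav <- trav %||% utree_traversal(ut)
  spec <- prep$spec
  rates <- if (spec$rates == "gamma") {
    gamma_category_rates(params$alpha %||% 1, spec$n_rate_categories)
  } else 1
  total <- 0
  for (grp in prep$groups) {
    k <- grp$k
    cats <- if (k == 2L && spec$freq_model != "homogeneous") {
      sym_mixture_categories(spec$mixture_categories, params$beta %||% 1)
    } else if (k == 2L) {
      tibble::tibble(pi0 = 0.5, pi1 = 0.5, weight = 1)
    } else NULL
    if (!is.null(cats)) {
      site <- matrix(0, nrow(cats), length(grp$weights))
      pobs <- numeric(nrow(cats))
      for (ci in seq_len(nrow(cats))) {
        fr <- c(cats$pi0[ci], cats$pi1[ci])
        ll <- .mk_site_loglik(ut, grp$patterns, 2L, fr, rates,
                              trav = trav, tipL = grp$tipL)
        mx <- apply(ll, 1L, max)
        site[ci, ] <- exp(log(rowMeans(exp(ll - mx))) + mx)
        pobs[ci] <- ascertainment_probability(ut, 2L, fr, rates,
                                              spec$ascertainment, trav = trav)
        if (pobs[ci] <= 0) abort_gc("ascertainment probability is zero", "degenerate_model")
      }
      cond <- colSums(cats$weight * site / pobs)
      total <- total + sum(log(cond) * grp$weights)
    } else {
      fr <- rep(1 / k, k)
      ll <- .mk_site_loglik(ut, grp$patterns, k, fr, rates,
                            trav = trav, tipL = grp$tipL)
      mx <- apply(ll, 1L, max)
      site <- exp(log(rowMeans(exp(ll - mx))) + mx)
      pobs <- ascertainment_probability(ut, k, fr, rates,
                                        spec$ascertainment, trav = trav)
      if (pobs <= 0) abort_gc("ascertainment probability is zero", "degenerate_model")
      total <- total + sum((log(site) - log(pobs)) * grp$weights)
    }
  }
  total
}

#' Ascertainment-corrected log-likelihood of a morphological matrix
#'
#' Characters are partitioned by state count k. Binary characters use the
#' spec's frequency model (homogeneous, or a symmetric beta mixture whose
#' per-category conditional likelihoods — each divided by its own
#' ascertainment probability — are averaged with equal weights); characters
#' with k >= 3 use equal frequencies. Gamma rate categories are averaged in
#' both the pattern probability and the ascertainment probability before
#' the conditioning division.
#'
#' @param x A [morph_matrix()].
#' @param tree A `phylo` tree with branch lengths.
#' @param spec A [morph_model_spec()].
#' @param alpha Gamma shape (needed when `spec$rates == "gamma"`).
#' @param beta Mixture concentration (needed for mixture frequency models).
#' @return Total log-likelihood.
#' @export
morph_loglik <- function(x, tree, spec, alpha = 1, beta = 1) {
  stopifnot(inherits(x, "gc_morphmatrix"), inherits(spec, "gc_morph_model"))
  ut <- as_utree(tree)
  prep <- .morph_prep(x, spec, ut$tip_label)
  .morph_loglik_prep(prep, ut, list(alpha = alpha, beta = beta))
}
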