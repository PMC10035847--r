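#' Reversible binary substitution model specification
#'
#' A two-state (absence/presence) reversible continuous-time Markov chain
#' with stationary frequencies `(1 - pi1, pi1)`, normalised so that one unit
#' of branch length corresponds to one expected state change at
#' stationarity. Optional among-character rate variation uses the discrete
#' gamma approximation with `n_rate_categories` equal-weight categories.
#' `window` records the observability window the likelihood conditions on
#' (NULL for no ascertainment correction).
#'
#' @param pi1 Stationary frequency of presence, in (0, 1).
#' @param gamma_shape Shape of the gamma rate distribution, or `NULL` for
#'   equal rates.
#' @param n_rate_categories Number of discrete rate categories (>= 1).
#' @param window `NULL`, or integer pair `c(m_min, m_max)`.
#' @return An object of class `gc_binary_model`.
#' @export
binary_model_spec <- function(pi1 = 0.5, gamma_shape = NULL,
                              n_rate_categories = if (is.null(gamma_shape)) 1L else 4L,
                              window = NULL) {
  check_prob(pi1, "pi1", open_left = TRUE, open_right = TRUE)
  if (!is.null(gamma_shape) && (!is.numeric(gamma_shape) || gamma_shape <= 0)) {
    abort_gc("gamma_shape must be positive", "invalid_spec")
  }
  n_rate_categories <- as.integer(n_rate_categories)
  if (n_rate_categories < 1L) abort_gc("n_rate_categories must be >= 1", "invalid_spec")
  rates <- if (is.null(gamma_shape) || n_rate_categories == 1L) {
    rep(1, n_rate_categories)
  } else {
    gamma_category_rates(gamma_shape, n_rate_categories)
  }
  structure(list(pi1 = pi1, gamma_shape = gamma_shape,
                 n_rate_categories = n_rate_categories,
                 rates = rates, window = window),
            class = "gc_binary_model")
}

#' Discrete gamma category rates
#'
#' Mean rate of each of `R` equal-probability quantile bins of a
#' Gamma(alpha, alpha) distribution (mean 1). The bin mean has the closed
#' form `R * (F_{alpha+1}(q_{i+1}) - F_{alpha+1}(q_i))` where `F_a` is the
#' Gamma(a, alpha) CDF and `q_i` are the bin boundary quantiles.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param R Number of categories (>= 1).
#' @return Numeric vector of length `R` averaging to 1.
#' @export
gamma_category_rates <- function(alpha, R) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort_gc("alpha must be positive", "invalid_spec")
  }
  R <- as.integer(R)
  if (R < 1L) abort_gc("R must be >= 1", "invalid_spec")
  if (R == 1L) return(1)
  q <- stats::qgamma(seq_len(R - 1L) / R, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  upper <- stats::pgamma(bounds[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(R + 1L)], shape = alpha + 1, rate = alpha)
  r <- R * (upper - lower)
  r / mean(r)  # guard rounding; already ~1
}

#' Binary transition probabilities
#'
#' 2x2 transition matrix of the reversible binary chain over branch length
#' `t`, with rate normalised so the expected number of changes per unit
#' length at stationarity is 1: `mu = 1 / (2 pi0 pi1)`,
#' `P(0 -> 1) = pi1 (1 - exp(-mu t))`, `P(1 -> 0) = pi0 (1 - exp(-mu t))`.
#'
#' @param pi1 Stationary frequency of state 1, in (0, 1).
#' @param t Branch length (>= 0), in expected changes per character.
#' @param rate Optional rate multiplier (e.g. a gamma category rate).
#' @return 2x2 row-stochastic matrix with rows/cols `0`, `1`.
#' @export
transition_probabilities <- function(pi1, t, rate = 1) {
  check_prob(pi1, "pi1", open_left = TRUE, open_right = TRUE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort_gc("branch length must be >= 0", "invalid_branch_length")
  }
  pi0 <- 1 - pi1
  mu <- 1 / (2 * pi0 * pi1)
  ef <- exp(-mu * t * rate)
  p01 <- pi1 * (1 - ef)
  p10 <- pi0 * (1 - ef)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2L, 2L,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Vectorised edge transition terms for the pruning recursion: for each edge
# length t (times rate), returns the 4 entries of P(t) as vectors.
.bin_pmats <- function(pi1, lens) {
  pi0 <- 1 - pi1
  ef <- exp(-lens / (2 * pi0 * pi1))
  list(p00 = pi0 + pi1 * ef, p01 = pi1 * (1 - ef),
       p10 = pi0 * (1 - ef), p11 = pi1 + pi0 * ef)
}

# Tip conditional-likelihood rows for a bank of binary patterns: a list
# over tips of 2 x P matrices (NA rows fully ambiguous). Data-dependent
# only, so precomputable once per analysis.
.bin_tip_partials <- function(X) {
  lapply(seq_len(nrow(X)), function(v) {
    x <- X[v, ]
    m <- matrix(1, 2L, length(x))
    obs <- !is.na(x)
    m[1L, obs] <- 1 - x[obs]
    m[2L, obs] <- x[obs]
    m
  })
}

# Core pruning likelihood for a bank of binary site patterns.
# X: n_tip x P matrix with entries 0/1/NA (NA marginalised).
# Returns a P x R matrix of per-category log site likelihoods.
# `trav` and `tipL` may be precomputed (topology / data caches).
.bin_site_loglik <- function(ut, X, pi1, rates, trav = NULL, tipL = NULL) {
  trav <- trav %||% utree_traversal(ut)
  tipL <- tipL %||% .bin_tip_partials(X)
  n <- utree_n_nodes(ut)
  P <- ncol(X)
  out <- matrix(NA_real_, P, length(rates))
  for (r in seq_along(rates)) {
    pm <- .bin_pmats(pi1, ut$length * rates[r])
    part <- vector("list", n)    # 2 x P conditional likelihoods
    logscale <- numeric(P)
    for (v in trav$order) {
      if (v <= ut$n_tip) next
      m0 <- 1; m1 <- 1
      for (w in trav$children[[v]]) {
        e <- trav$pedge[w]
        cw <- if (w <= ut$n_tip) tipL[[w]] else part[[w]]
        m0 <- m0 * (pm$p00[e] * cw[1L, ] + pm$p01[e] * cw[2L, ])
        m1 <- m1 * (pm$p10[e] * cw[1L, ] + pm$p11[e] * cw[2L, ])
      }
      # rescale to avoid underflow on large trees
      s <- pmax(m0, m1)
      s[s == 0] <- 1
      logscale <- logscale + log(s)
      part[[v]] <- rbind(m0 / s, m1 / s)
    }
    rootm <- part[[trav$root]]
    lik <- (1 - pi1) * rootm[1L, ] + pi1 * rootm[2L, ]
    out[, r] <- log(lik) + logscale
  }
  out
}

#' Log-likelihood of one binary site pattern
#'
#' Felsenstein pruning over an arbitrary rooting (the model is reversible,
#' so root placement does not change the value), averaged over the model's
#' rate categories with equal weights. `NA` (or `"?"`) entries are
#' marginalised.
#'
#' @param tree A `phylo` tree with branch lengths (or an internal `utree`).
#' @param pattern Named vector over the tree's tip labels with values 0, 1
#'   or NA.
#' @param model A [binary_model_spec()].
#' @return Log-probability of the pattern.
#' @export
pattern_loglik <- function(tree, pattern, model) {
  ut <- as_utree(tree)
  if (any(ut$length < 0)) abort_gc("negative branch length", "invalid_branch_length")
  x <- pattern_to_vector(pattern, ut$tip_label)
  ll <- .bin_site_loglik(ut, matrix(x, ncol = 1L), model$pi1, model$rates)
  as.vector(logmeanexp_rows(ll))
}

# row-wise log(mean(exp(.))) that is -Inf-safe
logmeanexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  out <- mx
  ok <- is.finite(mx)
  if (any(ok)) {
    out[ok] <- log(rowMeans(exp(m[ok, , drop = FALSE] - mx[ok]))) + mx[ok]
  }
  out
}

pattern_to_vector <- function(pattern, tip_label) {
  if (!is.null(names(pattern))) {
    missing <- setdiff(tip_label, names(pattern))
    if (length(missing)) {
      abort_gc(paste0("pattern lacks taxa: ", paste(missing, collapse = ", ")),
               "invalid_pattern")
    }
    pattern <- pattern[tip_label]
  } else if (length(pattern) != length(tip_label)) {
    abort_gc("pattern length does not match number of tips", "invalid_pattern")
  }
  if (is.character(pattern)) pattern <- ifelse(pattern == "?", NA, pattern)
  x <- suppressWarnings(as.integer(pattern))
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad)) abort_gc("pattern states must be 0, 1 or NA/?", "invalid_pattern")
  x
}

#' Distribution of the number of tips in state 1
#'
#' Probability vector of K = number of leaves observed in state 1 for a
#' single character under the binary model, computed by a pruning-style
#' dynamic program that tracks (node state, count of 1-tips below) and
#' combines children by convolution; averaged over rate categories. This is
#' the ingredient of the ascertainment-bias correction: the probability that
#' a character falls in the observability window is `sum(P(K = j))` over the
#' window.
#'
#' @inheritParams pattern_loglik
#' @return Numeric vector of length N+1, `P(K = 0) ... P(K = N)`.
#' @export
count_distribution <- function(tree, model) {
  ut <- as_utree(tree)
  if (any(ut$length < 0)) abort_gc("negative branch length", "invalid_branch_length")
  Reduce(`+`, lapply(model$rates, function(r) {
    .bin_count_dist_cat(ut, model$pi1, r)
  })) / length(model$rates)
}

# Single-category count distribution; returns length-(N+1) vector.
.bin_count_dist_cat <- function(ut, pi1, rate, trav = NULL) {
  trav <- trav %||% utree_traversal(ut)
  n <- utree_n_nodes(ut)
  pm <- .bin_pmats(pi1, ut$length * rate)
  tip_tab <- matrix(c(1, 0, 0, 1), 2L, 2L)  # state 0 -> j=0; state 1 -> j=1
  tab <- vector("list", n)  # 2 x (k+1): P(j one-tips below | node state s)
  for (v in trav$order) {
    if (v <= ut$n_tip) next
    acc <- NULL
    for (w in trav$children[[v]]) {
      e <- trav$pedge[w]
      cw <- if (w <= ut$n_tip) tip_tab else tab[[w]]
      a <- rbind(pm$p00[e] * cw[1L, ] + pm$p01[e] * cw[2L, ],
                 pm$p10[e] * cw[1L, ] + pm$p11[e] * cw[2L, ])
      acc <- if (is.null(acc)) a else .conv_states(acc, a)
    }
    tab[[v]] <- acc
  }
  rootm <- tab[[trav$root]]
  as.vector((1 - pi1) * rootm[1L, ] + pi1 * rootm[2L, ])
}

# convolve two (2 x .) count tables state-wise
.conv_states <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  out <- matrix(0, 2L, na + nb - 1L)
  for (i in seq_len(na)) {
    idx <- i:(i + nb - 1L)
    out[1L, idx] <- out[1L, idx] + a[1L, i] * b[1L, ]
    out[2L, idx] <- out[2L, idx] + a[2L, i] * b[2L, ]
  }
  out
}

#' Ascertainment-corrected log-likelihood of a presence/absence matrix
#'
#' Sum over characters of the pattern log-likelihood minus the log
#' probability that a character falls inside the observability window
#' (conditional likelihood). With rate categories, the per-character
#' numerator and the window probability are each averaged over categories
#' before the division, corresponding to a per-character latent rate shared
#' by the pattern and its observability. A window of `NULL` or `c(0, N)`
#' gives the unconditioned likelihood.
#'
#' @param x A [pa_matrix()] object (its recorded window must match the
#'   model's, when both are set).
#' @inheritParams pattern_loglik
#' @return Total log-likelihood (scalar).
#' @export
corrected_loglik <- function(x, tree, model) {
  stopifnot(inherits(x, "gc_pamatrix"))
  ut <- as_utree(tree)
  dat <- x$data[ut$tip_label, , drop = FALSE]
  if (!is.null(x$window) && !is.null(model$window) &&
      !identical(as.integer(x$window), as.integer(model$window))) {
    abort_gc("matrix window does not match model window", "window_mismatch")
  }
  cmp <- compress_patterns(dat)
  sll <- .bin_site_loglik(ut, cmp$patterns, model$pi1, model$rates)
  site_log <- logmeanexp_rows(sll)
  total <- sum(site_log * cmp$weights)
  w <- model$window
  if (!is.null(w) && !(w[1] == 0L && w[2] == ut$n_tip)) {
    pk <- count_distribution(ut, model)
    pwin <- sum(pk[(w[1] + 1L):(w[2] + 1L)])
    if (pwin <= 0) abort_gc("window probability is zero", "degenerate_window")
    total <- total - ncol(dat) * log(pwin)
  }
  total
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimises the branch lengths of `tree` under the binary model, either
#' with the ascertainment correction for the model's observability window
#' (`corrected = TRUE`) or ignoring the conditioning (`corrected = FALSE`,
#' useful to demonstrate the bias the correction removes). Optimisation is
#' quasi-Newton on log branch lengths.
#'
#' @inheritParams corrected_loglik
#' @param corrected Apply the window conditioning.
#' @return A list: `tree` (with fitted lengths), `loglik`, `tree_length`,
#'   `convergence` (0 = success).
#' @export
fit_branch_lengths <- function(x, tree, model, corrected = TRUE) {
  stopifnot(inherits(x, "gc_pamatrix"))
  ut <- as_utree(tree)
  trav <- utree_traversal(ut)
  dat <- x$data[ut$tip_label, , drop = FALSE]
  cmp <- compress_patterns(dat)
  w <- model$window %||% x$window
  condition <- corrected && !is.null(w) && !(w[1] == 0L && w[2] == ut$n_tip)
  mmin <- if (condition) w[1] else 0L
  mmax <- if (condition) w[2] else ut$n_tip
  nll <- function(loglen) {
    -bin_corrected_loglik_cpp(cmp$patterns, cmp$weights, ncol(dat),
                              trav$order, trav$parent, trav$pedge, trav$root,
                              exp(loglen), model$pi1, model$rates,
                              mmin, mmax, condition)
  }
  init <- log(pmax(ut$length, 1e-4))
  # box constraints keep the uncorrected fit finite when its likelihood
  # increases monotonically in tree length (see the methods vignette)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = log(1e-8), upper = log(100),
                      control = list(maxit = 500, factr = 1e4))
  ut$length <- exp(opt$par)
  list(tree = utree_to_phylo(ut), loglik = -opt$value,
       tree_length = sum(ut$length), convergence = opt$convergence)
}

# Collapse duplicate site patterns (columns) to unique patterns + weights.
compress_patterns <- function(dat) {
  key <- apply(dat, 2L, function(col) paste(ifelse(is.na(col), "?", col), collapse = ""))
  ux <- !duplicated(key)
  tabs <- table(key)
  patterns <- dat[, ux, drop = FALSE]
  weights <- as.numeric(tabs[key[ux]])
  list(patterns = patterns, weights = weights)
}
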