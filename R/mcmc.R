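# Metropolis-Hastings sampler over (topology, branch lengths, model
# parameters) for single-partition and linked two-partition models.
# One generation = a sweep of `moves_per_generation` proposals drawn by
# weight (by default the sum of the move weights, so each registered move
# fires about once per generation); all randomness is an explicit function
# of (seed, replicate index).

#' MCMC run configuration
#'
#' @param generations Number of generations (each a sweep of
#'   `moves_per_generation` proposals).
#' @param moves_per_generation Proposals per generation; default is the sum
#'   of the active move weights, so each move fires about once per
#'   generation.
#' @param sample_every Thinning interval for recording samples.
#' @param replicates Number of independent replicate chains (default 4).
#' @param burn_in_fraction Fraction of samples discarded by downstream
#'   summaries (default 0.25); recorded here so every consumer uses the
#'   same value.
#' @param move_weights Named numeric vector overriding default move weights
#'   (`nni`, `spr`, `brlen`, `pi1`, `alpha`, `beta`, `hyper_mean`,
#'   `scaler`).
#' @param seed Integer master seed; replicate r runs under
#'   `derive_seed(seed, paste0("replicate-", r))`.
#' @param likelihood If `FALSE`, sample from the prior only (validation of
#'   proposals and Hastings ratios).
#' @param brlen_lambda Tuning constant of the branch-length multiplier.
#' @return An object of class `gc_mcmc_config`.
#' @export
mcmc_config <- function(generations, sample_every = 10L, replicates = 4L,
                        burn_in_fraction = 0.25, move_weights = NULL,
                        seed = 1L, likelihood = TRUE, brlen_lambda = 2,
                        moves_per_generation = NULL) {
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 1L) abort_gc("generations must be >= 1", "invalid_config")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    abort_gc("burn_in_fraction must be in [0, 1)", "invalid_config")
  }
  if (!is.null(move_weights)) {
    if (is.null(names(move_weights)) || any(move_weights < 0)) {
      abort_gc("move_weights must be a named non-negative vector", "invalid_config")
    }
  }
  structure(list(generations = generations, sample_every = as.integer(sample_every),
                 replicates = as.integer(replicates),
                 burn_in_fraction = burn_in_fraction,
                 move_weights = move_weights, seed = as.integer(seed),
                 likelihood = likelihood, brlen_lambda = brlen_lambda,
                 moves_per_generation = moves_per_generation),
            class = "gc_mcmc_config")
}

#' Model partitions for MCMC
#'
#' A partition couples one data matrix with its substitution model. All
#' partitions of a combined model share the tree topology and branch
#' lengths (in expected gene-content changes for the reference partition);
#' every partition after the first gets a sampled rate scaler.
#'
#' @param x A [pa_matrix()] (binary) or [morph_matrix()] (morphology).
#' @param model A [binary_model_spec()]; its `window` (or the matrix's
#'   recorded window) drives the ascertainment correction.
#' @param sample_pi1 Sample the presence frequency (uniform prior) or keep
#'   it fixed.
#' @return A partition object for [combined_model()].
#' @export
binary_partition <- function(x, model = binary_model_spec(window = x$window),
                             sample_pi1 = TRUE) {
  stopifnot(inherits(x, "gc_pamatrix"))
  window <- model$window %||% x$window
  if (!is.null(x$window) && !is.null(model$window) &&
      !identical(as.integer(x$window), as.integer(model$window))) {
    abort_gc("matrix window does not match model window", "window_mismatch")
  }
  structure(list(type = "binary", data = x, model = model, window = window,
                 sample_pi1 = sample_pi1),
            class = "gc_partition")
}

#' @rdname binary_partition
#' @param spec A [morph_model_spec()].
#' @param alpha,beta Initial values of the gamma shape and mixture
#'   concentration (sampled when the spec uses them; exponential mean-1
#'   priors).
#' @export
morph_partition <- function(x, spec = morph_model_spec(), alpha = 1, beta = 1) {
  stopifnot(inherits(x, "gc_morphmatrix"))
  structure(list(type = "morph", data = x, spec = spec,
                 alpha = alpha, beta = beta),
            class = "gc_partition")
}

#' Linked multi-partition model
#'
#' @param ... Partition objects ([binary_partition()],
#'   [morph_partition()]); the first is the reference partition whose rate
#'   scaler is fixed at 1.
#' @param bl_prior Branch-length prior shared by all partitions:
#'   `"fixed_exponential"` (i.i.d. exponential, mean `bl_prior_mean`) or
#'   `"hierarchical"` (i.i.d. exponential with sampled mean, itself
#'   exponential with mean `bl_prior_mean`).
#' @param bl_prior_mean Mean of the (hyper)prior, default 0.1 expected
#'   changes per character per branch.
#' @param sample_scalers Sample the extra partition rate scalers
#'   (exponential mean-1 prior) or fix them at 1.
#' @return An object of class `gc_model`.
#' @export
combined_model <- function(..., bl_prior = c("fixed_exponential", "hierarchical"),
                           bl_prior_mean = 0.1, sample_scalers = TRUE) {
  partitions <- list(...)
  if (length(partitions) == 1L && is.list(partitions[[1L]]) &&
      !inherits(partitions[[1L]], "gc_partition")) {
    partitions <- partitions[[1L]]
  }
  if (length(partitions) == 0L) abort_gc("no partitions", "invalid_model")
  if (!all(vapply(partitions, inherits, TRUE, "gc_partition"))) {
    abort_gc("all partitions must be gc_partition objects", "invalid_model")
  }
  taxa <- sort(partition_taxa(partitions[[1L]]))
  for (p in partitions[-1L]) {
    if (!identical(sort(partition_taxa(p)), taxa)) {
      abort_gc("partitions have different taxon sets", "invalid_model")
    }
  }
  structure(list(partitions = partitions, bl_prior = match.arg(bl_prior),
                 bl_prior_mean = bl_prior_mean, sample_scalers = sample_scalers,
                 taxa = taxa),
            class = "gc_model")
}

partition_taxa <- function(p) rownames(p$data$data)

# Precompute per-partition likelihood structures for a fixed tip ordering.
.prep_partition <- function(p, tip_label) {
  if (p$type == "binary") {
    dat <- p$data$data[tip_label, , drop = FALSE]
    cmp <- compress_patterns(dat)
    list(type = "binary", X = cmp$patterns, w = cmp$weights,
         tipL = .bin_tip_partials(cmp$patterns),
         n_chars = ncol(dat), window = p$window,
         gamma = !is.null(p$model$gamma_shape),
         R = p$model$n_rate_categories,
         sample_pi1 = isTRUE(p$sample_pi1),
         init = list(pi1 = p$model$pi1, alpha = p$model$gamma_shape %||% 1))
  } else {
    prep <- .morph_prep(p$data, p$spec, tip_label)
    prep$type <- "morph"
    prep$sample_alpha <- p$spec$rates == "gamma"
    prep$sample_beta <- p$spec$freq_model != "homogeneous"
    prep$init <- list(alpha = p$alpha, beta = p$beta)
    prep
  }
}

.scaled_utree <- function(ut, s) {
  if (s != 1) ut$length <- ut$length * s
  ut
}

.partition_loglik <- function(prep, ut, params, trav = NULL) {
  if (prep$type == "binary") {
    rates <- if (prep$gamma) gamma_category_rates(params$alpha, prep$R) else 1
    trav <- trav %||% utree_traversal(ut)
    w <- prep$window
    condition <- !is.null(w) && !(w[1] == 0L && w[2] == ut$n_tip)
    bin_corrected_loglik_cpp(
      prep$X, prep$w, prep$n_chars,
      trav$order, trav$parent, trav$pedge, trav$root,
      ut$length, params$pi1, rates,
      if (condition) w[1] else 0L, if (condition) w[2] else ut$n_tip,
      condition)
  } else {
    .morph_loglik_prep(prep, ut, params, trav = trav)
  }
}

.model_loglik <- function(preps, ut, state, trav = NULL) {
  trav <- trav %||% utree_traversal(ut)
  total <- 0
  for (i in seq_along(preps)) {
    ut_i <- .scaled_utree(ut, state$scalers[i])
    ll <- .partition_loglik(preps[[i]], ut_i, state$params[[i]], trav = trav)
    if (!is.finite(ll)) return(-Inf)
    total <- total + ll
  }
  total
}

.model_logprior <- function(model, ut, state) {
  lp <- 0
  if (model$bl_prior == "fixed_exponential") {
    lp <- lp + sum(stats::dexp(ut$length, 1 / model$bl_prior_mean, log = TRUE))
  } else {
    m <- state$hyper_mean
    lp <- lp + sum(stats::dexp(ut$length, 1 / m, log = TRUE)) +
      stats::dexp(m, 1 / model$bl_prior_mean, log = TRUE)
  }
  for (i in seq_along(state$params)) {
    pr <- state$params[[i]]
    if (!is.null(pr$alpha_sampled) && pr$alpha_sampled) {
      lp <- lp + stats::dexp(pr$alpha, 1, log = TRUE)
    }
    if (!is.null(pr$beta_sampled) && pr$beta_sampled) {
      lp <- lp + stats::dexp(pr$beta, 1, log = TRUE)
    }
    # pi1 ~ Uniform(0,1): contributes 0
  }
  if (length(state$scalers) > 1L && model$sample_scalers) {
    lp <- lp + sum(stats::dexp(state$scalers[-1L], 1, log = TRUE))
  }
  lp
}

# Build the move list: (name, weight, proposal function).
.build_moves <- function(model, preps, config) {
  n_edge_fun <- function(ut) nrow(ut$edge)
  defaults <- c(nni = 5, spr = 1, brlen = 10, pi1 = 2, alpha = 1, beta = 1,
                hyper_mean = 1, scaler = 1)
  w <- defaults
  if (!is.null(config$move_weights)) {
    w[names(config$move_weights)] <- config$move_weights
  }
  moves <- list()
  add <- function(name, weight, fn) {
    if (weight > 0) moves[[length(moves) + 1L]] <<- list(name = name, weight = weight, fn = fn)
  }
  lambda <- config$brlen_lambda
  add("nni", w[["nni"]], function(st) {
    pr <- utree_nni(st$ut)
    if (is.null(pr)) return(NULL)
    st$ut <- pr$tree; list(state = st, logh = pr$log_hastings, topology = TRUE)
  })
  add("spr", w[["spr"]], function(st) {
    pr <- utree_spr(st$ut)
    if (is.null(pr)) return(NULL)
    st$ut <- pr$tree; list(state = st, logh = pr$log_hastings, topology = TRUE)
  })
  add("brlen", w[["brlen"]], function(st) {
    e <- sample.int(nrow(st$ut$edge), 1L)
    f <- exp(lambda * (stats::runif(1L) - 0.5))
    st$ut$length[e] <- st$ut$length[e] * f
    list(state = st, logh = log(f))
  })
  for (i in seq_along(preps)) {
    local({
      ii <- i
      if (preps[[ii]]$type == "binary" && preps[[ii]]$sample_pi1) {
        add(paste0("pi1.", ii), w[["pi1"]], function(st) {
          x <- st$params[[ii]]$pi1 + stats::runif(1L, -0.15, 0.15)
          # reflect into (0,1)
          while (x <= 0 || x >= 1) x <- ifelse(x <= 0, -x, 2 - x)
          st$params[[ii]]$pi1 <- x
          list(state = st, logh = 0)
        })
      }
      sample_alpha <- (preps[[ii]]$type == "binary" && preps[[ii]]$gamma) ||
        (preps[[ii]]$type == "morph" && isTRUE(preps[[ii]]$sample_alpha))
      if (sample_alpha) {
        add(paste0("alpha.", ii), w[["alpha"]], function(st) {
          f <- exp(stats::runif(1L, -0.7, 0.7))
          st$params[[ii]]$alpha <- st$params[[ii]]$alpha * f
          list(state = st, logh = log(f))
        })
      }
      if (preps[[ii]]$type == "morph" && isTRUE(preps[[ii]]$sample_beta)) {
        add(paste0("beta.", ii), w[["beta"]], function(st) {
          f <- exp(stats::runif(1L, -0.7, 0.7))
          st$params[[ii]]$beta <- st$params[[ii]]$beta * f
          list(state = st, logh = log(f))
        })
      }
    })
  }
  if (model$bl_prior == "hierarchical") {
    add("hyper_mean", w[["hyper_mean"]], function(st) {
      f <- exp(stats::runif(1L, -0.7, 0.7))
      st$hyper_mean <- st$hyper_mean * f
      list(state = st, logh = log(f))
    })
  }
  if (length(preps) > 1L && model$sample_scalers) {
    for (i in 2L:length(preps)) {
      local({
        ii <- i
        add(paste0("scaler.", ii), w[["scaler"]], function(st) {
          f <- exp(stats::runif(1L, -0.7, 0.7))
          st$scalers[ii] <- st$scalers[ii] * f
          list(state = st, logh = log(f))
        })
      })
    }
  }
  moves
}

#' Run replicate MCMC chains
#'
#' Metropolis-Hastings sampling of tree topology (NNI and SPR moves),
#' branch lengths (single-branch multipliers) and model parameters
#' (sliders/scalers with the appropriate Hastings ratios). Starting trees
#' are random topologies with exponential branch lengths. Each replicate is
#' fully reproducible from `(seed, replicate index)`.
#'
#' @param model A [combined_model()] (or a single partition, which is
#'   wrapped).
#' @param config An [mcmc_config()].
#' @return A list of `gc_trace` objects, one per replicate.
#' @export
run_mcmc <- function(model, config) {
  if (inherits(model, "gc_partition")) model <- combined_model(model)
  stopifnot(inherits(model, "gc_model"), inherits(config, "gc_mcmc_config"))
  lapply(seq_len(config$replicates), function(r) {
    .run_chain(model, config, r)
  })
}

.run_chain <- function(model, config, replicate) {
  seed_r <- derive_seed(config$seed, paste0("replicate-", replicate))
  with_seed(seed_r, function() {
    taxa <- model$taxa
    start <- ape::rtopology(length(taxa), rooted = FALSE, tip.label = taxa)
    start$edge.length <- stats::rexp(nrow(start$edge), 1 / model$bl_prior_mean)
    ut <- as_utree(start)
    preps <- lapply(model$partitions, .prep_partition, tip_label = ut$tip_label)
    state <- list(
      ut = ut,
      params = lapply(seq_along(preps), function(i) {
        p <- preps[[i]]
        list(pi1 = p$init$pi1 %||% 0.5,
             alpha = p$init$alpha %||% 1,
             beta = p$init$beta %||% 1,
             alpha_sampled = (p$type == "binary" && isTRUE(p$gamma)) ||
               (p$type == "morph" && isTRUE(p$sample_alpha)),
             beta_sampled = p$type == "morph" && isTRUE(p$sample_beta))
      }),
      scalers = rep(1, length(preps)),
      hyper_mean = model$bl_prior_mean
    )
    loglik_fun <- if (config$likelihood) {
      function(st, trav) .model_loglik(preps, st$ut, st, trav)
    } else {
      function(st, trav) 0
    }
    cur_trav <- utree_traversal(state$ut)
    cur_ll <- loglik_fun(state, cur_trav)
    tries <- 0L
    while (!is.finite(cur_ll) && tries < 20L) {
      start <- ape::rtopology(length(taxa), rooted = FALSE, tip.label = taxa)
      start$edge.length <- stats::rexp(nrow(start$edge), 1 / model$bl_prior_mean)
      state$ut <- as_utree(start)
      cur_trav <- utree_traversal(state$ut)
      cur_ll <- loglik_fun(state, cur_trav)
      tries <- tries + 1L
    }
    if (!is.finite(cur_ll)) abort_gc("no finite-likelihood starting tree found", "bad_start")
    cur_lp <- .model_logprior(model, state$ut, state)

    moves <- .build_moves(model, preps, config)
    mw <- vapply(moves, `[[`, 1, "weight")
    mprob <- mw / sum(mw)
    mpg <- as.integer(config$moves_per_generation %||% max(1, round(sum(mw))))
    n_samples <- config$generations %/% config$sample_every
    trees <- character(n_samples)
    splits <- vector("list", n_samples)
    param_names <- c("iteration", "log_likelihood", "log_prior", "tree_length",
                     unlist(lapply(seq_along(preps), function(i) {
                       paste0(c("pi1", "alpha", "beta"), ".", i)
                     })), "hyper_mean",
                     paste0("scaler.", seq_along(preps)))
    stats_m <- matrix(NA_real_, n_samples, length(param_names),
                      dimnames = list(NULL, param_names))
    attempts <- accepts <- stats::setNames(numeric(length(moves)),
                                           vapply(moves, `[[`, "", "name"))
    si <- 0L
    for (gen in seq_len(config$generations)) {
      for (k in seq_len(mpg)) {
        mi <- sample.int(length(moves), 1L, prob = mprob)
        attempts[mi] <- attempts[mi] + 1
        prop <- moves[[mi]]$fn(state)
        if (is.null(prop)) next
        prop_trav <- if (isTRUE(prop$topology)) {
          utree_traversal(prop$state$ut)
        } else cur_trav
        new_ll <- loglik_fun(prop$state, prop_trav)
        if (is.finite(new_ll)) {
          new_lp <- .model_logprior(model, prop$state$ut, prop$state)
          logr <- (new_ll + new_lp) - (cur_ll + cur_lp) + prop$logh
          if (log(stats::runif(1L)) < logr) {
            state <- prop$state; cur_ll <- new_ll; cur_lp <- new_lp
            cur_trav <- prop_trav
            accepts[mi] <- accepts[mi] + 1
          }
        }
      }
      if (gen %% config$sample_every == 0L) {
        si <- si + 1L
        trees[si] <- utree_to_newick(state$ut)
        splits[[si]] <- utree_splits(state$ut)
        row <- c(gen, cur_ll, cur_lp, sum(state$ut$length),
                 unlist(lapply(state$params, function(p) c(p$pi1, p$alpha, p$beta))),
                 state$hyper_mean, state$scalers)
        stats_m[si, ] <- row
      }
    }
    structure(list(
      trees = trees[seq_len(si)],
      splits = splits[seq_len(si)],
      stats = tibble::as_tibble(as.data.frame(stats_m[seq_len(si), , drop = FALSE])),
      taxa = sort(taxa),
      seed = seed_r,
      replicate = replicate,
      config = config,
      acceptance = tibble::tibble(move = names(attempts), attempts = attempts,
                                  accepts = accepts,
                                  rate = ifelse(attempts > 0, accepts / attempts, NA))
    ), class = "gc_trace")
  })
}

#' @export
print.gc_trace <- function(x, ...) {
  cat(sprintf("MCMC trace: %d samples over %d taxa (replicate %d, seed %d)\n",
              length(x$trees), length(x$taxa), x$replicate, x$seed))
  invisible(x)
}

#' Tidy an MCMC trace
#'
#' @param x A `gc_trace`.
#' @param ... Unused.
#' @return The scalar parameter trace as a tibble (one row per sample).
#' @importFrom generics tidy
#' @export
tidy.gc_trace <- function(x, ...) x$stats

#' One-row summary of an MCMC trace
#'
#' @param x A `gc_trace`.
#' @param ... Unused.
#' @return Tibble with sample count, post-burn-in log-likelihood ESS and
#'   mean acceptance rate.
#' @importFrom generics glance
#' @export
glance.gc_trace <- function(x, ...) {
  b <- x$config$burn_in_fraction
  ll <- post_burn_in(x$stats$log_likelihood, b)
  tibble::tibble(
    n_samples = length(x$trees),
    burn_in_fraction = b,
    ess_log_likelihood = tryCatch(ess(ll), error = function(e) NA_real_),
    mean_acceptance = mean(x$acceptance$rate, na.rm = TRUE)
  )
}

post_burn_in <- function(x, burn_in_fraction) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  drop <- floor(n * burn_in_fraction)
  if (is.data.frame(x)) x[(drop + 1):n, , drop = FALSE] else x[(drop + 1):n]
}

#' Write / read tree samples as newick list files
#'
#' One tree per line, compatible with common `.t`/`.trees` conventions.
#'
#' @param trace A `gc_trace` (or character vector of newick strings).
#' @param path File path.
#' @return `path` invisibly; `read_tree_samples()` returns a character
#'   vector of newick strings.
#' @export
write_tree_samples <- function(trace, path) {
  trees <- if (inherits(trace, "gc_trace")) trace$trees else trace
  writeLines(trees, path)
  invisible(path)
}

#' @rdname write_tree_samples
#' @export
read_tree_samples <- function(path) {
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}

#' Autoplot method for MCMC traces
#'
#' Trace plots of the scalar parameters.
#'
#' @param object A `gc_trace`.
#' @param parameters Columns of the stats table to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_trace <- function(object, parameters = c("log_likelihood", "tree_length"), ...) {
  df <- object$stats[, c("iteration", intersect(parameters, names(object$stats)))]
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL)
}

# minimal long-format pivot (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  cols <- setdiff(names(df), "iteration")
  do.call(rbind, lapply(cols, function(cn) {
    data.frame(iteration = df$iteration, parameter = cn, value = df[[cn]])
  }))
}
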