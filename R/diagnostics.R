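# Convergence diagnostics: effective sample size on scalar traces and the
# across-run maximum bipartition frequency difference (maxdiff/bpdiff).
# Conventional thresholds: ESS > 300 and maxdiff < 0.3.

#' Effective sample size of a scalar trace
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence rule (consecutive pairs of
#' autocorrelations are summed until a pair turns non-positive).
#'
#' @param x Numeric trace (length >= 10, non-constant).
#' @return Effective sample size.
#' @export
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) abort_gc("trace too short for ESS (need >= 10)", "invalid_trace")
  if (stats::var(x) == 0) abort_gc("constant trace has no ESS", "invalid_trace")
  lag_max <- min(n - 1L, 2000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  s <- 0
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    pair <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (pair <= 0) break
    s <- s + pair
    m <- m + 1L
  }
  n / (1 + 2 * s)
}

#' Compare replicate runs by bipartition frequencies
#'
#' Computes per-run post-burn-in bipartition frequencies and their maximum
#' pairwise absolute difference over all bipartitions (the maxdiff/bpdiff
#' convergence statistic; < 0.3 is the conventional convergence threshold).
#'
#' @param traces List of `gc_trace` objects over the same taxon set (>= 2).
#' @param burn_in_fraction Fraction of each trace discarded (default: the
#'   first trace's configured value).
#' @return A list with `maxdiff` (scalar) and `frequencies` (tibble: one
#'   row per bipartition, one frequency column per run).
#' @export
compare_runs <- function(traces, burn_in_fraction = NULL) {
  if (inherits(traces, "gc_trace")) traces <- list(traces)
  if (length(traces) < 1L) abort_gc("need at least one trace", "invalid_trace")
  b <- burn_in_fraction %||% traces[[1L]]$config$burn_in_fraction
  taxa <- traces[[1L]]$taxa
  for (tr in traces) {
    if (!identical(tr$taxa, taxa)) abort_gc("traces have different taxon sets", "taxon_mismatch")
  }
  per_run <- lapply(traces, function(tr) {
    sp <- trace_split_list(tr)
    sp <- post_burn_in(sp, b)
    if (length(sp) == 0L) abort_gc("no post-burn-in samples", "empty_pool")
    tab <- table(unlist(sp))
    tab / length(sp)
  })
  all_splits <- sort(unique(unlist(lapply(per_run, names))))
  fm <- vapply(per_run, function(f) {
    out <- stats::setNames(numeric(length(all_splits)), all_splits)
    out[names(f)] <- as.numeric(f)
    out
  }, numeric(length(all_splits)))
  fm <- matrix(fm, nrow = length(all_splits),
               dimnames = list(all_splits, paste0("run", seq_along(per_run))))
  maxdiff <- if (length(all_splits) == 0L || length(traces) < 2L) 0 else {
    max(apply(fm, 1L, function(r) max(r) - min(r)))
  }
  freq_tbl <- tibble::as_tibble(cbind(
    tibble::tibble(split = all_splits),
    as.data.frame(fm, optional = TRUE)))
  list(maxdiff = maxdiff, frequencies = freq_tbl)
}

# splits per sample, computing from newick if the trace lacks cached splits
trace_split_list <- function(trace) {
  if (!is.null(trace$splits)) return(trace$splits)
  phys <- ape::read.tree(text = paste(trace$trees, collapse = "\n"))
  if (inherits(phys, "phylo")) phys <- list(phys)
  lapply(phys, function(p) utree_splits(as_utree(p)))
}
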