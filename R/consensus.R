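# Majority-rule consensus and the Total Posterior Consensus Tree (TPCT):
# pooling post-burn-in tree samples across runs (and datasets) that share a
# taxon set, then assembling the strictly-majority bipartitions.

#' Pooled bipartition frequencies
#'
#' Pools the post-burn-in samples of all traces (simple concatenation, so
#' traces are weighted by their sample counts) and counts each internal
#' bipartition once per sampled tree.
#'
#' @param traces A `gc_trace` or list of them, sharing one taxon set.
#' @param burn_in_fraction Fraction of each trace discarded (default: the
#'   first trace's configured value).
#' @return A tibble with columns `split` (taxon labels of the side not
#'   containing the reference taxon, `|`-separated), `count`, `frequency`;
#'   attributes `taxa` and `n_samples`.
#' @export
bipartition_frequencies <- function(traces, burn_in_fraction = NULL) {
  if (inherits(traces, "gc_trace")) traces <- list(traces)
  if (length(traces) == 0L) abort_gc("no traces", "invalid_trace")
  b <- burn_in_fraction %||% traces[[1L]]$config$burn_in_fraction
  taxa <- traces[[1L]]$taxa
  pooled <- list()
  total <- 0L
  for (tr in traces) {
    if (!identical(tr$taxa, taxa)) abort_gc("traces have different taxon sets", "taxon_mismatch")
    sp <- post_burn_in(trace_split_list(tr), b)
    total <- total + length(sp)
    pooled <- c(pooled, sp)
  }
  if (total == 0L) abort_gc("no post-burn-in samples", "empty_pool")
  tab <- sort(table(unlist(pooled)), decreasing = TRUE)
  out <- tibble::tibble(split = names(tab), count = as.integer(tab),
                        frequency = as.numeric(tab) / total)
  attr(out, "taxa") <- taxa
  attr(out, "n_samples") <- total
  out
}

#' Majority-rule consensus tree
#'
#' Assembles every bipartition with pooled frequency strictly greater than
#' 0.5 (such a set is always mutually compatible) into a tree; remaining
#' conflict is left as polytomies. Clade posterior probabilities equal the
#' pooled bipartition frequencies exactly.
#'
#' @param freqs A frequency table from [bipartition_frequencies()], or a
#'   trace / list of traces (passed through it).
#' @param burn_in_fraction Used when `freqs` is a trace list.
#' @return An object of class `gc_consensus`: the consensus `phylo` tree
#'   with PP node labels, the full split table, and provenance.
#' @export
majority_consensus <- function(freqs, burn_in_fraction = NULL) {
  if (!is.data.frame(freqs)) {
    freqs <- bipartition_frequencies(freqs, burn_in_fraction)
  }
  taxa <- attr(freqs, "taxa")
  if (is.null(taxa)) abort_gc("frequency table lacks its taxon set", "invalid_freqs")
  kept <- freqs[freqs$frequency > 0.5, , drop = FALSE]
  tree <- .build_consensus_tree(kept$split, kept$frequency, taxa)
  structure(list(tree = tree, splits = freqs, taxa = taxa,
                 n_samples = attr(freqs, "n_samples"),
                 provenance = list()),
            class = "gc_consensus")
}

# Assemble compatible ref-excluded splits (all frequency > 0.5) into a
# phylo tree with PP node labels via the containment hierarchy.
.build_consensus_tree <- function(splits, freqs, taxa) {
  ref <- sort(taxa)[1L]
  sets <- lapply(strsplit(splits, "|", fixed = TRUE), sort)
  if (length(sets) > 1L) {
    for (i in seq_along(sets)) {
      for (j in seq_len(i - 1L)) {
        a <- sets[[i]]; b <- sets[[j]]
        inter <- length(intersect(a, b))
        if (inter > 0L && inter < min(length(a), length(b))) {
          stop("internal error: incompatible majority splits")  # nocov
        }
      }
    }
  }
  ord <- order(vapply(sets, length, 1L), decreasing = TRUE)
  sets <- sets[ord]; pp <- freqs[ord]
  fmt_pp <- function(p) formatC(p, digits = 6L, format = "g")
  # recursive assembly: node over `members`, with available splits `idx`
  build <- function(members, idx) {
    idx <- idx[vapply(idx, function(i) all(sets[[i]] %in% members), TRUE)]
    maximal <- idx[!vapply(idx, function(i) {
      any(vapply(idx, function(j) {
        j != i && length(sets[[i]]) < length(sets[[j]]) && all(sets[[i]] %in% sets[[j]])
      }, TRUE))
    }, TRUE)]
    parts <- character(0)
    covered <- character(0)
    for (i in maximal) {
      inner <- setdiff(idx, i)
      sub <- build(sets[[i]], inner[vapply(inner, function(j) {
        all(sets[[j]] %in% sets[[i]])
      }, TRUE)])
      parts <- c(parts, paste0(sub, fmt_pp(pp[i])))
      covered <- c(covered, sets[[i]])
    }
    loose <- setdiff(members, covered)
    parts <- c(parts, loose)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nonref <- setdiff(sort(taxa), ref)
  top <- build(nonref, seq_along(sets))
  # attach the reference taxon at the (unrooted) base
  inner <- substr(top, 2L, nchar(top) - 1L)
  newick <- paste0("(", ref, ",", inner, ");")
  ape::read.tree(text = newick)
}

#' @export
print.gc_consensus <- function(x, ...) {
  nint <- x$tree$Nnode
  cat(sprintf("Majority-rule consensus: %d taxa, %d internal node(s), %s pooled samples\n",
              length(x$taxa), nint, format(x$n_samples %||% NA)))
  res <- sum(x$splits$frequency > 0.5)
  cat(sprintf("  %d/%d bipartitions above 0.5\n", res, length(x$taxa) - 3L))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.gc_consensus <- function(x, ...) x$splits

#' @importFrom generics glance
#' @export
glance.gc_consensus <- function(x, ...) {
  kept <- x$splits$frequency > 0.5
  tibble::tibble(n_taxa = length(x$taxa),
                 n_splits_majority = sum(kept),
                 n_splits_possible = length(x$taxa) - 3L,
                 min_pp = if (any(kept)) min(x$splits$frequency[kept]) else NA_real_,
                 n_samples = x$n_samples %||% NA_integer_)
}

#' Plot a consensus tree
#'
#' @param x A `gc_consensus`.
#' @param show_pp Show posterior probabilities as node labels.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.gc_consensus <- function(x, show_pp = TRUE, ...) {
  ape::plot.phylo(x$tree, ...)
  if (show_pp && !is.null(x$tree$node.label)) {
    ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.1, -0.3), cex = 0.7)
  }
  invisible(x)
}

#' Total Posterior Consensus Trees
#'
#' For each group of traces sharing a taxon set (e.g. all converged runs of
#' all dataset variants with the same taxon sampling), pools every
#' post-burn-in sample regardless of dataset parameters and returns the
#' majority-rule consensus of the pool. Pooling weights traces by their
#' sample counts (plain concatenation); pass equally thinned traces for an
#' equal-weight-per-dataset summary.
#'
#' @param grouped_traces Named list: taxon-set group -> list of `gc_trace`.
#' @param burn_in_fraction Fraction of each trace discarded.
#' @return Named list of `gc_consensus` objects, one per group, each with
#'   per-trace sample counts in `provenance`.
#' @export
tpct <- function(grouped_traces, burn_in_fraction = NULL) {
  stopifnot(is.list(grouped_traces), length(grouped_traces) > 0L)
  out <- lapply(grouped_traces, function(traces) {
    if (inherits(traces, "gc_trace")) traces <- list(traces)
    if (length(traces) == 0L) abort_gc("empty trace group", "empty_pool")
    cons <- majority_consensus(traces, burn_in_fraction)
    b <- burn_in_fraction %||% traces[[1L]]$config$burn_in_fraction
    cons$provenance$trace_samples <- vapply(traces, function(tr) {
      length(post_burn_in(tr$trees, b))
    }, 1L)
    cons
  })
  out
}

#' Root a tree on an outgroup
#'
#' Places the root on the branch separating the outgroup (taxon or clade)
#' from the remaining taxa; node labels (posterior probabilities) are
#' preserved.
#'
#' @param tree A `phylo` tree or `gc_consensus`.
#' @param outgroup Taxon label or vector of labels forming the outgroup
#'   clade.
#' @return A rooted `phylo` tree.
#' @export
root_tree <- function(tree, outgroup) {
  phy <- if (inherits(tree, "gc_consensus")) tree$tree else tree
  stopifnot(inherits(phy, "phylo"))
  missing <- setdiff(outgroup, phy$tip.label)
  if (length(missing)) {
    abort_gc(paste0("outgroup taxa absent from tree: ",
                    paste(missing, collapse = ", ")), "invalid_outgroup")
  }
  if (length(outgroup) > 1L) {
    if (!ape::is.monophyletic(phy, outgroup)) {
      abort_gc("outgroup is not monophyletic on this tree", "invalid_outgroup")
    }
  }
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
}
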