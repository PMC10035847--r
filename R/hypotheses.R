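# Posterior-odds tests of competing topological hypotheses: classify each
# posterior tree sample against rooted constraints (monophyly, sister
# group, paraphyly), estimate the posterior fraction satisfying each
# hypothesis, and report the log posterior odds with the conventional
# support categories (lnPO > 1 substantial, > 3 strong, > 5 very strong,
# assuming equal prior odds).

#' Topological constraint hypothesis
#'
#' @param name Short hypothesis label.
#' @param kind `"monophyly"` (group 1 forms a clade), `"sister_group"`
#'   (groups 1 and 2 are adjacent clades whose union is a clade), or
#'   `"paraphyly"` (group 1 is not a clade; when group 2 is given, the
#'   union of the two must be a clade, i.e. group 1 is a grade subtending
#'   group 2).
#' @param groups List of 1 or 2 disjoint, non-empty taxon vectors.
#' @param outgroup Taxon (or clade) used to root each tree before
#'   evaluation.
#' @return An object of class `gc_hypothesis`.
#' @export
constraint_hypothesis <- function(name, kind = c("monophyly", "sister_group", "paraphyly"),
                                  groups, outgroup) {
  kind <- match.arg(kind)
  if (!is.list(groups)) groups <- list(groups)
  if (length(groups) < 1L || any(lengths(groups) == 0L)) {
    abort_gc("groups must be non-empty taxon vectors", "invalid_hypothesis")
  }
  if (kind == "sister_group" && length(groups) != 2L) {
    abort_gc("sister_group needs exactly two groups", "invalid_hypothesis")
  }
  if (length(groups) == 2L && length(intersect(groups[[1L]], groups[[2L]]))) {
    abort_gc("groups must be disjoint", "invalid_hypothesis")
  }
  if (length(intersect(unlist(groups), outgroup))) {
    abort_gc("outgroup must be disjoint from the constraint groups", "invalid_hypothesis")
  }
  structure(list(name = name, kind = kind,
                 groups = lapply(groups, as.character),
                 outgroup = as.character(outgroup)),
            class = "gc_hypothesis")
}

#' @export
print.gc_hypothesis <- function(x, ...) {
  cat(sprintf("Hypothesis '%s': %s of {%s}%s, rooted on %s\n", x$name, x$kind,
              paste(x$groups[[1L]], collapse = ","),
              if (length(x$groups) > 1L) {
                paste0(" / {", paste(x$groups[[2L]], collapse = ","), "}")
              } else "",
              paste(x$outgroup, collapse = ",")), ...)
  invisible(x)
}

# clade test on a rooted phylo: does `group` label exactly the tip set of
# some node (or a single tip)?
.is_clade <- function(phy, group, clades = NULL) {
  group <- sort(group)
  if (length(group) == 1L) return(group %in% phy$tip.label)
  clades <- clades %||% .rooted_clades(phy)
  any(vapply(clades, identical, TRUE, y = group))
}

.rooted_clades <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  lapply(pp, function(idx) sort(labs[idx]))
}

#' Classify one tree against a hypothesis
#'
#' The tree is rooted on the hypothesis's outgroup, then tested:
#' monophyly — the group is a clade; sister group — both groups and their
#' union are clades; paraphyly — the group is not a clade (and, when a
#' second group is given, their union is a clade).
#'
#' @param tree A `phylo` tree (rooted or not) or newick string.
#' @param hypothesis A [constraint_hypothesis()].
#' @return Logical.
#' @export
classify_tree <- function(tree, hypothesis) {
  stopifnot(inherits(hypothesis, "gc_hypothesis"))
  phy <- if (is.character(tree)) ape::read.tree(text = tree) else tree
  needed <- unique(c(unlist(hypothesis$groups), hypothesis$outgroup))
  missing <- setdiff(needed, phy$tip.label)
  if (length(missing)) {
    abort_gc(paste0("tree lacks constraint taxa: ", paste(missing, collapse = ", ")),
             "invalid_hypothesis")
  }
  phy <- tryCatch(root_tree(phy, hypothesis$outgroup),
                  gcphylo_error = function(e) NULL)
  if (is.null(phy)) return(FALSE)  # outgroup clade not recoverable: no match
  clades <- .rooted_clades(phy)
  g1 <- hypothesis$groups[[1L]]
  g2 <- if (length(hypothesis$groups) > 1L) hypothesis$groups[[2L]] else NULL
  switch(hypothesis$kind,
    monophyly = .is_clade(phy, g1, clades),
    sister_group = .is_clade(phy, g1, clades) && .is_clade(phy, g2, clades) &&
      .is_clade(phy, c(g1, g2), clades),
    paraphyly = {
      ok <- !.is_clade(phy, g1, clades)
      if (!is.null(g2)) ok <- ok && .is_clade(phy, c(g1, g2), clades)
      ok
    })
}

#' Posterior odds between two topological hypotheses
#'
#' Pools the post-burn-in tree samples of the traces, classifies each
#' against H0 and H1, and reports the posterior fractions `p0`, `p1` (trees
#' matching neither count toward neither), the posterior odds
#' `PO = p0 / p1`, the natural-log odds, and the support category on the
#' thresholds lnPO > 1 (substantial), > 3 (strong), > 5 (very strong);
#' equal prior odds are assumed. When one count is zero the odds are
#' infinite and a continuity-corrected bound `ln((count + 0.5) / 0.5)` is
#' reported alongside.
#'
#' @param traces A `gc_trace` or list of them.
#' @param h0,h1 [constraint_hypothesis()] objects (the null and the
#'   alternative).
#' @param burn_in_fraction Fraction of each trace discarded.
#' @return An object of class `gc_hyptest`.
#' @export
posterior_odds <- function(traces, h0, h1, burn_in_fraction = NULL) {
  if (inherits(traces, "gc_trace")) traces <- list(traces)
  if (length(traces) == 0L) abort_gc("no traces", "invalid_trace")
  b <- burn_in_fraction %||% traces[[1L]]$config$burn_in_fraction
  taxa <- traces[[1L]]$taxa
  has_splits <- all(vapply(traces, function(tr) !is.null(tr$splits), TRUE))
  if (has_splits) {
    pooled <- unlist(lapply(traces, function(tr) post_burn_in(tr$splits, b)),
                     recursive = FALSE)
    if (length(pooled) == 0L) abort_gc("no post-burn-in samples", "empty_pool")
    m0 <- vapply(pooled, .classify_from_splits, TRUE, hypothesis = h0, taxa = taxa)
    m1 <- vapply(pooled, .classify_from_splits, TRUE, hypothesis = h1, taxa = taxa)
    n <- length(pooled)
  } else {
    trees <- unlist(lapply(traces, function(tr) post_burn_in(tr$trees, b)))
    if (length(trees) == 0L) abort_gc("no post-burn-in samples", "empty_pool")
    phys <- ape::read.tree(text = paste(trees, collapse = "\n"))
    if (inherits(phys, "phylo")) phys <- list(phys)
    m0 <- vapply(phys, classify_tree, TRUE, hypothesis = h0)
    m1 <- vapply(phys, classify_tree, TRUE, hypothesis = h1)
    n <- length(phys)
  }
  n0 <- sum(m0); n1 <- sum(m1)
  p0 <- n0 / n; p1 <- n1 / n
  po <- if (n1 == 0L) Inf else p0 / p1
  lnpo <- log(po)
  lnpo_bound <- log((n0 + 0.5) / (n1 + 0.5))
  category <- ln_po_category(lnpo)
  structure(list(h0 = h0, h1 = h1, n = n, n0 = n0, n1 = n1,
                 p0 = p0, p1 = p1, unclassified = 1 - (n0 + n1) / n,
                 p0_renormalized = if (n0 + n1 > 0) n0 / (n0 + n1) else NA_real_,
                 posterior_odds = po, ln_posterior_odds = lnpo,
                 ln_posterior_odds_bound = lnpo_bound,
                 category = category, burn_in_fraction = b),
            class = "gc_hyptest")
}

# Split-set equivalent of classify_tree: a group G (disjoint from the
# outgroup) is a rooted clade iff the unrooted tree has the bipartition
# {G | rest} (trivial for |G| = 1 or G = whole ingroup). Agreement with
# classify_tree is covered by a property test.
.classify_from_splits <- function(splits, hypothesis, taxa) {
  og <- hypothesis$outgroup
  is_clade <- function(group) {
    group <- sort(unique(group))
    if (length(group) == 1L) return(group %in% taxa)
    if (setequal(group, setdiff(taxa, og))) return(TRUE)   # whole ingroup
    if (setequal(group, taxa)) return(TRUE)
    .split_key(group, taxa) %in% splits
  }
  if (length(og) > 1L && !is_clade(og)) return(FALSE)  # cannot root as declared
  g1 <- hypothesis$groups[[1L]]
  g2 <- if (length(hypothesis$groups) > 1L) hypothesis$groups[[2L]] else NULL
  switch(hypothesis$kind,
    monophyly = is_clade(g1),
    sister_group = is_clade(g1) && is_clade(g2) && is_clade(c(g1, g2)),
    paraphyly = {
      ok <- !is_clade(g1)
      if (!is.null(g2)) ok <- ok && is_clade(c(g1, g2))
      ok
    })
}

.split_key <- function(group, taxa) {
  ref <- sort(taxa)[1L]
  side <- if (ref %in% group) setdiff(taxa, group) else group
  paste(sort(side), collapse = "|")
}

#' Support category from log posterior odds
#'
#' @param lnpo Natural-log posterior odds of H0 over H1.
#' @return `"indecisive"`, `"substantial"`, `"strong"` or `"very_strong"`.
#' @export
ln_po_category <- function(lnpo) {
  if (is.na(lnpo)) return(NA_character_)
  if (lnpo > 5) "very_strong" else if (lnpo > 3) "strong" else if (lnpo > 1) "substantial" else "indecisive"
}

#' @export
print.gc_hyptest <- function(x, ...) {
  cat(sprintf("Posterior odds: '%s' (H0) vs '%s' (H1) on %d samples\n",
              x$h0$name, x$h1$name, x$n))
  cat(sprintf("  p0 = %.4f, p1 = %.4f, unclassified = %.4f\n", x$p0, x$p1, x$unclassified))
  cat(sprintf("  PO = %s, lnPO = %s (%s)\n", format(x$posterior_odds),
              format(x$ln_posterior_odds), x$category))
  if (!is.finite(x$ln_posterior_odds)) {
    cat(sprintf("  continuity-corrected bound: lnPO >= %.3f\n", x$ln_posterior_odds_bound))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.gc_hyptest <- function(x, ...) {
  tibble::tibble(h0 = x$h0$name, h1 = x$h1$name, n = x$n,
                 p0 = x$p0, p1 = x$p1, unclassified = x$unclassified,
                 posterior_odds = x$posterior_odds,
                 ln_posterior_odds = x$ln_posterior_odds,
                 ln_posterior_odds_bound = x$ln_posterior_odds_bound,
                 category = x$category)
}

#' Read hypothesis definitions from a structured-text file
#'
#' YAML with a top-level `hypotheses` list; each entry has `name`, `kind`,
#' `groups` (list of taxon lists) and `outgroup`.
#'
#' @param path File path.
#' @return List of [constraint_hypothesis()] objects, named.
#' @export
read_hypotheses <- function(path) {
  y <- yaml::read_yaml(path)
  hyps <- y$hypotheses %||% y
  out <- lapply(hyps, function(h) {
    constraint_hypothesis(h$name, h$kind, h$groups, h$outgroup)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Write a hypothesis-test report
#'
#' Tab-separated table with one row per test (hypothesis pair, posterior
#' fractions, log odds, category).
#'
#' @param results A `gc_hyptest` or list of them.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_hypothesis_report <- function(results, path) {
  if (inherits(results, "gc_hyptest")) results <- list(results)
  tbl <- dplyr::bind_rows(lapply(results, tidy))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
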