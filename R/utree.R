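# Internal unrooted-tree representation used by the MCMC kernel.
#
# A `utree` is a plain edge list over node ids: tips 1..n_tip (carrying
# labels), internal nodes n_tip+1 .. 2*n_tip-2.  A binary unrooted tree has
# 2N-3 edges and N-2 internal nodes of degree 3.  Edge rows are unordered
# pairs; orientation is imposed per traversal.  This avoids repeatedly
# re-rooting ape's rooted edge matrix during topology moves.

utree <- function(edge, length, tip_label) {
  structure(list(edge = edge, length = length, tip_label = tip_label,
                 n_tip = length(tip_label), n_node = max(edge)),
            class = "utree")
}

#' @export
print.utree <- function(x, ...) {
  cat("Unrooted tree:", x$n_tip, "tips,", nrow(x$edge), "edges\n")
  invisible(x)
}

as_utree <- function(phy) {
  if (inherits(phy, "utree")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::unroot(phy)
  len <- phy$edge.length
  if (is.null(len)) len <- rep(0, nrow(phy$edge))
  utree(phy$edge, len, phy$tip.label)
}

utree_n_nodes <- function(ut) ut$n_node %||% (2L * ut$n_tip - 2L)

# adjacency: list over nodes; each element matrix with columns (neighbor, edge id)
utree_adjacency <- function(ut) {
  n <- utree_n_nodes(ut)
  e <- ut$edge
  node <- c(e[, 1L], e[, 2L])
  nbr <- c(e[, 2L], e[, 1L])
  eid <- rep.int(seq_len(nrow(e)), 2L)
  o <- order(node)
  cnt <- tabulate(node, n)
  ends <- cumsum(cnt)
  starts <- ends - cnt + 1L
  nb <- vector("list", n)
  for (v in seq_len(n)) {
    if (cnt[v] == 0L) next
    idx <- o[starts[v]:ends[v]]
    nb[[v]] <- cbind(nbr[idx], eid[idx])
  }
  nb
}

# Postorder traversal from `root` (an internal node).  Returns a list with
# `order` (node ids, children before parents), `parent` and `pedge`
# (parent node / connecting edge id per node; 0 for root).
utree_traversal <- function(ut, root = ut$n_tip + 1L) {
  nb <- utree_adjacency(ut)
  n <- utree_n_nodes(ut)
  parent <- integer(n); pedge <- integer(n)
  order_ <- integer(n)
  stack <- integer(n); stack[1L] <- root
  sp <- 1L; oi <- n
  seen <- logical(n); seen[root] <- TRUE
  # iterative DFS; fill order_ back-to-front to get a valid postorder
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    order_[oi] <- v; oi <- oi - 1L
    m <- nb[[v]]
    for (j in seq_len(nrow(m))) {
      w <- m[j, 1L]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v; pedge[w] <- m[j, 2L]
        sp <- sp + 1L; stack[sp] <- w
      }
    }
  }
  children <- vector("list", n)
  for (v in order_) {
    p <- parent[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }
  list(order = order_, parent = parent, pedge = pedge, root = root,
       adj = nb, children = children)
}

# Newick serialisation (used for trace storage); deterministic formatting.
utree_to_newick <- function(ut, digits = 8L) {
  tr <- utree_traversal(ut)
  nb <- tr$adj
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  build <- function(v, from) {
    m <- nb[[v]]
    kids <- m[m[, 1L] != from, , drop = FALSE]
    if (nrow(kids) == 0L) return(ut$tip_label[v])
    parts <- character(nrow(kids))
    for (j in seq_len(nrow(kids))) {
      w <- kids[j, 1L]
      parts[j] <- paste0(build(w, v), ":", fmt(ut$length[kids[j, 2L]]))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(tr$root, 0L), ";")
}

utree_to_phylo <- function(ut) {
  ape::read.tree(text = utree_to_newick(ut))
}

# ---- Topology moves -------------------------------------------------------

utree_internal_edges <- function(ut) {
  which(ut$edge[, 1L] > ut$n_tip & ut$edge[, 2L] > ut$n_tip)
}

# Nearest-neighbour interchange on a uniformly chosen internal edge; the two
# alternative topologies are proposed with equal probability (symmetric move).
utree_nni <- function(ut) {
  ie <- utree_internal_edges(ut)
  if (length(ie) == 0L) return(list(tree = ut, log_hastings = 0))
  i <- ie[sample.int(length(ie), 1L)]
  u <- ut$edge[i, 1L]; v <- ut$edge[i, 2L]
  eu <- which((ut$edge[, 1L] == u | ut$edge[, 2L] == u) & seq_len(nrow(ut$edge)) != i)
  ev <- which((ut$edge[, 1L] == v | ut$edge[, 2L] == v) & seq_len(nrow(ut$edge)) != i)
  ea <- eu[sample.int(2L, 1L)]  # edge carrying subtree a, attached at u
  ec <- ev[sample.int(2L, 1L)]  # edge carrying subtree c, attached at v
  e <- ut$edge
  # reattach: a's edge endpoint u -> v; c's edge endpoint v -> u
  e[ea, ][e[ea, ] == u] <- v
  e[ec, ][e[ec, ] == v] <- u
  ut$edge <- e
  list(tree = ut, log_hastings = 0)
}

# Subtree prune and regraft.  A (edge, orientation) pair with an internal
# attachment node is drawn uniformly; the pruned subtree is reattached at a
# uniform position on a uniformly chosen remaining edge.  The number of valid
# prune pairs (3N-6) and of regraft edges depends only on the pruned subtree
# size, so the Hastings ratio reduces to len(target)/len(merged).
utree_spr <- function(ut) {
  ne <- nrow(ut$edge)
  repeat {
    i <- sample.int(ne, 1L)
    flip <- sample.int(2L, 1L) == 1L
    a <- if (flip) ut$edge[i, 1L] else ut$edge[i, 2L]  # attachment node
    b <- if (flip) ut$edge[i, 2L] else ut$edge[i, 1L]  # root of pruned subtree
    if (a > ut$n_tip) break
  }
  # component of b with edge i removed
  nb <- utree_adjacency(ut)
  n <- utree_n_nodes(ut)
  inS <- logical(n); inS[b] <- TRUE
  stack <- b
  sub_edges <- logical(ne); sub_edges[i] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    m <- nb[[v]]
    for (j in seq_len(nrow(m))) {
      eid <- m[j, 2L]
      if (eid == i || sub_edges[eid]) next
      sub_edges[eid] <- TRUE
      w <- m[j, 1L]
      if (!inS[w]) { inS[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  m <- nb[[a]]
  rest <- m[m[, 1L] != b, , drop = FALSE]  # the two edges to merge
  ex <- rest[1L, 2L]; ey <- rest[2L, 2L]
  x <- rest[1L, 1L]; y <- rest[2L, 1L]
  merged_len <- ut$length[ex] + ut$length[ey]
  candidates <- which(!sub_edges & seq_len(ne) != ex & seq_len(ne) != ey)
  if (length(candidates) == 0L) return(NULL)  # no regraft position: reject
  f <- candidates[sample.int(length(candidates), 1L)]
  p <- ut$edge[f, 1L]; q <- ut$edge[f, 2L]
  flen <- ut$length[f]
  upos <- stats::runif(1L)
  # merge x--a--y into x--y (row ex); reuse row ey for the new half of f
  e <- ut$edge; len <- ut$length
  e[ex, ] <- c(x, y);       len[ex] <- merged_len
  e[f, ]  <- c(p, a);       len[f]  <- upos * flen
  e[ey, ] <- c(a, q);       len[ey] <- (1 - upos) * flen
  ut$edge <- e; ut$length <- len
  list(tree = ut, log_hastings = log(flen) - log(merged_len))
}

# Unordered label-set bipartitions induced by internal edges; each split is
# keyed by the lexicographically sorted tips of the side *not* containing
# the reference taxon (alphabetically first label), so complements collapse
# to one key and keys are comparable across trees.
utree_splits <- function(ut) {
  ie <- utree_internal_edges(ut)
  if (length(ie) == 0L) return(character(0))
  ref <- which(ut$tip_label == min(ut$tip_label))[1L]
  nb <- utree_adjacency(ut)
  n <- utree_n_nodes(ut)
  out <- character(length(ie))
  for (k in seq_along(ie)) {
    i <- ie[k]
    b <- ut$edge[i, 2L]
    inS <- logical(n); inS[b] <- TRUE
    stack <- b
    while (length(stack) > 0L) {
      v <- stack[[1L]]; stack <- stack[-1L]
      m <- nb[[v]]
      for (j in seq_len(nrow(m))) {
        if (m[j, 2L] == i) next
        w <- m[j, 1L]
        if (!inS[w]) { inS[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    tips <- which(inS[seq_len(ut$n_tip)])
    if (ref %in% tips) tips <- setdiff(seq_len(ut$n_tip), tips)
    out[k] <- paste(sort(ut$tip_label[tips]), collapse = "|")
  }
  out
}
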