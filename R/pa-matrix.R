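#' Presence/absence matrix
#'
#' Container for a taxa-by-characters binary matrix, as produced by coding a
#' gene-family clustering at the homogroup or orthogroup level, or by
#' simulation. Carries the coding level, the observability window applied to
#' it (if any), and free-form provenance (dataset name, grid parameters).
#'
#' @param data Integer or logical matrix, taxa in rows (rownames required),
#'   characters in columns; entries 0/1 (NA allowed for missing).
#' @param level `"homogroup"`, `"orthogroup"` or `"simulated"`.
#' @param window Integer pair `c(m_min, m_max)` recording the filter already
#'   applied, or `NULL` for an unfiltered matrix.
#' @param provenance Named list of free-form metadata.
#' @return An object of class `gc_pamatrix`.
#' @export
pa_matrix <- function(data, level = c("simulated", "homogroup", "orthogroup"),
                      window = NULL, provenance = list()) {
  level <- match.arg(level)
  data <- as.matrix(data)
  if (is.logical(data)) data <- data + 0L
  storage.mode(data) <- "integer"
  if (is.null(rownames(data))) abort_gc("taxa must be named (rownames)", "invalid_matrix")
  if (anyDuplicated(rownames(data))) abort_gc("duplicate taxon labels", "invalid_matrix")
  bad <- !(data %in% c(0L, 1L, NA))
  if (any(bad)) abort_gc("matrix entries must be 0, 1 or NA", "invalid_matrix")
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("c%0*d", nchar(ncol(data)), seq_len(ncol(data)))
  }
  structure(list(data = data, level = level, window = window,
                 provenance = provenance),
            class = "gc_pamatrix")
}

#' @export
print.gc_pamatrix <- function(x, ...) {
  cat(sprintf("Presence/absence matrix: %d taxa x %d characters (%s level)\n",
              nrow(x$data), ncol(x$data), x$level))
  if (!is.null(x$window)) {
    cat(sprintf("  observability window: [%d, %d]\n", x$window[1], x$window[2]))
  }
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L, x$provenance)
  if (length(scalars)) {
    cat("  provenance:", paste(names(scalars), unlist(lapply(scalars, format)),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.gc_pamatrix <- function(x) dim(x$data)

pa_taxa <- function(x) rownames(x$data)

#' Tidy a presence/absence matrix into long form
#'
#' @param x A [pa_matrix()] object.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `character`, `state`.
#' @importFrom generics tidy
#' @export
tidy.gc_pamatrix <- function(x, ...) {
  tibble::tibble(
    taxon = rep(rownames(x$data), times = ncol(x$data)),
    character = rep(colnames(x$data), each = nrow(x$data)),
    state = as.integer(x$data)
  )
}

#' Default observability window for N taxa
#'
#' Characters must be present in at least two and at most all-but-two taxa;
#' this is the singleton/near-constant filter the likelihood conditions on.
#'
#' @param n_taxa Number of taxa N.
#' @return Integer pair `c(2, N - 2)`.
#' @export
default_window <- function(n_taxa) c(2L, as.integer(n_taxa) - 2L)

#' Filter characters to the observability window
#'
#' Keeps exactly the characters whose number of presences (1s) lies in
#' `[m_min, m_max]`, preserving column order, and records the window on the
#' result. Missing entries do not count as presences.
#'
#' @param x A [pa_matrix()] object.
#' @param m_min,m_max Window bounds; default `[2, N - 2]`.
#' @return A filtered `gc_pamatrix`; if no character survives, the result is
#'   additionally of class `gc_empty_matrix` and a warning is raised.
#' @export
apply_observability_filter <- function(x, m_min = 2L, m_max = nrow(x$data) - 2L) {
  stopifnot(inherits(x, "gc_pamatrix"))
  n <- nrow(x$data)
  m_min <- as.integer(m_min); m_max <- as.integer(m_max)
  if (m_min < 0L || m_min > m_max || m_max > n) {
    abort_gc("invalid window: need 0 <= m_min <= m_max <= N", "invalid_window")
  }
  counts <- colSums(x$data == 1L, na.rm = TRUE)
  keep <- counts >= m_min & counts <= m_max
  out <- x
  out$data <- x$data[, keep, drop = FALSE]
  out$window <- c(m_min, m_max)
  if (!any(keep)) {
    warning("observability filter removed every character", call. = FALSE)
    class(out) <- c("gc_empty_matrix", class(out))
  }
  out
}

#' Prune taxa from a matrix and re-apply the observability filter
#'
#' Removes the given taxa, then re-runs [apply_observability_filter()] with
#' the window recomputed for the reduced taxon count (the "pruning" strategy;
#' characters that become singletons or near-constant — orphans — are
#' dropped).
#'
#' @param x A [pa_matrix()] object.
#' @param remove Character vector of taxon labels to delete.
#' @return A pruned, re-filtered `gc_pamatrix`.
#' @export
prune_taxa <- function(x, remove) {
  stopifnot(inherits(x, "gc_pamatrix"))
  remove <- as.character(remove)
  if (length(remove) == 0L) return(x)
  unknown <- setdiff(remove, pa_taxa(x))
  if (length(unknown)) {
    abort_gc(paste0("unknown taxa: ", paste(unknown, collapse = ", ")), "invalid_taxa")
  }
  keep <- setdiff(pa_taxa(x), remove)
  if (length(keep) < 4L) abort_gc("pruning must leave at least 4 taxa", "invalid_taxa")
  out <- x
  out$data <- x$data[keep, , drop = FALSE]
  out$provenance$pruned <- c(out$provenance$pruned, remove)
  apply_observability_filter(out, 2L, length(keep) - 2L)
}

# ---- Readers / writers ----------------------------------------------------

#' Read and write presence/absence matrices
#'
#' Supported formats: tab-separated (taxa in rows, labelled character
#' columns), relaxed PHYLIP with 0/1 symbols, and NEXUS `datatype=standard`.
#' A round-trip through any format preserves taxa, states and (for TSV)
#' column labels.
#'
#' @param x A [pa_matrix()] object.
#' @param path File path.
#' @param format `"tsv"`, `"phylip"` or `"nexus"`.
#' @param ... Passed to [pa_matrix()] on read (level, provenance).
#' @return `write_pa_matrix()` returns `path` invisibly; `read_pa_matrix()`
#'   returns a `gc_pamatrix`.
#' @export
write_pa_matrix <- function(x, path, format = c("tsv", "phylip", "nexus")) {
  stopifnot(inherits(x, "gc_pamatrix"))
  format <- match.arg(format)
  m <- x$data
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "phylip") {
    ch <- apply(m, 1L, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
    lines <- c(paste(nrow(m), ncol(m)),
               paste(rownames(m), ch, sep = "  "))
    writeLines(lines, path)
  } else {
    dat <- lapply(seq_len(nrow(m)), function(i) {
      ifelse(is.na(m[i, ]), "?", as.character(m[i, ]))
    })
    names(dat) <- rownames(m)
    ape::write.nexus.data(dat, path, format = "standard", interleaved = FALSE)
  }
  invisible(path)
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path, format = c("tsv", "phylip", "nexus"), ...) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m[m == "?"] <- NA
    storage.mode(m) <- "integer"
  } else if (format == "phylip") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    taxa <- vapply(rows, `[[`, "", 1L)
    seqs <- vapply(rows, function(r) paste(r[-1L], collapse = ""), "")
    m <- t(vapply(strsplit(seqs, ""), function(s) {
      as.integer(ifelse(s == "?", NA, s))
    }, integer(hdr[2L])))
    rownames(m) <- taxa
  } else {
    dat <- ape::read.nexus.data(path)
    m <- t(vapply(dat, function(s) as.integer(ifelse(s == "?", NA, s)),
                  integer(length(dat[[1L]]))))
  }
  pa_matrix(m, ...)
}
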