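#' Morphological character matrix
#'
#' Taxa-by-characters matrix of multistate characters coded `0..k-1`, with
#' `?` for missing and `-` for inapplicable cells. The per-character state
#' count k is the maximum observed state index plus one, over the whole
#' column. A `coding_scheme` tag records whether characters were coded
#' non-additively or reductively; in the likelihood both `?` and `-` are
#' treated as fully ambiguous.
#'
#' @param data Character matrix (taxa in rows, rownames required) over the
#'   alphabet `0-9`, `?`, `-`.
#' @param coding_scheme `"non_additive"` or `"reductive"`.
#' @param provenance Named list of metadata.
#' @return An object of class `gc_morphmatrix`.
#' @export
morph_matrix <- function(data, coding_scheme = c("non_additive", "reductive"),
                         provenance = list()) {
  coding_scheme <- match.arg(coding_scheme)
  data <- as.matrix(data)
  storage.mode(data) <- "character"
  if (is.null(rownames(data))) abort_gc("taxa must be named (rownames)", "invalid_matrix")
  if (anyDuplicated(rownames(data))) abort_gc("duplicate taxon labels", "invalid_matrix")
  ok <- data %in% c(as.character(0:9), "?", "-")
  if (!all(ok)) {
    abort_gc(paste0("invalid state symbol(s): ",
                    paste(unique(data[!ok]), collapse = " ")), "invalid_matrix")
  }
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("m%0*d", nchar(ncol(data)), seq_len(ncol(data)))
  }
  structure(list(data = data, coding_scheme = coding_scheme,
                 provenance = provenance),
            class = "gc_morphmatrix")
}

#' @export
print.gc_morphmatrix <- function(x, ...) {
  k <- morph_state_counts(x)
  cat(sprintf("Morphological matrix: %d taxa x %d characters (%s coding)\n",
              nrow(x$data), ncol(x$data), x$coding_scheme))
  cat("  state counts:", paste(names(table(k)), as.integer(table(k)),
                               sep = "-state: ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.gc_morphmatrix <- function(x) dim(x$data)

#' Per-character state count
#'
#' k for each character: maximum observed state index + 1, with a floor of
#' 2 (a character with only one observed state is still binary).
#'
#' @param x A [morph_matrix()].
#' @return Integer vector over characters.
#' @export
morph_state_counts <- function(x) {
  apply(x$data, 2L, function(col) {
    obs <- suppressWarnings(as.integer(col[!col %in% c("?", "-")]))
    max(2L, if (length(obs)) max(obs) + 1L else 2L)
  })
}

#' @importFrom generics tidy
#' @export
tidy.gc_morphmatrix <- function(x, ...) {
  tibble::tibble(
    taxon = rep(rownames(x$data), times = ncol(x$data)),
    character = rep(colnames(x$data), each = nrow(x$data)),
    state = as.character(x$data)
  )
}

#' Read and write morphological matrices as NEXUS
#'
#' `datatype=standard` NEXUS with `MISSING=?` and `GAP=-`.
#'
#' @param x A [morph_matrix()].
#' @param path File path.
#' @param ... Passed to [morph_matrix()] on read.
#' @return `read_morph_matrix()` returns a `gc_morphmatrix`.
#' @export
write_morph_matrix <- function(x, path) {
  dat <- lapply(seq_len(nrow(x$data)), function(i) x$data[i, ])
  names(dat) <- rownames(x$data)
  ape::write.nexus.data(dat, path, format = "standard", interleaved = FALSE)
  invisible(path)
}

#' @rdname write_morph_matrix
#' @export
read_morph_matrix <- function(path, ...) {
  dat <- ape::read.nexus.data(path)
  m <- t(vapply(dat, as.character, character(length(dat[[1L]]))))
  rownames(m) <- names(dat)
  morph_matrix(m, ...)
}
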