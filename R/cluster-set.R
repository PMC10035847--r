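#' Two-level gene-family clustering
#'
#' A `gc_clusterset` holds gene families (homogroups), each subdivided into
#' orthogroups, each mapping species to the gene identifiers that species
#' contributes. This is the common structure of MCL-style homology
#' clusterings and OrthoFinder orthogroup tables.
#'
#' @param families Named list of families; each family is a named list of
#'   orthogroups; each orthogroup is a named list `species -> character
#'   vector of gene ids`.
#' @param species Ordered character vector of all species.
#' @param provenance Named list (e.g. `E_value`, `I_value`, `strategy`).
#' @return An object of class `gc_clusterset`.
#' @export
cluster_set <- function(families, species, provenance = list()) {
  if (length(families) == 0L) abort_gc("cluster set has no families", "invalid_clusters")
  if (is.null(names(families)) || anyDuplicated(names(families))) {
    abort_gc("families must be uniquely named", "invalid_clusters")
  }
  for (fam in families) {
    if (length(fam) == 0L) abort_gc("empty family", "invalid_clusters")
    for (og in fam) {
      unknown <- setdiff(names(og), species)
      if (length(unknown)) {
        abort_gc(paste0("gene ids resolve to unknown species: ",
                        paste(unknown, collapse = ", ")), "invalid_clusters")
      }
    }
  }
  structure(list(families = families, species = species, provenance = provenance),
            class = "gc_clusterset")
}

#' @export
print.gc_clusterset <- function(x, ...) {
  n_og <- sum(vapply(x$families, length, 1L))
  cat(sprintf("Cluster set: %d families / %d orthogroups over %d species\n",
              length(x$families), n_og, length(x$species)))
  invisible(x)
}

n_orthogroups <- function(cs) sum(vapply(cs$families, length, 1L))

#' Default species resolver: prefix before the first delimiter
#'
#' @param delimiter Single character separating the species prefix from the
#'   gene identifier (default `"|"`).
#' @return A function mapping gene-id vectors to species names (NA where the
#'   delimiter is absent).
#' @export
species_prefix_resolver <- function(delimiter = "|") {
  force(delimiter)
  function(ids) {
    hit <- regexpr(delimiter, ids, fixed = TRUE)
    out <- rep(NA_character_, length(ids))
    ok <- hit > 1L
    out[ok] <- substr(ids[ok], 1L, hit[ok] - 1L)
    out
  }
}

#' Parse a gene-family cluster file
#'
#' Reads one-level clusterings in either the OrthoFinder dialect
#' (`OG0000001: spA|g1 spB|g7 ...`) or the MCL dialect (one
#' whitespace-separated cluster per line). Each input cluster becomes one
#' family with a single orthogroup; attach orthogroups to families with
#' [parse_two_level_clusters()].
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param dialect `"orthofinder"` or `"mcl"`.
#' @param species_resolver Function mapping gene ids to species names;
#'   default [species_prefix_resolver()].
#' @param text Optional character vector of lines (overrides `path`).
#' @param provenance Passed to [cluster_set()].
#' @return A `gc_clusterset`.
#' @export
parse_cluster_file <- function(path = NULL, dialect = c("orthofinder", "mcl"),
                               species_resolver = species_prefix_resolver(),
                               text = NULL, provenance = list()) {
  dialect <- match.arg(dialect)
  lines <- text %||% readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_gc("empty cluster file", "parse_error")
  families <- list()
  species <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (dialect == "orthofinder") {
      m <- regexpr(":", ln, fixed = TRUE)
      if (m < 1L) abort_gc(sprintf("line %d: missing 'ID:' prefix", i), "parse_error")
      fam_id <- trimws(substr(ln, 1L, m - 1L))
      body <- trimws(substr(ln, m + 1L, nchar(ln)))
    } else {
      fam_id <- sprintf("F%05d", i)
      body <- ln
    }
    ids <- strsplit(body, "\\s+")[[1L]]
    if (length(ids) == 0L || !nzchar(ids[1L])) {
      abort_gc(sprintf("line %d: empty cluster", i), "parse_error")
    }
    sp <- species_resolver(ids)
    if (anyNA(sp)) {
      abort_gc(sprintf("line %d: cannot resolve species for gene id '%s'",
                       i, ids[which(is.na(sp))[1L]]), "parse_error")
    }
    og <- split(ids, sp)
    families[[fam_id]] <- stats::setNames(list(og), paste0(fam_id, ".1"))
    species <- union(species, names(og))
  }
  cluster_set(families, sort(species), provenance)
}

#' Attach an orthogroup-level clustering to a family-level clustering
#'
#' Combines a homogroup (family) file and an orthogroup file into one
#' two-level cluster set: each orthogroup is assigned to the family that
#' contains its genes. Orthogroups spanning several families, and genes in
#' no family, are errors.
#'
#' @param family_clusters,orthogroup_clusters `gc_clusterset` objects from
#'   [parse_cluster_file()].
#' @return A two-level `gc_clusterset` with the families of
#'   `family_clusters`.
#' @export
parse_two_level_clusters <- function(family_clusters, orthogroup_clusters) {
  gene_to_family <- list()
  for (fid in names(family_clusters$families)) {
    genes <- unlist(family_clusters$families[[fid]], use.names = FALSE)
    gene_to_family[genes] <- fid
  }
  families <- lapply(family_clusters$families, function(f) list())
  counter <- stats::setNames(integer(length(families)), names(families))
  for (fam in orthogroup_clusters$families) {
    for (og in fam) {
      genes <- unlist(og, use.names = FALSE)
      fids <- vapply(genes, function(g) gene_to_family[[g]] %||% NA_character_, "")
      if (anyNA(fids)) abort_gc("orthogroup genes not in any family", "parse_error")
      fid <- unique(fids)
      if (length(fid) > 1L) abort_gc("orthogroup spans multiple families", "parse_error")
      counter[fid] <- counter[fid] + 1L
      families[[fid]][[paste0(fid, ".", counter[fid])]] <- og
    }
  }
  families <- families[vapply(families, length, 1L) > 0L]
  cluster_set(families, family_clusters$species, family_clusters$provenance)
}

#' Write a cluster set to OrthoFinder or MCL dialect
#'
#' @param x A `gc_clusterset`.
#' @param path Output file.
#' @param dialect `"orthofinder"` or `"mcl"`.
#' @param level `"homogroup"` writes one line per family, `"orthogroup"` one
#'   line per orthogroup.
#' @return `path`, invisibly.
#' @export
write_cluster_file <- function(x, path, dialect = c("orthofinder", "mcl"),
                               level = c("homogroup", "orthogroup")) {
  dialect <- match.arg(dialect); level <- match.arg(level)
  units <- if (level == "homogroup") {
    lapply(x$families, function(f) unlist(f, use.names = FALSE))
  } else {
    fl <- unlist(unname(lapply(x$families, function(f) {
      lapply(f, function(og) unlist(og, use.names = FALSE))
    })), recursive = FALSE)
    fl
  }
  ids <- if (level == "homogroup") names(x$families) else {
    unlist(lapply(x$families, names), use.names = FALSE)
  }
  body <- vapply(units, paste, "", collapse = " ")
  lines <- if (dialect == "orthofinder") paste0(ids, ": ", body) else body
  writeLines(lines, path)
  invisible(path)
}

#' Code a cluster set into a presence/absence matrix
#'
#' At the homogroup level, one binary character per family: a species scores
#' 1 iff it has at least one gene in any orthogroup of the family. At the
#' orthogroup level, one character per orthogroup. The result is unfiltered;
#' apply [apply_observability_filter()] downstream.
#'
#' @param x A `gc_clusterset`.
#' @param level `"homogroup"` or `"orthogroup"`.
#' @return A [pa_matrix()] with stable character labels (family/orthogroup
#'   ids).
#' @export
code_matrix <- function(x, level = c("homogroup", "orthogroup")) {
  level <- match.arg(level)
  sp <- x$species
  if (level == "homogroup") {
    cols <- lapply(x$families, function(f) {
      present <- unique(unlist(lapply(f, names), use.names = FALSE))
      as.integer(sp %in% present)
    })
    labels <- names(x$families)
  } else {
    cols <- list(); labels <- character(0)
    for (fid in names(x$families)) {
      f <- x$families[[fid]]
      for (oid in names(f)) {
        cols[[length(cols) + 1L]] <- as.integer(sp %in% names(f[[oid]]))
        labels <- c(labels, oid)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sp
  colnames(m) <- labels
  pa_matrix(m, level = level,
            provenance = c(x$provenance, list(coding = level)))
}

#' Build a named taxon sampling from an annotation table
#'
#' Given the full taxon table with group annotations, constructs the
#' standard taxon samplings: `Opi` is the full set; `Aco` is the core set
#' plus the Acoelomorpha (no Xenoturbellida); `Xen` is the core set plus the
#' Xenoturbellida (no Acoelomorpha); `Hol` keeps only Ichthyosporea and
#' Choanoflagellata among the outgroups; `Cho` keeps only Choanoflagellata;
#' `custom` returns the given list.
#'
#' @param annotations Data frame with columns `taxon`, `group`,
#'   `is_outgroup`, and optionally `is_core` (defaults to every taxon not in
#'   Xenoturbellida/Acoelomorpha).
#' @param sampling One of `"Opi"`, `"Aco"`, `"Xen"`, `"Hol"`, `"Cho"`,
#'   `"custom"`.
#' @param custom Explicit taxon vector when `sampling = "custom"`.
#' @return Character vector of retained taxa, in table order.
#' @export
make_taxon_sampling <- function(annotations,
                                sampling = c("Opi", "Aco", "Xen", "Hol", "Cho", "custom"),
                                custom = NULL) {
  sampling <- match.arg(sampling)
  req <- c("taxon", "group", "is_outgroup")
  if (!all(req %in% names(annotations))) {
    abort_gc("annotations need columns taxon, group, is_outgroup", "invalid_annotation")
  }
  ann <- annotations
  xeno_groups <- c("Xenoturbellida", "Acoelomorpha")
  if (is.null(ann$is_core)) ann$is_core <- !(ann$group %in% xeno_groups)
  if (sampling == "custom") {
    if (is.null(custom) || length(custom) == 0L) {
      abort_gc("custom sampling needs a non-empty taxon list", "invalid_sampling")
    }
    unknown <- setdiff(custom, ann$taxon)
    if (length(unknown)) {
      abort_gc(paste0("unknown taxa: ", paste(unknown, collapse = ", ")),
               "invalid_sampling")
    }
    return(ann$taxon[ann$taxon %in% custom])
  }
  keep <- switch(sampling,
    Opi = rep(TRUE, nrow(ann)),
    Aco = ann$is_core | ann$group == "Acoelomorpha",
    Xen = ann$is_core | ann$group == "Xenoturbellida",
    Hol = !ann$is_outgroup | ann$group %in% c("Ichthyosporea", "Choanoflagellata"),
    Cho = !ann$is_outgroup | ann$group == "Choanoflagellata")
  ann$taxon[keep]
}

#' Read a taxon annotation table
#'
#' Tab-separated with columns `taxon`, `group`, `is_outgroup` (and optional
#' `is_core`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_taxon_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  req <- c("taxon", "group", "is_outgroup")
  if (!all(req %in% names(df))) {
    abort_gc("annotations need columns taxon, group, is_outgroup", "invalid_annotation")
  }
  df$is_outgroup <- as.logical(df$is_outgroup)
  if (!is.null(df$is_core)) df$is_core <- as.logical(df$is_core)
  tibble::as_tibble(df)
}
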