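# Dataset-grid enumeration with the standard naming convention:
# <sampling>-<coding>[-<strategy>][-E<e>][-I<i>][-r<rep>], e.g.
# "Opi-ortho-E1e-05-I1.5".

#' Enumerate the gene-content dataset grid
#'
#' Full cross-product of taxon samplings, coding levels, homology-search
#' E-values and MCL inflation (I) values, in deterministic order with
#' unique names. With the standard settings — samplings Opi/Aco/Xen,
#' homogroup and orthogroup coding, four E-values (1e-2, 1e-5, 1e-9,
#' 1e-12) and five I-values (1.5, 2, 2.5, 4, 6) — this yields 20 parameter
#' combinations per (sampling, coding) and 120 datasets in total.
#'
#' @param samplings Character vector of taxon samplings.
#' @param codings Character vector of coding levels (`"homo"`, `"ortho"`).
#' @param e_values Numeric vector of E-value thresholds.
#' @param i_values Numeric vector of inflation values.
#' @param strategy Optional strategy tag (`"full"`, `"Ab"` for ab initio,
#'   `"P"` for pruning); `"full"` is omitted from names.
#' @param replicate Optional replicate index appended to names.
#' @return A tibble with one row per dataset spec and a unique `name`.
#' @export
enumerate_gene_content_grid <- function(samplings = c("Opi", "Aco", "Xen"),
                                        codings = c("homo", "ortho"),
                                        e_values = c(1e-2, 1e-5, 1e-9, 1e-12),
                                        i_values = c(1.5, 2, 2.5, 4, 6),
                                        strategy = "full",
                                        replicate = NULL) {
  grid <- expand.grid(I_value = i_values, E_value = e_values,
                      coding = codings, sampling = samplings,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sampling", "coding", "E_value", "I_value")]
  grid$strategy <- strategy
  grid$name <- dataset_name(grid$sampling, grid$coding, grid$strategy,
                            grid$E_value, grid$I_value, replicate)
  if (anyDuplicated(grid$name)) abort_gc("duplicate dataset names", "invalid_grid")
  tibble::as_tibble(grid)
}

#' Dataset name grammar
#'
#' `<sampling>-<coding>[-<strategy>][-E<e>][-I<i>][-r<rep>]`; the `full`
#' strategy tag is omitted.
#'
#' @param sampling,coding,strategy,e_value,i_value,replicate Spec fields
#'   (vectorised); `e_value`, `i_value`, `replicate` may be `NULL`.
#' @return Character vector of names.
#' @export
dataset_name <- function(sampling, coding, strategy = "full",
                         e_value = NULL, i_value = NULL, replicate = NULL) {
  nm <- paste(sampling, coding, sep = "-")
  tag <- ifelse(strategy == "full", "", paste0("-", strategy))
  nm <- paste0(nm, tag)
  if (!is.null(e_value)) nm <- paste0(nm, "-E", format(e_value, scientific = TRUE))
  if (!is.null(i_value)) nm <- paste0(nm, "-I", format(i_value))
  if (!is.null(replicate)) nm <- paste0(nm, "-r", replicate)
  nm
}

#' Enumerate the morphology analysis grid
#'
#' Cross-product of the given morphological datasets with the full
#' 24-member model grid of [morph_model_grid()] (2 ascertainment
#' corrections x 2 branch-length priors x 2 rate models x 3 frequency
#' models); 10 datasets give 240 analyses.
#'
#' @param datasets Character vector of dataset names (or a named list of
#'   matrices, whose names are used).
#' @return A tibble with one row per (dataset, model) pair.
#' @export
enumerate_morphology_grid <- function(datasets) {
  if (is.list(datasets)) datasets <- names(datasets)
  if (length(datasets) == 0L) {
    out <- morph_model_grid()[0, ]
    out$dataset <- character(0)
    return(out)
  }
  models <- morph_model_grid()
  out <- dplyr::cross_join(tibble::tibble(dataset = datasets), models)
  out$analysis_id <- paste(out$dataset, out$model_id, sep = ":")
  out
}

#' Synthetic taxon-annotation table with the standard group structure
#'
#' Builds an annotation table shaped like the full taxon sampling of a
#' deep-animal-phylogeny study: a core set, Acoelomorpha and
#' Xenoturbellida ingroup additions, and a ladder of outgroups
#' (Choanoflagellata, Ichthyosporea, and more distant ones). Entirely
#' synthetic labels; useful for exercising [make_taxon_sampling()] and the
#' dataset grid.
#'
#' @param n_core Core taxa (default 40).
#' @param n_acoelomorpha,n_xenoturbellida Xenacoelomorpha additions
#'   (defaults 4 and 1).
#' @param n_extra_outgroups Distant outgroups outside the core set
#'   (default 2).
#' @return A tibble with columns `taxon`, `group`, `is_outgroup`,
#'   `is_core`.
#' @export
synthetic_taxon_table <- function(n_core = 40L, n_acoelomorpha = 4L,
                                  n_xenoturbellida = 1L, n_extra_outgroups = 2L) {
  core_groups <- c("Choanoflagellata", "Ichthyosporea", rep("Metazoa", n_core - 2L))
  core <- tibble::tibble(
    taxon = sprintf("core%02d", seq_len(n_core)),
    group = core_groups,
    is_outgroup = core_groups != "Metazoa",
    is_core = TRUE)
  aco <- tibble::tibble(taxon = sprintf("acoel%02d", seq_len(n_acoelomorpha)),
                        group = "Acoelomorpha", is_outgroup = FALSE, is_core = FALSE)
  xen <- tibble::tibble(taxon = sprintf("xeno%02d", seq_len(n_xenoturbellida)),
                        group = "Xenoturbellida", is_outgroup = FALSE, is_core = FALSE)
  extra <- tibble::tibble(taxon = sprintf("outg%02d", seq_len(n_extra_outgroups)),
                          group = "Fungi", is_outgroup = TRUE, is_core = FALSE)
  dplyr::bind_rows(core, aco, xen, extra)
}
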