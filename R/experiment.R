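# End-to-end experiment orchestration: build matrices (from cluster files
# or simulation), run replicate MCMC chains per dataset, write traces,
# diagnostics, consensus trees, TPCT groups and hypothesis reports, with a
# manifest recording every seed, parameter and file checksum.

#' Run a configured experiment
#'
#' The configuration is a named list (or YAML file path) with entries:
#' \describe{
#'   \item{out_dir}{Output directory (created).}
#'   \item{seed}{Master seed; all dataset and replicate seeds derive from
#'     it.}
#'   \item{tree}{`list(n_taxa, branch_length_mean)` for the simulated true
#'     tree shared by simulated datasets.}
#'   \item{datasets}{List of dataset entries. Each has `name`, and either
#'     `cluster_file` + `dialect` + `coding` (parse and code a cluster
#'     file) or simulation parameters `n_families`, `coding`, and
#'     optionally `g`, `pi1`, `per_orthogroup_loss`, `origination_mode`.}
#'   \item{mcmc}{`list(generations, sample_every, replicates,
#'     burn_in_fraction)`.}
#'   \item{hypotheses}{Optional path to a hypothesis YAML
#'     ([read_hypotheses()]) plus `h0`/`h1` names per test entry.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return The manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% abort_gc("config needs out_dir", "invalid_config")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mc <- config$mcmc %||% list()
  mcfg_base <- list(generations = as.integer(mc$generations %||% 2000L),
                    sample_every = as.integer(mc$sample_every %||% 10L),
                    replicates = as.integer(mc$replicates %||% 2L),
                    burn_in_fraction = mc$burn_in_fraction %||% 0.25)
  tree_cfg <- config$tree %||% list(n_taxa = 8L, branch_length_mean = 0.1)
  true_tree <- sample_tree(tree_cfg$n_taxa %||% 8L,
                           tree_cfg$branch_length_mean %||% 0.1,
                           seed = derive_seed(seed, "true-tree"))
  tree_path <- file.path(out_dir, "true_tree.nwk")
  ape::write.tree(true_tree, tree_path)

  manifest <- list(seed = seed, created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   config = config, datasets = list(), files = list())
  add_file <- function(path, role, dataset = NA_character_) {
    manifest$files[[length(manifest$files) + 1L]] <<- list(
      path = basename(path), role = role, dataset = dataset,
      md5 = unname(tools::md5sum(path)))
  }
  add_file(tree_path, "true_tree")

  all_traces <- list()
  for (ds in config$datasets %||% list()) {
    name <- ds$name %||% abort_gc("dataset entry needs a name", "invalid_config")
    ds_seed <- derive_seed(seed, paste0("dataset-", name))
    coding <- ds$coding %||% "homo"
    level <- if (coding == "ortho") "orthogroup" else "homogroup"
    mat <- if (!is.null(ds$cluster_file)) {
      cs <- parse_cluster_file(ds$cluster_file, dialect = ds$dialect %||% "orthofinder")
      code_matrix(cs, level)
    } else {
      spec <- gene_family_sim_spec(
        n_families = ds$n_families %||% 500L,
        origination_mode = ds$origination_mode %||% "root_only",
        pi1 = ds$pi1 %||% 0.5,
        g = ds$g %||% 1.5,
        per_orthogroup_loss = ds$per_orthogroup_loss %||% 0.1,
        seed = ds_seed)
      cs <- simulate_gene_families(true_tree, spec)
      code_matrix(cs, level)
    }
    mat <- apply_observability_filter(mat)
    mat_path <- file.path(out_dir, paste0(name, ".tsv"))
    write_pa_matrix(mat, mat_path, "tsv")
    add_file(mat_path, "matrix", name)

    mcfg <- mcmc_config(generations = mcfg_base$generations,
                        sample_every = mcfg_base$sample_every,
                        replicates = mcfg_base$replicates,
                        burn_in_fraction = mcfg_base$burn_in_fraction,
                        seed = derive_seed(ds_seed, "mcmc"))
    traces <- run_mcmc(combined_model(binary_partition(mat)), mcfg)
    for (tr in traces) {
      tpath <- file.path(out_dir, sprintf("%s-r%d.trees", name, tr$replicate))
      write_tree_samples(tr, tpath)
      add_file(tpath, "trace_trees", name)
      lpath <- file.path(out_dir, sprintf("%s-r%d.log", name, tr$replicate))
      utils::write.table(tr$stats, lpath, sep = "\t", quote = FALSE, row.names = FALSE)
      add_file(lpath, "trace_log", name)
    }
    diag <- compare_runs(traces)
    ll_ess <- vapply(traces, function(tr) {
      tryCatch(ess(post_burn_in(tr$stats$log_likelihood, mcfg$burn_in_fraction)),
               error = function(e) NA_real_)
    }, 1)
    diag_out <- list(maxdiff = diag$maxdiff,
                     maxdiff_ok = diag$maxdiff < 0.3,
                     ess_log_likelihood = ll_ess,
                     ess_ok = all(!is.na(ll_ess)) && all(ll_ess > 300))
    dpath <- file.path(out_dir, paste0(name, "-diagnostics.json"))
    jsonlite::write_json(diag_out, dpath, auto_unbox = TRUE, digits = NA)
    add_file(dpath, "diagnostics", name)

    cons <- majority_consensus(traces)
    cpath <- file.path(out_dir, paste0(name, "-consensus.nwk"))
    ape::write.tree(cons$tree, cpath)
    add_file(cpath, "consensus", name)

    manifest$datasets[[name]] <- list(
      seed = ds_seed, coding = coding, n_taxa = nrow(mat$data),
      n_characters = ncol(mat$data), window = mat$window,
      mcmc_seed = mcfg$seed, replicates = mcfg$replicates,
      generations = mcfg$generations,
      diagnostics = diag_out)
    all_traces[[name]] <- traces
  }

  # TPCT: pool every dataset's traces per taxon set
  if (length(all_traces)) {
    taxa_keys <- vapply(all_traces, function(trs) paste(trs[[1L]]$taxa, collapse = "|"), "")
    for (key in unique(taxa_keys)) {
      group <- unlist(all_traces[taxa_keys == key], recursive = FALSE)
      cons <- tpct(list(pool = group))$pool
      gname <- paste0("tpct-", substr(digest_key(key), 1L, 8L))
      gpath <- file.path(out_dir, paste0(gname, ".nwk"))
      ape::write.tree(cons$tree, gpath)
      add_file(gpath, "tpct")
      manifest$tpct[[gname]] <- list(taxa = strsplit(key, "|", fixed = TRUE)[[1L]],
                                     n_samples = cons$n_samples)
    }
  }

  # hypothesis tests on the pooled traces
  if (!is.null(config$hypotheses) && length(all_traces)) {
    hyps <- if (is.character(config$hypotheses)) {
      read_hypotheses(config$hypotheses)
    } else {
      lapply(config$hypotheses, function(h) {
        constraint_hypothesis(h$name, h$kind, h$groups, h$outgroup)
      })
    }
    if (length(hyps) >= 2L) {
      pool <- unlist(all_traces, recursive = FALSE)
      res <- posterior_odds(pool, hyps[[1L]], hyps[[2L]])
      hpath <- file.path(out_dir, "hypothesis-report.tsv")
      write_hypothesis_report(res, hpath)
      add_file(hpath, "hypothesis_report")
    }
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

digest_key <- function(key) {
  sprintf("%08x", derive_seed(0L, key))
}
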