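test_that("the two cluster dialects parse to the same content", {
  mcl <- parse_cluster_file(text = c("A|g1 B|g2", "A|g3"), dialect = "mcl")
  of <- parse_cluster_file(text = c("OG1: A|g1 B|g2", "OG2: A|g3"),
                           dialect = "orthofinder")
  expect_equal(length(mcl$families), 2L)
  expect_equal(mcl$species, c("A", "B"))
  expect_equal(unname(lapply(mcl$families, function(f) unname(unlist(f)))),
               unname(lapply(of$families, function(f) unname(unlist(f)))))

  expect_error(parse_cluster_file(text = "A|g1 Bg2", dialect = "mcl"),
               regexp = "Bg2", class = "gcphylo_error")
  expect_error(parse_cluster_file(text = character(0), dialect = "mcl"),
               class = "gcphylo_error")
  expect_error(parse_cluster_file(text = "A|g1 B|g2", dialect = "orthofinder"),
               class = "gcphylo_error")  # missing "ID:" prefix
})

test_that("cluster files round-trip through both dialects", {
  tr <- sample_tree(5, 0.2, seed = 3)
  cs <- simulate_gene_families(tr, gene_family_sim_spec(80, g = 2, seed = 4))
  for (dialect in c("orthofinder", "mcl")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_cluster_file(cs, path, dialect, level = "orthogroup")
    back <- parse_cluster_file(path, dialect = dialect)
    genes_in <- sort(unlist(lapply(cs$families, unlist), use.names = FALSE))
    genes_out <- sort(unlist(lapply(back$families, unlist), use.names = FALSE))
    expect_identical(genes_out, genes_in)
    expect_identical(back$species, cs$species)
  }
})

test_that("two-level input attaches orthogroups to their families", {
  fam <- parse_cluster_file(text = c("F1: A|g1 B|g2 C|g3", "F2: A|g4"),
                            dialect = "orthofinder")
  og <- parse_cluster_file(text = c("O1: A|g1 B|g2", "O2: C|g3", "O3: A|g4"),
                           dialect = "orthofinder")
  two <- parse_two_level_clusters(fam, og)
  expect_equal(vapply(two$families, length, 1L), c(F1 = 2L, F2 = 1L))
  bad <- parse_cluster_file(text = "OX: A|g1 A|g4", dialect = "orthofinder")
  expect_error(parse_two_level_clusters(fam, bad), class = "gcphylo_error")
})

test_that("coding levels follow their definitions", {
  # one family, two orthogroups; A in both, B in one
  families <- list(F1 = list(
    F1.1 = list(A = "A|g1", B = "B|g1"),
    F1.2 = list(A = "A|g2")))
  cs <- cluster_set(families, c("A", "B"))
  mh <- code_matrix(cs, "homogroup")
  expect_equal(unname(mh$data), matrix(c(1L, 1L), 2, 1))
  mo <- code_matrix(cs, "orthogroup")
  expect_equal(unname(mo$data), matrix(c(1L, 1L, 1L, 0L), 2, 2))
  expect_equal(colnames(mo$data), c("F1.1", "F1.2"))
})

test_that("the observability filter keeps exactly the window", {
  m <- matrix(0L, 5, 6, dimnames = list(paste0("t", 1:5), paste0("c", 0:5)))
  for (j in 1:6) if (j > 1) m[seq_len(j - 1), j] <- 1L
  x <- pa_matrix(m)
  f <- apply_observability_filter(x)   # defaults [2, 3]
  expect_equal(colnames(f$data), c("c2", "c3"))
  expect_equal(f$window, c(2L, 3L))

  # identity window
  f0 <- apply_observability_filter(x, 0, 5)
  expect_equal(f0$data, x$data)

  # idempotence
  expect_equal(apply_observability_filter(f, 2, 3)$data, f$data)

  # all-removed: warning and empty-matrix class
  xs <- pa_matrix(matrix(c(0L, 0L, 0L, 0L, 1L), 5, 1,
                         dimnames = list(paste0("t", 1:5), "c")))
  expect_warning(fe <- apply_observability_filter(xs), "removed every")
  expect_s3_class(fe, "gc_empty_matrix")
  expect_equal(ncol(fe$data), 0L)

  expect_error(apply_observability_filter(x, 3, 2), class = "gcphylo_error")
})

test_that("pruning removes rows then re-filters with the new window", {
  taxa <- c("A", "B", "C", "D", "E")
  m <- matrix(0L, 5, 3, dimnames = list(taxa, c("c1", "c2", "c3")))
  m[c("A", "B", "C"), "c1"] <- 1L
  m[c("A", "E"), "c2"] <- 1L
  m[c("B", "C"), "c3"] <- 1L
  x <- apply_observability_filter(pa_matrix(m))
  pr <- prune_taxa(x, "E")
  # new N = 4, window [2,2]: c1 (count 3) and c2 (count 1) drop, c3 stays
  expect_equal(colnames(pr$data), "c3")
  expect_equal(pr$window, c(2L, 2L))

  expect_equal(prune_taxa(x, character(0))$data, x$data)
  expect_error(prune_taxa(x, c("A", "B")), class = "gcphylo_error")
  expect_error(prune_taxa(x, "nope"), class = "gcphylo_error")
})

test_that("sequential pruning equals pruning the union", {
  withr::with_seed(14, {
    for (i in 1:5) {
      m <- matrix(rbinom(6 * 40, 1, 0.45), 6, 40,
                  dimnames = list(paste0("t", 1:6), paste0("c", 1:40)))
      x <- apply_observability_filter(pa_matrix(m))
      both <- tryCatch(prune_taxa(x, c("t1", "t2")), gcphylo_error = function(e) NULL)
      seq2 <- tryCatch(prune_taxa(prune_taxa(x, "t1"), "t2"),
                       gcphylo_error = function(e) NULL)
      if (is.null(both) || is.null(seq2)) next
      expect_identical(seq2$data, both$data)
    }
  })
})

test_that("matrices round-trip through tsv, phylip and nexus", {
  tr <- sample_tree(6, 0.2, seed = 7)
  x <- simulate_binary_matrix(tr, 25, binary_model_spec(0.5), seed = 8)
  x$data[2, 3] <- NA
  for (fmt in c("tsv", "phylip", "nexus")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_pa_matrix(x, path, fmt)
    back <- read_pa_matrix(path, fmt)
    expect_equal(unname(back$data), unname(x$data), info = fmt)
    expect_equal(rownames(back$data), rownames(x$data), info = fmt)
    if (fmt == "tsv") expect_equal(colnames(back$data), colnames(x$data))
  }
})

test_that("morphology matrices round-trip through nexus", {
  tr <- sample_tree(5, 0.3, seed = 9)
  mm <- simulate_morphology(tr, morph_sim_spec(15, missing_prob = 0.1,
                                               inapplicable_block_prob = 0.3,
                                               seed = 10))
  path <- withr::local_tempfile(fileext = ".nex")
  write_morph_matrix(mm, path)
  back <- read_morph_matrix(path)
  expect_equal(unname(back$data), unname(mm$data))
  expect_equal(rownames(back$data), rownames(mm$data))
})

test_that("taxon samplings follow the group annotations", {
  ann <- synthetic_taxon_table()   # 40 core + 4 Acoelomorpha + 1 Xenoturbellida + 2
  expect_equal(nrow(ann), 47L)
  expect_equal(length(make_taxon_sampling(ann, "Opi")), 47L)
  expect_equal(length(make_taxon_sampling(ann, "Aco")), 44L)
  expect_equal(length(make_taxon_sampling(ann, "Xen")), 41L)
  hol <- make_taxon_sampling(ann, "Hol")
  cho <- make_taxon_sampling(ann, "Cho")
  expect_false(any(ann$taxon[ann$group == "Fungi"] %in% hol))
  expect_false(any(ann$taxon[ann$group == "Ichthyosporea"] %in% cho))
  expect_true(all(ann$taxon[ann$group == "Choanoflagellata"] %in% cho))

  expect_equal(make_taxon_sampling(ann, "custom", custom = c("core01", "acoel01")),
               c("core01", "acoel01"))
  expect_error(make_taxon_sampling(ann, "custom", custom = character(0)),
               class = "gcphylo_error")
  expect_error(make_taxon_sampling(ann[, 1:2], "Opi"), class = "gcphylo_error")
})

test_that("taxon tables round-trip through tsv", {
  ann <- synthetic_taxon_table(6, 2, 1, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_taxon_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})
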