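test_that("evolve_cds_pair is deterministic, respects omega = 0 and ks = 0", {
  anc <- random_cds(120)
  p1 <- evolve_cds_pair(anc, 0.3, 0.2, seed = 9)
  p2 <- evolve_cds_pair(anc, 0.3, 0.2, seed = 9)
  expect_identical(p1, p2)

  # no divergence requested: sequences equal the ancestor
  p0 <- evolve_cds_pair(anc, 0, 0, seed = 9)
  expect_identical(p0, c(anc, anc))

  # omega = 0: no nonsynonymous event, Ka exactly 0
  pn <- evolve_cds_pair(anc, 0.4, 0, seed = 10)
  r <- ng86_pair(pn[1], pn[2])
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)

  expect_error(evolve_cds_pair(paste0(anc, "TAA"), 0.1, 0.1, seed = 1),
               "stop codon")
})

test_that("frozen residues never change their amino acid", {
  set.seed(2)
  anc <- random_cds(100)
  frozen <- c(10L, 50L, 90L)
  aa_anc <- .oracle_gc[substring(anc, frozen * 3 - 2, frozen * 3)]
  for (s in 1:5) {
    p <- evolve_cds_pair(anc, 0.8, 0.5, seed = s, frozen_aa = frozen)
    for (k in 1:2) {
      aa <- .oracle_gc[substring(p[k], frozen * 3 - 2, frozen * 3)]
      expect_equal(unname(aa), unname(aa_anc))
    }
  }
})

test_that("simulate_genome plants the stated world and flank retention extremes", {
  b <- default_bundle()
  cfg <- b$config
  expect_equal(sum(b$truth$pairs$mechanism == "tandem"), cfg$n_tandem_pairs)
  expect_equal(sum(b$truth$pairs$mechanism == "segmental"),
               cfg$n_segmental_pairs)
  expect_equal(sum(!b$truth$genes$is_member), cfg$n_decoys)
  expect_equal(sum(b$truth$genes$pseudogene), 1L)
  # ranks are unique and consecutive per chromosome
  for (chr in unique(b$loci$chrom)) {
    r <- sort(b$loci$rank[b$loci$chrom == chr])
    expect_equal(r, seq_along(r) - 1L)
  }

  # retention 1: every segmental pair fully conserved (count 20)
  b1 <- simulate_genome(sim_config(seed = 3, n_segmental_pairs = 2,
                                   flank_retention = 1))
  seg <- b1$truth$pairs[b1$truth$pairs$mechanism == "segmental", ]
  expect_true(all(seg$true_conserved == 20L))
  for (i in seq_len(nrow(seg))) {
    expect_equal(flanking_conservation(c(seg$gene1[i], seg$gene2[i]),
                                       b1$loci, b1$homology,
                                       family_ids = b1$truth$genes$gene_id),
                 20L)
  }

  # retention 0: no conserved flanks, pipeline says undetermined
  b0 <- simulate_genome(sim_config(seed = 3, n_segmental_pairs = 2,
                                   flank_retention = 0))
  seg0 <- b0$truth$pairs[b0$truth$pairs$mechanism == "segmental", ]
  expect_true(all(seg0$true_conserved == 0L))
  cl <- classify_duplication(c(seg0$gene1[1], seg0$gene2[1]), b0$loci,
                             b0$homology,
                             family_ids = b0$truth$genes$gene_id)
  expect_equal(cl$mechanism, "undetermined")
})

test_that("planted conserved-flank counts follow the binomial expectation", {
  # 5 segmental pairs per bundle; each count ~ Binomial(20, 0.35)
  counts <- unlist(lapply(1:12, function(s) {
    b <- simulate_genome(sim_config(seed = 100 + s))
    b$truth$pairs$true_conserved[b$truth$pairs$mechanism == "segmental"]
  }))
  expect_lt(abs(mean(counts) - 20 * 0.35), 2)
})

test_that("write_bundle round-trips through the package readers and is byte-stable", {
  b <- simulate_genome(sim_config(seed = 19, n_segmental_pairs = 1,
                                  n_singletons = 1, n_decoys = 1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_bundle(b, d1)
  f2 <- write_bundle(simulate_genome(sim_config(seed = 19,
                                                n_segmental_pairs = 1,
                                                n_singletons = 1,
                                                n_decoys = 1)), d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), info = nm)
  }

  prot <- read_protein_fasta(f1[["proteins"]])
  expect_identical(prot, b$proteins)
  cds <- read_cds_fasta(f1[["cds"]])
  expect_identical(cds, b$cds)
  loci <- read_gene_loci(f1[["genes"]])
  expect_equal(loci$gene_id, b$loci$gene_id)
  expect_equal(loci$rank, b$loci$rank)
  hom <- read_homology_map(f1[["homology"]])
  expect_equal(nrow(hom), nrow(b$homology))
  doms <- read_domain_table(f1[["domains"]])
  expect_equal(doms$gene_id, b$domains$gene_id)
  defs <- read_motif_table(f1[["motifs"]])
  expect_equal(defs$pattern, b$motifs$pattern)
  truth <- jsonlite::read_json(f1[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$pairs$gene1, b$truth$pairs$gene1)
})

test_that("a family-free bundle still writes valid, parseable files", {
  b <- simulate_genome(sim_config(seed = 4, n_singletons = 0,
                                  n_tandem_pairs = 0, n_segmental_pairs = 0,
                                  n_decoys = 0, include_pseudogene = FALSE))
  expect_equal(length(b$alignment), 0L)
  d <- withr::local_tempdir()
  f <- write_bundle(b, d)
  expect_equal(nrow(read_homology_map(f[["homology"]])), 0L)
  expect_gt(nrow(read_gene_loci(f[["genes"]])), 0L)
})

test_that("the full pipeline recovers every planted mechanism and date", {
  b <- default_bundle()
  fam <- identify_family(b$proteins, b$cds, b$domains)
  members <- fam$gene_id[fam$is_member & !fam$pseudogene]
  expect_setequal(members,
                  b$truth$genes$gene_id[b$truth$genes$is_member &
                                        !b$truth$genes$pseudogene])
  tr <- nj_tree(p_distance_matrix(b$alignment))
  pairs <- terminal_paralog_pairs(tr, b$species_of)
  expect_equal(nrow(pairs), nrow(b$truth$pairs))
  rep <- duplication_report(pairs, b$loci, b$homology, cds = b$cds,
                            family_ids = b$truth$genes$gene_id)
  m <- merge(rep, b$truth$pairs, by = c("gene1", "gene2"))
  expect_equal(m$mechanism.x, m$mechanism.y)
  seg <- m[m$mechanism.y == "segmental", ]
  expected_ma <- date_duplication(0.25, species_rate("Poplar"))
  expect_true(all(abs(seg$date_ma - expected_ma) / expected_ma < 0.3))
})
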