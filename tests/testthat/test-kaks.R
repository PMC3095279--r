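test_that("ng86_site_counts matches enumeration for hand-checked codons", {
  expect_equal(ng86_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_site_counts("ATG"), c(s = 0, n = 3))
  expect_equal(ng86_site_counts("GGG"), c(s = 1, n = 2))
  expect_error(ng86_site_counts("TAA"), "stop")
  expect_error(ng86_site_counts("XYZ"), "invalid")
  for (cd in sense_codons()) {
    expect_lte(ng86_site_counts(cd)[["s"]], 3)
  }
})

test_that("ng86_pair scores single and multi-step codon differences", {
  expect_equal(ng86_pair("TTT", "TTT")[c("Sd", "Nd", "Ka", "Ks")],
               list(Sd = 0, Nd = 0, Ka = 0, Ks = 0))
  r <- ng86_pair("TTT", "TTC")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  # two pathways, one blocked-free each: average of (1,1) and (0,2)
  r2 <- ng86_pair("TTT", "GTA")
  expect_equal(r2$Sd, 0.5)
  expect_equal(r2$Nd, 1.5)
})

test_that("ng86_pair is symmetric and matches pathway enumeration on random pairs", {
  set.seed(55)
  for (i in 1:100) {
    c1 <- sample(sense_codons(), 1)
    c2 <- sample(sense_codons(), 1)
    r <- ng86_pair(c1, c2)
    o <- oracle_pair_diffs(c1, c2)
    expect_equal(r$Sd, o[["sd"]], info = paste(c1, c2))
    expect_equal(r$Nd, o[["nd"]], info = paste(c1, c2))
    rs <- ng86_pair(c2, c1)
    expect_equal(r$Sd, rs$Sd)
    expect_equal(r$Nd, rs$Nd)
    expect_equal(r$Ks, rs$Ks)
  }
})

test_that("jukes_cantor implements the closed form and saturates at 3/4", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), 0.383119, tolerance = 1e-6)
  expect_error(jukes_cantor(0.75), "saturation")
  expect_error(jukes_cantor(-0.1), "proportion")
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jukes_cantor(p)) > 0))  # monotone
})

test_that("omega sentinels: 0/0 undefined, Ka>0 with Ks=0 infinite", {
  # ATG ATG vs ATG AGG: one nonsynonymous difference, no synonymous sites hit
  r <- ng86_pair("ATGATG", "ATGAGG")
  expect_gt(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_equal(r$omega, Inf)
  r0 <- ng86_pair("ATGATG", "ATGATG")
  expect_true(is.na(r0$omega))
})

test_that("codon_align back-translates and drops gapped/ambiguous columns", {
  a <- codon_align("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(a$n_codons, 2L)
  expect_equal(a$seq1, "ATGAAA")
  expect_equal(a$seq2, "ATGAAG")

  a2 <- codon_align("M-K", "MLK", "ATGAAA", "ATGCTGAAG")
  expect_equal(a2$n_codons, 2L)
  expect_equal(a2$seq2, "ATGAAG")

  # trailing stop tolerated
  a3 <- codon_align("MK", "MK", "ATGAAATAA", "ATGAAG")
  expect_equal(a3$n_codons, 2L)

  expect_error(codon_align("MK", "MK", "ATGCCC", "ATGAAG"), "residue 2")

  # random 100-codon pair with 10 planted gaps equals brute-force filter
  set.seed(66)
  cds1 <- random_cds(100)
  cds2 <- random_cds(100)
  p1 <- strsplit(paste(.oracle_gc[substring(cds1, seq(1, 298, 3),
                                            seq(3, 300, 3))], collapse = ""),
                 "")[[1]]
  p2 <- strsplit(paste(.oracle_gc[substring(cds2, seq(1, 298, 3),
                                            seq(3, 300, 3))], collapse = ""),
                 "")[[1]]
  gap_cols <- sample(100, 10)
  a1 <- p1; a1[gap_cols[1:5]] <- "-"
  a2 <- p2; a2[gap_cols[6:10]] <- "-"
  # a gapped protein row must drop those residues from its own CDS
  cds1_kept <- paste(substring(cds1, (1:100) * 3 - 2, (1:100) * 3)[
    -gap_cols[1:5]], collapse = "")
  cds2_kept <- paste(substring(cds2, (1:100) * 3 - 2, (1:100) * 3)[
    -gap_cols[6:10]], collapse = "")
  al <- codon_align(paste(a1, collapse = ""), paste(a2, collapse = ""),
                    cds1_kept, cds2_kept)
  expect_equal(al$n_codons, 90L)
  kept <- setdiff(1:100, gap_cols)
  expect_equal(al$seq1, paste(substring(cds1, kept * 3 - 2, kept * 3),
                              collapse = ""))
  expect_equal(al$seq2, paste(substring(cds2, kept * 3 - 2, kept * 3),
                              collapse = ""))
})

test_that("sliding windows are laid out on nt coordinates and match the global result", {
  set.seed(91)
  anc <- random_cds(400)  # 1200 nt
  pair <- evolve_cds_pair(anc, 0.3, 0.3, seed = 12)
  prof <- sliding_window_omega(pair[1], pair[2])
  expect_equal(nrow(prof), 19L)
  expect_equal(prof$start, seq(1, 901, by = 50))
  expect_equal(prof$end - prof$start + 1, rep(300, 19))

  whole <- sliding_window_omega(pair[1], pair[2], window_nt = 1200)
  glob <- ng86_pair(pair[1], pair[2])
  expect_equal(whole$Ks, glob$Ks)
  expect_equal(whole$Ka, glob$Ka)
  expect_equal(whole$Sd, glob$Sd)

  expect_warning(short <- sliding_window_omega("ATGAAA", "ATGAAG",
                                               window_nt = 300),
                 "shorter than window")
  expect_equal(nrow(short), 1L)

  # identical pair: no differences anywhere
  same <- sliding_window_omega(pair[1], pair[1])
  expect_true(all(same$Sd == 0 & same$Nd == 0))
  expect_true(all(is.na(same$omega)))
})

test_that("elevated nonsynonymous changes in the first 300 nt surface there", {
  set.seed(14)
  anc <- random_cds(400)
  # neutral tail, strongly nonsynonymous head
  head_pair <- evolve_cds_pair(substr(anc, 1, 300), 0.4, 3.0, seed = 5)
  tail_pair <- evolve_cds_pair(substr(anc, 301, 1200), 0.4, 0.05, seed = 6)
  s1 <- paste0(head_pair[1], tail_pair[1])
  s2 <- paste0(head_pair[2], tail_pair[2])
  prof <- sliding_window_omega(s1, s2)
  expect_equal(which.max(prof$omega), 1L)
})

test_that("mean_ks discards saturated values and handles empties", {
  expect_equal(mean_ks(c(0.21, 0.25, 2.5)), 0.23)
  expect_equal(mean_ks(0.2120), 0.2120)
  expect_true(is.na(mean_ks(c(2.5, 3))))
  expect_true(is.na(mean_ks(numeric(0))))
  expect_error(mean_ks(c(0.2, -0.1)), "negative")

  # simulated flanking-pair Ks at true 0.25 averages close to truth
  set.seed(33)
  ks <- vapply(1:20, function(i) {
    p <- evolve_cds_pair(random_cds(200), 0.25, 0.2, seed = 500 + i)
    ng86_pair(p[1], p[2])$Ks
  }, numeric(1))
  expect_lt(abs(mean_ks(ks) - 0.25) / 0.25, 0.1)
})
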