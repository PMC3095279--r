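# Seeded synthetic genomes with planted ground truth: chromosomes of
# background genes carrying a gene family with tandem and segmental
# duplicate pairs, single-HKD decoys, one premature-stop pseudogene, and
# codon sequences evolved to a chosen synonymous distance. Every pipeline
# stage can be exercised against the planted truth.

#' Simulation configuration
#'
#' Defaults state the simulated world once: five segmental pairs and one
#' tandem pair (the counts observed for the family that motivated this
#' package), flank windows of 10 genes per side, a flank-retention
#' probability of 0.35 (conserved-flank counts of a few per 20, matching
#' observed magnitudes of 1-12), a planted pairwise Ks of 0.25 with
#' omega = 0.2 (recent duplicates under purifying selection), and 300-codon
#' family genes.
#'
#' @param seed Integer; all randomness flows from it.
#' @param n_chromosomes,genes_per_chromosome Genome layout.
#' @param n_singletons Family members without a planted duplicate.
#' @param n_tandem_pairs,n_segmental_pairs Planted duplicate pairs.
#' @param n_decoys Single-HKD non-members.
#' @param include_pseudogene Plant one member with a premature stop codon.
#' @param flank_window Genes per flank side (default 10).
#' @param flank_retention Probability each flank gene keeps its homolog.
#' @param target_ks Planted pairwise synonymous distance.
#' @param omega Planted Ka/Ks of the evolving pairs.
#' @param codons_per_gene,flank_codons Codon lengths of family and flank
#'   genes.
#' @param pair_divergence_ks Synonymous distance separating the founders of
#'   different pairs/singletons from the family root.
#' @param species Species tag given to planted pairs.
#' @return A validated configuration list.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 4, genes_per_chromosome = 70,
                       n_singletons = 4, n_tandem_pairs = 1,
                       n_segmental_pairs = 5, n_decoys = 2,
                       include_pseudogene = TRUE, flank_window = 10,
                       flank_retention = 0.35, target_ks = 0.25, omega = 0.2,
                       codons_per_gene = 300, flank_codons = 200,
                       pair_divergence_ks = 0.8, species = "Poplar") {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              n_singletons = n_singletons, n_tandem_pairs = n_tandem_pairs,
              n_segmental_pairs = n_segmental_pairs, n_decoys = n_decoys,
              include_pseudogene = include_pseudogene,
              flank_window = flank_window, flank_retention = flank_retention,
              target_ks = target_ks, omega = omega,
              codons_per_gene = codons_per_gene, flank_codons = flank_codons,
              pair_divergence_ks = pair_divergence_ks, species = species)
  stopifnot(cfg$flank_retention >= 0, cfg$flank_retention <= 1,
            cfg$target_ks >= 0, cfg$omega >= 0, cfg$flank_window >= 1,
            cfg$codons_per_gene >= 60, cfg$n_chromosomes >= 1)
  counts <- c(cfg$n_singletons, cfg$n_tandem_pairs, cfg$n_segmental_pairs,
              cfg$n_decoys)
  if (any(counts < 0)) stop("counts must be >= 0")
  cfg
}

# random sense codons; amino acids in `exclude_aa` are avoided so planted
# motifs cannot arise by accident in backbones
.random_codons <- function(n, exclude_aa = character(0)) {
  pool <- .SENSE_CODONS[!.GC[.SENSE_CODONS] %in% exclude_aa]
  sample(pool, n, replace = TRUE)
}

.codon_for_aa <- function(aa) {
  pool <- .SENSE_CODONS[.GC[.SENSE_CODONS] == aa]
  sample(pool, 1L)
}

# plant an amino-acid string at 1-based residue position; '.' keeps the
# backbone codon. Returns list(codons, frozen) where frozen are the residue
# indices of the literal (non '.') letters.
.plant_aa <- function(codons, pos, aa_string) {
  aa <- strsplit(aa_string, "", fixed = TRUE)[[1]]
  frozen <- integer(0)
  for (k in seq_along(aa)) {
    if (aa[k] == ".") next
    codons[pos + k - 1L] <- .codon_for_aa(aa[k])
    frozen <- c(frozen, pos + k - 1L)
  }
  list(codons = codons, frozen = frozen)
}

# Evolve one lineage: Poisson numbers of synonymous and nonsynonymous
# events (NG86 site counts of the starting sequence set the expectations),
# applied in shuffled order; each event picks a codon weighted by its
# current number of legal single-base changes of the required class, then
# one such change uniformly. Nonsynonymous changes never create stops and
# are barred from `frozen` residue positions. Uses the ambient RNG stream.
.evolve_lineage <- function(codons, ks, omega, frozen = integer(0)) {
  n <- length(codons)
  s <- vapply(codons, function(cd) .CODON_TABLES[[cd]]$s, numeric(1))
  S <- sum(s)
  N <- 3 * n - S
  n_syn <- stats::rpois(1, S * ks)
  n_non <- stats::rpois(1, N * omega * ks)
  events <- sample(c(rep("s", n_syn), rep("n", n_non)))
  syn_w <- vapply(codons, function(cd) nrow(.CODON_TABLES[[cd]]$syn),
                  numeric(1))
  non_w <- vapply(codons, function(cd) nrow(.CODON_TABLES[[cd]]$non),
                  numeric(1))
  non_mask <- rep(1, n)
  non_mask[frozen] <- 0
  for (ev in events) {
    w <- if (ev == "s") syn_w else non_w * non_mask
    if (sum(w) == 0)
      stop("no ", if (ev == "s") "synonymous" else "nonsynonymous",
           " neighbor available anywhere in the sequence")
    i <- sample.int(n, 1L, prob = w)
    tab <- .CODON_TABLES[[codons[i]]]
    choices <- if (ev == "s") tab$syn else tab$non
    pick <- choices[sample.int(nrow(choices), 1L), ]
    codons[i] <- pick$codon
    syn_w[i] <- nrow(.CODON_TABLES[[codons[i]]]$syn)
    non_w[i] <- nrow(.CODON_TABLES[[codons[i]]]$non)
  }
  codons
}

#' Evolve a coding-sequence pair to a target synonymous distance
#'
#' From a stop-free ancestral CDS, each of the two lineages independently
#' accumulates a Poisson number of synonymous changes with expectation
#' `target_ks/2` per NG86 synonymous site, and nonsynonymous changes at
#' relative rate `omega` per nonsynonymous site; substitutions are sampled
#' uniformly among the single-base neighbors of the required class and
#' never create stop codons. Deterministic given `seed`.
#'
#' @param ancestral Ancestral CDS (length divisible by 3, no stops).
#' @param target_ks Expected pairwise synonymous distance.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param seed Integer seed.
#' @param frozen_aa Residue positions barred from nonsynonymous change
#'   (used to keep planted motifs intact).
#' @return Character vector of the two derived CDSs.
#' @export
evolve_cds_pair <- function(ancestral, target_ks, omega, seed,
                            frozen_aa = integer(0)) {
  stopifnot(target_ks >= 0, omega >= 0)
  cod <- .split_codons(toupper(ancestral))
  if (any(cod %in% .STOP_CODONS)) stop("ancestral CDS contains a stop codon")
  if (!all(cod %in% .SENSE_CODONS)) stop("ancestral CDS has invalid codons")
  set.seed(as.integer(seed))
  c1 <- .evolve_lineage(cod, target_ks / 2, omega, frozen_aa)
  c2 <- .evolve_lineage(cod, target_ks / 2, omega, frozen_aa)
  c(paste(c1, collapse = ""), paste(c2, collapse = ""))
}

.translate_codons <- function(codons) paste(.GC[codons], collapse = "")

#' Simulate a genome bundle with planted ground truth
#'
#' Generates chromosomes of ordered background genes; a gene family whose
#' members carry two planted HKD motifs (plus the core catalytic motif
#' `IYIENQFF` between them), single-HKD decoys and one premature-stop
#' pseudogene; one tandem pair placed at adjacent ranks; segmental pairs
#' placed on different chromosomes, each flank gene retained as a homolog
#' with probability `flank_retention` (retained flank pairs get coding
#' sequences evolved at the pair's planted Ks, so flanking-Ks dating can be
#' exercised). Reproducible given the config seed.
#'
#' @param config A [sim_config()].
#' @return A bundle list: `proteins`, `cds`, `alignment` (named character
#'   vectors), `loci` (ranked gene table), `homology`, `domains`, `motifs`
#'   (data.frames), `species_of`, and `truth` (planted ground truth).
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  W <- cfg$flank_window
  L <- cfg$codons_per_gene
  # insertion slots spaced so the 10-gene flanks of different planted genes
  # on one chromosome never overlap (flank ranges 2-22, 25-45, 48-68)
  slot_anchors <- c(12L, 35L, 58L)
  if (cfg$genes_per_chromosome < 69L)
    stop("genes_per_chromosome must be >= 69 to fit flank windows")
  n_slots_needed <- ceiling((cfg$n_tandem_pairs + 2 * cfg$n_segmental_pairs) /
                              cfg$n_chromosomes)
  if (n_slots_needed > length(slot_anchors))
    stop("infeasible placement: too many planted pairs for the genome size")

  # --- family sequence material -------------------------------------------
  hkd1_pos <- max(31L, floor(L * 0.40))
  hkd2_pos <- floor(L * 0.75)
  motif3_pos <- floor(L * 0.55)
  root <- .random_codons(L, exclude_aa = "H")
  pl <- .plant_aa(root, hkd1_pos, "H.K....D")
  frozen <- pl$frozen
  pl <- .plant_aa(pl$codons, hkd2_pos, "H.K....D")
  frozen <- c(frozen, pl$frozen)
  pl <- .plant_aa(pl$codons, motif3_pos, "IYIENQFF")
  frozen <- sort(c(frozen, pl$frozen))
  root <- pl$codons

  pair_ids <- list()
  truth_pairs <- list()
  proteins <- character(0)
  cds <- character(0)
  members <- character(0)
  species_of <- character(0)

  add_member <- function(id, codons, sp) {
    proteins[[id]] <<- .translate_codons(codons)
    cds[[id]] <<- paste(codons, collapse = "")
    members <<- c(members, id)
    species_of[[id]] <<- sp
  }

  n_pairs <- cfg$n_tandem_pairs + cfg$n_segmental_pairs
  pair_seeds <- sample.int(2147483646L, n_pairs + 1L)
  k <- 0L
  for (i in seq_len(cfg$n_tandem_pairs)) {
    k <- k + 1L
    founder <- .evolve_lineage(root, cfg$pair_divergence_ks, cfg$omega, frozen)
    pr <- evolve_cds_pair(paste(founder, collapse = ""), cfg$target_ks,
                          cfg$omega, pair_seeds[k], frozen)
    ids <- sprintf("FAM_T%d_%s", i, c("A", "B"))
    add_member(ids[1], .split_codons(pr[1]), cfg$species)
    add_member(ids[2], .split_codons(pr[2]), cfg$species)
    pair_ids[[k]] <- list(ids = ids, mechanism = "tandem")
  }
  for (i in seq_len(cfg$n_segmental_pairs)) {
    k <- k + 1L
    founder <- .evolve_lineage(root, cfg$pair_divergence_ks, cfg$omega, frozen)
    pr <- evolve_cds_pair(paste(founder, collapse = ""), cfg$target_ks,
                          cfg$omega, pair_seeds[k], frozen)
    ids <- sprintf("FAM_S%d_%s", i, c("A", "B"))
    add_member(ids[1], .split_codons(pr[1]), cfg$species)
    add_member(ids[2], .split_codons(pr[2]), cfg$species)
    pair_ids[[k]] <- list(ids = ids, mechanism = "segmental")
  }
  other_species <- unique(c("Grape", "Rice", "Arabidopsis", cfg$species))
  singleton_ids <- character(0)
  for (i in seq_len(cfg$n_singletons)) {
    id <- sprintf("FAM_M%d", i)
    seqc <- .evolve_lineage(root, cfg$pair_divergence_ks, cfg$omega, frozen)
    add_member(id, seqc, other_species[(i - 1L) %% length(other_species) + 1L])
    singleton_ids <- c(singleton_ids, id)
  }
  pseudo_id <- character(0)
  if (cfg$include_pseudogene) {
    pseudo_id <- "FAM_PSE1"
    seqc <- .evolve_lineage(root, cfg$pair_divergence_ks, cfg$omega, frozen)
    prot <- .translate_codons(seqc)          # annotated full-length model
    seqc[floor(L / 2)] <- "TAA"              # premature in-frame stop
    proteins[[pseudo_id]] <- prot
    cds[[pseudo_id]] <- paste(seqc, collapse = "")
    species_of[[pseudo_id]] <- cfg$species
  }
  decoy_ids <- character(0)
  for (i in seq_len(cfg$n_decoys)) {
    id <- sprintf("DECOY%d", i)
    backbone <- .random_codons(L, exclude_aa = "H")
    pl <- .plant_aa(backbone, floor(L / 2), "H.K....D")
    proteins[[id]] <- .translate_codons(pl$codons)
    cds[[id]] <- paste(pl$codons, collapse = "")
    species_of[[id]] <- cfg$species
    decoy_ids <- c(decoy_ids, id)
  }

  # --- chromosome layout ---------------------------------------------------
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  order_of <- stats::setNames(
    lapply(seq_len(cfg$n_chromosomes), function(c)
      sprintf("BG%02d_%03d", c, seq_len(cfg$genes_per_chromosome))),
    chroms)
  slot_used <- stats::setNames(rep(0L, cfg$n_chromosomes), chroms)
  insert_at_slot <- function(chrom, ids) {
    slot_used[[chrom]] <<- slot_used[[chrom]] + 1L
    if (slot_used[[chrom]] > length(slot_anchors))
      stop("infeasible placement: no free slot on ", chrom)
    anchor <- slot_anchors[slot_used[[chrom]]]
    # anchors index the original background order; earlier insertions on
    # this chromosome shift positions, so locate the anchor gene by name
    anchor_gene <- sprintf("BG%02d_%03d", match(chrom, chroms), anchor)
    pos <- match(anchor_gene, order_of[[chrom]])
    order_of[[chrom]] <<- append(order_of[[chrom]], ids, after = pos)
  }
  k <- 0L
  for (i in seq_len(cfg$n_tandem_pairs)) {
    k <- k + 1L
    chrom <- chroms[(k - 1L) %% cfg$n_chromosomes + 1L]
    insert_at_slot(chrom, pair_ids[[k]]$ids)
    pair_ids[[k]]$chroms <- c(chrom, chrom)
  }
  for (i in seq_len(cfg$n_segmental_pairs)) {
    k <- k + 1L
    ca <- chroms[(k - 1L) %% cfg$n_chromosomes + 1L]
    cb <- chroms[k %% cfg$n_chromosomes + 1L]
    insert_at_slot(ca, pair_ids[[k]]$ids[1])
    insert_at_slot(cb, pair_ids[[k]]$ids[2])
    pair_ids[[k]]$chroms <- c(ca, cb)
  }
  extras <- c(singleton_ids, pseudo_id, decoy_ids)
  for (j in seq_along(extras)) {
    chrom <- chroms[(j - 1L) %% cfg$n_chromosomes + 1L]
    order_of[[chrom]] <- c(order_of[[chrom]], extras[j])
  }

  loci <- do.call(rbind, lapply(chroms, function(chrom) {
    ids <- order_of[[chrom]]
    len <- sample(1000:2500, length(ids), replace = TRUE)
    gap <- sample(500:4000, length(ids), replace = TRUE)
    start <- 1000L + cumsum(c(0L, utils::head(len + gap, -1L)))
    data.frame(gene_id = ids, chrom = chrom, start = start,
               end = start + len - 1L,
               strand = sample(c("+", "-"), length(ids), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  loci <- gene_loci(loci)

  # --- flank homology for segmental pairs ----------------------------------
  family_all <- c(members, pseudo_id)
  hom_rows <- list()
  flank_seed_pool <- sample.int(2147483646L, cfg$n_segmental_pairs * 2L * W + 1L)
  fs <- 0L
  for (k in seq_along(pair_ids)) {
    p <- pair_ids[[k]]
    if (p$mechanism != "segmental") {
      truth_pairs[[k]] <- data.frame(
        gene1 = p$ids[1], gene2 = p$ids[2], mechanism = p$mechanism,
        true_conserved = NA_integer_, target_ks = cfg$target_ks,
        omega = cfg$omega, species = cfg$species, stringsAsFactors = FALSE)
      next
    }
    fa <- .flank_genes(loci, p$ids[1], W, family_all)
    fb <- .flank_genes(loci, p$ids[2], W, family_all)
    n_slots <- min(length(fa), length(fb))
    kept <- 0L
    for (j in seq_len(n_slots)) {
      if (stats::runif(1) >= cfg$flank_retention) next
      kept <- kept + 1L
      hom_rows[[length(hom_rows) + 1L]] <-
        data.frame(gene1 = fa[j], gene2 = fb[j], stringsAsFactors = FALSE)
      anc <- paste(.random_codons(cfg$flank_codons), collapse = "")
      fs <- fs + 1L
      fp <- evolve_cds_pair(anc, cfg$target_ks, cfg$omega,
                            flank_seed_pool[fs])
      cds[[fa[j]]] <- fp[1]
      cds[[fb[j]]] <- fp[2]
    }
    truth_pairs[[k]] <- data.frame(
      gene1 = p$ids[1], gene2 = p$ids[2], mechanism = "segmental",
      true_conserved = kept, target_ks = cfg$target_ks, omega = cfg$omega,
      species = cfg$species, stringsAsFactors = FALSE)
  }
  homology <- if (length(hom_rows)) do.call(rbind, hom_rows)
              else data.frame(gene1 = character(0), gene2 = character(0))

  # background placeholders for genes without real sequences
  placeholder_prot <- paste(rep("MGSTA", 8), collapse = "")
  for (chrom in chroms) {
    for (id in order_of[[chrom]]) {
      if (!id %in% names(proteins)) proteins[[id]] <- placeholder_prot
      if (!id %in% names(cds)) cds[[id]] <- "ATGGGTAGCACCGCA"
    }
  }

  # --- domains, subfamilies ------------------------------------------------
  sub_of <- stats::setNames(rep("C2", length(family_all)), family_all)
  if (length(singleton_ids) >= 1) sub_of[singleton_ids[1]] <- "PXPH"
  if (length(singleton_ids) >= 2) sub_of[singleton_ids[2]] <- "SP"
  dom_rows <- lapply(family_all, function(id) {
    switch(sub_of[[id]],
      C2 = data.frame(gene_id = id, domain = "C2", start = 5L, end = 120L),
      PXPH = data.frame(gene_id = rep(id, 2), domain = c("PX", "PH"),
                        start = c(10L, 130L), end = c(120L, 230L)),
      SP = data.frame(gene_id = id, domain = "SignalPeptide",
                      start = 1L, end = 25L))
  })
  domains <- do.call(rbind, dom_rows)
  if (is.null(domains))
    domains <- data.frame(gene_id = character(0), domain = character(0),
                          start = integer(0), end = integer(0))

  motifs <- data.frame(
    motif = c("3", "4", "HKD"),
    pattern = c("IYIENQ[FY]F",
                paste0("[GK]GPR[EQ]PWHD[LIV]H[CS][KR][IL][ED]GPA[YW]",
                       "DVLTNFE[QE]RWRK[AQ]G[G][PW][KD]GLVK"),
                "H.K....D"),
    stringsAsFactors = FALSE)

  truth_genes <- data.frame(
    gene_id = c(members, pseudo_id, decoy_ids),
    is_member = c(rep(TRUE, length(members) + length(pseudo_id)),
                  rep(FALSE, length(decoy_ids))),
    subfamily = c(unname(sub_of[c(members, pseudo_id)]),
                  rep("unclassified", length(decoy_ids))),
    pseudogene = c(rep(FALSE, length(members)),
                   rep(TRUE, length(pseudo_id)),
                   rep(FALSE, length(decoy_ids))),
    species = unname(species_of[c(members, pseudo_id, decoy_ids)]),
    stringsAsFactors = FALSE)

  list(config = cfg,
       proteins = unlist(proteins),
       cds = unlist(cds),
       alignment = unlist(proteins[members]),
       loci = loci,
       homology = homology,
       domains = domains,
       motifs = motifs,
       species_of = unlist(species_of),
       truth = list(pairs = if (length(truth_pairs))
                      do.call(rbind, truth_pairs)
                    else data.frame(gene1 = character(0),
                                    gene2 = character(0),
                                    mechanism = character(0)),
                    genes = truth_genes,
                    hkd_positions = c(hkd1 = hkd1_pos, hkd2 = hkd2_pos)))
}

#' Write a simulated bundle to disk
#'
#' Emits protein FASTA, CDS FASTA, aligned FASTA (the planted, indel-free
#' alignment of family members), GFF3 gene order, homology TSV, domain TSV,
#' motif TSV and ground-truth JSON. Byte-stable given the config seed.
#'
#' @param bundle Output of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.faa"),
             cds = file.path(dir, "cds.fna"),
             alignment = file.path(dir, "alignment.faa"),
             genes = file.path(dir, "genes.gff3"),
             homology = file.path(dir, "homology.tsv"),
             domains = file.path(dir, "domains.tsv"),
             motifs = file.path(dir, "motifs.tsv"),
             truth = file.path(dir, "truth.json"))
  .write_fasta(bundle$proteins, paths[["proteins"]], "AA")
  .write_fasta(bundle$cds, paths[["cds"]], "DNA")
  .write_fasta(bundle$alignment, paths[["alignment"]], "AA")
  gr <- GenomicRanges::GRanges(
    seqnames = bundle$loci$chrom,
    ranges = IRanges::IRanges(bundle$loci$start, bundle$loci$end),
    strand = bundle$loci$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- bundle$loci$gene_id
  S4Vectors::mcols(gr)$source <- "famevol"
  rtracklayer::export(gr, paths[["genes"]], format = "gff3")
  .write_tsv(bundle$homology, paths[["homology"]])
  .write_tsv(bundle$domains, paths[["domains"]])
  .write_tsv(bundle$motifs, paths[["motifs"]])
  jsonlite::write_json(bundle$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
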