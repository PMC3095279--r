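# Shared fixtures. The default synthetic bundle is expensive enough to be
# worth caching across test files (fixed seed, deterministic).

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function(seed = 7) {
  key <- paste0("bundle", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_genome(sim_config(seed = seed))
  .fixture_env[[key]]
}

# gene-order table with the printed coordinates of the tandem pair on
# grape chromosome 11, plus neighboring background genes
grape_chr11_loci <- function() {
  gene_loci(data.frame(
    gene_id = c("N1", "VvPLD7", "VvPLD8", "N2", "N3"),
    chrom = "chr11",
    start = c(4600000L, 4654107L, 4658773L, 4700000L, 4750000L),
    end = c(4601000L, 4656834L, 4665399L, 4701000L, 4751000L),
    strand = c("+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE))
}

# the printed duplicated-gene table (pair, species, conserved flank count,
# mean Ks, date) shipped as a package fixture
dup_table <- function() {
  utils::read.table(system.file("extdata", "pld_duplications.tsv",
                                package = "famevol"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# alignment with two well-separated 4-taxon blocks: within-block sequences
# differ at a few sites, between-block at many
two_block_alignment <- function(seed = 11, ncol = 200) {
  set.seed(seed)
  alpha <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  baseA <- sample(alpha, ncol, replace = TRUE)
  baseB <- sample(alpha, ncol, replace = TRUE)
  perturb <- function(base, k) {
    i <- sample(ncol, k)
    base[i] <- sample(alpha, k, replace = TRUE)
    paste(base, collapse = "")
  }
  c(a1 = perturb(baseA, 3), a2 = perturb(baseA, 3),
    a3 = perturb(baseA, 3), a4 = perturb(baseA, 3),
    b1 = perturb(baseB, 3), b2 = perturb(baseB, 3),
    b3 = perturb(baseB, 3), b4 = perturb(baseB, 3))
}
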