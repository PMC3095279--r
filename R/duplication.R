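# Paralog-pair extraction from the family tree and classification of each
# pair as tandem (adjacent in the gene order) or segmental (conserved
# flanking protein-coding genes), following the flanking-window approach of
# Maher-style synteny checks.

#' Build a homology lookup from a pair table
#'
#' @param pairs `data.frame` with columns `gene1`, `gene2` (unordered,
#'   irreflexive pairs).
#' @return An environment-backed lookup used by [flanking_conservation()];
#'   also usable via `homology_partners()`.
#' @export
homology_map <- function(pairs) {
  env <- new.env(parent = emptyenv())
  add <- function(a, b) {
    cur <- env[[a]]
    env[[a]] <- unique(c(cur, b))
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- as.character(pairs$gene1[k])
      b <- as.character(pairs$gene2[k])
      if (a == b) next
      add(a, b)
      add(b, a)
    }
  }
  structure(list(env = env), class = "homology_map")
}

#' @rdname homology_map
#' @param map A `homology_map`.
#' @param gene_id Gene identifier.
#' @export
homology_partners <- function(map, gene_id) {
  p <- map$env[[gene_id]]
  if (is.null(p)) character(0) else p
}

#' Same-species paralog pairs at the terminal nodes of a tree
#'
#' Returns every cherry (two-leaf sister clade) whose two leaves carry the
#' same species tag, optionally requiring a minimum bootstrap support on the
#' cherry's node.
#'
#' @param tree `ape::phylo`; if `min_support` is used, node labels must hold
#'   numeric supports (as from [bootstrap_supports()]).
#' @param species_of Named character vector mapping every leaf to a species.
#' @param min_support Optional numeric; cherries on nodes with support below
#'   it are dropped.
#' @return `data.frame` with columns `gene1, gene2, species` (pair ordered
#'   lexicographically).
#' @export
terminal_paralog_pairs <- function(tree, species_of, min_support = NULL) {
  miss <- setdiff(tree$tip.label, names(species_of))
  if (length(miss))
    stop("species tag missing for leaves: ", paste(miss, collapse = ", "))
  n <- length(tree$tip.label)
  rows <- list()
  for (node in unique(tree$edge[, 1])) {
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(ch) == 2L && all(ch <= n)) {
      g <- sort(tree$tip.label[ch])
      if (species_of[[g[1]]] != species_of[[g[2]]]) next
      if (!is.null(min_support)) {
        lab <- tree$node.label[node - n]
        sup <- suppressWarnings(as.numeric(lab))
        if (is.na(sup) || sup < min_support) next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(gene1 = g[1], gene2 = g[2],
                   species = species_of[[g[1]]], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      species = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene1, out$gene2), , drop = FALSE]
}

.locus_of <- function(loci, gene_id) {
  i <- match(gene_id, loci$gene_id)
  if (is.na(i)) NULL else loci[i, , drop = FALSE]
}

#' Tandem-duplication test
#'
#' TRUE when both genes sit on the same chromosome with at most
#' `max_intervening` genes between them in the gene order ("same or
#' neighboring intergenic regions"). An unplaced gene gives `NA`
#' (undetermined), not an error.
#'
#' @param pair Character vector of two gene ids.
#' @param loci Ranked gene-order table from [gene_loci()].
#' @param max_intervening Maximum number of intervening genes (default 1).
#' @return `TRUE`, `FALSE`, or `NA`.
#' @export
tandem_test <- function(pair, loci, max_intervening = 1) {
  a <- .locus_of(loci, pair[1])
  b <- .locus_of(loci, pair[2])
  if (is.null(a) || is.null(b)) return(NA)
  if (a$chrom != b$chrom) return(FALSE)
  (abs(a$rank - b$rank) - 1L) <= max_intervening
}

# nearest `window` non-family genes on each side of a gene in its
# chromosome's order
.flank_genes <- function(loci, gene_id, window, family_ids) {
  g <- .locus_of(loci, gene_id)
  if (is.null(g)) return(NULL)
  chr <- loci[loci$chrom == g$chrom, , drop = FALSE]
  chr <- chr[order(chr$rank), , drop = FALSE]
  pos <- which(chr$gene_id == gene_id)
  eligible <- !(chr$gene_id %in% family_ids)
  up <- rev(chr$gene_id[seq_len(pos - 1L)][eligible[seq_len(pos - 1L)]])
  dn_idx <- if (pos < nrow(chr)) (pos + 1L):nrow(chr) else integer(0)
  dn <- chr$gene_id[dn_idx][eligible[dn_idx]]
  c(utils::head(up, window), utils::head(dn, window))
}

# exact maximum bipartite matching (Kuhn's augmenting paths); adj is a list
# over left nodes of integer vectors of right-node indices. Returns the
# matched pair indices.
.max_matching <- function(adj, n_right) {
  match_r <- rep(0L, n_right)
  try_kuhn <- function(u, seen) {
    for (v in adj[[u]]) {
      if (seen[v]) next
      seen[v] <- TRUE
      if (match_r[v] == 0L) {
        match_r[v] <<- u
        return(list(ok = TRUE, seen = seen))
      }
      prev <- match_r[v]
      match_r[v] <<- u
      res <- try_kuhn(prev, seen)
      if (res$ok) return(list(ok = TRUE, seen = res$seen))
      match_r[v] <<- prev
      seen <- res$seen
    }
    list(ok = FALSE, seen = seen)
  }
  for (u in seq_along(adj)) try_kuhn(u, rep(FALSE, n_right))
  match_r
}

#' Conserved flanking-gene count for a paralog pair
#'
#' Takes up to `window` protein-coding genes upstream and `window`
#' downstream of each paralog (family members themselves excluded; flanks at
#' chromosome ends are truncated) and counts a one-to-one maximum matching
#' of homologous pairs between the two flank sets.
#'
#' @inheritParams tandem_test
#' @param homology A [homology_map()] (or a pair `data.frame`, converted on
#'   the fly).
#' @param window Flank size per side (default 10).
#' @param family_ids Gene ids belonging to the family under study, excluded
#'   from flanks.
#' @return Integer in `0 .. 2*window`, or `NA` if either gene is unplaced.
#' @export
flanking_conservation <- function(pair, loci, homology, window = 10,
                                  family_ids = pair) {
  stopifnot(window >= 1)
  if (is.data.frame(homology)) homology <- homology_map(homology)
  fa <- .flank_genes(loci, pair[1], window, family_ids)
  fb <- .flank_genes(loci, pair[2], window, family_ids)
  if (is.null(fa) || is.null(fb)) return(NA_integer_)
  if (length(fa) == 0L || length(fb) == 0L) return(0L)
  adj <- lapply(fa, function(g) which(fb %in% homology_partners(homology, g)))
  m <- .max_matching(adj, length(fb))
  sum(m > 0L)
}

#' Matched conserved flanking pairs (for flanking-Ks summaries)
#'
#' Like [flanking_conservation()] but returns the matched gene-id pairs
#' themselves, so their Ks values can be estimated and averaged for dating.
#'
#' @inheritParams flanking_conservation
#' @return `data.frame` with columns `gene1` (flank of `pair[1]`), `gene2`.
#' @export
flanking_matches <- function(pair, loci, homology, window = 10,
                             family_ids = pair) {
  if (is.data.frame(homology)) homology <- homology_map(homology)
  fa <- .flank_genes(loci, pair[1], window, family_ids)
  fb <- .flank_genes(loci, pair[2], window, family_ids)
  empty <- data.frame(gene1 = character(0), gene2 = character(0))
  if (is.null(fa) || is.null(fb) || !length(fa) || !length(fb)) return(empty)
  adj <- lapply(fa, function(g) which(fb %in% homology_partners(homology, g)))
  m <- .max_matching(adj, length(fb))
  hit <- which(m > 0L)
  if (!length(hit)) return(empty)
  data.frame(gene1 = fa[m[hit]], gene2 = fb[hit], stringsAsFactors = FALSE)
}

#' Classify a paralog pair as tandem, segmental, or undetermined
#'
#' Tandem takes precedence (physical adjacency is the stronger signal);
#' otherwise the pair is segmental when at least `min_conserved` of its
#' flanking genes are conserved, else undetermined.
#'
#' @inheritParams flanking_conservation
#' @param max_intervening Passed to [tandem_test()].
#' @param min_conserved Minimum conserved flank count for a segmental call
#'   (default 1).
#' @return List with `gene1, gene2, mechanism, conserved_flank_count`.
#' @export
classify_duplication <- function(pair, loci, homology, max_intervening = 1,
                                 min_conserved = 1, window = 10,
                                 family_ids = pair) {
  td <- tandem_test(pair, loci, max_intervening)
  cnt <- flanking_conservation(pair, loci, homology, window, family_ids)
  mech <- if (isTRUE(td)) {
    "tandem"
  } else if (!is.na(cnt) && cnt >= min_conserved) {
    "segmental"
  } else {
    "undetermined"
  }
  list(gene1 = pair[1], gene2 = pair[2], mechanism = mech,
       conserved_flank_count = cnt)
}

#' Duplication report for a set of paralog pairs
#'
#' Classifies every pair and, when coding sequences are supplied, estimates
#' the Ks of each conserved flanking homolog pair (NG86), averages them with
#' the saturation cutoff, and dates the duplication with the species clock
#' rate — the schema of a duplicated-gene table (pair, conserved flank
#' count, mean Ks, date in Ma).
#'
#' @param pairs `data.frame` with columns `gene1, gene2` and optionally
#'   `species`.
#' @inheritParams classify_duplication
#' @param cds Optional named character vector of CDS for flank genes
#'   (pairwise codon alignment is taken position-by-position; flank CDS of a
#'   matched pair must be equal-length and gap-free).
#' @param rates Clock-rate table (see [clock_rates()]).
#' @param ks_cutoff Saturation cutoff for [mean_ks()].
#' @return `data.frame`, one row per pair.
#' @export
duplication_report <- function(pairs, loci, homology, cds = NULL,
                               rates = clock_rates(), max_intervening = 1,
                               min_conserved = 1, window = 10,
                               family_ids = NULL, ks_cutoff = 2.0) {
  if (is.data.frame(homology)) homology <- homology_map(homology)
  if (is.null(family_ids))
    family_ids <- unique(c(pairs$gene1, pairs$gene2))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    pr <- c(pairs$gene1[k], pairs$gene2[k])
    cl <- classify_duplication(pr, loci, homology, max_intervening,
                               min_conserved, window, family_ids)
    mks <- NA_real_
    age <- NA_real_
    if (!is.null(cds) && cl$mechanism == "segmental") {
      mm <- flanking_matches(pr, loci, homology, window, family_ids)
      ks <- vapply(seq_len(nrow(mm)), function(i) {
        c1 <- cds[[mm$gene1[i]]]
        c2 <- cds[[mm$gene2[i]]]
        if (is.null(c1) || is.null(c2) || nchar(c1) != nchar(c2))
          return(NA_real_)
        tryCatch(ng86_pair(c1, c2)$Ks, error = function(e) NA_real_)
      }, numeric(1))
      mks <- mean_ks(ks, ks_cutoff)
      if (!is.na(mks) && "species" %in% names(pairs)) {
        lam <- species_rate(pairs$species[k], rates)
        age <- round_half_up(date_duplication(mks, lam), 2)
      }
    }
    data.frame(gene1 = pr[1], gene2 = pr[2], mechanism = cl$mechanism,
               conserved_flank_count = cl$conserved_flank_count,
               mean_flanking_ks = mks, date_ma = age,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
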