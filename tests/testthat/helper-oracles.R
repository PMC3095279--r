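# Independent brute-force oracles. These deliberately share no code with
# the package implementation beyond the standard genetic code table.

.oracle_gc <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

# position-by-position scan for H.K....D, leftmost non-overlapping
oracle_scan_hkd <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- NULL
  i <- 1L
  while (i <= length(ch) - 7L) {
    if (ch[i] == "H" && ch[i + 2L] == "K" && ch[i + 7L] == "D") {
      hits <- rbind(hits, c(i, i + 7L))
      i <- i + 8L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(hits)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = hits[, 1], end = hits[, 2])
}

# NG86 site counts by explicit enumeration of the nine single-base mutants
oracle_site_counts <- function(codon) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    nonstop <- 0L
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      m <- b
      m[pos] <- alt
      aa <- .oracle_gc[[paste(m, collapse = "")]]
      if (aa == "*") next
      nonstop <- nonstop + 1L
      if (aa == .oracle_gc[[codon]]) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# exhaustive recursive enumeration of substitution pathways between two
# sense codons; pathways through stop codons are excluded (all-pathway
# fallback if every one is blocked)
oracle_pair_diffs <- function(c1, c2, allow_stop = FALSE) {
  recurse <- function(cur) {
    if (cur == c2) return(list(c(0, 0)))
    bc <- strsplit(cur, "", fixed = TRUE)[[1]]
    bt <- strsplit(c2, "", fixed = TRUE)[[1]]
    out <- list()
    for (pos in which(bc != bt)) {
      nb <- bc
      nb[pos] <- bt[pos]
      nxt <- paste(nb, collapse = "")
      if (!allow_stop && .oracle_gc[[nxt]] == "*") next
      step_syn <- .oracle_gc[[cur]] == .oracle_gc[[nxt]] &&
        .oracle_gc[[nxt]] != "*"
      for (tail in recurse(nxt))
        out[[length(out) + 1L]] <- tail + if (step_syn) c(1, 0) else c(0, 1)
    }
    out
  }
  paths <- recurse(c1)
  if (length(paths) == 0L && !allow_stop)
    return(oracle_pair_diffs(c1, c2, allow_stop = TRUE))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# brute-force gap-free column filter and pairwise p-distance
oracle_complete_deletion <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- integer(0)
  for (j in seq_len(ncol(m)))
    if (!any(m[, j] == "-")) keep <- c(keep, j)
  keep
}

oracle_p_distance <- function(r1, r2, keep) {
  a <- strsplit(r1, "", fixed = TRUE)[[1]][keep]
  b <- strsplit(r2, "", fixed = TRUE)[[1]][keep]
  sum(a != b) / length(keep)
}

# fixed-width regex motif scan, leftmost non-overlapping
oracle_scan_fixed <- function(seq, pattern, width) {
  hits <- NULL
  i <- 1L
  n <- nchar(seq)
  while (i <= n - width + 1L) {
    if (grepl(paste0("^", pattern, "$"), substr(seq, i, i + width - 1L),
              perl = TRUE)) {
      hits <- rbind(hits, c(i, i + width - 1L))
      i <- i + width
    } else {
      i <- i + 1L
    }
  }
  if (is.null(hits)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = hits[, 1], end = hits[, 2])
}

random_protein <- function(n, alphabet = setdiff(LETTERS, c("B", "J", "O",
                                                            "U", "X", "Z"))) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

sense_codons <- function() {
  names(.oracle_gc)[.oracle_gc != "*"]
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}
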