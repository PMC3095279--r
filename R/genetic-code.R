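# Internal genetic-code tables shared by the Ka/Ks estimator and the
# codon-level simulator. All derived from the standard code
# (Biostrings::GENETIC_CODE); alternative code tables are out of scope.

.BASES <- c("A", "C", "G", "T")

.GC <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

.SENSE_CODONS <- names(.GC)[.GC != "*"]
.STOP_CODONS <- names(.GC)[.GC == "*"]

.aa_of <- function(codon) unname(.GC[codon])

.is_stop <- function(codon) codon %in% .STOP_CODONS

# The 9 single-base mutants of a codon (3 per position), as a data.frame
# with columns pos, alt_base, codon.
.single_mutants <- function(codon) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(.BASES, b[pos])) {
      m <- b
      m[pos] <- alt
      k <- k + 1L
      out[[k]] <- list(pos = pos, alt = alt, codon = paste(m, collapse = ""))
    }
  }
  do.call(rbind.data.frame, out)
}

# Per sense codon: NG86 fractional synonymous sites (stop mutants removed
# from each position's denominator) and the concrete synonymous /
# nonsynonymous single-base substitutions available (stops excluded).
.CODON_TABLES <- local({
  tabs <- list()
  for (cd in .SENSE_CODONS) {
    mut <- .single_mutants(cd)
    mut$aa <- .aa_of(mut$codon)
    mut$stop <- mut$aa == "*"
    mut$syn <- !mut$stop & mut$aa == .aa_of(cd)
    s <- 0
    for (pos in 1:3) {
      sub <- mut[mut$pos == pos, ]
      denom <- sum(!sub$stop)
      if (denom > 0) s <- s + sum(sub$syn) / denom
    }
    tabs[[cd]] <- list(
      s = s, n = 3 - s,
      syn = mut[mut$syn, c("pos", "alt", "codon")],
      non = mut[!mut$syn & !mut$stop, c("pos", "alt", "codon")]
    )
  }
  tabs
})

.check_sense_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("expected a single 3-base codon, got: ", paste(codon, collapse = ","))
  codon <- toupper(codon)
  if (.is_stop(codon)) stop("stop codon not allowed: ", codon)
  if (!codon %in% .SENSE_CODONS) stop("invalid codon: ", codon)
  codon
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
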