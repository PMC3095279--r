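#' Nei-Gojobori (1986) synonymous and nonsynonymous site counts for a codon
#'
#' For each codon position the synonymous fraction is the number of the three
#' single-base mutations that preserve the encoded amino acid, divided by the
#' number of the three that do not create a stop codon (mutations to stop
#' codons are excluded from the denominator). `s` is the sum over the three
#' positions and `n = 3 - s`.
#'
#' @param codon A single sense codon (3 characters over ACGT).
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' ng86_site_counts("TTT") # s = 1/3
#' ng86_site_counts("ATG") # s = 0
#' @export
ng86_site_counts <- function(codon) {
  codon <- .check_sense_codon(codon)
  tab <- .CODON_TABLES[[codon]]
  c(s = tab$s, n = tab$n)
}

#' Jukes-Cantor distance correction
#'
#' Converts a proportion of differing sites into an estimated number of
#' substitutions per site, `d = -(3/4) * ln(1 - 4p/3)`.
#'
#' @param p Proportion of observed differences, `0 <= p < 3/4`.
#' @return Corrected distance (substitutions per site).
#' @export
jukes_cantor <- function(p) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("p must be a finite proportion >= 0")
  if (any(p >= 0.75))
    stop("saturation: p >= 3/4, Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

# Pathway-averaged (sd, nd) for one codon pair. Codons differing at 2-3
# positions are scored by averaging over all orderings of the single-base
# steps; orderings passing through a stop codon are dropped. If every
# ordering is blocked by stops (not reachable for sense endpoints in the
# standard code in practice), all orderings are used with steps to/from
# stops scored as nonsynonymous.
.ng86_codon_diff <- local({
  cache <- new.env(parent = emptyenv())
  score_path <- function(c1, bases2, pos_order, allow_stop) {
    cur <- strsplit(c1, "", fixed = TRUE)[[1]]
    sd <- 0
    nd <- 0
    for (p in pos_order) {
      nxt <- cur
      nxt[p] <- bases2[p]
      cod_cur <- paste(cur, collapse = "")
      cod_nxt <- paste(nxt, collapse = "")
      if (!allow_stop && .is_stop(cod_nxt)) return(NULL)
      if (.GC[cod_cur] == .GC[cod_nxt] && .GC[cod_nxt] != "*") {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  function(c1, c2) {
    key <- paste0(c1, c2)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
    b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
    pos <- which(b1 != b2)
    if (length(pos) == 0L) {
      res <- c(sd = 0, nd = 0)
    } else if (length(pos) == 1L) {
      syn <- .GC[c1] == .GC[c2]
      res <- c(sd = as.numeric(syn), nd = as.numeric(!syn))
    } else {
      orders <- if (length(pos) == 2L) {
        list(pos, rev(pos))
      } else {
        idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
        lapply(idx, function(i) pos[i])
      }
      paths <- Filter(Negate(is.null),
                      lapply(orders, function(o) score_path(c1, b2, o, FALSE)))
      if (length(paths) == 0L)
        paths <- lapply(orders, function(o) score_path(c1, b2, o, TRUE))
      m <- do.call(rbind, paths)
      res <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
    }
    cache[[key]] <- res
    res
  }
})

# Per-codon NG86 profile of a gap-free codon alignment: site counts for each
# sequence and pathway-averaged differences per codon column. Shared by
# ng86_pair() and sliding_window_omega() so windows are simple slice sums.
.ng86_profile <- function(seq1, seq2) {
  cod1 <- .split_codons(toupper(seq1))
  cod2 <- .split_codons(toupper(seq2))
  if (length(cod1) != length(cod2))
    stop("codon sequences differ in length")
  if (length(cod1) == 0L) stop("empty codon alignment")
  bad <- which(!(cod1 %in% .SENSE_CODONS) | !(cod2 %in% .SENSE_CODONS))
  if (length(bad))
    stop("non-sense codon at codon position ", bad[1], ": ",
         cod1[bad[1]], "/", cod2[bad[1]])
  nc <- length(cod1)
  s1 <- vapply(cod1, function(cd) .CODON_TABLES[[cd]]$s, numeric(1))
  s2 <- vapply(cod2, function(cd) .CODON_TABLES[[cd]]$s, numeric(1))
  dm <- t(vapply(seq_len(nc),
                 function(i) .ng86_codon_diff(cod1[i], cod2[i]),
                 numeric(2)))
  list(n_codons = nc, s1 = unname(s1), s2 = unname(s2),
       sd = dm[, 1], nd = dm[, 2])
}

.ng86_from_profile <- function(prof, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(prof$n_codons)
  nc <- length(idx)
  S <- (sum(prof$s1[idx]) + sum(prof$s2[idx])) / 2
  N <- 3 * nc - S
  Sd <- sum(prof$sd[idx])
  Nd <- sum(prof$nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- if (is.na(pS) || pS >= 0.75) NA_real_ else jukes_cantor(pS)
  Ka <- if (is.na(pN) || pN >= 0.75) NA_real_ else jukes_cantor(pN)
  omega <- if (is.na(Ka) || is.na(Ks)) {
    NA_real_
  } else if (Ks == 0) {
    if (Ka == 0) NA_real_ else Inf
  } else {
    Ka / Ks
  }
  list(n_codons = nc, S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, Ka = Ka, Ks = Ks, omega = omega)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites averaged over
#' the two sequences, scores each differing codon column by equal-weight
#' averaging over all mutational pathways that avoid stop codons, and applies
#' the Jukes-Cantor correction to the proportions `pS = Sd/S` and `pN = Nd/N`.
#'
#' Saturated proportions (`>= 3/4`) yield `NA` for the corresponding
#' distance. When `Ka = Ks = 0` the ratio `omega` is `NA` (undefined, not 1);
#' when `Ks = 0 < Ka` it is `Inf`.
#'
#' @param seq1,seq2 Gap-free coding sequences of equal length (multiple of 3,
#'   over ACGT, no internal stop codons), or a list as returned by
#'   [codon_align()] passed as `seq1`.
#' @return A list with elements `n_codons, S, N, Sd, Nd, pS, pN, Ka, Ks,
#'   omega`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @examples
#' ng86_pair("TTT", "TTC") # one synonymous difference
#' @export
ng86_pair <- function(seq1, seq2 = NULL) {
  if (is.list(seq1) && is.null(seq2)) {
    seq2 <- seq1$seq2
    seq1 <- seq1$seq1
  }
  .ng86_from_profile(.ng86_profile(seq1, seq2))
}

#' Back-translate an aligned protein pair into a gap-free codon alignment
#'
#' Each CDS must translate (standard code) to its ungapped protein row; a
#' trailing stop codon on the CDS is tolerated and dropped. Codon columns
#' where either row has an alignment gap or an ambiguous base are removed.
#'
#' @param prot1,prot2 Aligned amino-acid strings of equal length ('-' gaps).
#' @param cds1,cds2 Unaligned coding sequences for the two proteins.
#' @return List with `seq1`, `seq2` (equal-length gap-free codon strings) and
#'   `n_codons`.
#' @export
codon_align <- function(prot1, prot2, cds1, cds2) {
  if (nchar(prot1) != nchar(prot2))
    stop("aligned protein rows differ in length")
  a1 <- strsplit(toupper(prot1), "", fixed = TRUE)[[1]]
  a2 <- strsplit(toupper(prot2), "", fixed = TRUE)[[1]]
  cods <- lapply(list(cds1, cds2), function(cds) {
    cds <- toupper(cds)
    cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
    .split_codons(cds)
  })
  prots <- list(a1[a1 != "-"], a2[a2 != "-"])
  for (k in 1:2) {
    cod <- cods[[k]]
    # tolerate one trailing stop codon
    if (length(cod) == length(prots[[k]]) + 1L && .is_stop(cod[length(cod)]))
      cods[[k]] <- cod <- cod[-length(cod)]
    if (length(cod) != length(prots[[k]]))
      stop("CDS ", k, " has ", length(cod), " codons but ungapped protein has ",
           length(prots[[k]]), " residues")
    aa <- ifelse(cod %in% names(.GC), unname(.GC[cod]), NA_character_)
    chk <- which(!is.na(aa) & aa != prots[[k]])
    if (length(chk))
      stop("CDS ", k, " translation mismatch at residue ", chk[1],
           ": codon ", cod[chk[1]], " (", aa[chk[1]], ") vs protein ",
           prots[[k]][chk[1]])
  }
  # map alignment columns back to codon indices of each sequence
  i1 <- cumsum(a1 != "-")
  i2 <- cumsum(a2 != "-")
  keep_cod1 <- character(0)
  keep_cod2 <- character(0)
  for (col in seq_along(a1)) {
    if (a1[col] == "-" || a2[col] == "-") next
    c1 <- cods[[1]][i1[col]]
    c2 <- cods[[2]][i2[col]]
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next # ambiguous base
    keep_cod1 <- c(keep_cod1, c1)
    keep_cod2 <- c(keep_cod2, c2)
  }
  list(seq1 = paste(keep_cod1, collapse = ""),
       seq2 = paste(keep_cod2, collapse = ""),
       n_codons = length(keep_cod1))
}

#' Sliding-window Ka/Ks scan
#'
#' Scores fixed-length windows (default 300 nt) advanced by a fixed step
#' (default 50 nt) along a gap-free codon alignment with [ng86_pair()].
#' Windows are laid out on nucleotide coordinates exactly as printed
#' (`300 bp` / `50 bp`); codons only partially covered by a window are
#' dropped from that window's score. Offsets run while a full window fits,
#' giving `floor((L - window)/step) + 1` windows. An alignment shorter than
#' the window is scored as a single whole-alignment window with a warning.
#'
#' @inheritParams ng86_pair
#' @param window_nt,step_nt Window length and step, nucleotides.
#' @return `data.frame` with window coordinates (1-based nt, inclusive) and
#'   the per-window NG86 statistics.
#' @export
sliding_window_omega <- function(seq1, seq2 = NULL, window_nt = 300,
                                 step_nt = 50) {
  if (is.list(seq1) && is.null(seq2)) {
    seq2 <- seq1$seq2
    seq1 <- seq1$seq1
  }
  stopifnot(window_nt >= 3, step_nt >= 1)
  L <- nchar(seq1)
  prof <- .ng86_profile(seq1, seq2)
  if (L < window_nt) {
    warning("alignment (", L, " nt) shorter than window (", window_nt,
            " nt); scoring one whole-alignment window")
    starts <- 1L
    ends <- L
  } else {
    starts <- seq(1L, L - window_nt + 1L, by = step_nt)
    ends <- starts + window_nt - 1L
  }
  rows <- lapply(seq_along(starts), function(w) {
    s <- starts[w]
    e <- ends[w]
    # codon i occupies nt 3i-2 .. 3i; keep codons fully inside the window
    first <- as.integer(ceiling((s + 2L) / 3L))
    last <- as.integer(floor(e / 3L))
    if (last < first) return(NULL)
    res <- .ng86_from_profile(prof, first:last)
    data.frame(start = s, end = e, n_codons = res$n_codons, S = res$S,
               N = res$N, Sd = res$Sd, Nd = res$Nd, Ka = res$Ka, Ks = res$Ks,
               omega = res$omega)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean synonymous distance with saturation cutoff
#'
#' Averages a set of pairwise Ks values after discarding values above the
#' saturation cutoff (default 2.0), as used to summarize the Ks of conserved
#' flanking gene pairs for dating.
#'
#' @param values Numeric Ks values (non-negative; `NA`s dropped).
#' @param cutoff Saturation cutoff; values above it are discarded.
#' @return Mean of retained values, or `NA` if none remain.
#' @export
mean_ks <- function(values, cutoff = 2.0) {
  values <- values[!is.na(values)]
  if (any(values < 0)) stop("negative Ks value")
  keep <- values[values <= cutoff]
  if (length(keep) == 0L) return(NA_real_)
  mean(keep)
}
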