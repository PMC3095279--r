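# Family membership from the duplicated HxKxxxxD catalytic motif, pseudogene
# calling from premature in-frame stops, and subfamily classification from
# N-terminal domain annotations.

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

.HKD_PATTERN <- "H.K....D"

.check_protein <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .AA_ALPHABET)
  if (length(bad))
    stop("invalid amino-acid character '", chars[bad[1]], "' at position ",
         bad[1])
  paste(chars, collapse = "")
}

#' Scan a protein for HxKxxxxD (HKD) catalytic motifs
#'
#' Finds every non-overlapping match of the 8-residue pattern H, any, K,
#' any, any, any, any, D, scanning left to right (after a match the scan
#' resumes at the following residue).
#'
#' @param sequence Amino-acid string (single-letter codes; X and `*`
#'   permitted).
#' @return `data.frame` with 1-based inclusive columns `start`, `end`; zero
#'   rows if there is no match (an empty sequence is not an error).
#' @examples
#' scan_hkd("HAKWWWWD")
#' @export
scan_hkd <- function(sequence) {
  if (nchar(sequence) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  sequence <- .check_protein(sequence)
  m <- gregexpr(.HKD_PATTERN, sequence)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# keep hits whose starts are at least min_separation apart, left to right
.separated_hits <- function(hits, min_separation) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- 1L
  last <- hits$start[1]
  for (i in 2:nrow(hits)) {
    if (hits$start[i] - last >= min_separation) {
      keep <- c(keep, i)
      last <- hits$start[i]
    }
  }
  hits[keep, , drop = FALSE]
}

.check_cds <- function(cds) {
  chars <- strsplit(toupper(cds), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid CDS character '", chars[bad[1]], "' at position ", bad[1])
  paste(chars, collapse = "")
}

#' Family membership and pseudogene status for one candidate gene
#'
#' A gene is a family member when its protein carries at least two
#' well-separated HKD motifs. It is flagged as a pseudogene when its coding
#' sequence contains an in-frame stop codon before the final codon (a
#' trailing partial codon is trimmed first).
#'
#' @param sequence Amino-acid string of the candidate protein.
#' @param cds Optional nucleotide coding sequence.
#' @param min_separation Minimum distance between the starts of two HKD hits
#'   for them to count as distinct domains (residues). The two catalytic
#'   motifs of an active enzyme sit hundreds of residues apart, so the
#'   default of 50 only guards against re-counting one region.
#' @return List with `is_member`, `pseudogene`, `hkd_hits` (data.frame of
#'   retained spans), `n_hkd`.
#' @export
qualify_member <- function(sequence, cds = NULL, min_separation = 50) {
  hits <- .separated_hits(scan_hkd(sequence), min_separation)
  pseudo <- FALSE
  if (!is.null(cds) && !is.na(cds) && nchar(cds) >= 3L) {
    cds <- .check_cds(cds)
    cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
    cod <- .split_codons(cds)
    internal <- cod[-length(cod)]
    pseudo <- any(internal %in% .STOP_CODONS)
  }
  list(is_member = nrow(hits) >= 2L, pseudogene = pseudo,
       hkd_hits = hits, n_hkd = nrow(hits))
}

#' Subfamily from N-terminal domain annotations
#'
#' `C2` when a C2 domain is present; `PXPH` when both PX and PH are present
#' (and no C2); `SP` when a signal peptide is present and none of C2/PX/PH;
#' otherwise `unclassified`. Conflicting annotation sets (e.g. C2 together
#' with PX+PH) are resolved by the precedence C2 > PXPH > SP with a warning.
#'
#' @param annotations `data.frame` of domain annotations for one gene (see
#'   [read_domain_table()]) or a character vector of domain names.
#' @return One of `"C2"`, `"PXPH"`, `"SP"`, `"unclassified"`.
#' @export
classify_subfamily <- function(annotations) {
  doms <- if (is.data.frame(annotations)) annotations$domain else annotations
  doms <- unique(as.character(doms))
  has <- function(d) d %in% doms
  c2 <- has("C2")
  pxph <- has("PX") && has("PH")
  sp <- has("SignalPeptide")
  if ((c2 && (pxph || sp)) || (pxph && sp))
    warning("conflicting domain annotations (", paste(doms, collapse = ","),
            "); applying precedence C2 > PXPH > SP")
  if (c2) return("C2")
  if (pxph) return("PXPH")
  if (sp && !has("PX") && !has("PH")) return("SP")
  "unclassified"
}

#' Identify family members across a protein set
#'
#' Applies [qualify_member()] and [classify_subfamily()] to every protein,
#' producing one assignment row per gene.
#'
#' @param proteins Named character vector of protein sequences.
#' @param cds Optional named character vector of coding sequences.
#' @param domains Optional domain-annotation `data.frame`
#'   (see [read_domain_table()]).
#' @param min_separation Passed to [qualify_member()].
#' @return `data.frame` with columns `gene_id, is_member, subfamily,
#'   n_hkd, hkd_spans, pseudogene`.
#' @export
identify_family <- function(proteins, cds = NULL, domains = NULL,
                            min_separation = 50) {
  rows <- lapply(names(proteins), function(id) {
    q <- qualify_member(proteins[[id]],
                        cds = if (!is.null(cds) && id %in% names(cds))
                          cds[[id]] else NULL,
                        min_separation = min_separation)
    sub <- if (!is.null(domains)) {
      ann <- domains[domains$gene_id == id, , drop = FALSE]
      if (nrow(ann)) classify_subfamily(ann) else "unclassified"
    } else "unclassified"
    data.frame(gene_id = id, is_member = q$is_member, subfamily = sub,
               n_hkd = q$n_hkd,
               hkd_spans = paste(sprintf("%d-%d", q$hkd_hits$start,
                                         q$hkd_hits$end), collapse = ";"),
               pseudogene = q$pseudogene, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
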