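# Motif-architecture analysis: scan proteins with user-supplied
# regular-expression motifs, partition hits around the two HKD domains into
# N-terminal / middle / C-terminal regions, and compare shared and
# subfamily-specific motif sets.

#' Scan a protein with regular-expression motifs
#'
#' Finds, per motif, all non-overlapping matches, leftmost first (the scan
#' resumes after each match).
#'
#' @param sequence Amino-acid string.
#' @param defs `data.frame` with columns `motif` (id) and `pattern`
#'   (regular expression), as from [read_motif_table()].
#' @return `data.frame` with columns `motif, start, end` (1-based inclusive
#'   spans), sorted by `start`.
#' @export
scan_motifs <- function(sequence, defs) {
  stopifnot(is.data.frame(defs), all(c("motif", "pattern") %in% names(defs)))
  rows <- lapply(seq_len(nrow(defs)), function(k) {
    pat <- defs$pattern[k]
    m <- tryCatch(gregexpr(pat, sequence, perl = TRUE)[[1]],
                  error = function(e)
                    stop("invalid pattern for motif '", defs$motif[k], "': ",
                         conditionMessage(e)))
    if (m[1] == -1L) return(NULL)
    data.frame(motif = defs$motif[k], start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0)))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition motif hits into the three regions around the HKD domains
#'
#' N-terminal: the hit ends before the first HKD domain starts. Middle: the
#' hit overlaps the interval from the start of HKD1 to the end of HKD2 (the
#' region in and between the two HKD domains). C-terminal: the hit starts
#' after HKD2 ends. With missing HKD spans all hits are tagged
#' `"unpartitioned"`.
#'
#' @param hits `data.frame` from [scan_motifs()].
#' @param hkd1,hkd2 Numeric length-2 spans `(start, end)` of the two HKD
#'   domains; `hkd1` must end before `hkd2` starts.
#' @return `hits` with an added `region` column.
#' @export
partition_regions <- function(hits, hkd1 = NULL, hkd2 = NULL) {
  if (is.null(hkd1) || is.null(hkd2) || anyNA(hkd1) || anyNA(hkd2)) {
    hits$region <- rep("unpartitioned", nrow(hits))
    return(hits)
  }
  if (hkd1[2] >= hkd2[1]) stop("hkd1 must end before hkd2 starts")
  hits$region <- vapply(seq_len(nrow(hits)), function(i) {
    if (hits$end[i] < hkd1[1]) return("N-terminal")
    if (hits$start[i] > hkd2[2]) return("C-terminal")
    "middle"
  }, character(1))
  hits
}

#' Motif architecture of a protein set
#'
#' Scans each protein, locates its HKD domains with [scan_hkd()] (filtered
#' by the membership separation rule) and partitions hits into regions.
#'
#' @param proteins Named character vector of protein sequences.
#' @param defs Motif-definition table.
#' @param min_separation HKD-hit separation passed to [qualify_member()].
#' @return `data.frame` with columns `gene_id, motif, start, end, region`.
#' @export
motif_architecture <- function(proteins, defs, min_separation = 50) {
  rows <- lapply(names(proteins), function(id) {
    hits <- scan_motifs(proteins[[id]], defs)
    hkd <- .separated_hits(scan_hkd(proteins[[id]]), min_separation)
    if (nrow(hkd) >= 2L) {
      hits <- partition_regions(hits, c(hkd$start[1], hkd$end[1]),
                                c(hkd$start[2], hkd$end[2]))
    } else {
      hits <- partition_regions(hits, NULL, NULL)
    }
    if (nrow(hits)) cbind(gene_id = id, hits, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      region = character(0))
  rownames(out) <- NULL
  out
}

#' Presence/absence matrix of motifs across proteins
#'
#' @param architecture Output of [motif_architecture()] (or any table with
#'   `gene_id` and `motif`).
#' @param proteins Gene ids to include as rows (default: those observed).
#' @param motifs Motif ids to include as columns (default: those observed).
#' @return Logical matrix proteins x motifs.
#' @export
presence_matrix <- function(architecture, proteins = NULL, motifs = NULL) {
  if (is.null(proteins)) proteins <- unique(architecture$gene_id)
  if (is.null(motifs)) motifs <- unique(architecture$motif)
  m <- matrix(FALSE, length(proteins), length(motifs),
              dimnames = list(proteins, as.character(motifs)))
  if (nrow(architecture)) {
    keep <- architecture$gene_id %in% proteins &
      as.character(architecture$motif) %in% as.character(motifs)
    a <- architecture[keep, , drop = FALSE]
    m[cbind(a$gene_id, as.character(a$motif))] <- TRUE
  }
  m
}

#' Shared and group-specific motifs between two subfamilies
#'
#' A motif is shared when its within-group prevalence reaches `threshold`
#' in both groups; group-specific when it reaches the threshold in exactly
#' one. The default threshold 0.5 tolerates member-level motif losses.
#'
#' @param mat Logical presence matrix (proteins x motifs).
#' @param groups Named character vector: protein id -> group label.
#' @param group_a,group_b The two group labels to compare.
#' @param threshold Prevalence threshold in `[0, 1]`.
#' @return List with `shared`, `a_specific`, `b_specific`, `neither`
#'   (motif-id character vectors) and the prevalence matrix.
#' @export
shared_motifs <- function(mat, groups, group_a, group_b, threshold = 0.5) {
  ga <- names(groups)[groups == group_a]
  gb <- names(groups)[groups == group_b]
  ga <- intersect(ga, rownames(mat))
  gb <- intersect(gb, rownames(mat))
  if (!length(ga) || !length(gb)) stop("both groups must be non-empty")
  prev_a <- colMeans(mat[ga, , drop = FALSE])
  prev_b <- colMeans(mat[gb, , drop = FALSE])
  in_a <- prev_a >= threshold
  in_b <- prev_b >= threshold
  list(shared = colnames(mat)[in_a & in_b],
       a_specific = colnames(mat)[in_a & !in_b],
       b_specific = colnames(mat)[!in_a & in_b],
       neither = colnames(mat)[!in_a & !in_b],
       prevalence = rbind(a = prev_a, b = prev_b))
}
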