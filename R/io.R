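# File-format helpers. FASTA via Biostrings, GFF3 via rtracklayer, tables
# as plain TSV.

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read coding sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of nucleotide sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

.write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' TSV with header `gene_id, domain, start, end` (1-based inclusive residue
#' coordinates). Domains are expected among C2, PX, PH, SignalPeptide.
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_domain_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "domain", "start", "end")
  if (!all(need %in% names(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a motif-definition table
#'
#' TSV with header `motif, pattern`; patterns are amino-acid regular
#' expressions such as `IYIENQ[FY]F`.
#' @param path TSV file.
#' @return `data.frame` with columns `motif`, `pattern`.
#' @export
read_motif_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("motif", "pattern") %in% names(d)))
    stop("motif table must have columns: motif, pattern")
  d
}

#' Read a homology map
#'
#' Two-column TSV (header `gene1, gene2`) of gene-id pairs declared
#' homologous; treated as symmetric and irreflexive.
#' @param path TSV file.
#' @return `data.frame` with columns `gene1`, `gene2`.
#' @export
read_homology_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("homology map needs two columns")
  names(d)[1:2] <- c("gene1", "gene2")
  d[d$gene1 != d$gene2, 1:2]
}

#' Read gene loci from GFF3 or a BED-like TSV
#'
#' GFF3 input (`.gff`/`.gff3`) is parsed with rtracklayer; `gene` features
#' are kept and the identifier is taken from the `ID` (or `Name`) attribute.
#' TSV input needs columns `gene_id, chrom, start, end, strand`. Genes are
#' ranked 0-based within each chromosome by start coordinate (strand
#' ignored).
#'
#' @param path Input file.
#' @return `data.frame` of gene loci with a `rank` column (see
#'   [gene_loci()]).
#' @export
read_gene_loci <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::import(path)
    g <- g[g$type == "gene"]
    id <- if (!is.null(g$ID)) g$ID else g$Name
    df <- data.frame(gene_id = as.character(id),
                     chrom = as.character(GenomicRanges::seqnames(g)),
                     start = GenomicRanges::start(g),
                     end = GenomicRanges::end(g),
                     strand = as.character(GenomicRanges::strand(g)),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  }
  gene_loci(df)
}

#' Build a ranked gene-order table
#'
#' Validates coordinates and assigns each gene its 0-based rank in the
#' chromosomal gene order sorted by start coordinate.
#'
#' @param df `data.frame` with columns `gene_id, chrom, start, end, strand`.
#' @return The same `data.frame`, sorted, with a `rank` column.
#' @export
gene_loci <- function(df) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$strand)) df$strand <- "+"
  if (any(df$start > df$end)) stop("gene with start > end")
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in gene table")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$rank <- as.integer(stats::ave(seq_len(nrow(df)), df$chrom,
                                   FUN = seq_along)) - 1L
  rownames(df) <- NULL
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
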