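# Neighbor-joining phylogeny from a protein alignment: p-distance with
# complete deletion, deterministic Saitou-Nei agglomeration, column
# bootstrap, and anchor-based subgroup labelling. Trees are ape "phylo"
# objects throughout; only the NJ agglomeration itself is implemented here
# (deterministic tie-breaking and negative-branch clamping are part of the
# contract).

.as_aln_matrix <- function(aln) {
  if (inherits(aln, "AAStringSet") || inherits(aln, "DNAStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  if (!is.character(aln) || is.null(names(aln)))
    stop("alignment must be a named character vector or XStringSet")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Columns retained under complete deletion
#'
#' Returns, in order, the indices of alignment columns containing no gap
#' (`-`) in any row; every other column is excluded before distance
#' calculation.
#'
#' @param aln Named character vector of equal-length aligned sequences (or
#'   an `XStringSet`).
#' @return Integer vector of 1-based column indices.
#' @export
complete_deletion <- function(aln) {
  m <- .as_aln_matrix(aln)
  keep <- which(colSums(m == "-") == 0L)
  if (length(keep) == 0L) stop("no comparable sites: every column has a gap")
  keep
}

#' Pairwise p-distance matrix under complete deletion
#'
#' `d(i, j)` is the proportion of retained (gap-free) columns at which rows
#' `i` and `j` differ.
#'
#' @inheritParams complete_deletion
#' @return Symmetric numeric matrix with the alignment ids as dimnames.
#' @export
p_distance_matrix <- function(aln) {
  m <- .as_aln_matrix(aln)
  m <- m[, complete_deletion(aln), drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  L <- ncol(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- sum(m[i, ] != m[j, ]) / L
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion with two
#' determinism/robustness conventions: (i) when several pairs tie for the
#' minimal Q (within 1e-12), the pair whose subtrees contain the
#' lexicographically smallest leaf ids is joined; (ii) a negative branch
#' length is clamped to 0 and the deficit transferred to its sister branch,
#' preserving the path length between the joined nodes.
#'
#' @param D Symmetric distance matrix with taxon ids as dimnames (n >= 3).
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D needs taxon ids as dimnames")
  if (any(D < 0)) stop("negative distance entry")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  ids <- rownames(D)
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  # active nodes: newick fragment + smallest contained leaf id (tie-break key)
  nwk <- ids
  key <- ids
  d <- D
  while (length(nwk) > 3L) {
    nn <- length(nwk)
    R <- rowSums(d)
    Q <- (nn - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1L, function(rc) {
      ks <- sort(c(key[rc[1]], key[rc[2]]))
      paste(ks, collapse = "\r")
    })
    best <- cand[order(ck)[1L], ]
    i <- best[[1]]
    j <- best[[2]]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    mkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(nn), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nwk <- c(nwk[keep], merged)
    key <- c(key[keep], mkey)
  }
  # resolve the final three nodes around a central vertex
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb), ",",
                nwk[3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

# Canonical bipartition keys for every internal edge of an unrooted tree:
# the side of the split NOT containing the overall smallest leaf label,
# sorted and collapsed. Trivial splits (single leaf) are skipped.
.bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  anchor <- sort(labs)[1]
  for (p in parts) {
    if (length(p) <= 1L || length(p) >= n - 1L) next
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# node -> bipartition key (NA for trivial/root), aligned with internal
# node numbering of the phylo object
.node_keys <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  anchor <- sort(labs)[1]
  keys <- rep(NA_character_, tree$Nnode)
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) <= 1L || length(p) >= n - 1L) next
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    keys[k] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement (to the original length) `replicates` times,
#' rebuilds the tree per replicate, and records for each internal edge the
#' percentage of replicate trees containing the same bipartition
#' (branch lengths and rooting ignored). Each replicate uses a seed derived
#' deterministically from `seed` and the replicate index, so increasing
#' `replicates` does not reshuffle earlier replicates.
#'
#' @inheritParams complete_deletion
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer root seed.
#' @return `ape::phylo` with supports (percent, 0-100) as `node.label`;
#'   trivial/root nodes get `NA`.
#' @export
bootstrap_supports <- function(aln, replicates = 1000, seed = 1) {
  stopifnot(replicates >= 1)
  m <- .as_aln_matrix(aln)
  main <- nj_tree(p_distance_matrix(aln))
  counts <- new.env(parent = emptyenv())
  ok <- 0L
  for (r in seq_len(replicates)) {
    rs <- (as.numeric(seed) * 48271 + r * 16807) %% 2147483647
    set.seed(as.integer(rs))
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- stats::setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                                     collapse = ""), rownames(m))
    tr <- tryCatch(nj_tree(p_distance_matrix(rep_aln)), error = function(e) NULL)
    if (is.null(tr)) next
    ok <- ok + 1L
    for (k in .bipartitions(tr))
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  if (ok == 0L) stop("all bootstrap replicates failed")
  keys <- .node_keys(main)
  supp <- vapply(keys, function(k) {
    if (is.na(k)) return(NA_real_)
    c0 <- counts[[k]]
    100 * (if (is.null(c0)) 0 else c0) / ok
  }, numeric(1))
  main$node.label <- ifelse(is.na(supp), "", formatC(supp, format = "g"))
  attr(main, "support") <- unname(supp)
  attr(main, "replicates_used") <- ok
  main
}

#' Propagate subgroup labels from anchor taxa
#'
#' Each unlabeled leaf receives the label of the smallest clade containing
#' it in which the anchor labels are non-empty and unanimous; if the first
#' anchors encountered walking rootward disagree, the leaf is
#' `"unclassified"`. Anchor leaves keep their own label.
#'
#' @param tree `ape::phylo`.
#' @param anchors Named character vector: `gene_id -> subgroup label`.
#' @return Named character vector over all leaves.
#' @export
assign_subgroups <- function(tree, anchors) {
  if (length(anchors) == 0L) stop("anchors must be non-empty")
  missing_ids <- setdiff(names(anchors), tree$tip.label)
  if (length(missing_ids))
    stop("anchor id(s) absent from tree: ", paste(missing_ids, collapse = ", "))
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # anchor labels under each internal node
  parts <- ape::prop.part(tree)
  node_labels <- lapply(parts, function(p) {
    tips <- tree$tip.label[p]
    unique(unname(anchors[intersect(tips, names(anchors))]))
  })
  root <- n + 1L
  out <- stats::setNames(rep("unclassified", n), tree$tip.label)
  for (tip in seq_len(n)) {
    id <- tree$tip.label[tip]
    if (id %in% names(anchors)) {
      out[id] <- anchors[[id]]
      next
    }
    node <- parent[tip]
    while (node != 0L) {
      labs <- node_labels[[node - n]]
      if (length(labs) == 1L) {
        out[id] <- labs
        break
      }
      if (length(labs) > 1L) break # conflicting anchors -> unclassified
      node <- if (node == root) 0L else parent[node]
    }
  }
  out
}
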