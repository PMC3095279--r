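test_that("complete deletion keeps exactly the gap-free columns", {
  expect_equal(complete_deletion(c(a = "AAAA", b = "AAAT")), 1:4)
  expect_equal(complete_deletion(c(a = "A-AA", b = "AAAA")), c(1L, 3L, 4L))
  expect_error(complete_deletion(c(a = "-A", b = "A-")), "no comparable sites")

  set.seed(21)
  for (i in 1:10) {
    rows <- vapply(1:4, function(k) {
      ch <- sample(c(LETTERS[1:5], "-"), 60, replace = TRUE,
                   prob = c(rep(0.14, 5), 0.3))
      paste(ch, collapse = "")
    }, character(1))
    names(rows) <- paste0("s", 1:4)
    if (length(oracle_complete_deletion(rows)) == 0) next
    expect_equal(complete_deletion(rows), oracle_complete_deletion(rows))
  }
})

test_that("p-distance matches brute-force counting, is symmetric and bounded", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(p_distance_matrix(c(a = "GAT", b = "GAT"))["a", "b"], 0)

  set.seed(31)
  rows <- stats::setNames(vapply(1:10, function(k) random_protein(100),
                                 character(1)), paste0("t", 1:10))
  D <- p_distance_matrix(rows)
  keep <- oracle_complete_deletion(rows)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(D[i, j], oracle_p_distance(rows[[i]], rows[[j]], keep))
  }
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diag(D) == 0))
})

test_that("nj_tree reproduces additive trees exactly", {
  # 4-taxon additive matrix with known branch lengths 1,2,3,4 + internal 1
  ids <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), ids)
  P <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(P, D, tolerance = 1e-12)
  # AB|CD split present
  cherries <- terminal_paralog_pairs(tr, setNames(rep("x", 4), ids))
  expect_true(any(cherries$gene1 == "A" & cherries$gene2 == "B"))

  # 3 taxa: closed-form star resolution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  P3 <- ape::cophenetic.phylo(t3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(P3, D3, tolerance = 1e-12)

  # random additive matrices (more in the acceptance suite)
  for (i in 1:10) {
    set.seed(400 + i)
    rt <- ape::rtree(sample(4:10, 1))
    D <- ape::cophenetic.phylo(rt)
    tr <- nj_tree(D)
    P <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(P - D)), 1e-9)
  }
})

test_that("nj_tree validates its input", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "at least 3")
  Dn <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(Dn), "negative")
  Da <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(Da), "symmetric")
})

test_that("bootstrap supports are deterministic, bounded, and strong for planted splits", {
  aln <- two_block_alignment()
  t1 <- bootstrap_supports(aln, replicates = 100, seed = 42)
  t2 <- bootstrap_supports(aln, replicates = 100, seed = 42)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  s <- attr(t1, "support")
  expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 100))

  # the planted A|B bipartition is near-certain at 200 replicates
  t3 <- bootstrap_supports(aln, replicates = 200, seed = 1)
  keys <- famevol:::.node_keys(t3)
  ab_key <- paste(sort(c("a1", "a2", "a3", "a4")), collapse = "|")
  ba_key <- paste(sort(c("b1", "b2", "b3", "b4")), collapse = "|")
  hit <- which(keys %in% c(ab_key, ba_key))
  expect_true(length(hit) >= 1)
  expect_true(all(attr(t3, "support")[hit] >= 95))

  # support is invariant to leaf input order (same bipartition keys)
  perm <- c(5, 2, 8, 1, 6, 3, 7, 4)
  t4 <- bootstrap_supports(aln[perm], replicates = 100, seed = 42)
  m1 <- stats::setNames(attr(t1, "support"), famevol:::.node_keys(t1))
  m4 <- stats::setNames(attr(t4, "support"), famevol:::.node_keys(t4))
  shared <- intersect(names(m1)[!is.na(names(m1))],
                      names(m4)[!is.na(names(m4))])
  expect_gt(length(shared), 0)
  expect_equal(m1[shared], m4[shared])
})

test_that("a cherry of two identical sequences gets support 100", {
  set.seed(77)
  aln <- c(u = random_protein(80), v = random_protein(80),
           w = random_protein(80))
  aln["x"] <- aln[["w"]]  # x identical to w
  t1 <- bootstrap_supports(aln, replicates = 50, seed = 3)
  keys <- famevol:::.node_keys(t1)
  k <- which(keys == "w|x")
  expect_equal(length(k), 1L)
  expect_equal(attr(t1, "support")[k], 100)
})

test_that("assign_subgroups propagates anchor labels and flags conflicts", {
  tr <- ape::read.tree(text = "((u:1,a1:1):1,(b1:1,b2:1):1);")
  out <- assign_subgroups(tr, c(a1 = "alpha", b1 = "beta", b2 = "beta"))
  expect_equal(out[["u"]], "alpha")
  expect_equal(out[["b1"]], "beta")

  # u sister to a conflicting {alpha, beta} clade -> unclassified
  tr2 <- ape::read.tree(text = "((u:1,(a1:1,b1:1):1):1,(c1:1,c2:1):1);")
  out2 <- assign_subgroups(tr2, c(a1 = "alpha", b1 = "beta", c1 = "gamma",
                                  c2 = "gamma"))
  expect_equal(out2[["u"]], "unclassified")

  expect_error(assign_subgroups(tr, c(zz = "alpha")), "absent")

  # 6 planted labeled clades, every unlabeled member recovers its label
  clades <- vapply(1:6, function(i)
    sprintf("(g%d_a:1,(g%d_b:1,g%d_u:1):1)", i, i, i), character(1))
  spine <- Reduce(function(acc, cl) sprintf("(%s:1,%s:1)", cl, acc), clades)
  tr6 <- ape::read.tree(text = paste0(spine, ";"))
  anchors <- stats::setNames(
    rep(paste0("L", 1:6), each = 2),
    as.vector(t(outer(paste0("g", 1:6), c("_a", "_b"), paste0))))
  out6 <- assign_subgroups(tr6, anchors)
  for (i in 1:6)
    expect_equal(out6[[sprintf("g%d_u", i)]], paste0("L", i))
})
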