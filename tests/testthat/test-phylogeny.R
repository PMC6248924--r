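test_that("core distances follow the p-distance arithmetic", {
  msa <- flg_msa(c("a", "b", "c"),
                 c("MKVLAAGFKR", "MKVLAAGFKR", "MKVLAAGFKV"))
  D <- core_distance_matrix(msa, "p_distance")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.1) # 1 mismatch over 10 shared columns
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), c("a", "b", "c")))

  Dp <- core_distance_matrix(msa, "poisson_corrected")
  expect_equal(Dp["a", "c"], -log(1 - 0.1))

  # a pair with zero shared columns is an error naming the pair
  msa2 <- flg_msa(c("a", "b", "c"), c("MK--", "--VL", "MKVL"))
  expect_error(core_distance_matrix(msa2), "'a' and 'b'")
})

test_that("NJ is exact on additive matrices and label-order invariant", {
  tr <- read_newick("((a:2,b:3):1.5,(c:1,d:2.5):2);")
  dm <- ape::cophenetic.phylo(tr) # additive by construction
  nj <- neighbor_joining(dm)
  expect_equal(oracle_rf(nj, tr), 0)
  # exact branch lengths: leaf-to-leaf path distances reproduced
  expect_equal(ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)

  # permuting the input order never changes the topology
  set.seed(81)
  tr10 <- ape::rtree(10)
  dm10 <- ape::cophenetic.phylo(tr10)
  nj1 <- neighbor_joining(dm10)
  perm <- sample(rownames(dm10))
  nj2 <- neighbor_joining(dm10[perm, perm])
  expect_equal(oracle_rf(nj1, nj2), 0)
  expect_equal(oracle_rf(nj1, tr10), 0)

  # 3 taxa: the unique unrooted topology, no negative lengths
  nj3 <- neighbor_joining(dm10[1:3, 1:3])
  expect_equal(ape::Ntip(nj3), 3)
  expect_true(all(nj3$edge.length >= 0))

  asym <- dm10; asym[1, 2] <- asym[1, 2] + 1
  expect_error(neighbor_joining(asym), "symmetric")
})

test_that("RF distance equals the brute-force bipartition count", {
  expect_true(requireNamespace("phangorn", quietly = TRUE))
  set.seed(82)
  for (rep in 1:8) {
    ta <- ape::rtree(10); tb <- ape::rtree(10)
    tb$tip.label <- sample(ta$tip.label) # same leaf set, shuffled order
    cmp <- rf_congruence(ta, tb)
    expect_equal(cmp$rf_distance, oracle_rf(ta, tb))
    # and agrees with an established implementation
    expect_equal(cmp$rf_distance,
                 as.numeric(phangorn::RF.dist(ape::unroot(ta),
                                              ape::unroot(tb))))
    expect_equal(cmp$max_rf, 2 * (10 - 3))
    expect_gte(cmp$normalised, 0)
    expect_lte(cmp$normalised, 1)
  }

  ta <- ape::rtree(8)
  self <- rf_congruence(ta, ta)
  expect_equal(self$rf_distance, 0)

  tb <- ape::rtree(8)
  tb$tip.label <- paste0("other", 1:8)
  expect_error(rf_congruence(ta, tb), "leaf sets differ")
})

test_that("RF behaves like a metric on random binary trees", {
  set.seed(83)
  for (rep in 1:5) {
    trees <- replicate(3, {
      t <- ape::rtree(8); t$tip.label <- paste0("x", 1:8); t
    }, simplify = FALSE)
    ab <- rf_congruence(trees[[1]], trees[[2]])$rf_distance
    ba <- rf_congruence(trees[[2]], trees[[1]])$rf_distance
    bc <- rf_congruence(trees[[2]], trees[[3]])$rf_distance
    ac <- rf_congruence(trees[[1]], trees[[3]])$rf_distance
    expect_equal(ab, ba)
    expect_lte(ac, ab + bc)
    if (ab == 0) # identity of indiscernibles on binary trees
      expect_equal(oracle_rf(trees[[1]], trees[[2]]), 0)
  }
})

test_that("insert annotation covers every leaf and giant leaves cluster", {
  cfg <- synthetic_config(seed = 84, n_taxa = 8, tree_shape = "balanced",
                          divergence = 0.15,
                          insert_model = c(rep("tandem_DE_plus_DX", 4),
                                           rep("none", 4)))
  gen <- generate_flagellins(cfg)
  arch <- data.frame(id = names(gen$records),
                     insert_len = Biostrings::width(gen$records) - 360,
                     n_de = ifelse(gen$truth$models == "none", 0L, 2L),
                     size_class = size_class(gen$records))
  ann <- annotate_inserts(gen$truth$tree, arch)
  expect_equal(nrow(ann$legend), 8)
  expect_equal(ann$legend$insert_len[match("t1", ann$legend$id)],
               arch$insert_len[arch$id == "t1"])

  # on the balanced tree the tandem clade (t1..t4) is monophyletic: the
  # DE-count-2 leaves form a connected subtree
  de2 <- ann$legend$id[ann$legend$n_de == 2]
  expect_true(ape::is.monophyletic(gen$truth$tree, de2))

  expect_error(annotate_inserts(gen$truth$tree, arch[-1, ]), "t1")
})

test_that("DE copies evolved vertically give trees congruent with the species tree", {
  # balanced topology at 0.25 substitutions/site root-to-tip: each
  # internal branch carries ~20 expected substitutions over a 260-aa DE
  # copy, so a congruent history is recoverable
  hits <- vapply(1:20, function(i) {
    cfg <- synthetic_config(seed = 9000 + i, n_taxa = 6,
                            tree_shape = "balanced", divergence = 0.25,
                            de_length = 260, insert_model = "tandem_DE")
    gen <- generate_flagellins(cfg)
    iv <- gen$truth$intervals
    de <- iv[iv$segment %in% c("de1", "de2"), ]
    seqs <- setNames(substr(as.character(gen$records)[de$id], de$start,
                            de$end),
                     paste0(de$id, "/", sub("de", "", de$segment), "half"))
    dm <- pairwise_pdistance(seqs)
    de_tree <- neighbor_joining(dm)
    cmp <- de_congruence(de_tree, gen$truth$tree)
    max(cmp$normalised)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})
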