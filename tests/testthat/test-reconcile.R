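# A hand-built gene tree mirroring the published workflow figure: one clade of
# six same-species paralogs (all-duplication -> UP) and one clade of six
# single-copy orthologs (all-speciation -> SO), in a 10-species tree.
# an ancient duplication at the root separates a species-congruent single-copy
# subfamily (the SO cluster) from a six-paralog single-species expansion (UP)
figure_tree <- function() {
  st <- default_species_tree()
  gt <- ape::read.tree(text = paste0(
    "(((mono1_g1:1,(mono2_g1:1,(mono3_g1:1,(mono4_g1:1,mono5_g1:1):1):1):1)",
    ":1,dico1_g1:1):1,",
    "(((((dico3_g1:1,dico3_g2:1):1,dico3_g3:1):1,dico3_g4:1):1,dico3_g5:1)",
    ":1,dico3_g6:1):1);"))
  list(gt = gt, st = st)
}

test_that("single-species clade is all duplications; orthologs are speciations", {
  f <- figure_tree()
  rec <- reconcile_label(f$gt, f$st)
  expect_true(all(!is.na(rec$event[-seq_len(length(f$gt$tip.label))])))
  # 5 duplications inside the dico3 expansion plus the ancient one at the root
  expect_equal(rec$n_duplications, 6L)
  ups <- extract_up_clusters(rec, 6, tree_id = "fig")
  expect_length(ups, 1L)
  expect_setequal(ups[[1]]$members, paste0("dico3_g", 1:6))
  expect_equal(ups[[1]]$species, "dico3")
  # SO: with min 6 only the six-species ortholog clade survives
  sos <- extract_so_clusters(rec, 6, tree_id = "fig")
  expect_length(sos, 1L)
  expect_setequal(sos[[1]]$members,
                  c("mono1_g1", "mono2_g1", "mono3_g1", "mono4_g1",
                    "mono5_g1", "dico1_g1"))
  # the expansion side contributes no speciation-only subtree at any min_size
  sos2 <- extract_so_clusters(rec, 2, tree_id = "fig")
  expect_length(sos2, 1L)
})

test_that("species-tree-congruent gene tree has zero duplications", {
  st <- toy_species_tree()
  gt <- ape::read.tree(text = "((A_g1:1,B_g1:1):1,(C_g1:1,D_g1:1):1);")
  rec <- reconcile_label(gt, st)
  expect_equal(rec$n_duplications, 0L)
  expect_length(extract_up_clusters(rec, 2, "t"), 0L)
})

test_that("single-species family yields no SO clusters", {
  st <- toy_species_tree()
  gt <- ape::read.tree(text = "((A_g1:1,A_g2:1):1,(A_g3:1,A_g4:1):1);")
  rec <- reconcile_label(gt, st)
  expect_length(extract_so_clusters(rec, 2, "t"), 0L)
  ups <- extract_up_clusters(rec, 4, "t")
  expect_length(ups, 1L)
  expect_equal(ups[[1]]$size, 4L)
})

test_that("unknown species raises a mapping error naming the leaf", {
  st <- toy_species_tree()
  gt <- ape::read.tree(text = "((A_g1:1,B_g1:1):1,X_g1:1);")
  expect_error(reconcile_label(gt, st), "X")
})

test_that("labels match the clade-set oracle on random trees", {
  st <- toy_species_tree()
  for (seed in 1:10) {
    gt <- random_gene_tree(8, c("A", "B", "C", "D"), seed)
    sp <- tip_species(gt)
    rec <- reconcile_label(gt, st)
    oracle <- oracle_reconcile(gt, st, sp)
    expect_identical(rec$event, oracle, label = paste("seed", seed))
  }
})

test_that("UP/SO extraction equals brute-force enumeration (<=12 leaves)", {
  st <- toy_species_tree()
  for (seed in 1:10) {
    n <- sample(4:12, 1)
    gt <- random_gene_tree(n, c("A", "B", "C", "D"), seed + 100)
    rec <- reconcile_label(gt, st)
    for (min_size in c(2L, 3L, 6L)) {
      br <- oracle_clusters(gt, rec$species, rec$event, min_size)
      ups <- lapply(extract_up_clusters(rec, min_size, "t"),
                    function(cl) sort(cl$members))
      sos <- lapply(extract_so_clusters(rec, min_size, "t"),
                    function(cl) sort(cl$members))
      expect_setequal(ups, br$up)
      expect_setequal(sos, br$so)
    }
  }
})

test_that("extraction invariants hold on simulated families", {
  stree <- default_species_tree()
  cfg <- simulation_config(n_families = 1, seed = 1)
  for (seed in 21:28) {
    fam <- simulate_gene_family(stree, cfg, seed = seed)
    rec <- reconcile_label(fam$tree, stree)
    ups <- extract_up_clusters(rec, 2, "t")
    sos <- extract_so_clusters(rec, 2, "t")
    for (u in ups) expect_length(u$species, 1L)
    for (s in sos) {
      expect_lte(s$size, length(stree$tip.label))
      expect_false(anyDuplicated(s$species) > 0)
    }
    # same-type clusters are leaf-disjoint
    for (set in list(ups, sos)) {
      all_members <- unlist(lapply(set, `[[`, "members"))
      expect_false(anyDuplicated(all_members) > 0)
    }
  }
})

test_that("unrooted input is rooted by duplication-count minimization", {
  st <- toy_species_tree()
  gt <- ape::read.tree(text = "((A_g1:1,B_g1:1):1,(C_g1:1,D_g1:1):1);")
  ugt <- ape::unroot(gt)
  expect_false(ape::is.rooted(ugt))
  rec <- reconcile_label(ugt, st)
  expect_equal(rec$n_duplications, 0L)
  expect_error(reconcile_label(ugt, st, auto_root = FALSE), "unrooted")
})

test_that("category partition follows tree co-occurrence", {
  mk <- function(id, tree, type)
    structure(list(id = id, tree_id = tree, type = type,
                   category = NA_character_, upps = FALSE,
                   members = character(0), species = "A", size = 6L,
                   node = 1L), class = "lse_cluster")
  cl <- list(mk("u1", "t1", "UP"), mk("s1", "t1", "SO"),
             mk("u2", "t2", "UP"), mk("s2", "t3", "SO"))
  out <- partition_categories(cl)
  cats <- vapply(out, `[[`, character(1), "category")
  expect_equal(cats, c("UP1", "SO1", "UP2", "SO2"))
})

test_that("one-per-tree sampling is uniform and seed-deterministic", {
  mk <- function(id)
    structure(list(id = id, tree_id = "t1", type = "UP",
                   category = NA_character_, upps = FALSE,
                   members = character(0), species = "A", size = 6L,
                   node = 1L), class = "lse_cluster")
  cl <- list(mk("a"), mk("b"), mk("c"))
  picks <- vapply(1:3000, function(s)
    sample_one_per_tree(cl, seed = s)[[1]]$id, character(1))
  expect_true(all(table(picks) > 0))
  chi <- chisq.test(table(picks))
  expect_gt(chi$p.value, 0.01)
  expect_identical(sample_one_per_tree(cl, seed = 42)[[1]]$id,
                   sample_one_per_tree(cl, seed = 42)[[1]]$id)
  # a tree with 1 UP and 1 SO keeps both
  so <- mk("s"); so$type <- "SO"
  expect_length(sample_one_per_tree(list(mk("a"), so), seed = 1), 2L)
})

test_that("gene tree estimation recovers simulated topologies", {
  # three sequences: unique unrooted topology, no error
  aln3 <- random_codon_alignment(c("a", "b", "c"), 30, seed = 5)
  tr3 <- estimate_gene_tree(aln3)
  expect_s3_class(tr3, "phylo")
  expect_setequal(tr3$tip.label, c("a", "b", "c"))
  expect_error(estimate_gene_tree(random_codon_alignment(c("a", "b"), 10, 1)),
               "at least 3")
  # identical sequences: branch lengths ~ 0
  ct <- codon_tables()
  s <- paste0(sample(ct$codons, 50, replace = TRUE), collapse = "")
  aln_id <- codon_alignment(c(a = s, b = s, c = s, d = s))
  tr_id <- estimate_gene_tree(aln_id)
  expect_lt(sum(tr_id$edge.length), 1e-4)
  # simulation recovery at generous length
  tr6 <- ape::read.tree(text = paste0(
    "(((t1:0.08,t2:0.08):0.1,(t3:0.09,t4:0.09):0.06):0.05,",
    "(t5:0.1,t6:0.1):0.12):0;"))
  sim <- simulate_codon_alignment(tr6, site_model_spec("M0", omega = 0.4),
                                  gy94_params(2, 1, "uniform"), 1500,
                                  seed = 77)
  est <- estimate_gene_tree(sim$alignment)
  rf <- phangorn::RF.dist(ape::unroot(est), ape::unroot(tr6))
  expect_equal(rf, 0)
  # external tree override wins
  expect_identical(estimate_gene_tree(aln3, config = list(tree = tr6)), tr6)
})
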