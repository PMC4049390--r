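test_that("duplication/loss-free families are congruent with the species tree", {
  stree <- default_species_tree()
  cfg <- simulation_config(n_families = 1, dup_rate = 0, loss_rate = 0,
                           stem_multiplier = 0, burst_fraction = 0, seed = 1)
  fam <- simulate_gene_family(stree, cfg, seed = 3)
  expect_equal(length(fam$tree$tip.label), 10L)
  expect_true(all(fam$truth$event[!is.na(fam$truth$event)] == "S"))
  got <- ape::unroot(fam$tree)
  got$tip.label <- sub("_.*", "", got$tip.label)
  expect_equal(phangorn::RF.dist(got, ape::unroot(stree)), 0)
})

test_that("fixed seeds reproduce gene families exactly", {
  stree <- default_species_tree()
  cfg <- simulation_config(n_families = 1, seed = 1)
  a <- simulate_gene_family(stree, cfg, seed = 11)
  b <- simulate_gene_family(stree, cfg, seed = 11)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$truth, b$truth)
})

test_that("burst multiplier drives the UP cluster count upward", {
  stree <- default_species_tree()
  mean_up <- function(mult) {
    cfg <- simulation_config(n_families = 1, burst_multiplier = mult,
                             burst_fraction = 1, burst_subfamily_prob = 1,
                             loss_rate = 0, seed = 1)
    n <- 0
    for (s in 1:12) {
      fam <- simulate_gene_family(stree, cfg, seed = 1000 + s)
      rec <- reconcile_label(fam$tree, stree)
      n <- n + length(extract_up_clusters(rec, 6, "t"))
    }
    n / 12
  }
  counts <- vapply(c(1, 40, 150), mean_up, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("with loss, reconciliation still recovers true event labels when loss-free", {
  stree <- default_species_tree()
  cfg <- simulation_config(n_families = 1, loss_rate = 0, seed = 1)
  for (s in 51:56) {
    fam <- simulate_gene_family(stree, cfg, seed = s)
    rec <- reconcile_label(fam$tree, stree)
    expect_identical(rec$event, fam$truth$event, label = paste("seed", s))
  }
})

test_that("codon alignments carry exact substitution truth", {
  tr <- ape::read.tree(text = "((A_1:0.2,A_2:0.2):0.1,B_1:0.3):0;")
  spec <- site_model_spec("M1a", p0 = 0.7, omega0 = 0.2)
  params <- gy94_params(2, 1, "uniform")
  sim <- simulate_codon_alignment(tr, spec, params, 100, seed = 5)
  expect_equal(sim$alignment$n_codons, 100L)
  expect_length(sim$truth$site_class, 100L)
  # no stop codons by construction: the constructor would reject them
  expect_s3_class(sim$alignment, "codon_alignment")
  expect_true(all(!is.na(sim$alignment$states)))
  # zero-length tree: identical sequences, zero substitutions
  tr0 <- tr
  tr0$edge.length[] <- 0
  sim0 <- simulate_codon_alignment(tr0, spec, params, 50, seed = 6)
  expect_equal(length(unique(sim0$alignment$seqs)), 1L)
  expect_equal(sum(sim0$truth$branch_syn) + sum(sim0$truth$branch_nonsyn), 0L)
  # determinism
  sim_b <- simulate_codon_alignment(tr, spec, params, 100, seed = 5)
  expect_identical(sim$alignment$seqs, sim_b$alignment$seqs)
  expect_identical(sim$truth$branch_syn, sim_b$truth$branch_syn)
})

test_that("realized substitution ratios track the true omega", {
  tr <- ape::read.tree(text = "(A_1:1.5,B_1:1.5):0;")
  params <- gy94_params(2, 1, "uniform")
  for (w in c(0.1, 1)) {
    sim <- simulate_codon_alignment(tr, site_model_spec("M0", omega = w),
                                    params, 4000, seed = 70 + 10 * w)
    sc <- count_syn_nonsyn_sites(sim$alignment, kappa = 2)
    S <- sum(sim$truth$branch_syn)
    NS <- sum(sim$truth$branch_nonsyn)
    w_real <- (NS / sc$NSsites) / (S / sc$Ssites)
    expect_equal(w_real, w, tolerance = 0.15)
  }
})

test_that("long simulations approach the stationary codon frequencies", {
  tr <- ape::read.tree(text = "(A_1:4,B_1:4):0;")
  params <- gy94_params(2, 1, "uniform")
  tv <- function(n, seed) {
    sim <- simulate_codon_alignment(tr, site_model_spec("M0", omega = 1),
                                    params, n, seed = seed)
    emp <- tabulate(sim$alignment$states, 61) / (2 * n)
    sum(abs(emp - params$pi)) / 2
  }
  expect_lt(tv(8000, 81), tv(500, 82))
})

test_that("fixture studies are complete, truthful and bit-reproducible", {
  cfg <- simulation_config(n_families = 6, n_codons = 60, seed = 77,
                           loss_rate = 0)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_fixture_study(cfg, d1)
  m2 <- generate_fixture_study(cfg, d2)
  expect_identical(m1$files, m2$files)  # content digests equal
  expect_error(generate_fixture_study(cfg, d1), "not empty")
  # pipeline-side extraction matches the stored truth tables (loss-free)
  stree <- read_species_tree(file.path(d1, "species_tree.nwk"))
  truth <- read.table(file.path(d1, "truth_clusters.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  got <- list()
  for (f in sprintf("fam%03d", 1:6)) {
    gt <- ape::read.tree(file.path(d1, paste0(f, ".nwk")))
    rec <- reconcile_label(gt, stree)
    got[[f]] <- clusters_table(partition_categories(
      c(extract_up_clusters(rec, 6, f), extract_so_clusters(rec, 6, f))))
  }
  got <- do.call(rbind, got)
  rownames(got) <- NULL
  ord <- function(df) df[order(df$cluster_id),
                         c("cluster_id", "tree_id", "type", "category",
                           "size", "member_ids")]
  expect_equal(ord(got), ord(truth), ignore_attr = TRUE)
  # empty study is valid
  d0 <- file.path(tempdir(), "study_0")
  unlink(d0, recursive = TRUE)
  m0 <- generate_fixture_study(simulation_config(n_families = 0, seed = 1), d0)
  expect_true(file.exists(file.path(d0, "manifest.json")))
  expect_equal(m0$n_families, 0L)
  unlink(c(d0, d1, d2), recursive = TRUE)
})
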