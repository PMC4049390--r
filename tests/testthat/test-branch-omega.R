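mkfit_manual <- function(omegas, probs, kappa = 2, pi = rep(1 / 61, 61),
                         scale = 1, tree = NULL) {
  structure(list(model = "manual", pi = pi, kappa = kappa, scale = scale,
                 omegas = omegas, class_probs = probs, tree = tree),
            class = "site_model_fit")
}

test_that("zero-length branches carry zero expected counts", {
  ct <- codon_tables()
  tree <- ape::read.tree(text = "(A:0,B:0):0;")
  aln <- codon_alignment(c(A = ct$codons[5], B = ct$codons[5]))
  rec <- map_substitutions(aln, tree, mkfit_manual(0.5, 1))
  expect_equal(rec$nbNS, c(0, 0))
  expect_equal(rec$nbS, c(0, 0))
})

test_that("expected counts match 100k simulated CTMC paths (one branch)", {
  ct <- codon_tables()
  params <- gy94_params(2, 0.6, "uniform")
  Q <- build_gy94_generator(params)
  start <- 5L
  t <- 0.5
  set.seed(3)
  mc <- lseselect:::cpp_simulate_branch_paths(start - 1L, Q, ct$pairtype, t,
                                              100000L)
  # mapping with the end state unobserved = unconditional expectation
  aln <- codon_alignment(c(A = ct$codons[start], B = "NNN"))
  tree <- ape::read.tree(text = "(A:0,B:0.5):0;")
  rec <- map_substitutions(aln, tree, mkfit_manual(0.6, 1))
  b <- which(rec$child_label == "B")
  for (lab in c("syn", "nonsyn")) {
    x <- if (lab == "syn") mc[, 2] else mc[, 3]
    got <- if (lab == "syn") rec$nbS[b] else rec$nbNS[b]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(got - mean(x)), 3 * se)
  }
  # and conditionally on an observed end state
  end_mode <- as.integer(names(which.max(table(mc[, 1]))))
  sel <- mc[, 1] == end_mode
  aln2 <- codon_alignment(c(A = ct$codons[start], B = ct$codons[end_mode + 1]))
  rec2 <- map_substitutions(aln2, tree, mkfit_manual(0.6, 1))
  for (lab in c("syn", "nonsyn")) {
    x <- if (lab == "syn") mc[sel, 2] else mc[sel, 3]
    got <- if (lab == "syn") rec2$nbS[b] else rec2$nbNS[b]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(got - mean(x)), 3 * se)
  }
})

test_that("mapped expectations track realized counts on simulated data", {
  tr <- ape::read.tree(text = "((A:0.25,B:0.3):0.15,C:0.4):0;")
  sim <- simulate_codon_alignment(tr, site_model_spec("M0", omega = 0.5),
                                  gy94_params(2, 1, "uniform"), 2000,
                                  seed = 19)
  rec <- map_substitutions(sim$alignment, tr, mkfit_manual(0.5, 1))
  expect_true(all(rec$nbNS >= 0 & rec$nbS >= 0))
  # total expected counts near the realized truth (relative Monte-Carlo slack)
  expect_equal(sum(rec$nbS), sum(sim$truth$branch_syn), tolerance = 0.1)
  expect_equal(sum(rec$nbNS), sum(sim$truth$branch_nonsyn), tolerance = 0.1)
  # and per branch, up to more noise on short branches
  expect_equal(rec$nbS + rec$nbNS,
               sim$truth$branch_syn + sim$truth$branch_nonsyn,
               tolerance = 0.2)
})

test_that("branch omega arithmetic and filters follow the definitions", {
  counts <- list(NSsites = 400, Ssites = 200)
  expect_equal(compute_branch_omega(12, 9, counts), (12 / 400) / (9 / 200),
               tolerance = 1e-12)
  expect_equal(compute_branch_omega(12, 9, counts), 0.6667, tolerance = 1e-4)
  # equal per-site rates give omega 1
  expect_equal(compute_branch_omega(4, 2, counts), 1)
  expect_true(is.na(compute_branch_omega(3, 0, counts)))

  rec <- data.frame(branch = 1:4, parent = 5L, child = 1:4,
                    child_label = letters[1:4],
                    is_internal = c(TRUE, TRUE, FALSE, FALSE),
                    nbNS = c(6, 2, 0, 2.6), nbS = c(2, 1, 0, 1))
  fc <- filter_and_classify_branches(rec, counts)
  expect_true(fc$cluster_kept)
  # the all-zero branch is dropped
  expect_false(3 %in% fc$records$branch)
  expect_equal(fc$dropped$reason, "no substitutions")
  # classification: omega = 1.5 -> gt1_2; 1.0 -> lt1 (boundary); 1.3 -> gt1_2
  omg <- fc$records$omega
  expect_equal(fc$records$class[fc$records$branch == 1],
               "gt1_2")  # (6/400)/(2/200) = 1.5
  expect_equal(fc$records$class[fc$records$branch == 2], "lt1")  # exactly 1
  expect_equal(fc$records$class[fc$records$branch == 4], "gt1_2")  # 1.3
  # exactly 1.2 is gt1, not gt1_2 (strict)
  rec12 <- data.frame(branch = 1:2, parent = 3L, child = 1:2,
                      child_label = c("a", "b"), is_internal = FALSE,
                      nbNS = c(2.4, 2), nbS = c(1, 2))
  fc12 <- filter_and_classify_branches(rec12, counts)
  expect_equal(fc12$records$class, c("gt1", "lt1"))

  # cluster lacking synonymous substitutions is dropped wholesale
  rec0 <- data.frame(branch = 1:2, parent = 3L, child = 1:2,
                     child_label = c("a", "b"), is_internal = FALSE,
                     nbNS = c(2, 1.2), nbS = c(0, 0))
  fc0 <- filter_and_classify_branches(rec0, counts)
  expect_false(fc0$cluster_kept)
  expect_equal(nrow(fc0$records), 0L)
})

test_that("neutral simulation calibrates branch omega around 1", {
  tr <- ape::read.tree(text = paste0(
    "(((t1:0.15,t2:0.15):0.1,t3:0.25):0.05,(t4:0.2,t5:0.2):0.1):0;"))
  omg <- c()
  for (s in 65:68) {
    sim <- simulate_codon_alignment(tr, site_model_spec("M0", omega = 1),
                                    gy94_params(2, 1, "uniform"), 1000,
                                    seed = s)
    f0 <- fit_site_model(sim$alignment, tr, "M0", pi = "uniform")
    rec <- map_substitutions(sim$alignment, tr, f0)
    fc <- filter_and_classify_branches(rec, f0$site_counts)
    expect_true(fc$cluster_kept)
    omg <- c(omg, fc$records$omega)
  }
  # under neutrality branches scatter on both sides of 1...
  expect_gt(mean(omg > 1), 0.2)
  expect_gt(mean(omg < 1), 0.2)
  # ...evenly, within binomial error
  expect_gt(binom.test(sum(omg > 1), length(omg))$p.value, 0.01)
  # and the mean branch omega sits within 1 +/- 0.1
  expect_equal(mean(omg), 1, tolerance = 0.1)
})

test_that("internal/external branch split is recorded", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4):0;")
  aln <- random_codon_alignment(c("A", "B", "C"), 20, seed = 3)
  rec <- map_substitutions(aln, tr, mkfit_manual(0.5, 1))
  expect_equal(sum(rec$is_internal), 1L)  # one internal edge in a rooted triplet
  expect_setequal(rec$child_label[!rec$is_internal], c("A", "B", "C"))
})
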