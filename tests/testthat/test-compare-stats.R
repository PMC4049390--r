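test_that("Fisher tests match published worked examples and the oracle", {
  tab <- data.frame(size = c(6L, 5L, 4L),
                    up_sel = c(24L, 16L, 0L), up_not = c(474L, 51017L, 10L),
                    so_sel = c(0L, 0L, 0L), so_not = c(487L, 4187L, 10L))
  out <- fisher_by_size_category(tab)
  expect_equal(out$p[1], 9.27e-08, tolerance = 0.005)
  # the published 0.62 is a truncation of 0.628
  expect_lt(abs(out$p[2] - 0.62), 0.01)
  expect_equal(out$p[3], 1)
  # enumeration oracle on all small tables
  for (seed in 1:10) {
    set.seed(seed)
    cnt <- as.integer(sample(0:8, 4, replace = TRUE))
    t1 <- data.frame(size = 1L, up_sel = cnt[1], up_not = cnt[2],
                     so_sel = cnt[3], so_not = cnt[4])
    expect_equal(fisher_by_size_category(t1)$p,
                 oracle_fisher(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9)
  }
  # symmetry under simultaneous row and column swap
  t2 <- data.frame(size = 1L, up_sel = 2L, up_not = 3L, so_sel = 1L,
                   so_not = 4L)
  t2s <- data.frame(size = 1L, up_sel = 4L, up_not = 1L, so_sel = 3L,
                    so_not = 2L)
  expect_equal(fisher_by_size_category(t2)$p, fisher_by_size_category(t2s)$p)
  expect_error(fisher_by_size_category(
    data.frame(size = 1L, up_sel = -1L, up_not = 1L, so_sel = 1L,
               so_not = 1L)), "nonnegative")
})

test_that("Mann-Whitney: exact small-sample case and enumeration oracle", {
  mw <- mann_whitney_omega(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(mw$p, 0.1, tolerance = 1e-12)
  expect_true(mw$exact)
  expect_equal(mw$p, oracle_mann_whitney(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)),
               tolerance = 1e-12)
  for (seed in 1:5) {
    set.seed(seed)
    a <- round(runif(5), 3); b <- round(runif(4), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(mann_whitney_omega(a, b)$p, oracle_mann_whitney(a, b),
                 tolerance = 1e-9)
  }
  # identical samples: p ~ 1 (ties force the corrected normal approximation)
  big <- rep(c(0.2, 0.4, 0.6), 30)
  expect_gt(mann_whitney_omega(big, big)$p, 0.9)
  expect_error(mann_whitney_omega(numeric(0), 1), "non-empty")
  # shifted distributions are detected
  set.seed(5)
  x <- rnorm(200); y <- rnorm(200, 0.3)
  expect_lt(mann_whitney_omega(x, y)$p, 0.05)
})

test_that("sliding-window tests respect the minimum-count rule", {
  set.seed(11)
  mk <- function(n, ds_lo, ds_hi, omega_shift = 0) {
    data.frame(dS = runif(n, ds_lo, ds_hi),
               omega = rlnorm(n, -0.7 + omega_shift, 0.4))
  }
  a <- mk(500, 0, 0.05)
  b <- mk(500, 0, 0.05)
  # a window where one group has 99 values emits no test
  a99 <- rbind(mk(99, 0.05, 0.06), mk(200, 0, 0.01))
  b99 <- rbind(mk(150, 0.05, 0.06), mk(200, 0, 0.01))
  w <- sliding_window_ds_test(a99, b99, min_n = 100)
  expect_false(any(w$interval_lo == 0.05))
  expect_true(any(w$interval_lo == 0))
  # windows partition the axis: no record is used twice
  w2 <- sliding_window_ds_test(a, b, min_n = 100)
  expect_true(all(w2$interval_hi - w2$interval_lo == 0.01))
  expect_false(any(duplicated(w2$interval_lo)))
  expect_true(all(w2$n_a >= 100 & w2$n_b >= 100))
  # constructed signal: omega differs only in [0.02, 0.03)
  a_sig <- rbind(mk(300, 0, 0.02), mk(300, 0.02, 0.03, omega_shift = 1.2),
                 mk(300, 0.03, 0.05))
  b_sig <- rbind(mk(300, 0, 0.02), mk(300, 0.02, 0.03), mk(300, 0.03, 0.05))
  ws <- sliding_window_ds_test(a_sig, b_sig, min_n = 100)
  sig <- ws$p < 0.01
  expect_true(all(ws$interval_lo[sig] >= 0.02 - 1e-9))
  expect_true(any(sig))
  expect_true(all(ws$interval_hi[sig] <= 0.03 + 1e-9))
})

test_that("Spearman correlation handles ties and directions", {
  expect_equal(spearman_clusters_vs_divergence(1:8, (1:8) * 2)$rho, 1)
  expect_equal(spearman_clusters_vs_divergence(1:8, rev(1:8))$rho, -1)
  expect_error(spearman_clusters_vs_divergence(1:2, 1:2), "at least 3")
  set.seed(9)
  x <- sample(1:5, 10, replace = TRUE)  # forced ties
  y <- sample(1:5, 10, replace = TRUE)
  got <- spearman_clusters_vs_divergence(x, y)
  rho_oracle <- cor(rank(x), rank(y))
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  tstat <- rho_oracle * sqrt((10 - 2) / (1 - rho_oracle^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-9)
})

test_that("branch-category summary equals a direct recomputation", {
  set.seed(21)
  n <- 300
  br <- data.frame(
    category = sample(c("UP1", "UP2", "SO1", "SO2"), n, replace = TRUE),
    upps = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.2, 0.8)),
    is_internal = sample(c(TRUE, FALSE), n, replace = TRUE),
    omega = rlnorm(n, -0.5, 0.6))
  out <- summarize_branch_categories(br)
  # percentages across the two primary strata sum to 100
  expect_equal(out$pct_lt1 + out$pct_gt1, rep(100, nrow(out)))
  row <- out[out$category == "UP2", ]
  x <- br$omega[br$category == "UP2"]
  expect_equal(row$n_branches, length(x))
  expect_equal(row$mean_omega, mean(x))
  expect_equal(row$pct_gt1_2, 100 * mean(x > 1.2))
  expect_equal(row$mean_omega_gt1, mean(x[x > 1]))
  upint <- out[out$category == "UPint", ]
  xi <- br$omega[br$category %in% c("UP1", "UP2") & br$is_internal]
  expect_equal(upint$n_branches, length(xi))
  # degenerate: all omega below 1
  br2 <- data.frame(category = "UP1", upps = FALSE, is_internal = FALSE,
                    omega = rep(0.5, 4))
  out2 <- summarize_branch_categories(br2)
  expect_equal(out2$pct_lt1[out2$category == "UP1"], 100)
  expect_equal(out2$mean_omega[out2$category == "UP1"], 0.5)
  expect_equal(out2$pct_gt1[out2$category == "UP1"], 0)
})

test_that("dataset summary computes medians and quartiles per category", {
  ci <- data.frame(
    cluster_id = paste0("c", 1:6),
    category = c("UP1", "UP1", "UP2", "SO1", "SO2", "SO2"),
    upps = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    size = c(6L, 8L, 7L, 7L, 6L, 9L),
    aln_length_nt = c(900L, 1200L, 600L, 1500L, 300L, 900L),
    n_sites = c(300L, 400L, 200L, 500L, 100L, 300L),
    fitted = TRUE, mapped = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    n_branches = c(10L, 14L, 12L, 12L, 10L, 16L),
    n_branches_analysed = c(8L, 12L, 0L, 11L, 9L, 15L))
  out <- summarize_dataset(ci)
  up1 <- out[out$category == "UP1", ]
  expect_equal(up1$clusters_codeml, 2)
  expect_equal(up1$median_size, 7)
  expect_equal(up1$total_sites, 700)
  expect_equal(out[out$category == "UPps", "clusters_codeml"], 1)
})
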