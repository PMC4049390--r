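#' Fisher's exact tests by cluster-size category
#'
#' Two-sided Fisher's exact test of "under selection" vs "not" for UP against
#' SO, one 2x2 table per cluster-size category and counting unit (clusters,
#' codons or branches).
#'
#' @param tables data frame with columns `size`, `up_sel`, `up_not`, `so_sel`,
#'   `so_not` (nonnegative integers); an optional `unit` column is carried
#'   through.
#' @return the input with a `p` column appended.
#' @export
fisher_by_size_category <- function(tables) {
  stopifnot(is.data.frame(tables),
            all(c("size", "up_sel", "up_not", "so_sel", "so_not") %in%
                  names(tables)))
  cnt <- as.matrix(tables[, c("up_sel", "up_not", "so_sel", "so_not")])
  if (any(cnt < 0)) stop("counts must be nonnegative")
  if (any(cnt != round(cnt))) stop("counts must be integers")
  tables$p <- vapply(seq_len(nrow(tables)), function(i) {
    m <- matrix(cnt[i, ], nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }, numeric(1))
  tables
}

#' Mann-Whitney comparison of two omega samples
#'
#' Exact enumeration when both groups are small (n <= 20) and tie-free,
#' otherwise the normal approximation with tie correction; always two-sided.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `U`, `p`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_omega <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 20 && length(b) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(a), n_b = length(b), exact = exact)
}

#' Sliding-window Mann-Whitney tests of omega along the dS axis
#'
#' The dS axis is partitioned into consecutive half-open intervals
#' `[k*width, (k+1)*width)` starting at zero; within each interval the omega
#' values of the two groups are compared with a two-sided Mann-Whitney test,
#' but only when both groups contribute at least `min_n` values.
#'
#' @param records_a,records_b data frames with columns `dS` and `omega`
#'   (e.g. internal UP branches vs all SO branches).
#' @param width interval width (default 0.01 dS).
#' @param min_n minimum values per group for a test to be emitted (default
#'   100; 25 reproduces the less stringent published figure threshold).
#' @return data frame: `interval_lo`, `interval_hi`, `n_a`, `n_b`, `U`, `p`.
#' @export
sliding_window_ds_test <- function(records_a, records_b, width = 0.01,
                                   min_n = 100L) {
  empty <- data.frame(interval_lo = numeric(0), interval_hi = numeric(0),
                      n_a = integer(0), n_b = integer(0), U = numeric(0),
                      p = numeric(0))
  if (!nrow(records_a) || !nrow(records_b)) return(empty)
  hi <- max(c(records_a$dS, records_b$dS), na.rm = TRUE)
  n_win <- ceiling((hi + 1e-12) / width)
  out <- list()
  for (k in seq_len(n_win)) {
    lo <- (k - 1) * width
    up <- k * width
    ia <- records_a$dS >= lo & records_a$dS < up
    ib <- records_b$dS >= lo & records_b$dS < up
    if (sum(ia) < min_n || sum(ib) < min_n) next
    mw <- mann_whitney_omega(records_a$omega[ia], records_b$omega[ib])
    out[[length(out) + 1L]] <-
      data.frame(interval_lo = lo, interval_hi = up, n_a = sum(ia),
                 n_b = sum(ib), U = mw$U, p = mw$p)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Spearman correlation of cluster counts against divergence time
#'
#' @param counts number of detected clusters per species.
#' @param divergence_times matching divergence times (to each species'
#'   closest relative).
#' @return list with `rho` and `p` (two-sided), class `correlation_result`.
#' @export
spearman_clusters_vs_divergence <- function(counts, divergence_times) {
  stopifnot(length(counts) == length(divergence_times))
  if (length(counts) < 3L) stop("at least 3 paired observations required")
  ct <- suppressWarnings(
    cor.test(counts, divergence_times, method = "spearman",
             alternative = "two.sided"))
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 n = length(counts)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d)\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Category summaries of the branch analysis
#'
#' Per category (UP1, UP2, UPps, UPint, SO1, SO2): branch counts and
#' percentages in the omega strata (omega < 1, omega > 1, omega > 1.2), mean
#' omega within each stratum, and overall mean omega with its standard error.
#' UPps covers branches of UP clusters with validated positively selected
#' codons; UPint covers internal branches of all UP clusters.
#'
#' @param branch_records data frame with columns `category`, `upps`,
#'   `is_internal`, `omega`.
#' @return data frame, one row per category present.
#' @export
summarize_branch_categories <- function(branch_records) {
  br <- branch_records[!is.na(branch_records$omega), , drop = FALSE]
  groups <- list()
  for (cat in c("UP1", "UP2", "SO1", "SO2"))
    groups[[cat]] <- br[br$category == cat, , drop = FALSE]
  groups[["UPps"]] <- br[br$category %in% c("UP1", "UP2") & br$upps, ,
                         drop = FALSE]
  groups[["UPint"]] <- br[br$category %in% c("UP1", "UP2") & br$is_internal, ,
                          drop = FALSE]
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]$omega
    n <- length(x)
    if (!n) return(NULL)
    lt1 <- x <= 1
    gt1 <- x > 1
    gt12 <- x > 1.2
    data.frame(
      category = g, n_branches = n,
      n_lt1 = sum(lt1), pct_lt1 = 100 * mean(lt1),
      mean_omega_lt1 = if (any(lt1)) mean(x[lt1]) else NA_real_,
      n_gt1 = sum(gt1), pct_gt1 = 100 * mean(gt1),
      mean_omega_gt1 = if (any(gt1)) mean(x[gt1]) else NA_real_,
      n_gt1_2 = sum(gt12), pct_gt1_2 = 100 * mean(gt12),
      mean_omega_gt1_2 = if (any(gt12)) mean(x[gt12]) else NA_real_,
      mean_omega = mean(x), se_omega = sd(x),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Dataset description summary
#'
#' Per category: cluster counts at the site-model and branch-mapping stages,
#' branch totals, median (quartile) cluster size and alignment length, total
#' sites.
#'
#' @param cluster_info data frame with columns `category`, `upps`, `size`,
#'   `aln_length_nt`, `n_sites`, `fitted` (logical), `mapped` (logical),
#'   `n_branches`, `n_branches_analysed`.
#' @return data frame, one row per category (UP1, UP2, UPps, SO1, SO2 when
#'   present).
#' @export
summarize_dataset <- function(cluster_info) {
  ci <- cluster_info
  groups <- list()
  for (cat in c("UP1", "UP2", "SO1", "SO2"))
    groups[[cat]] <- ci[ci$category == cat, , drop = FALSE]
  groups[["UPps"]] <- ci[ci$category %in% c("UP1", "UP2") & ci$upps, ,
                         drop = FALSE]
  q <- function(x, p) if (length(x)) unname(quantile(x, p, type = 7)) else NA_real_
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (!nrow(x)) return(NULL)
    data.frame(
      category = g,
      clusters_codeml = sum(x$fitted),
      clusters_mapnh = sum(x$mapped),
      total_branches = sum(x$n_branches),
      branches_analysed = sum(x$n_branches_analysed),
      median_size = median(x$size), q1_size = q(x$size, 0.25),
      q3_size = q(x$size, 0.75),
      median_length = median(x$aln_length_nt),
      q1_length = q(x$aln_length_nt, 0.25),
      q3_length = q(x$aln_length_nt, 0.75),
      total_sites = sum(x$n_sites),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
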