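#' Pipeline configuration
#'
#' All thresholds default to the study design: minimum cluster size 6 at
#' extraction, minimum 4 sequences after cleaning, posterior cutoff 0.95,
#' omega cutoffs 1 and 1.2, dS window width 0.01 with a minimum of 100 values
#' per group (25 reproduces the figure-caption variant).
#'
#' @param study_dir directory produced by [generate_fixture_study()] (or laid
#'   out the same way: `species_tree.nwk`, per-family `famXXX.nwk` /
#'   `famXXX.fasta`).
#' @param seed study-level seed (cluster sampling, model-fit determinism).
#' @param models site models to fit (default `c("M1a", "M2a")`; add
#'   `"M8a", "M8"` for the full quartet).
#' @param min_cluster_size,min_sequences extraction / post-cleaning minima.
#' @param posterior_cutoff flagging cutoff (strict).
#' @param omega_cutoffs branch classification thresholds.
#' @param window_width,window_min_n sliding-window parameters.
#' @param tree_method `"given"` (use the per-family tree pruned to the
#'   cluster; default) or `"ml"` (re-estimate per cluster).
#' @param call_rule `"either"` (cluster called positive when either LRT is
#'   Bonferroni-significant and at least one site is flagged) or `"both"`.
#' @param outdir optional report directory for [write_reports()].
#' @export
pipeline_config <- function(study_dir, seed, models = c("M1a", "M2a"),
                            min_cluster_size = 6L, min_sequences = 4L,
                            posterior_cutoff = 0.95,
                            omega_cutoffs = c(1, 1.2),
                            min_branch_subst = 0.5, min_syn_subst = 0.5,
                            window_width = 0.01, window_min_n = 100L,
                            tree_method = c("given", "ml"),
                            call_rule = c("either", "both"),
                            outdir = NULL) {
  stopifnot(!missing(study_dir), !missing(seed))
  models <- match.arg(models, c("M1a", "M2a", "M8a", "M8"), several.ok = TRUE)
  if (!("M2a" %in% models) && !("M8" %in% models))
    stop("at least one positive-selection model (M2a or M8) is required")
  list(study_dir = study_dir, seed = as.integer(seed), models = models,
       min_cluster_size = as.integer(min_cluster_size),
       min_sequences = as.integer(min_sequences),
       posterior_cutoff = posterior_cutoff, omega_cutoffs = omega_cutoffs,
       min_branch_subst = min_branch_subst, min_syn_subst = min_syn_subst,
       window_width = window_width, window_min_n = as.integer(window_min_n),
       tree_method = match.arg(tree_method),
       call_rule = match.arg(call_rule), outdir = outdir)
}

log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full analysis pipeline on a study directory
#'
#' Reconcile every family tree against the species tree, extract and
#' partition UP/SO clusters, sample one cluster per tree and type, apply CDS
#' and size filters, fit the configured site models per cluster, run the
#' LRTs with Bonferroni correction (family size = clusters tested within each
#' category), flag positively selected codons, map substitutions onto
#' branches, compute branch omega with the published filters, and assemble
#' the comparative statistics.
#'
#' @param config a [pipeline_config()].
#' @return object of class `lse_pipeline_result`: `clusters` (per-cluster
#'   table), `fits` (per cluster, per model), `lrt` (per-cluster LRT table),
#'   `sites` (per-site posterior table), `branches` (branch records),
#'   `tables` (dataset/branch/fisher summaries, window tests), `manifest`.
#' @export
run_pipeline <- function(config) {
  dir <- config$study_dir
  stree <- read_species_tree(file.path(dir, "species_tree.nwk"))
  fam_trees <- sort(list.files(dir, pattern = "^fam[0-9]+\\.nwk$"))
  log_stage("reconcile: ", length(fam_trees), " family trees")

  clusters <- list()
  trees <- list()
  for (tf in fam_trees) {
    fam_id <- sub("\\.nwk$", "", tf)
    gt <- ape::read.tree(file.path(dir, tf))
    rec <- reconcile_label(gt, stree)
    trees[[fam_id]] <- rec
    ups <- extract_up_clusters(rec, config$min_cluster_size, tree_id = fam_id)
    sos <- extract_so_clusters(rec, config$min_cluster_size, tree_id = fam_id)
    clusters <- c(clusters, ups, sos)
  }
  n_extracted <- length(clusters)
  clusters <- partition_categories(clusters)
  clusters <- sample_one_per_tree(clusters, seed = config$seed)
  n_sampled <- length(clusters)
  log_stage("clusters: ", n_extracted, " extracted, ", n_sampled,
            " after one-per-tree sampling")

  # QC + per-cluster alignment
  kept <- list()
  n_reject_cds <- 0L
  n_reject_size <- 0L
  for (cl in clusters) {
    fam_id <- cl$tree_id
    aln_all <- read_codon_fasta(file.path(dir, paste0(fam_id, ".fasta")))
    seqs <- setNames(aln_all$seqs, aln_all$ids)[cl$members]
    val <- validate_cds_cluster(seqs)
    if (!val$pass) {
      n_reject_cds <- n_reject_cds + 1L
      next
    }
    aln <- clean_alignment(codon_alignment(val$sequences))
    if (!apply_min_size(aln, config$min_sequences)$pass) {
      n_reject_size <- n_reject_size + 1L
      next
    }
    cl$alignment <- aln
    kept[[cl$id]] <- cl
  }
  log_stage("qc: ", length(kept), " clusters kept (", n_reject_cds,
            " CDS-rejected, ", n_reject_size, " below minimum size)")

  # per-cluster tree + model fits
  null_model <- intersect(config$models, c("M1a", "M8a"))
  alt_model <- intersect(config$models, c("M2a", "M8"))
  fits <- list()
  lrt_rows <- list()
  site_rows <- list()
  fit_fail <- 0L
  for (cl in kept) {
    fam_id <- cl$tree_id
    tr <- if (config$tree_method == "ml") {
      estimate_gene_tree(cl$alignment)
    } else {
      ape::keep.tip(trees[[fam_id]]$tree, cl$members)
    }
    res <- tryCatch({
      fl <- list()
      for (m in config$models)
        fl[[m]] <- fit_site_model(cl$alignment, tr, m)
      fl
    }, error = function(e) NULL)
    if (is.null(res)) {
      fit_fail <- fit_fail + 1L
      next
    }
    fits[[cl$id]] <- res
    for (pair in list(c("M1a", "M2a"), c("M8a", "M8"))) {
      if (all(pair %in% config$models)) {
        lr <- lrt_positive_selection(res[[pair[1]]], res[[pair[2]]])
        lrt_rows[[length(lrt_rows) + 1L]] <- data.frame(
          cluster_id = cl$id, category = cl$category, pair = lr$pair,
          statistic = lr$statistic, df = lr$df, p = lr$p,
          stringsAsFactors = FALSE)
      }
    }
    for (m in alt_model) {
      post <- site_posterior_omega_gt1(res[[m]], config$posterior_cutoff)
      if (length(post$flagged))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          cluster_id = cl$id, model = m, site = post$flagged,
          posterior = post$prob[post$flagged], stringsAsFactors = FALSE)
    }
  }
  log_stage("fits: ", length(fits), " clusters fitted (", fit_fail,
            " failures)")
  kept <- kept[names(fits)]

  lrt <- if (length(lrt_rows)) do.call(rbind, lrt_rows)
    else data.frame(cluster_id = character(0), category = character(0),
                    pair = character(0), statistic = numeric(0),
                    df = integer(0), p = numeric(0))
  # Bonferroni family: clusters tested within each category
  lrt$p_adjusted <- rep(NA_real_, nrow(lrt))
  for (cat in unique(lrt$category)) {
    idx <- lrt$category == cat
    # family size: clusters tested within the category
    m <- length(unique(lrt$cluster_id[idx]))
    lrt$p_adjusted[idx] <- pmin(1, m * lrt$p[idx])
  }
  lrt$significant <- lrt$p_adjusted < 0.05

  sites <- if (length(site_rows)) do.call(rbind, site_rows)
    else data.frame(cluster_id = character(0), model = character(0),
                    site = integer(0), posterior = numeric(0))

  # cluster-level positive-selection call (+ UPps flag)
  called <- vapply(kept, function(cl) {
    sig <- lrt$significant[lrt$cluster_id == cl$id]
    has_flag <- cl$id %in% sites$cluster_id
    if (!length(sig)) return(FALSE)
    ok <- if (config$call_rule == "either") any(sig) else all(sig)
    ok && has_flag
  }, logical(1))
  for (i in seq_along(kept))
    kept[[i]]$upps <- kept[[i]]$type == "UP" && called[[i]]

  # branch analysis
  branch_rows <- list()
  mapped <- logical(length(kept))
  names(mapped) <- names(kept)
  for (cl in kept) {
    alt <- alt_model[1]
    fit <- fits[[cl$id]][[alt]]
    rec <- map_substitutions(cl$alignment, fit = fit)
    fc <- filter_and_classify_branches(rec, fit$site_counts,
                                       omega_cutoffs = config$omega_cutoffs,
                                       min_branch_subst = config$min_branch_subst,
                                       min_syn_subst = config$min_syn_subst)
    mapped[cl$id] <- fc$cluster_kept
    if (!fc$cluster_kept) next
    if (nrow(fc$records)) {
      fc$records$cluster_id <- cl$id
      fc$records$category <- cl$category
      fc$records$upps <- cl$upps
      branch_rows[[length(branch_rows) + 1L]] <- fc$records
    }
  }
  branches <- if (length(branch_rows)) do.call(rbind, branch_rows)
    else data.frame(branch = integer(0), parent = integer(0),
                    child = integer(0), child_label = character(0),
                    is_internal = logical(0), nbNS = numeric(0),
                    nbS = numeric(0), omega = numeric(0), dS = numeric(0),
                    class = character(0), cluster_id = character(0),
                    category = character(0), upps = logical(0))
  rownames(branches) <- NULL
  log_stage("branches: ", nrow(branches), " analysed")

  # summaries
  cluster_info <- data.frame(
    cluster_id = vapply(kept, `[[`, character(1), "id"),
    category = vapply(kept, `[[`, character(1), "category"),
    type = vapply(kept, `[[`, character(1), "type"),
    upps = vapply(kept, `[[`, logical(1), "upps"),
    size = vapply(kept, function(cl) length(cl$alignment$ids), integer(1)),
    aln_length_nt = vapply(kept, function(cl) 3 * as.numeric(cl$alignment$n_codons),
                           numeric(1)),
    n_sites = vapply(kept, function(cl) as.numeric(cl$alignment$n_codons),
                     numeric(1)),
    fitted = rep(TRUE, length(kept)),
    stringsAsFactors = FALSE)
  cluster_info$called <- as.logical(called[cluster_info$cluster_id])
  cluster_info$mapped <- as.logical(mapped[cluster_info$cluster_id])
  nb <- table(factor(branches$cluster_id, levels = cluster_info$cluster_id))
  cluster_info$n_branches_analysed <- as.integer(nb)
  cluster_info$n_branches <- vapply(kept, function(cl)
    2L * length(cl$alignment$ids) - 2L, integer(1))

  tables <- list(
    dataset = summarize_dataset(cluster_info),
    branch_categories = if (nrow(branches))
      summarize_branch_categories(branches) else NULL,
    fisher = build_fisher_tables(cluster_info, sites, branches,
                                 omega_cutoffs = config$omega_cutoffs),
    windows = {
      up_int <- branches[branches$category %in% c("UP1", "UP2") &
                           branches$is_internal, , drop = FALSE]
      so <- branches[branches$category %in% c("SO1", "SO2"), , drop = FALSE]
      sliding_window_ds_test(up_int, so, width = config$window_width,
                             min_n = config$window_min_n)
    })

  manifest <- list(
    seed = config$seed, models = config$models,
    counts = list(
      families = length(fam_trees),
      clusters_extracted = n_extracted,
      clusters_sampled = n_sampled,
      rejected_cds = n_reject_cds,
      rejected_min_size = n_reject_size,
      fit_failures = fit_fail,
      clusters_fitted = length(fits),
      clusters_mapped = sum(cluster_info$mapped),
      clusters_called_positive = sum(cluster_info$called),
      upps_clusters = sum(cluster_info$upps),
      branches_analysed = nrow(branches),
      flagged_sites = nrow(sites)),
    thresholds = config[c("min_cluster_size", "min_sequences",
                          "posterior_cutoff", "omega_cutoffs",
                          "window_width", "window_min_n")])
  stopifnot(manifest$counts$clusters_sampled ==
              manifest$counts$rejected_cds + manifest$counts$rejected_min_size +
              manifest$counts$fit_failures + manifest$counts$clusters_fitted)

  fit_rows <- list()
  for (cid in names(fits)) for (m in names(fits[[cid]])) {
    f <- fits[[cid]][[m]]
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      cluster_id = cid, model = m, loglik = f$loglik, kappa = f$kappa,
      scale = f$scale,
      omegas = paste(signif(f$omegas, 6), collapse = ";"),
      class_probs = paste(signif(f$class_probs, 6), collapse = ";"),
      NSsites = f$site_counts$NSsites, Ssites = f$site_counts$Ssites,
      n_flagged = length(f$flagged_sites), stringsAsFactors = FALSE)
  }
  fit_table <- if (length(fit_rows)) do.call(rbind, fit_rows)
    else data.frame(cluster_id = character(0), model = character(0),
                    loglik = numeric(0), kappa = numeric(0),
                    scale = numeric(0), omegas = character(0),
                    class_probs = character(0), NSsites = numeric(0),
                    Ssites = numeric(0), n_flagged = integer(0))

  structure(list(clusters = cluster_info, fits = fits,
                 fit_table = fit_table, lrt = lrt,
                 sites = sites, branches = branches, tables = tables,
                 manifest = manifest, config = config),
            class = "lse_pipeline_result")
}

#' @export
print.lse_pipeline_result <- function(x, ...) {
  cat("lse_pipeline_result:\n")
  utils::str(x$manifest$counts, give.head = FALSE)
  invisible(x)
}

# 2x2 UP-vs-SO tables per cluster-size category for the three counting units
build_fisher_tables <- function(cluster_info, sites, branches,
                                omega_cutoffs = c(1, 1.2)) {
  ci <- cluster_info
  sizes <- sort(unique(ci$size))
  rows <- list()
  for (unit in c("clusters", "codons", "branches")) {
    for (s in sizes) {
      sub <- ci[ci$size == s, , drop = FALSE]
      up <- sub[sub$type == "UP", , drop = FALSE]
      so <- sub[sub$type == "SO", , drop = FALSE]
      if (!nrow(up) && !nrow(so)) next
      cell <- function(grp) {
        if (!nrow(grp)) return(c(0L, 0L))
        switch(unit,
          clusters = c(sum(grp$called), sum(!grp$called)),
          codons = {
            fl <- sum(sites$cluster_id %in% grp$cluster_id[grp$called])
            c(fl, sum(grp$n_sites) - fl)
          },
          branches = {
            b <- branches[branches$cluster_id %in% grp$cluster_id, ,
                          drop = FALSE]
            hi <- sum(b$omega > omega_cutoffs[2])
            c(hi, nrow(b) - hi)
          })
      }
      u <- cell(up); v <- cell(so)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, size = s, up_sel = u[1], up_not = u[2],
        so_sel = v[1], so_not = v[2], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(unit = character(0), size = integer(0),
                      up_sel = integer(0), up_not = integer(0),
                      so_sel = integer(0), so_not = integer(0),
                      p = numeric(0)))
  fisher_by_size_category(do.call(rbind, rows))
}

#' Write pipeline report tables
#'
#' Emits TSVs mirroring the published table structures (dataset description,
#' branch-category summary, Fisher-by-size, per-site and per-branch tables,
#' window tests) plus the JSON manifest.
#'
#' @param result an `lse_pipeline_result`.
#' @param outdir target directory (created if needed).
#' @return (invisibly) the vector of written paths.
#' @export
write_reports <- function(result, outdir) {
  stopifnot(inherits(result, "lse_pipeline_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(outdir, name)
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  paths <- c(
    wt(result$clusters, "clusters.tsv"),
    wt(result$fit_table, "fits.tsv"),
    wt(result$lrt, "lrt.tsv"),
    wt(result$sites, "sites.tsv"),
    wt(result$branches, "branches.tsv"),
    wt(result$tables$dataset, "table1_dataset.tsv"),
    wt(result$tables$branch_categories, "table3_branches.tsv"),
    wt(result$tables$fisher, "table4_fisher.tsv"),
    wt(result$tables$windows, "figure5_windows.tsv"))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result$manifest, mpath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, mpath))
}
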