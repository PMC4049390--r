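#' Site-class mixture specifications (M0, M1a, M2a, M8a, M8)
#'
#' M1a and M8a are the nearly-neutral null models (no omega > 1 class);
#' M2a and M8 add a positive-selection class.  M8a is M8 with the extra class
#' pinned at omega = 1.  M0 (single ratio) is provided for simulation and
#' branch-level work.
#'
#' @param model one of `"M0"`, `"M1a"`, `"M2a"`, `"M8a"`, `"M8"`.
#' @param omega single ratio (M0 only).
#' @param p0,p1 class proportions (model dependent; remaining mass goes to the
#'   last class).
#' @param omega0 purifying-class ratio in (0,1).
#' @param omega2 positive-class ratio (> 1, M2a).
#' @param p,q beta shape parameters (M8/M8a).
#' @param omega_s selection-class ratio (M8; fixed at 1 for M8a).
#' @param K number of equal-probability beta discretization categories
#'   (default 10).
#' @return object of class `site_model_spec`.
#' @export
site_model_spec <- function(model, omega = NULL, p0 = NULL, p1 = NULL,
                            omega0 = NULL, omega2 = NULL, p = NULL, q = NULL,
                            omega_s = NULL, K = 10L) {
  model <- match.arg(model, c("M0", "M1a", "M2a", "M8a", "M8"))
  spec <- switch(model,
    M0 = {
      stopifnot(!is.null(omega), omega >= 0)
      list(omega = omega)
    },
    M1a = {
      stopifnot(p0 >= 0, p0 <= 1, omega0 > 0, omega0 < 1)
      list(p0 = p0, omega0 = omega0)
    },
    M2a = {
      stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, omega0 > 0, omega0 < 1,
                omega2 >= 1)
      list(p0 = p0, p1 = p1, p2 = 1 - p0 - p1, omega0 = omega0,
           omega2 = omega2)
    },
    M8a = {
      stopifnot(p0 >= 0, p0 <= 1, p > 0, q > 0)
      list(p0 = p0, p = p, q = q, omega_s = 1, K = as.integer(K))
    },
    M8 = {
      stopifnot(p0 >= 0, p0 <= 1, p > 0, q > 0, omega_s >= 1)
      list(p0 = p0, p = p, q = q, omega_s = omega_s, K = as.integer(K))
    })
  structure(c(list(model = model), spec), class = "site_model_spec")
}

# mean of each of K equal-probability categories of Beta(p, q)
beta_category_means <- function(p, q, K) {
  # extreme shapes trip qbeta accuracy warnings; the guard below caps the
  # resulting means anyway
  br <- suppressWarnings(qbeta(seq(0, 1, length.out = K + 1), p, q))
  cdf1 <- pbeta(br, p + 1, q)
  means <- K * (p / (p + q)) * diff(cdf1)
  # guard against round-off at extreme shapes
  pmin(pmax(means, 1e-8), 1 - 1e-8)
}

#' Expand a site-model spec into its omega classes and proportions
#' @param spec a [site_model_spec()].
#' @return list with `omegas` and `probs` (same length, probs sum to 1).
#' @export
mixture_classes <- function(spec) {
  stopifnot(inherits(spec, "site_model_spec"))
  switch(spec$model,
    M0 = list(omegas = spec$omega, probs = 1),
    M1a = list(omegas = c(spec$omega0, 1), probs = c(spec$p0, 1 - spec$p0)),
    M2a = list(omegas = c(spec$omega0, 1, spec$omega2),
               probs = c(spec$p0, spec$p1, spec$p2)),
    M8a = ,
    M8 = {
      means <- beta_category_means(spec$p, spec$q, spec$K)
      list(omegas = c(means, spec$omega_s),
           probs = c(rep(spec$p0 / spec$K, spec$K), 1 - spec$p0))
    })
}

# ---- internal likelihood plumbing -----------------------------------------

# Align tree and alignment; compress site patterns.  Returns everything the
# C++ core needs.
prepare_likelihood_data <- function(alignment, tree) {
  stopifnot(inherits(alignment, "codon_alignment"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, alignment$ids))
    stop("tree tip labels do not match alignment sequence ids")
  ord <- match(tree$tip.label, alignment$ids)
  states <- alignment$states[ord, , drop = FALSE]
  tip <- states
  tip[is.na(tip)] <- 0L
  tip <- tip - 1L  # 0-based, -1 = missing
  key <- apply(tip, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- tip[, first, drop = FALSE]
  weights <- as.numeric(table(factor(key, levels = key[first])))
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  list(tipstates = pat, weights = weights,
       site_to_pattern = match(key, key[first]),
       edge = tree$edge, blen = tree$edge.length, ntip = length(tree$tip.label))
}

#' Mixture log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense-codon states, mixed over the site
#' classes of `spec`: `lnL = sum_sites log sum_k p_k L_site(k)`.  Gaps and Ns
#' are missing data.  The model is time-reversible, so the root placement does
#' not affect the value.
#'
#' @param alignment a [codon_alignment()].
#' @param tree a rooted `phylo` with branch lengths in expected substitutions
#'   per codon; tip labels must match the alignment ids.
#' @param spec a [site_model_spec()].
#' @param params a [gy94_params()] (its `omega` is ignored; class omegas come
#'   from `spec`).
#' @param scale multiplier applied to all branch lengths (default 1).
#' @return log-likelihood (numeric scalar).
#' @export
alignment_log_likelihood <- function(alignment, tree, spec, params, scale = 1) {
  dat <- prepare_likelihood_data(alignment, tree)
  mix <- mixture_classes(spec)
  ct <- codon_tables()
  res <- cpp_mix_loglik(dat$tipstates, dat$weights, dat$edge, dat$blen,
                        ct$pairtype, params$pi, params$kappa, mix$omegas,
                        mix$probs, scale, FALSE)
  res$loglik
}

# ---- fitting ---------------------------------------------------------------

#' Options controlling site-model optimization
#'
#' @param omega2_starts deterministic starts for the positive-selection class
#'   ratio (default `c(1.5, 3, 8)`).
#' @param lnl_tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxit iteration cap per start.
#' @param branch_lengths `"scale"` (one free multiplier on the input branch
#'   lengths, default) or `"optimize"` (slow mode: every branch length free).
#' @export
fit_options <- function(omega2_starts = c(1.5, 3, 8), lnl_tol = 1e-8,
                        maxit = 500L, branch_lengths = c("scale", "optimize")) {
  list(omega2_starts = omega2_starts, lnl_tol = lnl_tol,
       maxit = as.integer(maxit), branch_lengths = match.arg(branch_lengths))
}

# Outer parameter packing: the mixture weights are NOT free outer parameters;
# they are profiled out exactly by the concave inner problem (see
# profile_weights).  The outer vector holds (log kappa, log scale) plus the
# model's omega/shape block.
model_par_info <- function(model, opts, w2_start = 3) {
  lgt <- function(x) log(x / (1 - x))
  base <- list(names = c("lkappa", "lscale"),
               start = c(log(2), 0),
               lower = c(log(0.05), log(1e-3)),
               upper = c(log(50), log(1e3)))
  blk <- switch(model,
    M0 = list(names = "lomega", start = log(0.5),
              lower = log(1e-4), upper = log(50)),
    M1a = list(names = "zw0", start = lgt(0.3),
               lower = -12, upper = lgt(1 - 1e-6)),
    M2a = list(names = c("zw0", "lw2m1"),
               start = c(lgt(0.3), log(w2_start - 1)),
               lower = c(-12, log(1e-4)),
               upper = c(lgt(1 - 1e-6), log(50))),
    M8a = list(names = c("lp", "lq"),
               start = c(log(0.5), log(1.5)),
               lower = c(log(0.005), log(0.005)),
               upper = c(log(99), log(99))),
    M8 = list(names = c("lp", "lq", "lwsm1"),
              start = c(log(0.5), log(1.5), log(w2_start - 1)),
              lower = c(log(0.005), log(0.005), log(1e-4)),
              upper = c(log(99), log(99), log(50))))
  list(names = c(base$names, blk$names), start = c(base$start, blk$start),
       lower = c(base$lower, blk$lower), upper = c(base$upper, blk$upper))
}

# omega classes for an outer parameter vector (weights handled separately)
outer_omegas <- function(model, th, K = 10L) {
  ilgt <- function(z) 1 / (1 + exp(-z))
  switch(model,
    M0 = exp(th[["lomega"]]),
    M1a = c(ilgt(th[["zw0"]]), 1),
    M2a = c(ilgt(th[["zw0"]]), 1, 1 + exp(th[["lw2m1"]])),
    M8a = c(beta_category_means(exp(th[["lp"]]), exp(th[["lq"]]), K), 1),
    M8 = c(beta_category_means(exp(th[["lp"]]), exp(th[["lq"]]), K),
           1 + exp(th[["lwsm1"]])))
}

# weight layout: "free" = all class weights free on the simplex (M0/M1a/M2a);
# "m8" = K equal-weight beta categories sharing mass p0, plus one free class
weight_structure <- function(model) {
  if (model %in% c("M8", "M8a")) "m8" else "free"
}

# Exact profiling of mixture weights: the log-likelihood is concave in the
# weights (log of a linear function per site), so EM converges to the global
# optimum; a boundary candidate (last class emptied) guards nesting against
# slow boundary approach.  class_loglik is K x npat; wpat are pattern counts.
profile_weights <- function(class_loglik, wpat, structure = "free",
                            init = NULL, tol = 1e-10, max_iter = 2000L) {
  K <- nrow(class_loglik)
  m <- apply(class_loglik, 2, max)
  L <- exp(sweep(class_loglik, 2, m))  # K x npat, in (0, 1]
  W <- sum(wpat)
  lnl_of <- function(p) {
    mix <- colSums(L * p)
    sum(wpat * (log(mix) + m))
  }
  if (structure == "m8") {
    Kb <- K - 1L
    L2 <- rbind(colMeans(L[seq_len(Kb), , drop = FALSE]), L[K, ])
    sub <- profile_weights(log(L2), wpat, structure = "free",
                           init = if (!is.null(init))
                             c(sum(init[seq_len(Kb)]), init[K]) else NULL,
                           tol = tol, max_iter = max_iter)
    p <- c(rep(sub$probs[1] / Kb, Kb), sub$probs[2])
    return(list(probs = p, loglik = lnl_of(p),
                interior = c(rep(sub$interior[1] / Kb, Kb), sub$interior[2])))
  }
  if (K == 1L) return(list(probs = 1, loglik = lnl_of(1)))
  # floor the init: a zero is absorbing under EM's multiplicative update
  p0 <- if (!is.null(init) && length(init) == K)
    pmax(init, 1e-8) / sum(pmax(init, 1e-8)) else rep(1 / K, K)
  p <- as.vector(cpp_profile_weights_em(L, wpat, p0, tol, max_iter))
  # boundary candidate: empty the last class (the omega > 1 class in M2a),
  # guaranteeing lnL(alternative) >= lnL(embedded null)
  cand <- list(p)
  if (K > 1L) {
    pb <- p
    pb[K] <- 0
    if (sum(pb) > 0) cand <- c(cand, list(pb / sum(pb)))
  }
  vals <- vapply(cand, lnl_of, numeric(1))
  best <- which.max(vals)
  # `interior` is the EM iterate, safe to reuse as a warm start
  list(probs = cand[[best]], loglik = vals[best], interior = p)
}

# assemble the user-facing spec from outer parameters + profiled weights
assemble_spec <- function(model, th, probs, K = 10L) {
  ilgt <- function(z) 1 / (1 + exp(-z))
  switch(model,
    M0 = site_model_spec("M0", omega = exp(th[["lomega"]])),
    M1a = site_model_spec("M1a", p0 = probs[1], omega0 = ilgt(th[["zw0"]])),
    M2a = site_model_spec("M2a", p0 = probs[1], p1 = probs[2],
                          omega0 = ilgt(th[["zw0"]]),
                          omega2 = 1 + exp(th[["lw2m1"]])),
    M8a = site_model_spec("M8a", p0 = sum(probs[-length(probs)]),
                          p = exp(th[["lp"]]), q = exp(th[["lq"]]), K = K),
    M8 = site_model_spec("M8", p0 = sum(probs[-length(probs)]),
                         p = exp(th[["lp"]]), q = exp(th[["lq"]]),
                         omega_s = 1 + exp(th[["lwsm1"]]), K = K))
}

# mean substitution rate of the unnormalized GY94 generator per class
class_mean_rates <- function(omegas, kappa, pi) {
  ct <- codon_tables()
  vapply(omegas, function(w) cpp_gy94_Q(ct$pairtype, pi, kappa, w)$mu,
         numeric(1))
}

#' Fit a GY94 site model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization over kappa, the branch-length
#' scale and the omega/shape parameters, with the mixture weights profiled
#' out exactly at every step: for fixed omegas the per-site class likelihoods
#' do not depend on the weights (generators are normalized by a
#' weight-independent constant internally), the weight problem is concave,
#' and EM solves it to its global optimum.  This removes the flat boundary
#' directions that make codon mixture fits slow, and makes nesting
#' structural: the alternative can always empty its positive class and
#' recover the null.  Positive-selection models (M2a, M8) are started from
#' each value in `opts$omega2_starts` (screened coarsely, best polished);
#' null models use a single deterministic start.  Branch lengths from the
#' input tree are rescaled by one free multiplier by default; the reported
#' `scale` follows the mixture-mean-rate-one convention (branch length x
#' scale = expected substitutions per codon).
#'
#' @param alignment a [codon_alignment()].
#' @param tree `phylo` with branch lengths; tips must match alignment ids.
#' @param model `"M0"`, `"M1a"`, `"M2a"`, `"M8a"` or `"M8"`.
#' @param pi codon frequencies: `"F3x4"` (default), `"F61"`, `"uniform"` or a
#'   numeric vector of 61 frequencies.
#' @param opts a [fit_options()].
#' @param K beta discretization categories for M8/M8a.
#' @return object of class `site_model_fit`: `model`, `loglik`, `spec` (MLE),
#'   `kappa`, `scale`, `pi`, per-site class `posterior` (classes x sites),
#'   `site_prob_gt1`, `flagged_sites` (posterior > 0.95, strict),
#'   `site_counts` (NSsites/Ssites at the fitted kappa), `tree`, convergence
#'   info.
#' @export
fit_site_model <- function(alignment, tree, model = c("M1a", "M2a", "M8a", "M8", "M0"),
                           pi = "F3x4", opts = fit_options(), K = 10L,
                           init_fit = NULL) {
  model <- match.arg(model)
  dat <- prepare_likelihood_data(alignment, tree)
  ct <- codon_tables()
  if (is.character(pi)) pi <- codon_frequencies(alignment, pi)
  stopifnot(length(pi) == 61L, all(pi > 0))
  pi <- pi / sum(pi)

  opt_bl <- opts$branch_lengths == "optimize"
  nedge <- nrow(dat$edge)
  blen0 <- pmax(dat$blen, 1e-8)
  info <- model_par_info(model, opts)
  nout <- length(info$names)
  wstruct <- weight_structure(model)
  Kcl <- switch(model, M0 = 1L, M1a = 2L, M2a = 3L, M8a = K + 1L, M8 = K + 1L)
  dummy <- rep(1 / Kcl, Kcl)  # weight-independent normalization inside C++
  state <- new.env()
  state$w <- NULL  # EM warm start carried across objective evaluations

  # per-class site log-likelihoods at outer parameters, weights profiled out
  eval_outer <- function(th, want_classlik = FALSE) {
    omegas <- outer_omegas(model, setNames(th[seq_len(nout)], info$names), K)
    blen <- if (opt_bl) exp(th[-seq_len(nout)]) else dat$blen
    scale <- if (opt_bl) 1 else exp(th[[2]])
    kappa <- exp(th[[1]])
    res <- tryCatch(
      cpp_mix_loglik(dat$tipstates, dat$weights, dat$edge, blen, ct$pairtype,
                     pi, kappa, omegas, dummy, scale, TRUE),
      error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$class_loglik))) return(NULL)
    pw <- profile_weights(res$class_loglik, dat$weights, wstruct,
                          init = state$w)
    state$w <- pw$interior
    if (want_classlik)
      list(loglik = pw$loglik, probs = pw$probs,
           class_loglik = res$class_loglik, omegas = omegas)
    else list(loglik = pw$loglik, probs = pw$probs)
  }
  negll <- function(th) {
    out <- eval_outer(th)
    if (is.null(out) || !is.finite(out$loglik)) 1e10 else -out$loglik
  }

  start0 <- info$start
  # warm start from a (typically null-model) fit sharing kappa/scale/omega0
  if (!is.null(init_fit)) {
    lgt <- function(x) log(pmin(pmax(x, 1e-6), 1 - 1e-6) /
                             (1 - pmin(pmax(x, 1e-6), 1 - 1e-6)))
    start0[1] <- log(init_fit$kappa)
    start0[2] <- log(max(init_fit$scale, 1e-3))
    sp <- init_fit$spec
    if (!is.null(sp[["omega0"]]) && "zw0" %in% info$names)
      start0[match("zw0", info$names)] <- lgt(sp[["omega0"]])
    if (!is.null(sp[["p"]]) && "lp" %in% info$names) {
      start0[match("lp", info$names)] <- log(sp[["p"]])
      start0[match("lq", info$names)] <- log(sp[["q"]])
    }
  }
  starts <- list(start0)
  if (model %in% c("M2a", "M8")) {
    wname <- if (model == "M2a") "lw2m1" else "lwsm1"
    starts <- lapply(opts$omega2_starts, function(w2) {
      s <- start0
      s[match(wname, info$names)] <- log(w2 - 1)
      s
    })
  }
  lower <- info$lower; upper <- info$upper
  if (opt_bl) {
    starts <- lapply(starts, function(s) c(s, log(blen0)))
    lower <- c(lower, rep(log(1e-8), nedge))
    upper <- c(upper, rep(log(20), nedge))
  }
  factr <- opts$lnl_tol / .Machine$double.eps
  best <- NULL
  convergence <- 1L
  if (length(starts) > 1L) {
    # coarse screen of the deterministic starts, then polish the winner
    coarse <- lapply(starts, function(s) tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 12L, factr = 1e-2 / .Machine$double.eps)),
      error = function(e) NULL))
    vals <- vapply(coarse, function(r) if (is.null(r)) Inf else r$value,
                   numeric(1))
    if (all(!is.finite(vals))) stop("site-model optimization failed for every start")
    starts <- list(coarse[[which.min(vals)]]$par)
  }
  for (s in starts) {
    res <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = opts$maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      convergence <- res$convergence
    }
  }
  if (is.null(best)) stop("site-model optimization failed for every start")

  th <- setNames(best$par[seq_len(nout)], info$names)
  final <- eval_outer(best$par, want_classlik = TRUE)
  if (is.null(final)) stop("site-model fit is degenerate at the optimum")
  spec <- assemble_spec(model, th, final$probs, K)
  kappa <- exp(th[["lkappa"]])
  blen <- if (opt_bl) exp(best$par[-seq_len(nout)]) else dat$blen
  # convert the internal scale (weight-independent normalization) to the
  # mixture-mean-rate-one convention
  mu <- class_mean_rates(final$omegas, kappa, pi)
  conv <- sum(final$probs * mu) / mean(mu)
  scale <- if (opt_bl) 1 else exp(th[["lscale"]]) * conv
  if (opt_bl) blen <- blen * conv

  # NEB class posteriors per site (plug-in MLEs)
  cl <- final$class_loglik  # K x npat
  m <- apply(cl, 2, max)
  post_pat <- exp(sweep(cl, 2, m)) * final$probs
  post_pat <- sweep(post_pat, 2, colSums(post_pat), "/")
  posterior <- post_pat[, dat$site_to_pattern, drop = FALSE]
  gt1 <- final$omegas > 1
  site_prob_gt1 <- if (any(gt1)) colSums(posterior[gt1, , drop = FALSE])
    else rep(0, ncol(posterior))

  fitted_tree <- tree
  if (opt_bl) fitted_tree$edge.length <- blen

  structure(list(
    model = model, loglik = final$loglik, spec = spec,
    kappa = kappa, scale = scale, pi = pi,
    omegas = final$omegas, class_probs = final$probs,
    posterior = posterior, site_prob_gt1 = site_prob_gt1,
    flagged_sites = which(site_prob_gt1 > 0.95),
    site_counts = count_syn_nonsyn_sites(alignment, kappa),
    tree = fitted_tree, n_sites = alignment$n_codons,
    convergence = convergence, n_par = length(best$par) +
      length(final$probs) - 1L,
    alignment_ids = alignment$ids),
    class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("site_model_fit %s: lnL = %.4f, kappa = %.3f, scale = %.3f\n",
              x$model, x$loglik, x$kappa, x$scale))
  cat("  omegas:", paste(sprintf("%.3f", x$omegas), collapse = " "),
      "\n  probs: ", paste(sprintf("%.3f", x$class_probs), collapse = " "), "\n")
  if (length(x$flagged_sites))
    cat("  flagged sites:", paste(x$flagged_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood ratio test for positive selection
#'
#' `2 * (lnL_alt - lnL_null)` (clamped at zero) against chi-square with 2 df
#' for M1a/M2a and 1 df for M8a/M8 (the conservative plain chi-square at the
#' boundary; a 50:50 point-mass/chi-square mixture is available via
#' `mixture_null = TRUE`).
#'
#' @param null_fit,alt_fit `site_model_fit` objects from a nested pair.
#' @param mixture_null use the 50:50 boundary mixture for the M8a/M8 test.
#' @return object of class `lrt_result`: `statistic`, `df`, `p`,
#'   `p_adjusted` (NA until [bonferroni_adjust()] is applied), `significant`.
#' @export
lrt_positive_selection <- function(null_fit, alt_fit, mixture_null = FALSE) {
  pair <- paste(null_fit$model, alt_fit$model, sep = "/")
  df <- switch(pair, "M1a/M2a" = 2L, "M8a/M8" = 1L,
               stop("not a supported nested pair: ", pair))
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  if (mixture_null && df == 1L) p <- 0.5 * p + 0.5 * (stat == 0)
  structure(list(pair = pair, statistic = stat, df = df, p = p,
                 p_adjusted = NA_real_, significant = NA),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s: 2dl = %.4f (df %d), p = %.4g, adjusted p = %.4g\n",
              x$pair, x$statistic, x$df, x$p, x$p_adjusted))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p numeric p-values.
#' @param m family size (must be at least `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  pmin(1, m * p)
}

#' Per-site posterior probability of omega > 1
#'
#' Naive empirical Bayes on the fitted mixture: the posterior mass of the
#' site-class(es) with omega > 1.  Sites are flagged when the posterior is
#' strictly above the cutoff.  Fits of null models (no omega > 1 class)
#' return all-zero posteriors and no flags.
#'
#' @param fit a `site_model_fit` (M2a or M8 for a meaningful answer).
#' @param cutoff posterior cutoff (default 0.95, strict).
#' @return list with `prob` (per 1-based codon site) and `flagged`.
#' @export
site_posterior_omega_gt1 <- function(fit, cutoff = 0.95) {
  stopifnot(inherits(fit, "site_model_fit"))
  prob <- fit$site_prob_gt1
  list(prob = prob, flagged = which(prob > cutoff))
}

#' BEB-style site posteriors for M2a (optional mode)
#'
#' Integrates the per-site posterior of the positive-selection class over an
#' equal-weight grid on (p2, omega2) around plausible values (other
#' parameters held at their MLEs), weighting grid points by their data
#' likelihood under a uniform prior.  This tempers the plug-in (NEB)
#' posteriors when mixture weights are poorly determined; it is an
#' approximation in the spirit of Bayes empirical Bayes, not a full
#' reimplementation.
#'
#' @param alignment,tree the data the fit was produced from.
#' @param fit an M2a `site_model_fit`.
#' @param grid_n grid resolution per dimension (default 6).
#' @param cutoff flagging cutoff (default 0.95, strict).
#' @return list with `prob` and `flagged` as in [site_posterior_omega_gt1()].
#' @export
beb_site_posterior <- function(alignment, tree, fit, grid_n = 6L,
                               cutoff = 0.95) {
  stopifnot(inherits(fit, "site_model_fit"), fit$model == "M2a")
  dat <- prepare_likelihood_data(alignment, tree)
  ct <- codon_tables()
  sp <- fit$spec
  ratio01 <- if (sp$p0 + sp$p1 > 0) sp$p0 / (sp$p0 + sp$p1) else 0.5
  p2_grid <- seq(0.01, 0.4, length.out = grid_n)
  w2_grid <- exp(seq(log(1.05), log(12), length.out = grid_n))
  logZ <- matrix(NA_real_, grid_n, grid_n)
  post_acc <- matrix(0, grid_n * grid_n, alignment$n_codons)
  k <- 0L
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    k <- k + 1L
    p2 <- p2_grid[i]
    omegas <- c(sp$omega0, 1, w2_grid[j])
    probs <- c((1 - p2) * ratio01, (1 - p2) * (1 - ratio01), p2)
    res <- cpp_mix_loglik(dat$tipstates, dat$weights, dat$edge, dat$blen,
                          ct$pairtype, fit$pi, fit$kappa, omegas, probs,
                          fit$scale, TRUE)
    logZ[i, j] <- res$loglik
    cl <- res$class_loglik
    m <- apply(cl, 2, max)
    pp <- exp(sweep(cl, 2, m)) * probs
    pp <- sweep(pp, 2, colSums(pp), "/")
    post_acc[k, ] <- pp[3, dat$site_to_pattern]
  }
  w <- as.vector(t(exp(logZ - max(logZ))))
  w <- w / sum(w)
  prob <- as.vector(w %*% post_acc)
  list(prob = prob, flagged = which(prob > cutoff))
}
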