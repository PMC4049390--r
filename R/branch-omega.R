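#' Expected synonymous/nonsynonymous substitution counts per branch
#'
#' Posterior expected numbers of labeled substitutions (substitution mapping)
#' on every branch, summed over sites, with site classes mixed by their
#' posterior probability at each site.  Expectations are analytic (eigen
#' integral of the labeled generator), not stochastic draws, so the result is
#' deterministic given the fit.
#'
#' @param alignment a [codon_alignment()].
#' @param tree `phylo` with branch lengths; defaults to the fit's tree.
#' @param fit a `site_model_fit` providing kappa, scale, codon frequencies and
#'   the site-class mixture.
#' @return data frame of `branch_record`s: branch (edge index), parent/child
#'   node ids, child label where the child is a tip, `is_internal`, `nbNS`,
#'   `nbS`.
#' @export
map_substitutions <- function(alignment, tree = NULL, fit) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (is.null(tree)) tree <- fit$tree
  dat <- prepare_likelihood_data(alignment, tree)
  ct <- codon_tables()
  if (sum(dat$blen) * fit$scale == 0 &&
      any(apply(dat$tipstates, 2, function(col) length(unique(col[col >= 0])) > 1)))
    warning("zero-length tree with polymorphic columns: counts are zero")
  res <- cpp_expected_counts(dat$tipstates, dat$weights, dat$edge, dat$blen,
                             ct$pairtype, fit$pi, fit$kappa, fit$omegas,
                             fit$class_probs, fit$scale)
  ntip <- dat$ntip
  child <- dat$edge[, 2]
  data.frame(
    branch = seq_len(nrow(dat$edge)),
    parent = dat$edge[, 1],
    child = child,
    child_label = ifelse(child <= ntip, tree$tip.label[child], ""),
    is_internal = child > ntip,
    nbNS = res$nbNS,
    nbS = res$nbS,
    stringsAsFactors = FALSE)
}

#' Branch-level dN/dS from mapped counts and site opportunities
#'
#' `omega = (nbNS / NSsites) / (nbS / Ssites)`.  Undefined (NA) when
#' `nbS = 0`.
#'
#' @param nbNS,nbS expected nonsynonymous/synonymous counts (vectors).
#' @param counts list with `NSsites` and `Ssites` (see
#'   [count_syn_nonsyn_sites()]).
#' @return numeric vector of branch omega values.
#' @export
compute_branch_omega <- function(nbNS, nbS, counts) {
  stopifnot(counts$NSsites > 0, counts$Ssites > 0)
  ifelse(nbS > 0, (nbNS / counts$NSsites) / (nbS / counts$Ssites), NA_real_)
}

#' Filter and classify branch records
#'
#' Applies the cluster- and branch-level filters: a cluster is dropped unless
#' it has at least one expected synonymous and one expected nonsynonymous
#' substitution overall; branches with (near-)zero total counts are dropped;
#' branches with `nbS = 0` have no omega and are dropped with a reason.
#' Survivors are classified `lt1` (omega <= 1), `gt1` (1 < omega <= 1.2) or
#' `gt1_2` (omega > 1.2, strict; the strong positive-selection indicator).
#' `dS` is `nbS / Ssites`.
#'
#' @param records data frame from [map_substitutions()] (one cluster), or a
#'   row-bound set with a `cluster_id` column.
#' @param counts site opportunities for the cluster ([count_syn_nonsyn_sites()]);
#'   ignored when `records` already has `omega`.
#' @param omega_cutoffs classification thresholds, default `c(1, 1.2)`.
#' @param min_branch_subst drop branches whose `nbNS + nbS` falls below this
#'   (default 0.5: with expectation-based mapping a branch carrying less than
#'   half an expected substitution is the analogue of "no substitutions").
#' @param min_syn_subst drop branches whose `nbS` falls below this (default
#'   0.5: the realized-count analogue, zero synonymous substitutions, leaves
#'   omega undefined).
#' @return list with `records` (filtered data frame with `omega`, `dS`,
#'   `class`), `cluster_kept` (logical), `dropped` (data frame of dropped
#'   branches with reasons).
#' @export
filter_and_classify_branches <- function(records, counts,
                                         omega_cutoffs = c(1, 1.2),
                                         min_branch_subst = 0.5,
                                         min_syn_subst = 0.5) {
  stopifnot(is.data.frame(records))
  tot_s <- sum(records$nbS)
  tot_ns <- sum(records$nbNS)
  if (tot_s < 1 || tot_ns < 1) {
    return(list(records = records[0, , drop = FALSE], cluster_kept = FALSE,
                dropped = data.frame(branch = records$branch,
                                     reason = "cluster lacks >=1 syn and >=1 nonsyn substitution")))
  }
  drop_zero <- (records$nbNS + records$nbS) < min_branch_subst
  drop_nos <- !drop_zero & records$nbS < min_syn_subst
  keep <- !(drop_zero | drop_nos)
  reason <- character(nrow(records))
  reason[drop_zero] <- "no substitutions"
  reason[drop_nos] <- "no synonymous substitutions, omega undefined"
  dropped <- data.frame(branch = records$branch[!keep], reason = reason[!keep])
  out <- records[keep, , drop = FALSE]
  out$omega <- compute_branch_omega(out$nbNS, out$nbS, counts)
  out$dS <- out$nbS / counts$Ssites
  out$class <- ifelse(out$omega > omega_cutoffs[2], "gt1_2",
                      ifelse(out$omega > omega_cutoffs[1], "gt1", "lt1"))
  rownames(out) <- NULL
  list(records = out, cluster_kept = TRUE, dropped = dropped)
}
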