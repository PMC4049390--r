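#' Codon bookkeeping for the 61 sense codons of the standard genetic code
#'
#' Builds (once per session) the lookup tables the GY94 machinery relies on:
#' the ordered list of sense codons, their amino acids, and the classification
#' of every ordered codon pair as a synonymous/nonsynonymous transition or
#' transversion (single-nucleotide changes only).
#'
#' @return A list with elements `codons` (character, length 61), `aa`
#'   (amino-acid letters), `pairtype` (61 x 61 integer matrix; 0 = not a
#'   single-nucleotide change, 1 = synonymous transition, 2 = synonymous
#'   transversion, 3 = nonsynonymous transition, 4 = nonsynonymous
#'   transversion), and mutation-neighborhood tables used for site-opportunity
#'   counting (`nb_target`, `nb_ts`, `nb_syn`, `nb_stop`; 61 x 9).
#' @export
codon_tables <- function() {
  if (!is.null(.lse_env$codon_tables)) return(.lse_env$codon_tables)
  code <- Biostrings::GENETIC_CODE
  nucs <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nucs, nucs, nucs, stringsAsFactors = FALSE)[, 3:1],
                 1L, paste0, collapse = "")
  aa64 <- unname(code[all64])
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  stopifnot(length(sense) == 61L)
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  split3 <- do.call(rbind, strsplit(sense, ""))
  pairtype <- matrix(0L, 61L, 61L, dimnames = list(sense, sense))
  for (i in seq_len(61L)) {
    for (j in seq_len(61L)) {
      if (i == j) next
      diffpos <- which(split3[i, ] != split3[j, ])
      if (length(diffpos) != 1L) next
      ts <- is_ts(split3[i, diffpos], split3[j, diffpos])
      syn <- aa[i] == aa[j]
      pairtype[i, j] <- if (syn && ts) 1L else if (syn) 2L
        else if (ts) 3L else 4L
    }
  }
  # 9 single-nucleotide mutation targets per sense codon (stops included,
  # flagged); used by count_syn_nonsyn_sites()
  nb_target <- matrix(NA_integer_, 61L, 9L)
  nb_ts <- nb_syn <- nb_stop <- matrix(NA, 61L, 9L)
  for (i in seq_len(61L)) {
    k <- 0L
    for (pos in 1:3) {
      for (n in setdiff(nucs, split3[i, pos])) {
        k <- k + 1L
        mut <- split3[i, ]
        mut[pos] <- n
        mutc <- paste0(mut, collapse = "")
        nb_ts[i, k] <- is_ts(split3[i, pos], n)
        if (code[[mutc]] == "*") {
          nb_stop[i, k] <- TRUE
          nb_syn[i, k] <- NA
        } else {
          nb_stop[i, k] <- FALSE
          nb_target[i, k] <- match(mutc, sense)
          nb_syn[i, k] <- code[[mutc]] == aa[i]
        }
      }
    }
  }
  out <- list(codons = sense, aa = aa, pairtype = pairtype,
              nb_target = nb_target, nb_ts = nb_ts, nb_syn = nb_syn,
              nb_stop = nb_stop)
  .lse_env$codon_tables <- out
  out
}

codon_index <- function(codons) {
  match(toupper(codons), codon_tables()$codons)
}

#' Kappa-weighted synonymous and nonsynonymous site opportunities
#'
#' For each codon the 9 single-nucleotide mutations are enumerated; transitions
#' receive weight `kappa`, transversions weight 1, and mutations to stop codons
#' are excluded from the weights.  The synonymous fraction of each codon's
#' mutational opportunity, times 3, is that codon's synonymous site count.
#' Counts are averaged over sequences column by column (missing codons are
#' skipped), so `NSsites + Ssites = 3 * n_codons` always holds.
#'
#' @param alignment a [codon_alignment()].
#' @param kappa transition/transversion rate ratio (from the corresponding
#'   model fit).
#' @param pi ignored; accepted for interface compatibility (the opportunity
#'   counting is kappa-weighted only).
#' @return list with `Ssites`, `NSsites` (alignment totals) and `per_codon`
#'   synonymous-site vector.
#' @export
count_syn_nonsyn_sites <- function(alignment, kappa, pi = NULL) {
  ct <- codon_tables()
  stopifnot(inherits(alignment, "codon_alignment"), kappa > 0)
  # synonymous fraction per codon state under kappa weighting
  w <- ifelse(ct$nb_ts, kappa, 1)
  w[ct$nb_stop] <- 0
  syn_w <- w * ifelse(is.na(ct$nb_syn), 0, ct$nb_syn)
  sfrac <- rowSums(syn_w) / rowSums(w)      # length 61
  states <- alignment$states                # nseq x ncodon, NA = missing
  ncod <- ncol(states)
  per_codon <- numeric(ncod)
  for (j in seq_len(ncod)) {
    st <- states[, j]
    st <- st[!is.na(st)]
    per_codon[j] <- if (length(st)) 3 * mean(sfrac[st]) else 3 * mean(sfrac)
  }
  Ssites <- sum(per_codon)
  list(Ssites = Ssites, NSsites = 3 * ncod - Ssites, per_codon = per_codon)
}
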