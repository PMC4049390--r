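#' GY94 codon model parameters
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies over the 61 sense codons (summing to 1). A
#'   single name, `"uniform"`, is also accepted.
#' @return an object of class `gy94_params`.
#' @export
gy94_params <- function(kappa = 2, omega = 0.5, pi = "uniform") {
  if (identical(pi, "uniform")) pi <- rep(1 / 61, 61)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(omega), length(omega) == 1L, omega >= 0,
            length(pi) == 61L, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("codon frequencies must sum to 1")
  structure(list(kappa = kappa, omega = omega, pi = as.numeric(pi)),
            class = "gy94_params")
}

#' Build the GY94 instantaneous rate matrix
#'
#' Rates are zero for multi-nucleotide changes and proportional to
#' `pi_j`, `kappa*pi_j`, `omega*pi_j` or `omega*kappa*pi_j` for synonymous
#' transversions/transitions and nonsynonymous transversions/transitions
#' respectively.  The diagonal is set so rows sum to zero and, when
#' `normalize = TRUE`, the matrix is rescaled so the mean substitution rate at
#' stationarity equals one (branch lengths then read as expected substitutions
#' per codon).
#'
#' @param params a [gy94_params()] object.
#' @param normalize rescale to unit mean rate (default `TRUE`).
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
build_gy94_generator <- function(params, normalize = TRUE) {
  stopifnot(inherits(params, "gy94_params"))
  ct <- codon_tables()
  if (any(params$pi == 0))
    stop("codon frequencies must be strictly positive for the generator")
  res <- cpp_gy94_Q(ct$pairtype, params$pi, params$kappa, params$omega)
  Q <- res$Q
  if (normalize) {
    if (res$mu <= 0) stop("degenerate model: zero mean rate")
    Q <- Q / res$mu
  }
  dimnames(Q) <- list(ct$codons, ct$codons)
  Q
}

#' Empirical codon frequencies from an alignment (F3x4 and relatives)
#'
#' F3x4 multiplies position-specific nucleotide frequencies and renormalizes
#' over the 61 sense codons (codeml's common default).  `f61` uses observed
#' codon frequencies; `uniform` gives 1/61.  Frequencies are floored at a
#' small positive value so the likelihood machinery never sees a structural
#' zero for an observable codon.
#'
#' @param alignment a [codon_alignment()].
#' @param method one of `"F3x4"`, `"F61"`, `"uniform"`.
#' @return numeric vector of 61 codon frequencies summing to 1.
#' @export
codon_frequencies <- function(alignment, method = c("F3x4", "F61", "uniform")) {
  method <- match.arg(method)
  ct <- codon_tables()
  if (method == "uniform") return(rep(1 / 61, 61))
  states <- alignment$states
  obs <- table(factor(states[!is.na(states)], levels = seq_len(61L)))
  if (method == "F61") {
    pi <- as.numeric(obs) + 0.5  # light smoothing: every sense codon observable
    return(pi / sum(pi))
  }
  # F3x4: nucleotide frequencies per codon position
  split3 <- do.call(rbind, strsplit(ct$codons, ""))
  nucs <- c("T", "C", "A", "G")
  counts <- matrix(0, 3, 4, dimnames = list(NULL, nucs))
  tot <- as.numeric(obs)
  for (pos in 1:3)
    for (n in seq_along(nucs))
      counts[pos, n] <- sum(tot[split3[, pos] == nucs[n]])
  freqs <- counts / rowSums(counts)
  freqs <- pmax(freqs, 1e-4)
  freqs <- freqs / rowSums(freqs)
  pi <- freqs[1, split3[, 1]] * freqs[2, split3[, 2]] * freqs[3, split3[, 3]]
  pi / sum(pi)
}
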