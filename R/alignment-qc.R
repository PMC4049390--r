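#' Codon alignment container
#'
#' A light S3 container holding aligned coding sequences as both character
#' strings and a matrix of 61-state codon indices (NA for codons containing
#' gaps or Ns, which the likelihood treats as missing data).
#'
#' @param seqs named character vector of aligned sequences over
#'   `A,C,G,T,N,-` (equal lengths, divisible by three).
#' @param ids sequence identifiers; defaults to `names(seqs)`.
#' @return object of class `codon_alignment` with fields `ids`, `seqs`,
#'   `states` (nseq x ncodon integer matrix) and `n_codons`.
#' @export
codon_alignment <- function(seqs, ids = names(seqs)) {
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  stopifnot(length(seqs) >= 1L, length(ids) == length(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  if (lens[1] %% 3 != 0) stop("alignment length not divisible by three")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  ncod <- lens[1] %/% 3
  ct <- codon_tables()
  states <- matrix(NA_integer_, length(seqs), ncod)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    idx <- match(cods, ct$codons)
    internal_stop <- is.na(idx) & !grepl("[N-]", cods)
    if (any(internal_stop))
      stop("stop codon inside sequence ", ids[i], " at codon ",
           which(internal_stop)[1])
    states[i, ] <- idx
  }
  structure(list(ids = ids, seqs = unname(seqs), states = states,
                 n_codons = ncod),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$ids), "sequences x", x$n_codons, "codons\n")
  invisible(x)
}

#' Read/write FASTA codon alignments
#'
#' Thin wrappers around ape's FASTA I/O, returning/accepting
#' [codon_alignment()] objects. Output wraps at 60 columns.
#' @param path file path.
#' @rdname codon_fasta
#' @export
read_codon_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste0, character(1), collapse = "")
  codon_alignment(setNames(seqs, names(dna)))
}

#' @param alignment a [codon_alignment()].
#' @rdname codon_fasta
#' @export
write_codon_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$ids)) {
    writeLines(paste0(">", alignment$ids[i]), con)
    s <- alignment$seqs[i]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a cluster of unaligned CDS sequences
#'
#' The whole cluster is rejected if any member sequence has length not
#' divisible by three, contains an internal stop codon (standard code), or
#' contains characters other than `A,C,G,T,N`.  Terminal stop codons are
#' stripped, not fatal.
#'
#' @param sequences named character vector of CDS sequences.
#' @return list with `pass` (logical), `reasons` (character, one entry per
#'   offending sequence) and `sequences` (terminal stops stripped, only
#'   meaningful when `pass`).
#' @export
validate_cds_cluster <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  sequences <- toupper(as.character(sequences))
  stops <- c("TAA", "TAG", "TGA")
  reasons <- character(0)
  out <- sequences
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (grepl("[^ACGTN]", s)) {
      reasons <- c(reasons, paste0(ids[i], ": non-nucleotide characters"))
      next
    }
    if (nchar(s) %% 3 != 0) {
      reasons <- c(reasons, paste0(ids[i], ": length not divisible by three"))
      next
    }
    ncod <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    if (cods[ncod] %in% stops) {
      cods <- cods[-ncod]
      out[i] <- paste0(cods, collapse = "")
    }
    if (any(cods %in% stops)) {
      reasons <- c(reasons, paste0(ids[i], ": internal stop"))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       sequences = setNames(out, ids))
}

#' Alignment-cleaning configuration
#'
#' @param column_cutoff reliability cutoff applied to external per-column
#'   scores (default 0.97).
#' @param gap_cutoff built-in fallback: codon columns whose gap fraction
#'   exceeds this are dropped (default 0.5).
#' @param min_sequences minimum sequences a cluster must keep after cleaning
#'   (default 4).
#' @export
cleaning_config <- function(column_cutoff = 0.97, gap_cutoff = 0.5,
                            min_sequences = 4L) {
  stopifnot(column_cutoff >= 0, column_cutoff <= 1,
            gap_cutoff >= 0, gap_cutoff <= 1, min_sequences >= 1)
  list(column_cutoff = column_cutoff, gap_cutoff = gap_cutoff,
       min_sequences = as.integer(min_sequences))
}

#' Drop unreliable codon columns from an alignment
#'
#' If an external per-column reliability mask is supplied (one score per
#' nucleotide column or one per codon column), codon columns scoring below
#' `config$column_cutoff` are removed (a codon's score is the minimum of its
#' three nucleotide columns).  Without a mask, the fallback filter removes
#' codon columns whose gap fraction exceeds `config$gap_cutoff`.  Columns are
#' removed in whole codons only; cleaning is idempotent.
#'
#' @param alignment a [codon_alignment()].
#' @param mask optional numeric reliability scores.
#' @param config a [cleaning_config()].
#' @return cleaned [codon_alignment()]; attribute `"dropped_codons"` lists the
#'   removed 1-based codon positions.
#' @export
clean_alignment <- function(alignment, mask = NULL, config = cleaning_config()) {
  stopifnot(inherits(alignment, "codon_alignment"))
  ncod <- alignment$n_codons
  if (!is.null(mask)) {
    if (length(mask) == 3L * ncod) {
      codon_score <- apply(matrix(mask, nrow = 3), 2, min)
    } else if (length(mask) == ncod) {
      codon_score <- as.numeric(mask)
    } else {
      stop("mask length must equal the nucleotide or codon column count")
    }
    drop <- codon_score < config$column_cutoff
  } else {
    gapfrac <- colMeans(is.na(alignment$states))
    drop <- gapfrac > config$gap_cutoff
  }
  if (!any(drop)) {
    attr(alignment, "dropped_codons") <- integer(0)
    return(alignment)
  }
  keep <- which(!drop)
  nt_keep <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  seqs <- vapply(alignment$seqs, function(s) {
    paste0(strsplit(s, "")[[1]][nt_keep], collapse = "")
  }, character(1))
  out <- codon_alignment(setNames(unname(seqs), alignment$ids))
  attr(out, "dropped_codons") <- which(drop)
  out
}

#' Minimum-size filter for cleaned clusters
#'
#' @param alignment a [codon_alignment()].
#' @param min_sequences minimum number of sequences required (default 4).
#' @return list with `pass` and `n`.
#' @export
apply_min_size <- function(alignment, min_sequences = 4L) {
  n <- length(alignment$ids)
  list(pass = n >= min_sequences, n = n)
}

#' Read an optional per-column reliability mask
#'
#' Whitespace-separated scores, one per alignment column.
#' @param path text file of scores.
#' @export
read_column_mask <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}
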