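#' Default ten-species tree (two clades of five)
#'
#' Ultrametric, depth 1, mimicking a monocot clade and a dicot clade of five
#' well-annotated genomes each.
#'
#' @param depth root depth in time units (default 1).
#' @return rooted ultrametric `phylo` with tips `mono1..mono5`,
#'   `dico1..dico5`.
#' @export
default_species_tree <- function(depth = 1) {
  txt <- paste0(
    "((mono1:0.25,(mono2:0.2,(mono3:0.12,(mono4:0.06,mono5:0.06):0.06):0.08)",
    ":0.05):0.75,(dico1:0.25,(dico2:0.2,(dico3:0.12,(dico4:0.06,dico5:0.06)",
    ":0.06):0.08):0.05):0.75);")
  tr <- ape::read.tree(text = txt)
  tr$edge.length <- tr$edge.length * depth
  tr
}

#' Simulation configuration
#'
#' Defaults describe the emulated study: ten species in two clades of five,
#' gene families shaped by duplication/loss with lineage-specific bursts on
#' designated terminal lineages, and codon alignments evolved under
#' purifying/neutral/positive site-class mixtures.
#'
#' @param n_families number of gene families (default 50).
#' @param dup_rate background duplication/retention rate per gene lineage per
#'   unit time (default 0.08).
#' @param loss_rate loss rate per gene lineage per unit time (default 0.02).
#' @param stem_length length of the family stem above the species root
#'   (default 0.4); ancient duplications here create paralogous subfamilies,
#'   the way multi-subfamily plant gene families arise.
#' @param stem_multiplier duplication-rate multiplier on the stem (default
#'   25, so roughly half the families carry at least one ancient
#'   duplication).
#' @param burst_species terminal lineages eligible for a lineage-specific
#'   expansion burst (default the two longest terminal branches, one per
#'   clade).
#' @param burst_fraction fraction of families in which a burst is active, on
#'   one eligible lineage chosen uniformly (default 0.35).
#' @param burst_subfamily_prob probability that any given subfamily (lineage
#'   crossing the species root) of a bursting family actually expands
#'   (default 0.6), so families can hold both an expanded and a single-copy
#'   subfamily, as GreenPhyl-style families do.
#' @param burst_multiplier multiplier on the duplication rate along the
#'   bursting terminal branch (default 120; duplications compound, so this
#'   yields expansions of roughly 6-15 copies).
#' @param n_codons codon alignment length (default 400, matching typical
#'   ~1.2 kb plant CDS alignments).
#' @param clock_rate substitutions per codon per unit time scaling gene-tree
#'   branch lengths (default 0.3).
#' @param kappa transition/transversion ratio (default 2).
#' @param pi codon frequencies (default uniform over the 61 sense codons).
#' @param site_spec a [site_model_spec()] describing the site-class truth for
#'   ordinary families (default M1a, p0 = 0.8, omega0 = 0.2).
#' @param psel_fraction fraction of families evolved with a positive-selection
#'   class instead (default 0.1).
#' @param psel_spec site-class truth for those families (default M2a,
#'   p0 = 0.7, p1 = 0.15, omega0 = 0.2, omega2 = 4).
#' @param seed mandatory integer seed.
#' @export
simulation_config <- function(n_families = 50L, dup_rate = 0.08,
                              loss_rate = 0.02,
                              stem_length = 0.4, stem_multiplier = 25,
                              burst_species = c("mono1", "dico1"),
                              burst_fraction = 0.35,
                              burst_subfamily_prob = 0.6,
                              burst_multiplier = 100,
                              n_codons = 400L, clock_rate = 0.3,
                              kappa = 2, pi = "uniform",
                              site_spec = site_model_spec("M1a", p0 = 0.8,
                                                          omega0 = 0.2),
                              psel_fraction = 0.1,
                              psel_spec = site_model_spec("M2a", p0 = 0.7,
                                                          p1 = 0.15,
                                                          omega0 = 0.2,
                                                          omega2 = 4),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(dup_rate >= 0, loss_rate >= 0, burst_multiplier >= 0,
            stem_length >= 0, stem_multiplier >= 0,
            burst_fraction >= 0, burst_fraction <= 1,
            n_codons >= 1, clock_rate > 0, psel_fraction >= 0,
            psel_fraction <= 1)
  if (identical(pi, "uniform")) pi <- rep(1 / 61, 61)
  list(n_families = as.integer(n_families), dup_rate = dup_rate,
       loss_rate = loss_rate, stem_length = stem_length,
       stem_multiplier = stem_multiplier, burst_species = burst_species,
       burst_fraction = burst_fraction,
       burst_subfamily_prob = burst_subfamily_prob,
       burst_multiplier = burst_multiplier, n_codons = as.integer(n_codons),
       clock_rate = clock_rate, kappa = kappa, pi = pi,
       site_spec = site_spec, psel_fraction = psel_fraction,
       psel_spec = psel_spec, seed = as.integer(seed))
}

# internal: recursive birth-death of gene lineages along the species tree.
# `burst_on` marks subfamilies (lineages crossing the species root) in which
# the lineage-specific expansion is active.  Returns a nested list tree
# (time-based branch lengths) or NULL (extinct).
sim_lineage <- function(stree, sedge, node, t_remaining, cfg, state,
                        burst_on = FALSE) {
  # t_remaining: time left on the species-tree branch leading to `node`
  is_tip <- node <= length(stree$tip.label)
  is_root <- node == length(stree$tip.label) + 1L
  sp_label <- if (is_tip) stree$tip.label[node] else NA_character_
  rate_mult <- if (is_tip && burst_on && identical(sp_label, cfg$active_burst))
    cfg$burst_multiplier else if (is_root) cfg$stem_multiplier else 1
  d_rate <- cfg$dup_rate * rate_mult
  l_rate <- cfg$loss_rate
  t_dup <- if (d_rate > 0) rexp(1, d_rate) else Inf
  t_loss <- if (l_rate > 0) rexp(1, l_rate) else Inf
  if (min(t_dup, t_loss) < t_remaining) {
    if (t_loss <= t_dup) return(NULL)   # lineage lost
    left <- sim_lineage(stree, sedge, node, t_remaining - t_dup, cfg, state,
                        burst_on)
    right <- sim_lineage(stree, sedge, node, t_remaining - t_dup, cfg, state,
                         burst_on)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) { right$len <- right$len + t_dup; return(right) }
    if (is.null(right)) { left$len <- left$len + t_dup; return(left) }
    return(list(event = "D", len = t_dup, children = list(left, right)))
  }
  if (is_tip) {
    state$counter <- state$counter + 1L
    gid <- sprintf("%s_g%03d", sp_label, state$counter)
    return(list(event = "leaf", len = t_remaining, label = gid,
                species = sp_label))
  }
  if (is_root) {
    # stem lineage enters the species tree proper: decide whether this
    # subfamily carries the expansion
    burst_on <- length(cfg$active_burst) > 0 &&
      runif(1) < cfg$burst_subfamily_prob
  }
  ch_edges <- which(stree$edge[, 1] == node)
  kids <- list()
  for (e in ch_edges) {
    k <- sim_lineage(stree, sedge, stree$edge[e, 2], stree$edge.length[e],
                     cfg, state, burst_on)
    if (!is.null(k)) kids[[length(kids) + 1L]] <- k
  }
  if (!length(kids)) return(NULL)
  if (length(kids) == 1L) {
    kids[[1]]$len <- kids[[1]]$len + t_remaining
    return(kids[[1]])
  }
  list(event = "S", len = t_remaining, children = kids)
}

nested_to_newick <- function(node) {
  if (node$event == "leaf")
    return(sprintf("%s:%.8f", node$label, node$len))
  inner <- paste(vapply(node$children, nested_to_newick, character(1)),
                 collapse = ",")
  sprintf("(%s)%s:%.8f", inner, node$event, node$len)
}

#' Simulate one gene family along the species tree
#'
#' Birth-death process of gene lineages: duplications (optionally boosted on
#' designated terminal "burst" lineages) create paralog clades, losses prune
#' lineages, and surviving lineages split at every speciation node.  The
#' returned tree is time-based and carries true event labels (`D`/`S`) as
#' node labels.
#'
#' @param species_tree rooted ultrametric `phylo`.
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param max_retry resimulation attempts when the whole family dies out.
#' @return list with `tree` (`phylo`, branch lengths in time units), `species`
#'   (per tip), `truth` (list: `event` per internal node in ape numbering).
#' @export
simulate_gene_family <- function(species_tree, config, seed = config$seed,
                                 max_retry = 20L) {
  set.seed(seed)
  root <- length(species_tree$tip.label) + 1L
  config$active_burst <-
    if (length(config$burst_species) && runif(1) < config$burst_fraction)
      sample(config$burst_species, 1L) else character(0)
  for (try in seq_len(max_retry)) {
    state <- new.env()
    state$counter <- 0L
    nested <- sim_lineage(species_tree, NULL, root, config$stem_length,
                          config, state)
    if (is.null(nested) || nested$event == "leaf") next
    txt <- paste0(nested_to_newick(nested), ";")
    tr <- ape::read.tree(text = txt)
    sp <- tip_species(tr, sep = "_")
    ev <- tr$node.label
    ntip <- length(tr$tip.label)
    event <- rep(NA_character_, ntip + tr$Nnode)
    event[(ntip + 1L):(ntip + tr$Nnode)] <- ev
    return(list(tree = tr, species = sp,
                truth = list(event = event,
                             active_burst = config$active_burst)))
  }
  stop("gene family went extinct in every attempt")
}

#' Simulate a codon alignment along a gene tree
#'
#' Each site draws a class from `spec`, then evolves by the GY94 CTMC along
#' the tree; every realized substitution is recorded with its
#' synonymous/nonsynonymous label.  The state space is the 61 sense codons,
#' so no stop codon can ever be produced.  Generators are normalized so the
#' mixture-average rate is one: branch lengths read as expected substitutions
#' per codon.
#'
#' @param gene_tree rooted `phylo`; branch lengths in expected substitutions
#'   per codon.
#' @param spec a [site_model_spec()] (truth).
#' @param params a [gy94_params()] (its `omega` is ignored for mixtures).
#' @param length number of codons.
#' @param seed integer seed.
#' @return list with `alignment` ([codon_alignment()]), `truth`
#'   (`site_class`, `site_omega`, per-branch realized `branch_syn` /
#'   `branch_nonsyn` totals, per-site matrices).
#' @export
simulate_codon_alignment <- function(gene_tree, spec, params, length, seed) {
  set.seed(seed)
  stopifnot(all(params$pi > 0))
  ct <- codon_tables()
  mix <- mixture_classes(spec)
  K <- base::length(mix$omegas)
  Qs <- vector("list", K)
  c_norm <- 0
  for (k in seq_len(K)) {
    res <- cpp_gy94_Q(ct$pairtype, params$pi, params$kappa, mix$omegas[k])
    Qs[[k]] <- res$Q
    c_norm <- c_norm + mix$probs[k] * res$mu
  }
  Qs <- lapply(Qs, function(Q) Q / c_norm)
  site_class <- sample.int(K, length, replace = TRUE, prob = mix$probs)
  root_states <- sample.int(61L, length, replace = TRUE, prob = params$pi)
  tr <- gene_tree
  sim <- cpp_simulate_alignment(tr$edge, tr$edge.length,
                                base::length(tr$tip.label),
                                root_states - 1L, site_class - 1L, Qs,
                                ct$pairtype)
  tips <- sim$tipstates + 1L
  seqs <- apply(tips, 1, function(st) paste0(ct$codons[st], collapse = ""))
  names(seqs) <- tr$tip.label
  aln <- codon_alignment(seqs)
  list(alignment = aln,
       truth = list(site_class = site_class,
                    site_omega = mix$omegas[site_class],
                    branch_syn = rowSums(sim$branch_syn),
                    branch_nonsyn = rowSums(sim$branch_nonsyn),
                    branch_syn_by_site = sim$branch_syn,
                    branch_nonsyn_by_site = sim$branch_nonsyn,
                    edge = tr$edge))
}

#' Generate a complete self-contained synthetic study
#'
#' Writes, per family, a gapless codon FASTA and a newick gene tree (branch
#' lengths in substitutions per codon), plus truth tables (true node events,
#' true UP/SO memberships from the true labels, per-site omega classes,
#' realized per-branch substitution counts) and a JSON manifest with the
#' configuration, seed and content digests.
#'
#' @param config a [simulation_config()].
#' @param dir target directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) the manifest as a list.
#' @export
generate_fixture_study <- function(config, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("target directory exists and is not empty: ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stree <- default_species_tree()
  ape::write.tree(stree, file.path(dir, "species_tree.nwk"))
  truth_clusters <- list()
  events_rows <- list()
  set.seed(config$seed)
  fam_seeds <- sample.int(2^31 - 2, max(1L, config$n_families) * 2L)
  psel <- if (config$n_families > 0)
    runif(config$n_families) < config$psel_fraction else logical(0)
  for (f in seq_len(config$n_families)) {
    fam_id <- sprintf("fam%03d", f)
    fam <- simulate_gene_family(stree, config, seed = fam_seeds[2 * f - 1])
    tr <- fam$tree
    tr$edge.length <- tr$edge.length * config$clock_rate
    spec <- if (psel[f]) config$psel_spec else config$site_spec
    sim <- simulate_codon_alignment(tr, spec,
                                    gy94_params(config$kappa, 1, config$pi),
                                    config$n_codons,
                                    seed = fam_seeds[2 * f])
    write_codon_fasta(sim$alignment, file.path(dir, paste0(fam_id, ".fasta")))
    tr_out <- tr
    ape::write.tree(tr_out, file.path(dir, paste0(fam_id, ".nwk")))
    # truth: event labels & true clusters from true labels
    ntip <- length(tr$tip.label)
    rec_true <- structure(list(tree = tr, species = fam$species,
                               event = fam$truth$event,
                               n_duplications = sum(fam$truth$event == "D",
                                                    na.rm = TRUE)),
                          class = "reconciled_tree")
    ups <- extract_up_clusters(rec_true, min_size = 6L, tree_id = fam_id)
    sos <- extract_so_clusters(rec_true, min_size = 6L, tree_id = fam_id)
    truth_clusters[[f]] <- clusters_table(partition_categories(c(ups, sos)))
    idx <- (ntip + 1L):(ntip + tr$Nnode)
    events_rows[[f]] <- data.frame(family = fam_id, node = idx,
                                   event = fam$truth$event[idx],
                                   stringsAsFactors = FALSE)
    utils::write.table(
      data.frame(site = seq_len(config$n_codons),
                 class = sim$truth$site_class,
                 omega = sim$truth$site_omega),
      file.path(dir, paste0(fam_id, "_sites.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(branch = seq_len(nrow(tr$edge)),
                 parent = tr$edge[, 1], child = tr$edge[, 2],
                 n_syn = sim$truth$branch_syn,
                 n_nonsyn = sim$truth$branch_nonsyn),
      file.path(dir, paste0(fam_id, "_branches.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tc <- if (length(truth_clusters)) do.call(rbind, truth_clusters)
    else clusters_table(list())
  utils::write.table(tc, file.path(dir, "truth_clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ev <- if (length(events_rows)) do.call(rbind, events_rows)
    else data.frame(family = character(0), node = integer(0),
                    event = character(0))
  utils::write.table(ev, file.path(dir, "truth_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  digests <- as.list(tools::md5sum(file.path(dir, files)))
  names(digests) <- files
  manifest <- list(
    config = config[setdiff(names(config), c("site_spec", "psel_spec", "pi"))],
    site_spec = unclass(config$site_spec),
    psel_spec = unclass(config$psel_spec),
    seed = config$seed,
    n_families = config$n_families,
    psel_families = sprintf("fam%03d", which(psel)),
    files = digests)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
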