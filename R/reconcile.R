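#' Read a rooted species tree
#'
#' @param x path to a newick file, or a newick string.
#' @return rooted `phylo`; leaf labels must be unique.
#' @export
read_species_tree <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("could not parse species tree")
  if (anyDuplicated(tr$tip.label)) stop("species tree leaf labels not unique")
  if (!ape::is.rooted(tr)) stop("species tree must be rooted")
  tr
}

#' Species assignment for gene-tree tips
#'
#' Tips named `SPECIES_GENEID` are split at the first `sep`; alternatively a
#' two-column mapping (gene id, species id) can be supplied.
#'
#' @param tree gene tree (`phylo`).
#' @param species_map optional data frame / matrix with columns gene id and
#'   species id, or a named character vector (names = gene ids).
#' @param sep separator between species and gene id in tip labels.
#' @return character vector of species, named by tip label.
#' @export
tip_species <- function(tree, species_map = NULL, sep = "_") {
  tips <- tree$tip.label
  if (!is.null(species_map)) {
    if (is.data.frame(species_map) || is.matrix(species_map)) {
      sp <- setNames(as.character(species_map[, 2]),
                     as.character(species_map[, 1]))
    } else sp <- species_map
    out <- sp[tips]
    if (anyNA(out)) stop("species mapping missing for leaf: ",
                         tips[which(is.na(out))[1]])
    return(setNames(as.character(out), tips))
  }
  setNames(sub(paste0(sep, ".*$"), "", tips), tips)
}

# parent vector + depths of a phylo; nodes are ape codes
tree_parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  depth <- integer(n)
  ord <- tree$edge[order_edges_preorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(ord))) depth[ord[i, 2]] <- depth[ord[i, 1]] + 1L
  list(parent = parent, depth = depth, root = root)
}

# edge indices such that parents appear before children
order_edges_preorder <- function(tree) {
  rev(order_edges_postorder(tree))
}

order_edges_postorder <- function(tree) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  pending <- integer(nnode)
  for (e in seq_len(nrow(edge))) pending[edge[e, 1]] <- pending[edge[e, 1]] + 1L
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode - ntip))
  out <- integer(0)
  used <- rep(FALSE, nrow(edge))
  repeat {
    prog <- FALSE
    for (e in seq_len(nrow(edge))) {
      if (used[e] || !done[edge[e, 2]]) next
      used[e] <- TRUE
      out <- c(out, e)
      pending[edge[e, 1]] <- pending[edge[e, 1]] - 1L
      if (pending[edge[e, 1]] == 0L) done[edge[e, 1]] <- TRUE
      prog <- TRUE
    }
    if (length(out) == nrow(edge) || !prog) break
  }
  if (length(out) != nrow(edge)) stop("tree is not rooted/connected")
  out
}

species_lca_fun <- function(species_tree) {
  tp <- tree_parents(species_tree)
  function(a, b) {
    while (a != b) {
      if (tp$depth[a] >= tp$depth[b]) a <- tp$parent[a] else b <- tp$parent[b]
    }
    a
  }
}

#' Reconcile a gene tree against a species tree (LCA mapping)
#'
#' Each gene-tree node is mapped to the species-tree LCA of its leaf species.
#' An internal node is labeled a duplication iff its mapping equals the
#' mapping of at least one of its children (soft polytomies: any child
#' suffices), and a speciation otherwise.  Unrooted gene trees are first
#' rooted at the position minimizing the duplication count (ties broken by the
#' first edge in the stored traversal).
#'
#' @param gene_tree `phylo` (rooted, or unrooted if `auto_root = TRUE`).
#' @param species_tree rooted `phylo` of the species.
#' @param species optional explicit species per tip (see [tip_species()]).
#' @param species_map,sep passed to [tip_species()].
#' @param auto_root root unrooted input by duplication-count minimization.
#' @return object of class `reconciled_tree`: `tree`, `species`, `event`
#'   (named `"D"`/`"S"` per internal node id), `mapping` (gene node id ->
#'   species-tree node id), `n_duplications`.
#' @export
reconcile_label <- function(gene_tree, species_tree, species = NULL,
                            species_map = NULL, sep = "_", auto_root = TRUE) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!ape::is.rooted(gene_tree)) {
    if (!auto_root)
      stop("gene tree is unrooted; reconciliation requires a rooted tree")
    gene_tree <- root_minimize_duplications(gene_tree, species_tree,
                                            species_map = species_map,
                                            sep = sep, species = species)
  }
  sp <- if (is.null(species)) tip_species(gene_tree, species_map, sep)
    else species[gene_tree$tip.label]
  unknown <- !(sp %in% species_tree$tip.label)
  if (any(unknown))
    stop("leaf species not in species tree: ",
         paste(unique(sp[unknown]), collapse = ", "),
         " (leaf ", gene_tree$tip.label[which(unknown)[1]], ")")
  lca <- species_lca_fun(species_tree)
  ntip <- length(gene_tree$tip.label)
  nnode_tot <- ntip + gene_tree$Nnode
  mapping <- integer(nnode_tot)
  mapping[seq_len(ntip)] <- match(sp, species_tree$tip.label)
  event <- rep(NA_character_, nnode_tot)
  edge <- gene_tree$edge
  for (e in order_edges_postorder(gene_tree)) {
    # children processed before parents; accumulate mapping at parent
    par <- edge[e, 1]; ch <- edge[e, 2]
    mapping[par] <- if (mapping[par] == 0L) mapping[ch]
      else lca(mapping[par], mapping[ch])
  }
  for (node in (ntip + 1L):nnode_tot) {
    ch <- edge[edge[, 1] == node, 2]
    event[node] <- if (any(mapping[ch] == mapping[node])) "D" else "S"
  }
  structure(list(tree = gene_tree, species = sp,
                 event = event, mapping = mapping,
                 n_duplications = sum(event == "D", na.rm = TRUE)),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  cat("reconciled_tree:", length(x$tree$tip.label), "leaves,",
      x$n_duplications, "duplication nodes\n")
  invisible(x)
}

#' Root an unrooted gene tree by duplication-count minimization
#'
#' Tries every edge as a root position and keeps the rooting with the fewest
#' duplication nodes under LCA reconciliation (first edge wins ties).
#'
#' @inheritParams reconcile_label
#' @return rooted `phylo`.
#' @export
root_minimize_duplications <- function(gene_tree, species_tree, species = NULL,
                                       species_map = NULL, sep = "_") {
  if (ape::is.rooted(gene_tree)) return(gene_tree)
  ntip <- length(gene_tree$tip.label)
  best <- NULL
  best_d <- Inf
  for (e in seq_len(nrow(gene_tree$edge))) {
    child <- gene_tree$edge[e, 2]
    tips_below <- if (child <= ntip) gene_tree$tip.label[child]
      else gene_tree$tip.label[clade_tips(gene_tree, child)]
    if (length(tips_below) == ntip) next
    cand <- tryCatch(
      ape::root(gene_tree, outgroup = tips_below, resolve.root = TRUE),
      error = function(err) NULL)
    if (is.null(cand) || !ape::is.rooted(cand)) next
    d <- reconcile_label(cand, species_tree, species = species,
                         species_map = species_map, sep = sep,
                         auto_root = FALSE)$n_duplications
    if (d < best_d) {
      best_d <- d
      best <- cand
    }
  }
  if (is.null(best)) stop("could not root gene tree")
  best
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- edge[edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  sort(out)
}

new_cluster <- function(id, tree_id, type, members, species, node) {
  structure(list(id = id, tree_id = tree_id, type = type,
                 category = NA_character_, upps = FALSE,
                 members = members, species = unique(species),
                 size = length(members), node = node),
            class = "lse_cluster")
}

#' @export
print.lse_cluster <- function(x, ...) {
  cat(sprintf("cluster %s [%s%s] tree %s: %d genes (%s)\n", x$id, x$type,
              if (!is.na(x$category)) paste0("/", x$category) else "",
              x$tree_id, x$size, paste(x$species, collapse = ",")))
  invisible(x)
}

#' Extract ultraparalog (UP) clusters
#'
#' Maximal subtrees whose leaves all belong to a single species (hence, under
#' LCA reconciliation, whose internal nodes are all duplications): the
#' lineage-specific expansions.  Only clusters with at least `min_size` leaves
#' are returned; clusters are leaf-disjoint by maximality.
#'
#' @param labeled a `reconciled_tree` from [reconcile_label()].
#' @param min_size minimum leaf count (default 6).
#' @param tree_id identifier recorded on the clusters.
#' @return list of `lse_cluster` objects (possibly empty).
#' @export
extract_up_clusters <- function(labeled, min_size = 6L, tree_id = "tree") {
  tr <- labeled$tree
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  edge <- tr$edge
  tp <- tree_parents(tr)
  # single-species flag per node
  one_sp <- logical(nn)
  spid <- integer(nn)
  one_sp[seq_len(ntip)] <- TRUE
  spid[seq_len(ntip)] <- match(labeled$species, unique(labeled$species))
  for (e in order_edges_postorder(tr)) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    if (spid[par] == 0L) {
      spid[par] <- spid[ch]
      one_sp[par] <- one_sp[ch]
    } else {
      one_sp[par] <- one_sp[par] && one_sp[ch] && spid[par] == spid[ch]
      if (spid[par] != spid[ch]) spid[par] <- -1L
    }
  }
  out <- list()
  for (node in seq_len(nn)) {
    if (!one_sp[node]) next
    par <- tp$parent[node]
    if (par != 0L && one_sp[par]) next  # not maximal
    tips <- clade_tips(tr, node)
    if (length(tips) < min_size) next
    members <- tr$tip.label[tips]
    cl <- new_cluster(id = paste0(tree_id, "_UP", length(out) + 1L),
                      tree_id = tree_id, type = "UP", members = members,
                      species = labeled$species[members], node = node)
    stopifnot(length(cl$species) == 1L)
    out <- c(out, list(cl))
  }
  out
}

#' Extract superortholog (SO) clusters
#'
#' Maximal subtrees whose internal nodes are all speciations: single-copy
#' sets with at most one gene per species, so cluster size is bounded by the
#' species count.
#'
#' @inheritParams extract_up_clusters
#' @return list of `lse_cluster` objects (possibly empty).
#' @export
extract_so_clusters <- function(labeled, min_size = 6L, tree_id = "tree") {
  tr <- labeled$tree
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  edge <- tr$edge
  tp <- tree_parents(tr)
  allspec <- logical(nn)
  allspec[seq_len(ntip)] <- TRUE
  allspec[(ntip + 1L):nn] <- labeled$event[(ntip + 1L):nn] == "S"
  for (e in order_edges_postorder(tr)) {
    # child flags are final when the edge is emitted (postorder)
    par <- edge[e, 1]; ch <- edge[e, 2]
    allspec[par] <- allspec[par] && allspec[ch]
  }
  out <- list()
  for (node in (ntip + 1L):nn) {
    if (!allspec[node]) next
    par <- tp$parent[node]
    if (par != 0L && allspec[par]) next
    tips <- clade_tips(tr, node)
    if (length(tips) < min_size) next
    members <- tr$tip.label[tips]
    sp <- labeled$species[members]
    if (anyDuplicated(sp))
      stop("internal error: SO cluster with duplicated species")
    cl <- new_cluster(id = paste0(tree_id, "_SO", length(out) + 1L),
                      tree_id = tree_id, type = "SO", members = members,
                      species = sp, node = node)
    out <- c(out, list(cl))
  }
  out
}

#' Assign UP1/UP2/SO1/SO2 categories
#'
#' UP clusters from trees that also yielded at least one SO cluster become
#' UP1 (else UP2); SO clusters from trees that also yielded a UP cluster
#' become SO1 (else SO2).
#'
#' @param clusters list of `lse_cluster` objects (from one or many trees).
#' @return the same list with `category` filled in.
#' @export
partition_categories <- function(clusters) {
  if (!length(clusters)) return(clusters)
  tree_ids <- vapply(clusters, `[[`, character(1), "tree_id")
  types <- vapply(clusters, `[[`, character(1), "type")
  has_up <- tapply(types == "UP", tree_ids, any)
  has_so <- tapply(types == "SO", tree_ids, any)
  lapply(clusters, function(cl) {
    cl$category <- if (cl$type == "UP") {
      if (isTRUE(has_so[[cl$tree_id]])) "UP1" else "UP2"
    } else {
      if (isTRUE(has_up[[cl$tree_id]])) "SO1" else "SO2"
    }
    cl
  })
}

#' Keep at most one UP and one SO cluster per tree
#'
#' When a tree yields several clusters of the same type, one is retained
#' uniformly at random (deterministic for a fixed seed).
#'
#' @param clusters list of `lse_cluster` objects.
#' @param seed integer seed for the draw.
#' @return filtered list.
#' @export
sample_one_per_tree <- function(clusters, seed) {
  stopifnot(!missing(seed))
  if (!length(clusters)) return(clusters)
  withr_seed <- function(code) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    code
  }
  keys <- paste(vapply(clusters, `[[`, character(1), "tree_id"),
                vapply(clusters, `[[`, character(1), "type"))
  withr_seed({
    keep <- unlist(lapply(split(seq_along(clusters), keys), function(idx) {
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }))
  })
  clusters[sort(keep)]
}

#' Tabulate clusters
#'
#' @param clusters list of `lse_cluster` objects.
#' @return data frame with columns cluster_id, tree_id, type, category, upps,
#'   size, species, member_ids (semicolon-joined).
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster_id = character(0), tree_id = character(0),
                      type = character(0), category = character(0),
                      upps = logical(0), size = integer(0),
                      species = character(0), member_ids = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    cluster_id = vapply(clusters, `[[`, character(1), "id"),
    tree_id = vapply(clusters, `[[`, character(1), "tree_id"),
    type = vapply(clusters, `[[`, character(1), "type"),
    category = vapply(clusters, `[[`, character(1), "category"),
    upps = vapply(clusters, `[[`, logical(1), "upps"),
    size = vapply(clusters, `[[`, integer(1), "size"),
    species = vapply(clusters, function(cl) paste(cl$species, collapse = ";"),
                     character(1)),
    member_ids = vapply(clusters, function(cl) paste(cl$members, collapse = ";"),
                        character(1)),
    stringsAsFactors = FALSE)
}

#' Estimate a gene tree from a codon alignment
#'
#' Baseline nucleotide-level maximum-likelihood tree (GTR+Gamma via phangorn,
#' neighbor-joining start, optional NNI rearrangements), midpoint-rooted.  An
#' externally supplied tree (`config$tree` as `phylo` or `config$tree_file`)
#' overrides estimation.
#'
#' @param alignment a [codon_alignment()] with at least three sequences.
#' @param config list: `method` ("ml" default, or "nj"), `nni` (default TRUE),
#'   `tree`, `tree_file`.
#' @return rooted `phylo` with branch lengths (substitutions per nucleotide
#'   site).
#' @export
estimate_gene_tree <- function(alignment, config = list()) {
  if (!is.null(config$tree)) return(config$tree)
  if (!is.null(config$tree_file)) return(ape::read.tree(config$tree_file))
  n <- length(alignment$ids)
  if (n < 3L) stop("tree estimation requires at least 3 sequences")
  chars <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(chars) <- alignment$ids
  pd <- phangorn::phyDat(chars, type = "DNA")
  dm <- phangorn::dist.ml(pd)
  dm[!is.finite(dm)] <- 0
  start <- ape::nj(dm)
  start$edge.length[start$edge.length < 0] <- 0
  method <- if (is.null(config$method)) "ml" else config$method
  if (method == "nj" || max(dm) < 1e-10) return(phangorn::midpoint(start))
  start$edge.length <- pmax(start$edge.length, 1e-8)
  fit <- phangorn::pml(start, data = pd, k = 4)
  nni <- if (is.null(config$nni)) n > 3L else isTRUE(config$nni)
  fit <- quiet(phangorn::optim.pml(
    fit, model = "GTR", optGamma = TRUE, optNni = nni, optEdge = TRUE,
    control = phangorn::pml.control(trace = 0)))
  phangorn::midpoint(fit$tree)
}

quiet <- function(expr) {
  withCallingHandlers(suppressMessages(expr),
                      warning = function(w) invokeRestart("muffleWarning"))
}
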