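# Independent oracles used across the suite.  These deliberately avoid the
# package's computational paths: matrix exponentials come from Matrix::expm,
# likelihoods from explicit state enumeration, reconciliation from clade-set
# logic, Fisher/Mann-Whitney p-values from exhaustive enumeration.

oracle_class_generators <- function(spec, params) {
  mix <- mixture_classes(spec)
  ct <- codon_tables()
  Qs <- list()
  cnorm <- 0
  for (k in seq_along(mix$omegas)) {
    Q <- build_gy94_generator(
      gy94_params(params$kappa, mix$omegas[k], params$pi), normalize = FALSE)
    cnorm <- cnorm + mix$probs[k] * (-sum(params$pi * diag(Q)))
    Qs[[k]] <- Q
  }
  list(Qs = lapply(Qs, function(Q) Q / cnorm), probs = mix$probs)
}

# brute-force mixture log-likelihood by enumerating all internal-node states
oracle_loglik <- function(aln, tree, spec, params, scale = 1) {
  g <- oracle_class_generators(spec, params)
  edge <- tree$edge
  blen <- tree$edge.length * scale
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  root <- setdiff(edge[, 1], edge[, 2])[1]
  states <- aln$states[match(tree$tip.label, aln$ids), , drop = FALSE]
  grid <- as.matrix(do.call(expand.grid, rep(list(1:61), length(internal))))
  total <- 0
  for (s in seq_len(ncol(states))) {
    sitelik <- 0
    for (k in seq_along(g$Qs)) {
      P <- lapply(seq_len(nrow(edge)), function(e)
        as.matrix(Matrix::expm(g$Qs[[k]] * blen[e])))
      full <- matrix(NA_integer_, nrow(grid), nnode)
      for (i in seq_len(ntip)) full[, i] <- states[i, s]
      full[, internal] <- grid
      pr <- params$pi[full[, root]]
      for (e in seq_len(nrow(edge))) {
        b <- full[, edge[e, 2]]
        if (anyNA(b)) next  # missing tip marginalizes to 1
        pr <- pr * P[[e]][cbind(full[, edge[e, 1]], b)]
      }
      sitelik <- sitelik + g$probs[k] * sum(pr)
    }
    total <- total + log(sitelik)
  }
  total
}

# clade-set reconciliation oracle: species-tree mapping as the smallest clade
# containing the node's species set; duplication iff a child maps to the same
# clade
oracle_reconcile <- function(gene_tree, species_tree, species) {
  ntip <- length(gene_tree$tip.label)
  nnode <- ntip + gene_tree$Nnode
  sclades <- lapply(seq_len(length(species_tree$tip.label) +
                              species_tree$Nnode), function(n) {
    if (n <= length(species_tree$tip.label)) species_tree$tip.label[n]
    else ape::extract.clade(species_tree, n)$tip.label
  })
  smallest <- function(spset) {
    cand <- which(vapply(sclades, function(cl) all(spset %in% cl), logical(1)))
    cand[which.min(lengths(sclades)[cand])]
  }
  node_sp <- function(n) {
    if (n <= ntip) return(species[gene_tree$tip.label[n]])
    unique(species[ape::extract.clade(gene_tree, n)$tip.label])
  }
  event <- rep(NA_character_, nnode)
  for (n in (ntip + 1):nnode) {
    mn <- smallest(node_sp(n))
    ch <- gene_tree$edge[gene_tree$edge[, 1] == n, 2]
    dup <- any(vapply(ch, function(c) smallest(node_sp(c)) == mn, logical(1)))
    event[n] <- if (dup) "D" else "S"
  }
  event
}

# brute-force cluster enumeration from labels
oracle_clusters <- function(gene_tree, species, event, min_size) {
  ntip <- length(gene_tree$tip.label)
  nnode <- ntip + gene_tree$Nnode
  parent <- integer(nnode)
  parent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]
  tipsets <- lapply(seq_len(nnode), function(n) {
    if (n <= ntip) gene_tree$tip.label[n]
    else ape::extract.clade(gene_tree, n)$tip.label
  })
  single_sp <- vapply(seq_len(nnode), function(n)
    length(unique(species[tipsets[[n]]])) == 1L, logical(1))
  allspec <- vapply(seq_len(nnode), function(n) {
    if (n <= ntip) return(TRUE)
    inner <- setdiff(which(vapply(seq_len(nnode), function(m)
      all(tipsets[[m]] %in% tipsets[[n]]), logical(1))), seq_len(ntip))
    all(event[inner] == "S")
  }, logical(1))
  up <- Filter(function(n) single_sp[n] &&
                 (parent[n] == 0 || !single_sp[parent[n]]) &&
                 length(tipsets[[n]]) >= min_size, seq_len(nnode))
  so <- Filter(function(n) n > ntip && allspec[n] &&
                 (parent[n] == 0 || !allspec[parent[n]]) &&
                 length(tipsets[[n]]) >= min_size, seq_len(nnode))
  list(up = lapply(up, function(n) sort(tipsets[[n]])),
       so = lapply(so, function(n) sort(tipsets[[n]])))
}

# exhaustive two-sided Fisher p for a 2x2 table
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive two-sided Mann-Whitney p by enumerating group assignments
oracle_mann_whitney <- function(x, y) {
  all <- c(x, y)
  n1 <- length(x)
  r <- rank(all)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combs <- combn(length(all), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small random gene tree over a species set
random_gene_tree <- function(nleaf, species_pool, seed) {
  set.seed(seed)
  tr <- ape::rtree(nleaf, rooted = TRUE)
  sp <- sample(species_pool, nleaf, replace = TRUE)
  tr$tip.label <- sprintf("%s_g%02d", sp, seq_len(nleaf))
  tr
}

random_codon_alignment <- function(ids, n_codons, seed) {
  set.seed(seed)
  ct <- codon_tables()
  seqs <- vapply(ids, function(i)
    paste0(sample(ct$codons, n_codons, replace = TRUE), collapse = ""),
    character(1))
  codon_alignment(seqs)
}

# shared small species tree for reconciliation tests
toy_species_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}
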