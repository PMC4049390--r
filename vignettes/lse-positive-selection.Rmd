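---
title: "Detecting positive selection in lineage-specific expanded gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection in lineage-specific expanded gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Recurrent gene duplication followed by retention produces lineage-specific
expansions (LSE): clades of paralogs confined to one species. A long-standing
hypothesis holds that such expansions are fuel for adaptation, which predicts
more frequent footprints of positive selection in LSE genes than in
single-copy genes. `lseselect` implements the full comparative design needed
to test that prediction on a set of annotated genomes:

1. **Reconciliation** of rooted gene trees against a rooted species tree by
   LCA mapping, labeling every internal node a duplication or a speciation.
2. **Cluster extraction**: *ultraparalogs* (UP) are maximal subtrees whose
   leaves all belong to one species (all internal nodes duplications) — the
   LSE set; *superorthologs* (SO) are maximal subtrees whose internal nodes
   are all speciations — a single-copy reference with at most one gene per
   species, so SO size is bounded by the species count. Clusters with fewer
   than six sequences are ignored. Clusters are cross-classified by whether
   their source tree also yielded the other type (UP1/SO1) or not (UP2/SO2),
   to control for a family effect, and at most one cluster per type is kept
   per tree (uniformly at random, seeded).
3. **Alignment QC**: whole clusters are rejected when any CDS has an internal
   stop codon or a length not divisible by three (terminal stops are
   stripped); unreliable codon columns are removed using an external
   per-column reliability mask when available (cutoff 0.97) or a gap-fraction
   fallback; clusters keeping fewer than four sequences are dropped.
4. **Codon site models**: GY94 over the 61 sense codons, with site-class
   mixtures M1a/M2a and M8a/M8, likelihood-ratio tests with Bonferroni
   correction, and empirical-Bayes per-site posteriors of omega > 1 (sites
   flagged strictly above 0.95).
5. **Branch analysis**: expected synonymous and nonsynonymous substitution
   counts per branch by analytic substitution mapping, and the branch
   statistic `omega = (nbNS/NSsites) / (nbS/Ssites)`, with `NSsites`/`Ssites`
   the kappa-weighted mutational opportunities. Branches with omega > 1.2 are
   treated as the strong indicator of positive selection, because in a
   neutral regime branch omega fluctuates around 1 rather than sitting at it.
6. **Comparative statistics**: two-sided Fisher's exact tests of UP vs SO per
   cluster-size category (clusters, codons, branches), Mann-Whitney
   comparisons of omega, Mann-Whitney tests in consecutive dS windows of
   width 0.01 (emitted only when both groups contribute at least 100 values;
   25 available as a config variant), and Spearman correlation of per-species
   cluster counts against divergence times.

## The codon model

The GY94 generator has entries proportional to `pi_j` (synonymous
transversion), `kappa pi_j` (synonymous transition), `omega pi_j` and
`omega kappa pi_j` (nonsynonymous), zero for multi-nucleotide changes, and is
normalized so the mixture-average substitution rate at stationarity is one —
branch lengths read as expected substitutions per codon. Codon frequencies
default to F3x4 estimated from each alignment (with `F61` and `uniform` as
options); position-specific nucleotide frequencies are floored at 1e-4 so no
observable codon gets a structural zero.

Site-class mixtures: M1a has classes `omega0 < 1` (proportion `p0`) and
`omega1 = 1`; M2a adds `omega2 > 1`. M8 discretizes a Beta(p, q) into K = 10
equal-probability categories (category means computed from the incomplete
beta function) plus a selection class `omega_s > 1`; M8a pins that class at
1. The M1a/M2a LRT uses 2 degrees of freedom; M8a/M8 uses the conservative
plain chi-square with 1 df (the 50:50 boundary mixture is available via
`mixture_null = TRUE`).

Likelihood is computed by Felsenstein pruning over the 61 states in compiled
code, with gaps and Ns as missing data and per-pattern scaling. The engine is
tested against brute-force marginalization over all internal-node states
(tolerance 1e-8) and satisfies the pulley principle exactly.

**Optimization.** The mixture weights are *profiled out exactly*: for fixed
omega classes the per-site class likelihoods do not depend on the weights
(internally the generators are normalized by a weight-independent constant,
and the reported scale is converted back to the mixture-mean-rate-one
convention afterwards), the weight problem is concave — the log of a linear
function per site — and EM solves it to its global optimum at every outer
step, with a boundary candidate (positive class emptied) evaluated
alongside. This removes the notoriously flat boundary directions of codon
mixture fits, guarantees nesting structurally (the alternative can always
reproduce its null), and leaves a small outer problem — log kappa, log
scale, logit omega0, `log(omega2 - 1)` so the positive class stays above 1,
log beta shapes — solved by bounded L-BFGS-B at relative log-likelihood
tolerance 1e-8. Positive-selection models run the three deterministic starts
`omega2 in {1.5, 3, 8}`, screened coarsely and polished from the best; fits
can be warm-started from the corresponding null fit (`init_fit`), which the
pipeline does — the standard hierarchical strategy. Branch lengths from the
input tree are rescaled by a single free multiplier by default;
`fit_options(branch_lengths = "optimize")` frees every branch (slow mode).
One subtlety worth recording: the EM warm start carried across outer
evaluations must be the interior EM iterate, never the selected boundary
candidate — a zero weight is absorbing under EM's multiplicative update.

**Site posteriors.** The default is naive empirical Bayes (plug-in MLEs): the
posterior mass of the omega > 1 class(es) per site. A BEB-style mode
(`beb_site_posterior`) integrates over a uniform grid on (p2, omega2) for
M2a, weighting grid points by their data likelihood; it is an approximation
in the spirit of Bayes empirical Bayes, adequate for the comparative claims
the pipeline makes, and documented as such. Null-model fits return all-zero
posteriors rather than an error so the reporting path is uniform.

## Substitution mapping

Per-branch expected labeled substitution counts are conditional expectations
of Markov jumps given the data: with `Q = A diag(lambda) A^-1`,
`M_L(t) = A ((A^-1 (Q o L) A) o J(t)) A^-1` where
`J_ij = (e^{lambda_i t} - e^{lambda_j t}) / (lambda_i - lambda_j)`. Counts
are accumulated per site with an inside-outside pass and mixed over site
classes by their posterior probability at each site, consistent with the fit
that supplies `NSsites`/`Ssites`. Expectations (not stochastic draws) make
the output deterministic; they are validated against 100,000 simulated CTMC
paths on single-branch toys, both unconditionally and conditioned on the end
state.

Branch dS is `nbS / Ssites`, mirroring the omega construction. Cluster-level
filters: a cluster needs at least one expected synonymous and one expected
nonsynonymous substitution overall. Branch-level filters are the expectation
analogues of the realized-count rules: a branch carrying less than half an
expected substitution counts as "containing no substitutions" and is
dropped, and a branch with less than half an expected *synonymous*
substitution is dropped because its realized analogue (zero synonymous
substitutions) leaves omega undefined — keeping such branches would let a
single nonsynonymous event on a near-zero-dS branch produce omega in the
tens, an artifact of residual polymorphism on young branches rather than
selection. Both thresholds are configurable. Classification: omega <= 1,
(1, 1.2], and strictly above 1.2.

## The synthetic world

No public accessions exist for the original data, so the package ships a
generator whose defaults state the emulated world once:

- **Species tree**: ten species, two clades of five (a monocot-like and a
  dicot-like clade), ultrametric, depth 1.
- **Families**: a birth-death process of gene lineages along the species
  tree; duplication rate 0.08 and loss rate 0.02 per lineage per unit time.
  A *stem* of length 0.4 above the species root carries a 25-fold duplication
  rate: roughly half the families acquire ancient duplications and hence
  multiple subfamilies, the way multi-subfamily plant families arise. This is
  structurally necessary, not cosmetic: with two clades of five species, a
  speciation-only subtree of six or more sequences must span the root, so
  UP1/SO1 co-occurrence is only reachable in families with an ancient
  duplication.
- **Bursts**: 35% of families activate an LSE burst on one designated
  terminal lineage (the two longest tips by default); within such a family
  each subfamily expands independently with probability 0.6, at 100x the
  background duplication rate. Duplications compound, yielding expansions of
  roughly 6-15 copies and UP cluster sizes with median near 7-10, in line
  with published LSE cluster-size distributions.
- **Sequences**: 400 codons (about 1.2 kb, typical of plant CDS alignments),
  kappa 2, uniform codon frequencies, clock 0.3 substitutions per codon per
  unit time (pairwise dS up to about 0.2, matching the informative range of
  the dS-window analysis). 90% of families evolve under a purifying/neutral
  M1a truth (p0 = 0.8, omega0 = 0.2); 10% carry a positive-selection class
  (M2a with p1 = 0.15 at omega2 = 4).

Alignments are simulated on the 61-sense-codon state space, so stop codons
cannot occur, realized substitutions are recorded with their syn/nonsyn
labels (exact truth for the mapping tests), and every file is reproducible
bit-for-bit from the single study seed.

What the generator does **not** emulate: indels and alignment error (inputs
are gapless by construction, so the GUIDANCE-style mask path is exercised
with synthetic masks, not real misalignment), whole-genome duplication, gene
conversion, rate heterogeneity beyond the stated mixtures, and base-composition
biases (uniform pi). A green end-to-end test therefore establishes that the
machinery recovers planted truths under the stated world, not that real
alignment pathologies are handled; the published workflow's manual curation
step is replaced by automated flags only.

## Numerical and procedural choices

- Alignment coordinates are 0-based internally; reports use 1-based codon
  positions.
- Bonferroni family size is the number of clusters tested within each
  category, recorded in the manifest.
- A cluster is called "under positive selection" when **either** LRT
  (M1a/M2a or M8a/M8) is Bonferroni-significant **and** at least one site is
  flagged; both LRTs are always reported and the conjunction rule is a config
  switch (`call_rule = "both"`), since the original procedure is ambiguous
  on this point. UPps is the subset of UP clusters so called.
- The summary tables report the dispersion of branch omega as its standard
  deviation (labeled SE in the emulated table layout, whose magnitudes make
  clear it is the sample SD).
- Sliding windows are consecutive half-open intervals of width 0.01 starting
  at 0; "sliding" with no stated step is read as a partition, matching the
  per-interval points of the published figure.
- Unrooted gene trees are rooted at the position minimizing the duplication
  count (first edge in the stored traversal wins ties); polytomies are soft
  (a node is a duplication if any child shares its LCA mapping).
- Tree estimation for clusters is a GTR+Gamma ML baseline (phangorn; NJ
  start, NNI rearrangements), midpoint-rooted; an externally supplied tree
  always takes precedence, and branch-length units are absorbed by the free
  scale multiplier during fitting.

## Known limitations

- NEB posteriors understate uncertainty in mixture weights relative to full
  BEB; the grid mode tempers but does not remove this.
- The M8a/M8 test with plain chi-square(1) is conservative at the boundary.
- Expectation-based "no substitution" filtering cannot reproduce exactly the
  integer-count filtering of the original tools; thresholds are configurable.
- The pipeline analyzes clusters independently; it does not model
  polymorphism, and very recent duplicates can inflate omega on external
  branches — which is why the internal-branch subset (UPint) and the
  dS-window comparison exist.
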