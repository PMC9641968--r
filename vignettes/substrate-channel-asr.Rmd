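---
title: "Ancestral reconstruction of active-site residue combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral reconstruction of active-site residue combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancsr)
```

## The question the package addresses

Marginal ancestral sequence reconstruction (ASR) assigns, to every site of
an alignment and every internal node of a phylogeny, a posterior
distribution over the twenty amino acids. For a handful of functionally
critical sites — here, the residues lining the substrate channel of the
nitrogenase D subunit — several ancestral states can carry non-negligible
probability at once, and the cross-product of those per-site alternatives
grows into a library of candidate ancestral sequences far larger than can
be tested in the lab. `ancsr` makes that library explicit: it reconstructs
the target ancestor, finds the panel sites that are ancestrally ambiguous,
enumerates every residue combination those sites support, weighs each
combination by its joint posterior probability, and asks whether each
combination — at the exact-residue level and at a coarser physicochemical
level — is represented anywhere in extant sequence diversity.

## Model and procedure

**Likelihood engine.** Sites evolve independently under a reversible
continuous-time Markov chain. An empirical exchangeability matrix $S$ and
equilibrium frequencies $\pi$ (packaged: LG, WAG, BLOSUM62 in the standard
lower-triangle text dialect) define the generator $Q_{ij} = S_{ij}\pi_j$
($i \ne j$), with the diagonal set so rows sum to zero and a global
rescaling so $-\sum_i \pi_i Q_{ii} = 1$; branch lengths are then expected
substitutions per site. Among-site rate variation is a finite mixture of
rate categories $\{(w_k, r_k)\}$ with $\sum_k w_k r_k = 1$: either a
discretised gamma (equal-probability bins represented by their category
means) or explicit free-rate pairs taken from an external fit — the
package deliberately never fits rates, topologies or branch lengths; those
are inputs. Transition probabilities $P(t) = e^{Qrt}$ come from a spectral
decomposition of the symmetrised generator
$D_\pi^{1/2} Q D_\pi^{-1/2}$, which is exact for reversible models and
cheap to reuse across branches and categories.

**Pruning and marginal reconstruction.** Site likelihoods are computed by
Felsenstein's pruning algorithm with per-node, per-site, per-category
log-scaling to prevent underflow. Posteriors at a target node use the
standard inside–outside two-pass: the "outside" partial for each node
combines the root prior $\pi$ with the partials of all off-path subtrees,
and the posterior is proportional to the product of inside and outside
vectors, summed over rate categories with their site-specific posterior
weights (not the single best category — the conventional marginal
treatment). Under reversibility the result equals re-rooting the tree at
the target node, and is invariant to the original root placement; the test
suite checks this invariance at `1e-9` alongside exact agreement with a
brute-force sum over all internal-state assignments on trees of up to five
leaves.

**Rooting and the target node.** Trees are rooted on a user-stated
outgroup; the branch separating outgroup from ingroup is split equally
between the two root children. The split is cosmetic — reversible
likelihoods are invariant to where the root sits on that branch (tested) —
so the even split is chosen for symmetry. The reconstruction target is the
most recent common ancestor of the ingroup taxa.

**Variable sites and combinations.** Within a site panel (alignment
columns annotated with reference-sequence numbering and structural roles),
a site is *variable* when at least two states exceed the posterior
threshold, strictly: the default threshold is 0.10 and a state at exactly
0.10 does not count. Sub-threshold states are retained in reports but
excluded from enumeration. The combination space is the full cross-product
of listed states over the variable sites; each combination's joint
probability is the product of its per-site posteriors, consistent with the
engine's per-site independence. Combinations are ranked by descending
joint probability, ties broken lexicographically — no ties occur in the
packaged reference profile, so the tie-break is a determinism guarantee,
not a scientific choice. Because the per-site lists are truncated at the
threshold, joints need not sum to one; with complete per-site
distributions they form a product measure and sum to one exactly (a tested
invariant). Both the raw joint and the ratio to the top-ranked combination
are reported, since "likelihood ratio" is used with either normalisation
in practice.

**Physicochemical recoding.** Residues collapse to seven categories —
Acidic (E, D), Aliphatic (I, L, M, V), Amine (Q, N), Aromatic (W, Y, F),
Basic (K, R), Small Hydroxyl (S, T), Tiny (A, G). Cysteine, histidine and
proline belong to no group: each is a singleton category named by its
letter, so the recoding never asserts a similarity the scheme does not
contain; recoding one of them emits a message. Gaps and `X` recode to
`NA` ("unscorable") rather than erroring, because extant rows with
incomplete tuples are excluded from counting anyway.

**Extant comparison.** Residue tuples at the variable columns are tallied
across the ingroup only (outgroup rows are excluded by default — they are
not members of the protein family whose diversity is being probed;
configurable). Sequences with a gap or `X` at any profiled column are
excluded entirely and listed in an exclusion report: exact-tuple semantics
require complete tuples, and partial matching would silently change the
meaning of the counts. A combination is *absent* when its count is zero,
*rare* when at most `rare_max` (default 2) extant sequences carry it, and
*common* otherwise; the same rule applies to recoded type tuples. Summary
fractions use the combination-space size as denominator for presence and
type-absence, and the type-present count as denominator for the
rare-among-present fraction.

## The packaged reference profile

The package ships a 24-site substrate-channel panel for the nitrogenase D
subunit (keyed by alignment column, with *Azotobacter vinelandii* residue
labels and structural roles) and the published marginal posterior profile
of the Nif/Vnf/Anf ancestor at those sites, as a `state_table` under node
id `"AncNif"`. Published profiles list only states above the reporting
threshold; to make each row a proper distribution, the residual mass is
assigned to a single filler residue — the lexicographically first residue
with zero published probability at that site. Fillers never exceed the
detection threshold, so they cannot affect variable-site detection or
enumeration; they exist purely so the table passes the same invariants as
engine output. From this fixture the pipeline reproduces, at desk scale:
five variable sites (columns 348, 495, 496, 576, 603), 64 enumerated
combinations with `AATGG` at rank 2, and a minimum joint probability of
about `2.5e-4` (0.025%).

## What the simulator emulates — and what it does not

`simulate_alignment()` draws a root sequence from $\pi$ (or a fixed
string), assigns each site a rate category, and evolves every branch by
sampling from the exact transition probabilities, recording every internal
node's sequence as ground truth. Random topologies grow by successive
random splitting with iid exponential branch lengths (default mean 0.3
substitutions/site — a typical depth for a protein family alignment);
an optional outgroup clade is attached sister to the ingroup so rooting
and MRCA extraction can be exercised end to end. Columns can be forced to
the slowest or fastest rate category to emulate the conserved/variable
contrast of an active-site panel. `make_extant_fixture()` complements it
with a three-clade extant-diversity toy (two conserved clades fixed on
`LMNGG` and `AINGG`, one heterogeneous divergent clade) whose per-sequence
tuples are returned as bookkeeping.

The simulator is deliberately idealised: no indels (gap handling is tested
on hand-built cases), no alignment error, no model misspecification, no
among-lineage compositional drift, and topologies with no relationship to
any real gene tree. Passing tests on simulated data therefore demonstrate
the *internal* correctness of the machinery — likelihoods, posteriors,
counts — not that reconstructions on real alignments are accurate; on real
data, accuracy is limited by the usual ASR caveats (model adequacy,
alignment quality, taxon sampling).

## Numerical choices

- Underflow: per-node log-scaling accumulators, per site and rate
  category; posteriors recombine categories by log-sum-exp.
- Transition probabilities are clamped to $[0,1]$; violations beyond
  `1e-8` (never observed with the packaged models) would warn.
- State-table rows that sum to within `1e-4` of one are renormalised with
  a message; larger deviations are an error — silent renormalisation of a
  badly formed table would mask upstream bugs.
- Free-rate categories must have weights summing to one (error otherwise);
  rates are rescaled to weighted mean one with a message, matching the
  convention under which branch lengths are expected substitutions/site.
- Newick output prints branch lengths at 17 significant digits so
  parse–write–parse round trips are lossless; FASTA output is wrapped at
  60 columns in binary mode for byte-stable round trips.
- `X` and `-` at leaves enter the engine as all-ones partial vectors
  (missing data); a leaf absent from the alignment is an error, not
  missing data.

## Design decisions that were genuinely open

- **Marginal, not joint, reconstruction.** The combination analysis needs
  per-site posteriors at one node; joint maximum-probability ancestral
  sequences answer a different question and are out of scope.
- **Strict threshold inequality.** "More than one state with posterior
  above 0.10" is implemented as a strict `>`; the boundary case
  `{0.90, 0.10}` is not variable. The threshold is a parameter.
- **Singletons for C/H/P** rather than folding them into the nearest
  group: an unsupported merge would manufacture "conservative"
  substitutions that the scheme's authors never asserted.
- **Both joint normalisations reported.** The raw product is the primary
  statistic (it is what the per-site independence assumption defines); the
  ratio-to-top is reported alongside because relative likelihoods are the
  more common currency when comparing candidate ancestors.
- **Outgroup-only rooting input.** Monophyly of the outgroup in the
  unrooted tree is checked and violations are reported with the intruding
  leaves, because a silently mis-rooted tree changes the identity of the
  target ancestor.
- **State files as a first-class input.** The pipeline accepts a
  precomputed per-node state table in the common tab-delimited dialect in
  place of running the engine, so deposited reconstruction outputs from
  other tools can be re-analysed unchanged (a tested substitution
  identity).

## Problem sizes used by the test suite

Oracle comparisons enumerate all internal-state assignments on trees of
three to five leaves (up to $20^4$ terms). Parameter-recovery uses a fixed
20-leaf topology with 500 simulated sites per branch-length scale in
$\{0.01, 0.1, 1, 10\}$, checking that root-state recovery accuracy is
non-increasing in tree depth. Stationarity checks use a single
$10^4$-substitution branch over $2\times10^4$ sites. These sizes give
stable statistics while keeping the full suite under a minute on one core.

## Known limitations

- No fitting: substitution-model parameters, free-rate mixtures, topology
  and branch lengths must come from an external inference; the package
  only consumes them.
- Per-site independence means joint probabilities over a handful of sites
  are *not* whole-sequence likelihoods, and the top-ranked combination
  need not appear in the single most-likely full-length ancestor.
- The extant comparison is sampling-dependent: unsampled lineages may
  carry combinations scored "absent".
- Protein alphabets only; no codon or nucleotide models, no `+F`
  frequency re-estimation, no invariant-sites category.
- The combination space is truncated at the detection threshold by
  design; enumerating all $20^m$ tuples is supported only as a test hook
  on reduced alphabets.

## A worked run

```{r example, eval = FALSE}
fx <- nif_ancestor_fixture()
vs <- detect_variable_sites(fx$states, fx$panel, threshold = 0.10)
combos <- enumerate_combinations(vs)
combination_summary(combos)$min_joint_pct  # ~0.025 (%)
recode("AATGG", display = TRUE)

# synthetic end-to-end run over a four-column toy panel
sim <- simulate_alignment(simulation_spec(n_leaves = 10, n_sites = 40,
                                          outgroup_size = 3,
                                          branch_scale = 0.5, seed = 65))
panel <- site_panel(data.frame(column = c(5L, 12L, 20L, 33L),
                               reference_label = paste0("ref", 1:4),
                               role = "synthetic panel site",
                               conserved_residue = "A"))
res <- run_full(list(alignment = sim$alignment, tree = sim$tree,
                     outgroup = sim$truth$outgroup,
                     ingroup = sim$truth$ingroup,
                     panel = panel, outdir = tempfile()))
```
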