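# ancsr

Marginal ancestral sequence reconstruction and active-site combination
analysis for protein families.

## The problem

Maximum-likelihood ancestral sequence reconstruction (ASR) yields, for
each alignment site at an internal node of a phylogeny, a posterior
distribution over the twenty amino acids. At functionally critical sites —
the motivating case is the substrate channel of the nitrogenase D subunit
(NifD/VnfD/AnfD), whose FeMoCo active site reduces N₂ and, promiscuously,
other triple-bonded substrates — several ancestral states can be plausible
at once. The cross-product of those alternatives defines a library of
candidate ancestral active-site sequences. `ancsr` builds that library and
asks a concrete evolutionary question: are the high-probability ancestral
residue combinations actually represented in extant sequence diversity,
either exactly or up to conservative (same physicochemical category)
substitutions? Combinations absent from modern diversity point to
ancestral active-site chemistry with no modern analogue.

## What it computes

- **Pruning likelihood and marginal ASR.** For a reversible model with
  exchangeabilities S and frequencies π, the generator is
  `Q_ij = S_ij π_j` (rows summing to zero, rescaled so
  `-Σ_i π_i Q_ii = 1`), transition probabilities `P(t) = exp(Q r t)` per
  rate category, site likelihoods by Felsenstein pruning
  `log Σ_k w_k Σ_x π_x L_k,root(x)`, and per-site posteriors at a target
  node by the inside–outside two-pass, mixing rate categories by their
  site-specific posterior weight. LG, WAG and BLOSUM62 are packaged;
  discrete-gamma and free-rate mixtures are supported (never fitted —
  topology, branch lengths and rates are inputs).
- **Variable sites.** Panel sites with ≥ 2 states above a posterior
  threshold (default 0.10, strict).
- **Combination space.** The full cross-product of listed states, each
  combination weighted by the product of its per-site posteriors and
  ranked.
- **Physicochemical recoding.** Acidic (ED), Aliphatic (ILMV), Amine
  (QN), Aromatic (WYF), Basic (KR), Small Hydroxyl (ST), Tiny (AG);
  C/H/P are singleton categories.
- **Extant comparison.** Counts of each residue tuple and recoded type
  tuple across the ingroup, classifying every combination as
  absent / rare (≤ 2 sequences) / common, plus pairwise residue
  co-occurrence.
- **Model sensitivity.** Side-by-side posteriors across substitution
  models, flagging sites where the top residue flips but the top
  physicochemical type does not.
- **Simulator.** Sequence evolution along (optionally random) trees with
  full ground-truth bookkeeping, for end-to-end validation.

## Worked example

The package ships the 24-site nitrogenase substrate-channel panel and the
published posterior profile of the Nif/Vnf/Anf ancestor:

```r
library(ancsr)
fx <- nif_ancestor_fixture()
vs <- detect_variable_sites(fx$states, fx$panel, threshold = 0.10)
vs
#> variable_sites: 5/24 panel sites variable at P > 0.1 (node AncNif)
#>   site 348: A 0.29253; Q 0.27519; L 0.16779; K 0.16716
#>   site 495: A 0.74242; M 0.17555
#>   site 496: T 0.79331; N 0.14693
#>   site 576: G 0.87529; A 0.12413
#>   site 603: A 0.47988; G 0.46717

combos <- enumerate_combinations(vs)
combos
#> combination_set: 64 combinations over 5 sites (348, 495, 496, 576, 603)
#>    rank residues      joint ratio_to_top
#> 1     1    AATGA 0.07236817    1.0000000
#> 2     2    AATGG 0.07045145    0.9735142
#> 3     3    QATGA 0.06807848    0.9407240
#> ...

combination_summary(combos)$min_joint_pct
#> [1] 0.02500319
recode("AATGG", display = TRUE)
#> [1] "Tiny" "Tiny" "Small Hydroxyl" "Tiny" "Tiny"
```

Five of the 24 channel sites are ancestrally ambiguous; their listed
states generate 4×2×2×2×2 = 64 candidate ancestors. The top-ranked
combination is `AATGA`, with `AATGG` a close second (97% of the top
joint); even the least likely combination retains 0.025% joint
probability. `AATGG` recodes to a tuple of small/tiny categories —
classifying such tuples against extant diversity (`extract_profiles()`,
`classify()`) separates radical from conservative departures.

Reconstruction from raw data follows the same grammar:

```r
st <- run_asr_pipeline(aln = read_fasta("family.fasta"),
                       tree = read_newick("family.nwk"),
                       model = load_model("LG", categories = list(alpha = 1, k = 4)),
                       outgroup = readLines("outgroup.txt"),
                       ingroup = readLines("ingroup.txt"))
```

or, fully orchestrated with a report bundle, `run_full()` (see
`?run_full`; a thin shell wrapper lives at
`inst/scripts/run-pipeline.R`). A precomputed tab-delimited state file
can replace the engine stage via the `state_table` config key.

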