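---
title: "Host–symbiont screening surveys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host–symbiont screening surveys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiophy)
```

symbiophy implements the analysis chain of an endosymbiont screening
survey — the kind of study that collects insects across localities,
screens tissues for a heritable bacterium such as *Wolbachia*,
sequences a symbiont marker (*wsp*) and a host barcode (*cox*1), and
then asks three questions: how is infection distributed (prevalence,
tissue tropism, sex effects), how many symbiont strains are there and
how host-specific are they, and do host and symbiont phylogenies show
evidence of a shared history?

This vignette records the models, the defaults, and the design
decisions that were genuinely open, in enough detail to reproduce or
challenge each choice.

## Distances and trees

`k2p_distance()` computes Kimura two-parameter distances,
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with $P$ and $Q$ the
transition and transversion proportions over the columns retained for
each pair. The gap policy follows the barcoding convention: terminal
gaps and ambiguity codes are missing data; internal gaps are indels —
excluded from $P$ and $Q$ but tallied per pair, since indel columns
carry signal some users may want downstream. Saturated pairs (where a
logarithm's argument is non-positive) cannot take a finite K2P value;
they receive a sentinel of twice the largest finite distance, with a
warning. The sentinel keeps the matrix usable by neighbour joining
while making saturation loud; dropping the pair instead would silently
change the taxon set.

`nj_tree()` is the classic Saitou–Nei agglomeration. Two choices are
not fixed by the algorithm and had to be made deterministic:

* **Ties** in the Q criterion are broken toward the lexicographically
  smallest label pair (a cluster is labelled by its smallest member).
  Any fixed rule would do; this one is stable across platforms.
* **Negative branch estimates** are clamped to zero and the deficit is
  moved to the sibling edge, preserving the joined pair's path length —
  the common convention in distance-based software.

`bootstrap_support()` resamples alignment columns, rebuilds the tree
per replicate, and scores each internal edge of the full-data tree by
the fraction of replicates containing the same bipartition.
Bipartitions are counted **unrooted**: whether replicate trees are
rooted before counting is not specified in most method descriptions,
and the unrooted count is the one invariant to that choice. The random
stream is consumed replicate by replicate, so `n_reps = k` is a prefix
of `n_reps = k + 1` under the same seed — convenient when deciding
whether more replicates are worth the time.

Rooting: `midpoint_root()` (used for symbiont trees, where no natural
outgroup exists) and `outgroup_root()` (for host trees with designated
outgroups). Both preserve patristic distances; a non-monophyletic
outgroup is an error naming the offending split rather than a silent
re-rooting.

## Strain delimitation

`cluster_strains()` turns a supported tree into putative strains:
maximal clades of study sequences whose subtending edge has support at
least the **primary threshold** (default 0.97). Survey practice also
admits slightly weaker clades after case-by-case review; a
reproducible pipeline cannot do case-by-case, so the package
operationalizes the fallback as a **secondary threshold** (default
0.90): an unassigned sequence joins the unassigned members of its
smallest study-only clade with support at or above the threshold,
otherwise it stands alone. This is the one place where the package
replaces judgement with a rule; both thresholds are plain arguments,
and raising the primary threshold can only split strains, never merge
them (tested property).

Supergroup assignment uses labelled reference sequences: a strain
inherits supergroup A or B when the smallest enclosing clade that
contains any reference contains references of only that supergroup.
Strains whose members are all shorter than 400 ungapped sites are
unclassified (`UC`) — short amplicons place unreliably. Alignment
pathologies that force `UC` in practice cannot be detected
automatically; `assign_supergroup()` takes a manual `overrides`
argument for them.

Specialists are strains with exactly one host species; generalists
have two or more (`classify_specificity()`).

## Host specificity

For a generalist strain, `ps_score()` is the mean patristic distance
among its host species, and `sps_score()` standardizes it against a
permutation null (999 replicates by default): each replicate draws the
same number of host species uniformly without replacement from the
host tree. The description "random host–endosymbiont associations"
admits several nulls; the uniform draw preserves per-strain host
richness and is the simplest null consistent with the description. A
marginally equivalent tip-label shuffle is available
(`null = "tipshuffle"`). The P value is the lower-tail add-one rank:
clustered hosts give small PS and $P < 0.05$; phylogenetically even
hosts give $P > 0.95$. No multiple-testing correction is applied
across strains, matching how such tables are conventionally reported;
SPS is invariant to rescaling all branch lengths (tested), so trees in
different units are comparable.

On a star tree every null replicate equals the observed PS, the null
has zero spread, and SPS is undefined; the result carries a
`degenerate` flag instead of an arbitrary number.

## Congruence: ParaFit

`parafit_global()` computes the fourth-corner statistic
$\mathrm{tr}\,(C^{\mathsf T} A\, B)(\cdot)^{\mathsf T}$ — the sum of
squared entries of $C^{\mathsf T} A B$ — from Cailliez-corrected
principal coordinates $B$ (hosts) and $C$ (symbionts) and the binary
incidence $A$. The Cailliez constant is the smallest additive constant
making the configuration Euclidean, found as the largest real
eigenvalue of the standard $2n \times 2n$ companion matrix; axes with
eigenvalues above $10^{-8}$ of the leading one are kept. The
permutation null shuffles, independently within each symbiont row, its
host incidences — the scheme of the original method. P values use the
add-one convention.

Per-link tests (`parafit_links()`) use the contribution form: the
global statistic minus the statistic with the link removed. The same
row-wise permutation stream is applied to the full and the
link-deleted matrix, and permuted contributions are compared with the
observed one. The alternative normalized link statistic exists in the
literature; the contribution form is reported because it needs no
denominator guard, and the per-link P values are raw (no correction),
as link tests are conventionally reported.

Input distances are patristic distances from the trees; raw sequence
distances can be substituted by passing any labelled distance matrix.

## Event-based reconciliation

`reconcile()` embeds the symbiont tree into the host tree under five
events: cospeciation (cost 0 by default), duplication (1), duplication
with host shift (2), loss (1), and failure to diverge (1) — the usual
cost regime, changeable via `cost_scheme()`.

The model is **untimed**: no divergence-time estimates exist for
either tree, so host shifts are allowed to any host edge neither
ancestral nor descendant of the source edge. This is the weakest
constraint that still prevents a shift from travelling into its own
past. Failure to diverge arises from symbiont tips associated with
several hosts: the tip lineage covers the spanning subtree of its
hosts, each covered host speciation with the lineage in both daughters
costs one failure to diverge, and each uncovered side costs a loss.

Exact mode is a dynamic program over (symbiont node, host position)
pairs: at each internal symbiont node the options are cospeciation at
a host node, duplication on a host edge, or a host shift to the best
incomparable edge; descending a host node on one side costs a loss.
The DP is provably minimal for this event model and is tested against
an independent brute-force enumerator over all placements on every
small instance. Ties are resolved in fixed evaluation order
(cospeciation, duplication, shift; host positions in node order), so
results are deterministic.

Heuristic mode exists for trees too large for the DP's quadratic
host-position sweep: a population-based search over placement vectors
(default 300 candidates, 100 generations, uniform crossover, per-gene
mutation, 10% elitism) mirroring the search shape of the event-based
tools used in the field. It never reports better than the exact
optimum (tested) and flags its output `optimal = FALSE`.

`random_tip_mapping_test()` redraws the association (each symbiont
keeps its host count; hosts redrawn uniformly) and reports the
fraction of randomizations cheaper than the observed reconciliation;
at or below 5% is the conventional support criterion for
cospeciation.

**Known limitation.** Because failure to diverge is attached to tips,
a history in which a lineage persists through a host speciation and
*later* diverges within both daughters is not expressible; the
reconciler will represent that pattern with duplications and shifts,
possibly at higher cost than the generating history. Consequently the
guarantee "reconciled cost ≤ generating history's cost" holds for
histories without failure to diverge, and the end-to-end recovery test
simulates under `failure_to_diverge = 0`. Multi-host tips (the common
way failure to diverge manifests in screening data) are fully
supported.

## Prevalence, tissue tropism, sex effects

`prevalence_table()` aggregates either individual screening records or
pre-tabulated counts into infected/screened/percent per group with a
totals row; percentages are rounded to one decimal, the survey
convention (`pct()`).

`cochran_q()` evaluates Cochran's Q directly from its defining
formula; subjects positive or negative in every tissue cancel
algebraically, and the count of informative subjects is reported so a
"significant" Q resting on three discordant individuals is visible.
With two conditions Q reduces to the uncorrected McNemar chi-square
(tested identity). `mcnemar_pairwise()` defaults to the exact
two-sided binomial test on the discordant counts: published post hoc P
values rarely pin down which McNemar variant was used, so the variant
is an argument (`exact`, `chisq`, `chisq-cc`) and no multiplicity
adjustment is applied unless requested.

`logistic_sex_effect()` fits infection ~ sex by IRLS (logit link) and
reports the male-versus-female odds ratio with a Wald test
(df = n − 2). Survey write-ups sometimes swap "dependent" and
"independent" in describing this regression; infection is the outcome
here — the reported odds ratio is an odds ratio *of infection*, which
is the only reading under which such an odds ratio makes sense.
`sex_balance_subset()` implements the guard used before this
regression: keep species whose rarer sex is at least 60% of the
commoner one (inclusive boundary — a 10 F / 6 M species stays).
Complete separation is flagged, not estimated.

## What the simulators emulate — and what they do not

`simulate_cophylogeny()` grows a Yule host tree and tracks symbiont
lineages through every host speciation (cospeciate / follow one side
with loss / persist undivided), with independent per-interval
duplication and host-shift opportunities. Defaults
(cospeciation 0.2, duplication 0.05, host shift 0.25, loss 0.6,
failure to diverge 0.2) reflect the regime reported for
mosquito-*Wolbachia* systems — shifts and losses common, cospeciation
rare; they are not fitted to any dataset. The generator returns the
full event log, so tests can compare reconstructed costs against the
truth.

`simulate_sequences()` evolves sites independently under the
two-parameter model with closed-form branch transition probabilities;
with the default rates the total substitution rate is 1 and K2P
distances estimate patristic distances (tested at 20 000 sites).

`simulate_specimens()` draws sex, infection (log-odds additive sex
effect, default odds ratio 0.434), per-tissue detection given
infection (0.95 / 0.12 / 0.07 for reproductive / gut / leg) and
internal-control failures (10%). Because the overall call is "any
tissue positive", realized prevalence runs a few percent below the
latent parameter — real screening has exactly this detection gap.

None of the generators model host extinction, within-host symbiont
dynamics, rate heterogeneity across sites, recombination, or
geographic structure. Tests passing on this synthetic data show the
*algorithms* are correct and calibrated under the stated models; they
do not show that real surveys satisfy those models.

## Numerical choices and test scale

* Eigenvalue tolerance in PCoA: $10^{-8}$ relative to the leading
  eigenvalue; distance-matrix symmetry tolerance $10^{-8}$.
* GLM convergence: deviance tolerance $10^{-8}$, 100 iterations.
* Add-one permutation P values throughout, so no P is ever exactly 0.
* Newick branch lengths are written with 10 significant digits;
  round-trips preserve topology, lengths and support.
* Support values live in `node.label` as fractions; integer labels
  0–100 are divided by 100 on read, and written back as percentages.

The test suite exercises: 200 random small reconciliation instances
against brute force; ParaFit type-I error over 200 simulated systems
(999 permutations each) and power over 50 congruent 8-tip systems; SPS
null uniformity over 500 draws on a 32-tip tree; sex-effect coverage
over 300 simulated surveys (6 species × 60 individuals); and NJ
topology recovery over 100 alignments of 5000 sites on an 8-tip tree.
These sizes give the calibration checks enough resolution (binomial
standard errors of 1–2 points) while keeping a full run in a few
minutes on one core.
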