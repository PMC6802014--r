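---
title: "Typing, deconvolving and testing Wolbachia infections against a host mtDNA genealogy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing, deconvolving and testing Wolbachia infections against a host mtDNA genealogy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolmlst)
```

## The problem

*Wolbachia* are maternally inherited intracellular bacteria of arthropods.
Because they ride along with the mitochondria, a spreading strain can drag
one mtDNA haplotype to fixation (a selective sweep), confound mtDNA-based
phylogeography, and — through reproductive manipulation — has been proposed
as a trigger for transitions to unisexual reproduction. Testing such
hypotheses in a host system requires four linked analyses, all of which
this package implements on top of standard multilocus sequence typing
(MLST) data for the five *Wolbachia* housekeeping loci *gatB*, *coxA*,
*hcpA*, *ftsZ* and *fbpA*:

1. **Strain typing** — calling alleles from trimmed Sanger fragments
   (including IUPAC double-peak mixtures), assigning five-locus profiles
   to sequence types (STs), and grouping STs into strain classes by the
   *gatB* allele (`wCallA` for alleles a/b, `wCallB` for c, `wCallC` for
   d).
2. **Coinfection deconvolution** — a host carrying two strains shows, at
   every locus, the set union of their alleles; subtracting established
   types from that polymorphism recovers the coinfecting pair and, where
   needed, implies previously unseen ("deduced") STs.
3. **Association testing** — permutation chi-square contingency tests of
   infection codings against a nested-clade hierarchy of host *cox1*
   haplotypes (and against nuclear *Wg* genotypes), the categorical
   variant of nested-clade analysis.
4. **Ancestral states** — fixed-tree marginal reconstruction of infection
   states on the host genealogy under a symmetric k-state Markov model.

A packaged dataset (`fixture_cohort()`, `fixture_st_table()`,
`fixture_allele_db()`) mirrors a published continental survey of 506
*Calligrapha* leaf beetles (two bisexual species and two unisexual species
derived from them) carrying fifteen supergroup-A STs; the allele sequences
in it are synthetic stand-ins with the documented difference structure,
not the deposited reads.

## Deconvolution as explicit global parsimony

The deconvolution rule for one mixture is exact: a pair of profiles
$(S_1, S_2)$ explains an observation iff at every locus the observed
allele set equals $\{S_1\} \cup \{S_2\}$. The subtle part is cohort-level
consistency. A single mixture often admits several algebraically valid
pairs — for example the union of the two commonest types is identical to
the union of two rarer ones — and a locally greedy resolution can mint
spurious types. `classify_cohort()` therefore solves the whole cohort at
once:

* every distinct mixture *signature* enumerates all splits of its
  two-allele loci into unordered profile pairs;
* a candidate (not-yet-known) profile is admissible if it co-occurs in
  some pair with an admissible member and lies within `max_new_dist`
  (default 1) allele changes of the growing table — applied for two
  layers, so a deduction may anchor on another deduction but not on an
  arbitrary chain;
* a branch-and-bound search picks one pair per signature to optimise,
  lexicographically: specimens explained, fewest new types minted,
  largest support from the carrier counts of directly observed
  (single-infection) types;
* each signature is finally resolved to its best-supported consistent
  pair, with alternatives recorded in the record notes; equally supported
  alternatives stay `ambiguous`.

On the packaged cohort this recovers, from the seven observed types
alone, exactly the eight published deduced profiles (each one allele
change from another type in the final table) and every published pair —
including the signature that is only resolvable once a deduced type
implied elsewhere exists, the case that defeats greedy rules.

Two special cases are handled explicitly. A mixture whose *gatB* read is
flagged low-confidence (`"c/d?low"` in the observation dialect) resolves
normally but is marked `uncertain`; it counts as a double infection in
prevalence but contributes to no named type's carrier tally (this
reproduces the published carrier percentages exactly). A novel allele
that `detect_chimera()` certifies as a single-breakpoint mosaic of two
database alleles, and that occurs in no regular profile, mints a
*variant* ST (suffix `r`, e.g. `wCallB1r`) which is excluded from the
main inventory and tallied separately.

Deduced types are named by the smallest unused index within their *gatB*
group, minted in order of decreasing specimen support. On the packaged
cohort this reproduces the published names of the C-group deductions
exactly; the two A-group and the two B-group deductions swap labels
relative to the published table because their published numbering is not
derivable from the data. All internal comparisons are by profile, and the
fixture ST table preserves the published names.

## Networks and nested clades

`build_network()` constructs the minimum-spanning network: an edge
survives iff its endpoints are not connected by strictly lighter edges
(the cut characterisation of minimum-spanning-tree membership, i.e. the
union of all MSTs), plus every weight-1 edge, so all tied single-step
alternatives are retained. The default connection limit is unlimited for
ST/allele networks (five loci bound the distances); haplotype networks
can pass an explicit limit, which may split components. Cycles are
reported by `find_loops()` as a fundamental cycle basis; every node on a
basis cycle whose nodes span two or more strain groups is flagged a
recombinant candidate. On the packaged ST set the three published
recombinant proposals all sit on such multi-group cycles; because the MSN
keeps every tie-minimal inter-group bridge, other nodes share those
cycles, so the flag is a screen, not a verdict.

`nest_clades()` applies the tips-inward nesting rule: at each level,
terminal nodes join their interior neighbour (terminals sharing a
neighbour merge), assigned nodes are removed, and the rule repeats;
isolated leftovers form singleton clades, and purely cyclic components
seed from the node of highest eccentricity with lexicographic
tie-breaks — determinism the original verbal algorithm leaves open.
Externally built designs are imported and validated (strict coarsening)
by `import_nesting()`, preserving label dialects with Unicode hyphens.

## The contingency battery

Infection is encoded under seven codings (infection level; strain-group
combination; specific ST combination; each crossed with level and with or
without the uninfected class). `run_battery()` then tests, for the whole
dataset and for every clade at every level, the records' subclade
membership one level down against each coding, with the Pearson
chi-square statistic referred to its permutation distribution (default
9,999 permutations; add-one estimator $p = (1 + \#\{T^* \ge T\})/(1 +
n_{perm})$, so $p$ is never 0 and the estimator is unbiased). Tables
where either axis has a single observed category are skipped and listed
with reasons. Significance tiers use .05/.01/.001 with no multiplicity
correction, matching the source convention; every test derives its own
seed deterministically from the battery seed, so reports are
byte-identical across runs. Records with uncertain ST assignment stay in
level-based codings but are excluded (and listed) from genotype and
group codings. `wg_association()` reruns the machinery with the nuclear
*Wg* genotype as second axis, by default only where the mtDNA test was
significant.

The published statistics of the original survey's battery are not
reproducible here because the underlying clade-membership table of the
prior study is not public; the battery is validated instead by
calibration (type-I error within the binomial envelope of the nominal
level under a simulated null) and power (planted clade-exclusive strains
detected) — see the test suite.

## Ancestral infection states

The original analysis co-estimated host tree and infection trait in a
Bayesian MCMC; this package deliberately conditions on a fixed input tree
and replaces MCMC with maximum-likelihood rate estimation plus marginal
reconstruction, which is the reproducible surface of that analysis (its
exact posterior percentages are not). The trait model is the symmetric
k-state Markov (Mk) model, whose transition probabilities have the closed
form $P_{ii}(t) = 1/k + (k-1)/k\,e^{-k r t}$, $P_{ij}(t) = (1 -
e^{-krt})/k$. `trait_loglik()` is Felsenstein pruning; `fit_rate()`
maximises it by bounded one-dimensional search over the log rate;
`marginal_posteriors()` runs the standard two-pass (postorder partials,
preorder outside-probabilities) algorithm. Two codings mirror the source:
`full_st` (every non-variant ST, every observed double combination, and
uninfected — 31 states on the packaged cohort) and `grouped` (uninfected,
A, B, C, with doubles as ambiguity sets over their two groups). Ambiguous
tips take partials of 1 on their member states. The root prior defaults
to uniform, the symmetric model's equilibrium. Zero-length branches are
clamped to 1e-9.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 506 specimens over 86
haplotypes in 7 geographic lineages by default, matching the empirical
design. The host genealogy is a neutral coalescent (`ape::rcoal`);
regions are contiguous clades obtained by repeatedly splitting the
largest clade; the nested-clade table is derived from the tree through
the package's own network-nesting rules. Infection histories follow the
biology the analysis is meant to detect: a backbone strain (default the
widespread wCallA1) descends by vertical transmission with a per-branch
loss probability (default 0.05 — small, so lineages mostly keep their
infection, as observed); sampled hosts acquire their region's resident
strain (defaults alternating wCallB1/wCallC1) with a regional horizontal
rate (default 0.5, giving the mixed single/double cohorts the survey
reports); and under cytoplasmic-incompatibility exclusion a host never
ends up with both a B- and a C-class strain — the incoming acquisition is
rejected, modelling the standing pattern (B/C parapatry) rather than the
demography that produces it. Where the source states no value (loss and
horizontal rates), the defaults above were chosen once as field-plausible
and are not tuned.

`emit_dataset()` writes the exact observation dialect the classifier
reads (unions for doubles, optional per-locus dropout and `?low` faint
signals) plus ground truth (JSON with the seed embedded), so every
downstream stage can be scored against truth. What the generator does
*not* emulate: sequencing error within alleles, quantitative titers,
more-than-two-strain infections, mtDNA sequence evolution (haplotypes
are labels on a tree), or selection; passing tests therefore demonstrate
correctness of the inference machinery under the stated transmission
model, not robustness to every artefact of real chromatograms.

## Numerical choices and problem sizes

* Trimming requires a window identity of at least 0.80 against the best
  database allele (far below within-supergroup divergence; leftmost best
  window on ties). Mixture calls require the IUPAC code to equal the
  exact base union at every position; partial explanations are
  `unresolved`.
* Chimera detection uses a single-breakpoint, zero-mismatch model; the
  breakpoint window is the maximal interval of equally valid breakpoints
  (0-based, half-open), with the parent pair minimising the window start.
* Percentages are displayed rounded half-away-from-zero to one decimal;
  stored fractions are never rounded.
* The test suite validates the estimators at sizes chosen for exactness
  rather than scale: exhaustive deconvolution over all ~210 fixture ST
  pairs; union-of-MSTs checked against complete Prüfer-sequence
  enumeration on 6-node instances; permutation p-values against full
  n! enumeration for n ≤ 8; pruning likelihoods and marginals against
  brute-force summation on trees of up to 6 tips (2 and 4 states,
  agreement to 1e-10); calibration at n = 200 with 999 permutations and
  200 null replicates; power and root-state recovery on simulated
  cohorts of 300 specimens and trees of 25 tips.

## Known limitations

* The deconvolution's parsimony search is exact but assumes at most two
  strains per host and deductions anchored within two layers of the
  established table; hosts with three or more strains (not observed in
  the motivating system) would surface as `ambiguous`.
* `find_loops()` reports a cycle basis, not all cycles; the recombinant
  flag marks participation in multi-group cycles and needs sequence-level
  confirmation (e.g. `detect_chimera()`) for intralocus events.
* The published battery statistics and Bayesian posterior percentages are
  inputs-limited and model-replaced respectively, as discussed above; the
  package reproduces the inventory, prevalence and carrier arithmetic of
  the source tables exactly, and notes (rather than resolves) the small
  internal inconsistencies of the source narrative (an "18 alleles"
  count whose itemisation sums to 17 — the mosaic gatB allele would be
  the eighteenth — and an overall prevalence quoted as 83.4% where the
  tables sum to 83.6%).
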