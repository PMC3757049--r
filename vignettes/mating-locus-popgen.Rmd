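---
title: "Detecting cryptic genetic exchange in a dimorphic mating locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic genetic exchange in a dimorphic mating locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpopgen)
```

## Scope and model

`mtpopgen` analyses two kinds of data about a non-recombining,
two-haplotype mating-type locus: sequence panels of wild isolates labelled
by mating type, and genotype tables of progeny from crosses engineered so
that both parents carry the same haplotype. The questions are the same
throughout: how differentiated are the two haplotype groups, is there
evidence of genetic exchange (gene conversion, crossovers) between them,
and is recombination suppression symmetric between the haplotypes?

The package assumes haploid sequences over `{A,C,G,T,-,N}` in a fixed
multiple alignment; it never re-aligns. Group labels come from a sample
sheet; per-column region classes (exon / intron / UTR / intergenic) and
codon frames come from a 1-based block annotation. All positions in every
interface are 1-based and inclusive.

## Site masks

Statistics are computed over explicit site masks.

* **Complete deletion**: `ungapped_mask()` drops any column with a `-` or
  `N` in *any* sequence. `N` is treated like a gap because a miscalled
  base would otherwise fabricate polymorphism; with panels of 6–13
  sequences this costs little data and removes a whole error class.
  Pairwise deletion is deliberately not offered for panel statistics —
  one behaviour, one set of denominators. (The two-sequence divergence
  functions use pairwise deletion, where the distinction is vacuous.)
* **Silent sites**: `silent_mask()` keeps ungapped non-coding columns
  plus exon columns at which variation is synonymous. The synonymy rule
  is strict: a column is silent only if *every* observed allele leaves
  the amino acid unchanged in *every* sequence's codon context (gap-
  containing codons excluded; codons truncated by the annotation edge are
  conservatively non-silent). The lenient alternative — synonymous in at
  least one context — would admit columns where some backgrounds change
  the protein; with small panels the strict rule errs on the side of
  fewer, cleaner silent sites. Monomorphic exon columns pass trivially,
  so the silent-site *denominator* includes invariant silent positions,
  as in standard usage.

## Diversity and differentiation

`nucleotide_diversity()` computes π as the average pairwise difference
per masked site, via per-column sample heterozygosity
(1 − Σ<sub>a</sub> C(c<sub>a</sub>,2)/C(n,2)); the test suite checks this
against an exhaustive pair-loop oracle at 10⁻¹² tolerance. Its standard
deviation is a site bootstrap (default 1000 replicates, explicit seed).
The field's reference tool reports an analytic variance instead, so SDs
are comparable in magnitude but not digit-for-digit.

`differentiation()` reports:

* `d_xy`: Jukes–Cantor correction applied to the *mean* between-group
  p-distance (not the mean of corrected pairs) — stable for small panels
  and matching the usual d<sub>XY</sub> definition;
* `d_a = d_xy − (JC(π₁)+JC(π₂))/2`, held as an exact identity;
* `fst = 1 − H_w/H_b` (Hudson–Slatkin–Maddison), with
  H<sub>w</sub> = (π₁+π₂)/2 and H<sub>b</sub> the *uncorrected*
  between-group p-distance. This estimator was chosen because it can be
  negative, and negative values are a meaningful signature of panmixia in
  published tables of this kind. When H<sub>b</sub> = 0 the statistic is
  undefined and flagged rather than returned as NaN.

π itself is left uncorrected for multiple hits: the correction is only
documented for the between-group distance in the analyses this package
mirrors, and within-group silent diversities (π ≤ 0.05) are far below the
range where Jukes–Cantor matters.

`tajimas_d()` uses the 1989 constants with S and the *total* mean pairwise
difference count over the mask; `defined = FALSE` is returned for S = 0 or
n < 4 instead of NaN. No p-value is attached — significance in the
mirrored analyses is a table annotation, and the beta approximation adds
assumptions without changing any decision the package makes.

`subsample_statistic()` recomputes a statistic on a taxon subset with the
mask rebuilt on the subset (gap and synonymy patterns depend on the
sample). This is the sub-sampling control used to ask whether a
low-diversity result in a small panel is a sampling artefact.

## Polymorphism tables and gene-conversion tracts

`build_polymorphism_table()` lists every segregating ungapped column plus
indel polymorphisms (a maximal gapped run is one event; carriers `-`,
others `+`). Each site gets a mutually exclusive specificity class. The
class set required some interpretation: per-site, with groups G₁/G₂,

* `fixed` — both groups monomorphic, different alleles;
* `specific_G` — the other group monomorphic and G's **majority** allele
  different from it (a nearly fixed, haplotype-diagnostic site at which a
  minority of G matches the other haplotype — exactly the pattern a
  conversion event leaves);
* `segregating_G` — the other group monomorphic and G's majority equal to
  it (a low-frequency variant inside G); ties count as segregating;
* `other` — segregating within both groups.

`informative_sites()` returns sites where the two group majorities differ
and each majority frequency is at least `min_fixation` (default 1 = fully
fixed, lowered to admit nearly fixed sites).

`detect_tracts()` implements the Betrán-style scan. Runs are counted over
consecutive *informative* sites — intervening non-informative
polymorphisms do not interrupt them, since the method operates on the
informative-site sequence. A candidate run is split wherever the carrier
set changes, so every reported tract is a maximal run of ≥ 2 sites shared
by one fixed recipient subset. The tract probability is exactly
∏ψᵢ with ψᵢ the within-recipient-group donor-allele frequency; the
default report threshold is α = 0.05. Two deliberate choices:

* the internal informative-site threshold defaults to a strict majority
  (0.5) rather than 1, because a conversion tract *itself* de-fixes the
  sites it covers — at `min_fixation = 1` no tract could ever be seen;
* indel events are tabulated but never scored in tracts (their mutational
  process is not the per-site model ψ assumes).

## Divergence of duplicate genes

`tamura3p()` implements the Tamura (1992) three-parameter distance with
θ taken as the mean G+C fraction of the two sequences over the jointly
ungapped columns (the convention is not pinned down in the tools this
mirrors; taking both sequences jointly is symmetric and stable). Standard
errors are site bootstraps (seeded); gap runs are counted as single indel
events for reporting and excluded from the distance. Saturation (a
non-positive log argument) raises a typed error rather than returning
NaN.

`ng86_dnds()` is a from-scratch Nei–Gojobori (1986) implementation:
fractional synonymous-site counting per codon (changes to stop codons
count as non-synonymous), site totals averaged over the two sequences,
multi-difference codons averaged over all minimal mutational pathways
with stop-traversing pathways excluded when any alternative exists, and
Jukes–Cantor correction applied separately to pS and pN. The counting
method was chosen over likelihood-style dN/dS deliberately: it is
deterministic, desk-checkable against pathway enumeration, and adequate
for the comparative use these ratios serve; values may differ modestly
from ML-adjacent tools.

`cai()` computes relative adaptiveness w per codon within its synonymous
family from a user-supplied 64-row usage table and returns the geometric
mean over scored codons, excluding Met, Trp and stops (families of one,
which carry no information). Zero-usage codons floor w at a configurable
ε with a warning.

## Crosses

A `cross_table()` is progeny × marker calls in `{A, B, both, NA}` with a
kb marker map. `exclude_diploids()` removes any progeny with a `both`
call — from numerator *and* denominator, matching how diploid
contaminants are handled when scoring real crosses.
`recombination_frequency()` counts progeny whose two marker alleles come
from different parents; cM = 100 × rf with no map function — at the ≤ 5%
frequencies involved, interference corrections are smaller than the
counting noise. `chi_squared_test()` is a two-class goodness-of-fit with
1 df and no continuity correction:
(O−E)²/E + ((n−O)−(n−E))²/(n−E) with E = n·(kb/(kb/cM))/100. This exact
form reproduces printed test statistics for zero-recombinant crosses;
with E = 14.4 of n = 600 it gives 14.754. At the 511 kb/cM baseline the
same arithmetic gives 2.83 where 2.81 is printed — consistent with the
interval length "~240 kb" being a rounded input; the package recomputes,
it does not re-round. `assign_crossover_intervals()` reports, per
progeny, each interval between consecutive informative markers where the
parental origin switches (the minimal-crossover reading), flagging
intervals that span missing calls as ambiguous.

## Parsimony splits

`parsimony_splits()` scores every non-trivial bipartition A|B by quartet
support: s(aa′|bb′) counts columns where the within-side pairs agree and
the sides differ, and

w(A|B) = min over quartets of [ s(aa′|bb′) − min(s(ab|a′b′), s(ab′|a′b)) ],

accepted iff w > 0. Subtracting the smaller conflicting pairing is what
lets two crossing splits coexist — the boxes that make these networks
informative — while no quartet ever keeps its weakest pairing, which
yields weak compatibility in the Bandelt–Dress sense (verified
exhaustively over split triples by `is_weakly_compatible()`, itself
exercised in the tests). On homoplasy-free data the weights reduce to
per-branch site counts and the output is exactly the generating tree's
split set. Candidate splits are enumerated exhaustively (2^(n−1) over
distinct haplotypes, guarded at n ≤ 20); identical sequences are
collapsed before analysis and re-expanded afterwards, so the panel sizes
this package targets (≤ 13 isolates) stay trivially feasible. Bootstrap
supports resample alignment columns on the collapsed haplotypes
(collapse-first: duplicate sequences carry no resampling information) and
report the fraction of replicates containing each split. Layout/drawing
is out of scope; `write_splits_nexus()` exports a SPLITS block standard
viewers render.

## The synthetic-data generator

`simulate_panel()` is a parametric site-sprinkler, not a coalescent
simulator: an ancestral sequence receives (i) fixed inter-group
differences at per-site rate `delta_fixed`, (ii) within-group biallelic
polymorphisms at per-site rate `theta_within`, and (iii) planted
conversion tracts copied from donor to recipient subsets over consecutive
fixed-difference sites. The default group sizes are 7 + 6, the panel
design of the study setting this package mirrors. Derived-allele carrier
counts default to the neutral site-frequency spectrum (weights ∝ 1/k over
k = 1..n−1), so default panels are neutral in the Tajima's-D sense; a
supplied `maf_counts` set is drawn uniformly instead, which is how exact
carrier frequencies such as 2/6 are constructed. The `panmictic` switch
sprinkles polymorphisms over the pooled panel, making group labels
arbitrary — the collinear-flank/autosomal regime with F<sub>ST</sub> ≈ 0.

What the generator does *not* emulate: genealogical correlation between
sites (every site is independent), recombination graphs, demography,
sequencing error, and realistic indel processes. Passing tests therefore
demonstrate correctness of the estimators under controlled site-level
structure, not robustness to the full correlation structure of real
panels.

`simulate_cross()` generates haploid progeny marker-by-marker with
interval-wise switch probabilities, plus `both`-scored diploids at a
configurable rate. `fixture_fig6()` is a fully deterministic 7 + 6 panel
with an exon/intron layout, a fixed-difference backbone, asymmetric
within-group diversity (the swept-haplotype pattern) and one planted
4-site conversion tract carried by 2 of 6 recipients — the configuration
whose tract probability is (1/3)⁴ ≈ 0.012.

## Numerical choices and degenerate inputs

* Every stochastic routine takes an explicit integer seed and is
  bit-reproducible; nothing reads global RNG state implicitly.
* Jukes–Cantor and Tamura corrections raise typed saturation errors at
  their domain boundaries (p ≥ 3/4, log arguments ≤ 0).
* Undefined statistics (Tajima's D at S = 0; F_ST at H_b = 0; dN/dS at
  dS = 0) are returned as flagged NA, never NaN.
* Majority ties inside a group make a site non-informative and class it
  as segregating — ties carry no directional information.
* Problem sizes in the shipped tests and acceptance script (panels of
  10–13 sequences a few hundred sites long, 50–200 simulation replicates,
  100–1000 bootstrap replicates, 300-codon dN/dS pairs) were chosen so
  estimator noise is small relative to the tolerances being checked while
  the whole suite remains quick to run; they are stated here as the
  package's reference configuration.

## Known limitations

* The tract scorer assumes biallelic, independently evolving informative
  sites; ∏ψ is a descriptive probability under within-group independence,
  not a calibrated p-value under linkage.
* NG86 and the strict synonymy rule will diverge from ML codon models and
  from tools with laxer synonymy rules on deeply diverged pairs.
* Exhaustive split enumeration is exponential; panels beyond ~20 distinct
  haplotypes need a different (incremental) construction, which is out of
  scope here.
* Two-group analyses only: no multi-population F-statistics, sliding
  windows, coalescent inference, tetrad analysis or interference
  modelling.
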