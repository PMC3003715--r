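---
title: "Population genetics of clonal bacteria from MLST profiles and PFGE fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genetics of clonal bacteria from MLST profiles and PFGE fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlstpop)
library(dplyr)
```

## The problem this package addresses

Multilocus sequence typing (MLST) characterises bacterial isolates by the
sequences of a handful of core-genome loci. Each distinct sequence at a
locus is given an allele number, and the tuple of allele numbers across
loci defines the sequence type (ST). For an essentially clonal organism
such as *Lactococcus lactis* subsp. *lactis* — the workhorse of milk
fermentation — a well-chosen scheme supports a complete population
analysis: how diverse is the sample, is the population clonal or freely
recombining, which STs form clonal complexes and which ST founded them,
and how much of the within-complex variation arose by point mutation
versus homologous recombination. Pulsed-field gel electrophoresis (PFGE)
macrorestriction fingerprints complement the gene-level picture with a
genome-level one: band-sharing similarity, genome-size estimates, and
their (lack of) correlation with the gene-based phylogeny.

`mlstpop` implements this pipeline end to end, together with a synthetic
clonal-population generator so that every stage is testable without any
external database.

## Data model

Three tabular objects carry the analysis:

* an **allele library**: a tibble of `locus`, `allele`, `seq`, with fixed
  sequence length per locus, unique numbering, and no two numbers for
  the same sequence;
* a **profile table**: one row per isolate with one integer column per
  locus, plus `ST`, `origin` and `markers` metadata. The canonical locus
  order is alphabetical (`bcaT`, `glyA`, `pdp`, `pepXP`, `pgk`, `recN`
  for the default six-locus scheme), which fixes the column layout of
  concatenates; this is a documented convention, since pairwise
  statistics are unaffected by locus order and only reported site
  coordinates depend on it;
* a **site matrix**: an aligned character matrix over A/C/G/T (plus `N`
  for missing outgroup states), one row per ST representative. The
  default six-locus concatenate is 2,934 bp.

Allele numbering is input-order dependent, exactly as in MLST allele
databases; every downstream statistic is invariant to renumbering, and
the test suite checks this property explicitly. Ambiguity codes are
rejected at allele-definition time.

```{r}
pop <- simulate_population(seed = 42)
pop
head(pop$profiles, 4)
```

## Diversity statistics and their sampling behaviour

`diversity_summary()` reports the segregating-site count $S$, the
percentage of variable sites, the nucleotide diversity
$\pi$ (mean pairwise difference per site, in %), the maximal diversity
$\pi_{MAX}$ (the two most divergent sequences), and the ratio
$\pi_{MAX}/\pi$. All pair arithmetic uses exact integer difference
counts before any division.

The ratio is a sampling diagnostic: coherent single-species samples sit
roughly between 2 and 6, while chimeric sequences or mixed lineages
push it to 8 and beyond. `outlier_screen()` operationalises this with
greedy removal of the ST whose deletion most reduces $\pi_{MAX}$,
continuing while the ratio exceeds a threshold (default 8, the empirical
gap between coherent and aberrant samples).

The percentage of variable sites grows towards saturation with sample
size while $\pi$ is stable; `subsample_experiment()` demonstrates this
by re-computing the summary over random ST subsamples (default 1000
replicates, drawn without replacement from one representative per ST).

```{r}
diversity_summary(pop$site_matrix)
```

On the standard-deviation of $\pi$: the package reports the square root
of Nei's (1987, eq. 10.7) total sampling variance under no
recombination. Published MLST tables rarely state which variance their
"±" is, and data-dependent resampling variants differ; treat cross-study
comparisons of the ± as indicative only.

## Neutrality tests

`tajima_d()` implements Tajima's $D$ with the standard constants;
`fu_li_df()` implements the outgroup forms of Fu & Li's $D$ and $F$,
with $\eta_e$ the count of segregating sites at which exactly one
ingroup sequence carries the derived (outgroup-differing) state.
Infinite-sites bookkeeping is used throughout: a segregating site is one
mutation event in $\eta$; ingroup sites with three or more states are
counted once in $\eta$, excluded from $\eta_e$, and reported, as are
sites the outgroup cannot polarise (missing or ingroup-absent outgroup
state). This exclusion rule is a package decision — published analyses
rarely state theirs — and the exclusion counts in the output make the
alternative bookkeeping recomputable.

Significance uses coalescent Monte Carlo rather than transcribed
beta-approximation tables: `neutrality_significance()` simulates the
standard neutral coalescent conditioned on the observed $n$ and $S$ (no
recombination), recomputes the statistic per replicate, and returns the
coarse two-tailed band (`ns`, `0.05<p<0.1`, `p<0.05`) used in summary
tables. One mechanism serves all three statistics; for the Fu & Li
statistics the simulated ancestral sequence is a perfect outgroup. Note
that conditioning on $S$ leaves a small negative bias in the mean of
simulated $D$ (about $-0.05$ to $-0.1$ at $n = 10$, $S = 10$); the
calibration tests allow for exactly this.

```{r}
scan <- neutrality_scan(pop$profiles, pop$library)
scan %>% select(sequence, n, S, pi, pi_max, tajima_D)
```

## Linkage disequilibrium: the standardized index of association

`ias()` computes $I_A^S$ on allelic profiles (one representative per
ST), following the LIAN conventions: the pairwise distance is the
number of mismatched loci; $V_D$ is the population (divide-by-$N$)
variance over all pairs; $V_e = \sum_j h_j(1-h_j)$ with $h_j$ the
unbiased single-locus diversity $\frac{n}{n-1}(1-\sum_i p_{ij}^2)$; and
$I_A^S = (V_D/V_e - 1)/(l-1)$. The variance conventions matter (biased
$V_D$, unbiased $h_j$) and are frozen by a fully hand-computed fixture
in the tests (the duplicated-locus construction with $I_A^S = 1$).

`ias_test()` attaches a one-sided upper-tail Monte-Carlo p-value by
independently permuting each locus column across STs (clonality inflates
$V_D$; the permutation preserves $V_e$), with the add-one estimator
$(1 + \#\{V_D^* \ge V_D\})/(1 + B)$ and $B = 1000$ by default.

```{r}
ias_test(pop$profiles, permutations = 1000, seed = 1)
```

## Clonal complexes, founders and r/m

`eburst()` links STs sharing all but one locus (SLVs), takes connected
components of size two or more as clonal complexes, and predicts the
founder as the member with the highest SLV degree — ties broken by DLV
degree, then isolate count, then lowest ST id, with the tie-break path
recorded in the output. `relax_to_dlv()` reports only what changes when
the lineage definition is relaxed to shared-4-of-6 loci.

`rm_classify()` implements the per-site recombination-to-mutation
classification over founder-to-SLV allele changes: the SNPs of a variant
allele count as one point mutation only when the allele differs by
exactly one SNP **and** that variant is private — neither the exact
allele in any ST outside the complex nor the variant nucleotide at that
site in any other allele of the locus. Everything else counts all its
SNPs as recombinant. The privacy requirement is enforced at both the
allele and the nucleotide level (the stricter of the two possible
readings); each event's evidence string records which rule fired so the
looser reading can be recomputed from the event table. Only
founder-to-SLV comparisons are classified, and "unrelated ST" means any
ST outside the focal complex.

```{r}
eb <- eburst(pop$profiles)
eb
rmc <- rm_classify(eb, 1, pop$profiles, pop$library)
glance(rmc)
```

## Trees

`k2p()` and `k2p_matrix()` provide Kimura two-parameter distances
(transitions and transversions separated; pairwise deletion of missing
states; saturation is an error, not an `NaN`), `nj_tree()` the standard
neighbor-joining agglomeration, and `bootstrap_tree()` column-resampling
bootstrap supports (the classic seqboot convention: alignment columns,
not loci). Negative NJ branch lengths are clamped to zero for display
with the raw values retained in an attribute. The K2P and NJ machinery
is delegated to `ape`; the tests pin it to closed-form hand cases and
to exact recovery of additive four-taxon matrices.

## PFGE fingerprints and genome sizes

`band_matrix()` turns per-strain fragment-size lists into a binary
matrix by single-linkage clustering of sizes within a relative tolerance
(default 1.5% — gels are scored manually, so the tolerance is the
package's operationalisation, and two sizes of one strain collapsing
into a class is an error, not a guess). Band classes are global across
strains, chosen for reproducibility over pairwise lane alignment.
`dice_matrix()` computes $S_D = 2n_{AB}/(n_A+n_B)$ and the distance
$1-S_D$, flagging pairs under the conventional 0.6 "unrelated" line;
`upgma_bootstrap()` clusters on $1-S_D$ with band-class resampling.
`genome_size()` averages digest fragment sums into a chromosome size
with a half-range uncertainty (the "±" convention is not standardised;
half-range is the package's documented choice) and adds S1-linearised
plasmid sizes for the genome total. `feature_associations()` runs the
Spearman and rank-sum comparisons (plasmid versus genome/chromosome
size, sizes between origin classes) through the base R test machinery.

## Scheme design

`st_resolution()` counts distinct restricted profiles for any locus
subset; `augment_backbone()` searches single then pairwise candidate
additions exhaustively (raising the search depth automatically when
pairs do not reach the full-candidate resolution), reports the minimal
augmentation achieving the maximum, and reports ties instead of breaking
them. Monotonicity of resolution under subset inclusion is tested
property-style.

```{r}
augment_backbone(pop$profiles,
                 backbone = c("glyA", "pdp", "pepXP", "pgk", "recN"),
                 candidates = "bcaT")
```

## What the generator emulates — and what it does not

`simulate_population()` emulates the structure inferred for a small
clonal dairy population: divergent singleton lineages plus clonal
complexes grown from founders, one locus change per SLV. Defaults are
fixed study conditions, not tuning knobs: six loci of 516, 453, 492,
504, 480 and 489 bp; 14 singletons and two complexes of 9 and 2 STs (25
STs); singleton divergence 0.005 substitutions/site from the common
ancestor, which places the concatenate $\pi$ near 0.8–1.0%; an even
split (`rho = 0.5`) of SLV events between point mutation and
recombination import, with external imports carrying 2–4 SNPs — chosen
to mirror a complex whose handful of allelic changes decompose into a
few single-SNP mutations and a few multi-SNP imports.

Mutation events are rejection-sampled onto sites that are monomorphic
across every allele of the locus and unused by previous events, so their
privacy (and hence the r/m truth) is unambiguous by construction;
imports either carry two or more SNPs or are copies of an unrelated
lineage's allele (`import_source = "population"`), exercising the
"found in unrelated ST" evidence path. The generator records every event
in a truth table that replays exactly to the emitted sequences — a
tested invariant.

What it deliberately does **not** model: intra-locus recombination
within singleton lineages, rate heterogeneity across sites, codon
structure or selection, sequencing error, and missing data. Passing the
round-trip tests therefore shows that the inference machinery is correct
under clean clonal assumptions, not that real collections are free of
the complications above.

`simulate_neutral_alignment()` is a standard neutral coalescent
(exponential coalescence times, infinite sites mapped to distinct
alignment positions) used as the null for significance bands, supporting
both conditioned-on-$S$ and $\theta$ modes. `simulate_band_patterns()`
grows PFGE patterns by per-band loss and matched binomial gain at a
turnover rate $t$, giving an expected within-lineage Dice of about
$(1-t)^2$ — monotone in $t$, with the closed form used as the test
oracle.

## Numerical choices and problem sizes

Exact integer pair counts precede every division; percentages are
reported at full precision and rounded only for display. Permutation and
bootstrap p-values use add-one estimators. Seeds are single R RNG seeds
per call; every simulation function is byte-reproducible under a fixed
seed. The default test suite uses deliberately small problem sizes —
alignments up to a few dozen sequences, 200 permutations inside the
type-I-error calibration (500 datasets), 1000 neutral replicates for the
Tajima calibration, 100–300 bootstrap replicates — sizes at which every
check completes in seconds while the Monte-Carlo error bands stated in
the tests remain valid.

## Known limitations

* Founder prediction uses SLV degree with deterministic tie-breaks; no
  bootstrap confidence on founders is computed.
* $I_A^S$ significance is Monte-Carlo only; the parametric LIAN
  normal approximation is intentionally not implemented.
* The Fu & Li site-exclusion rules above are one defensible bookkeeping;
  outputs expose the counts needed to apply another.
* PFGE band matching assumes already-scored band sizes; no gel-image
  processing or lane normalisation is attempted.
* The fixtures shipped under `inst/extdata/` are synthetic (generated by
  the package's own simulator and labelled as such); analyses of real
  collections should load their own allele FASTA and profile TSV files.
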