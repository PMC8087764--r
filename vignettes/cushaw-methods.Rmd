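---
title: "Methods and models behind cushaw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind cushaw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cushaw)
```

`cushaw` re-implements, as tested and reusable components, the
population-genomic workflow used to study the domestication of the cushaw
pumpkin (*Cucurbita argyrosperma*) from its wild relative *C. argyrosperma*
subsp. *sororia*: SNP filtering, diversity and structure statistics,
SFS-based comparison of domestication scenarios, a three-test selection-scan
consensus, ABBA-BABA introgression statistics, and dual-caller
structural-variant consensus.  Because the study's raw reads are not
shippable, every stage is exercised against a structured-coalescent
synthetic-data generator whose defaults encode the study system; this
vignette explains the models, the defaults, and the choices made where the
design was genuinely open.

## The synthetic study system

`studyModel()` builds the generating demography: a wild taxon with two
sub-lineages ("jalisco" and "southern"), a domesticate derived from the
Jalisco lineage, and a *C. moschata*-like outgroup used only for
polarization.  Time is measured in generations, one generation per calendar
year (the species is annual).  Defaults, chosen once from the biology and
held fixed:

* domestication split `tDom = 8000` generations ago (the oldest
  archaeological record of the crop is roughly nine millennia old);
* wild-lineage split `tWild = 30000` (late-Pleistocene fragmentation of
  wild *Cucurbita* ranges);
* outgroup split `tOut = 6e5`;
* diploid sizes: wild demes 30,000, domesticate 10,000 (a mild bottleneck,
  as suggested by the near-equal observed diversity of crop and wild),
  ancestor 30,000;
* secondary contact: migration between the domesticate and both wild demes
  on the most recent 4,000 generations, at backward rates `5e-4` per
  lineage per generation toward/from Jalisco and `1e-4` for the southern
  deme — ongoing crop-wild gene flow at roughly ten effective migrants
  per generation for the sympatric pair, an order less for the
  allopatric one.

Under these conditions the wild-vs-domesticated Weir-Cockerham F_ST of the
emitted genotypes is about 0.05-0.1, matching the low differentiation
regime of the real system, which is what makes the scan-calibration
properties meaningful.

The simulator is a continuous-time structured coalescent (exponential
waiting times; the field's standard approximation of discrete generations)
with population splits, a migration window gated by the gene-flow mode, and
instantaneous admixture pulses.  The pairwise coalescence rate of haploid
lineages in a diploid deme of size N is 1/(2N) per generation.  Secondary
contact is interpreted backward in time: migration is active only at times
more recent than `secondaryContactEnd`.

Two details deserve emphasis:

* **Segregating-site sampling.**  Independent SNPs are generated one
  genealogy at a time, but a genealogy contributes sites in proportion to
  its total branch length (a Poisson draw at an auto-calibrated rate), not
  one site per tree; conditioning on segregation otherwise biases the
  frequency spectrum.
* **Event budget.**  Prior corners with extreme migration rates (the
  log-uniform prior reaches m = 0.5 per generation) imply millions of
  migration events per genealogy.  After 800 events a genealogy's
  migration-connected demes are collapsed into their panmictic limit — the
  strong-migration limit of the structured coalescent — which keeps such
  draws tractable while leaving moderate-migration models (tens to
  hundreds of events) untouched.

What the generator does *not* emulate: recombination and linkage (sites are
exchangeable; jackknife blocks are positional, and LD-pruning tests build
their own correlated fixtures), sequencing error, allelic dropout and
depth-dependent missingness (missingness is injected uniformly at random),
and selection dynamics (selected loci are spiked post hoc by shifting
derived-allele frequencies in the target populations).  Passing tests
therefore validate the statistical machinery under a idealized neutral
model with known truth, not the full messiness of reduced-representation
sequencing.

## Filters

The cascade is fixed as: site missingness, then sample missingness, then
minor-allele frequency recomputed after the removals (upstream tools leave
the order version-dependent, so it is pinned and reported).  Defaults are
the study-standard MAF 1%, 50% missingness both ways.  The Hardy-Weinberg
exact test enumerates heterozygote counts of the observed parity at fixed
allele counts and sums the probabilities no larger than the observed
table's (no mid-p).  LD pruning is a greedy left-to-right scan within 100
kbp windows at r² > 0.25, removing the later-positioned member of each
offending pair; r² is the squared dosage correlation on pairwise-complete
observations (the genotype-based convention), and a per-site anchored scan
is equivalent to any window step no larger than the inter-site spacing.

## Diversity and structure

Per-site nucleotide diversity is the unbiased expected heterozygosity
n/(n-1)·2p(1-p) with n the non-missing allele count; population means
average over variant sites (per-SNP π, the reduced-representation scale —
per-bp π would be orders of magnitude smaller).  F_ST is Weir & Cockerham
(1984) from genotype counts, multilocus as the ratio of summed components;
confidence intervals bootstrap loci (100 draws, percentile).  The PCA
centres dosages by 2p and scales by sqrt(2p(1-p)) after mean imputation of
missing dosages.

## Demographic scenarios and composite likelihood

Six scenarios cross the domestication origin (Jalisco vs southern wild)
with the gene-flow regime, under the constraint that the domesticate
diverged most recently.  Continuous gene flow carries independent
directional rates for every deme pair, from the present back to the
common ancestral population (k = 11 free parameters); secondary contact
carries the four domesticate-wild rates, active only during the recent
contact epoch, fixed by design to the most recent half of the
domestication branch (k = 9); the no-flow scenarios have k = 5.  Priors
are log-uniform: divergence times 1,000-200,000 generations, sizes
100-60,000, migration rates 1e-4-0.5.  Because migration involving the
domesticate necessarily stops when its lineage merges into the
progenitor, a free contact-window end would make secondary contact and
continuous flow nearly indistinguishable; distinguishing them through
the wild-wild migration directions and the fixed window follows the
structure of the original model descriptions.

The observed spectrum is the unfolded joint SFS over the three in-group
demes, polarized by a monomorphic outgroup, complete-case per site, with
the two monomorphic corner cells masked.  The expected spectrum is
estimated by simulation; the objective is the multinomial composite
log-likelihood (natural log) over cells with at least one observation
("minimum SFS count of 1"), with empty expected cells floored at
0.1/n_sim so unexplained observations are penalized rather than infinite.

Two identifiability facts shaped the fitter:

* A polymorphic-sites-only composite likelihood carries no information
  about the absolute coalescent scale — all sizes and times can be
  rescaled jointly.  The Jalisco deme size is therefore fixed at 30,000 in
  every scenario as the scale anchor, the way SFS fits anchor one size
  through external (theta-based) information.
* At desk scale (hundreds to a few thousand polarized SNPs) the surface
  has broad ridges: recent-contact migration can partially substitute for
  domestication-branch drift, so the domestication time is only weakly
  pinned even when the scenario ranking is clear.

The expected spectrum is estimated by branch-length accumulation over
simulated genealogies (every branch contributes its length to the cell
indexed by its subtree's joint leaf counts) — the Rao-Blackwellized
version of dropping mutations on the same genealogies, with no
mutation-placement noise.  This matters: with site sampling the
composite log-likelihood of a 21x21x41 spectrum at 20,000 simulations
carries a Monte-Carlo standard deviation near 17 log-units, larger than
typical between-scenario differences; accumulation brings it to ~4.

The optimizer is a seeded multi-start coordinate search: initial
log-uniform draws screened at a reduced simulation size, a
method-of-moments start (deme sizes from diversity ratios against the
anchor; split times from Hudson-F_ST drift approximations) plus
coalescent-rescaled variants of it, and, for the gene-flow scenarios, a
start inheriting the fitted no-flow parameters.  Each refinement cycle
perturbs one parameter at a time multiplicatively (shrinking steps,
direction memory) and adds structured moves for the known ridges of
this likelihood: a joint rescaling move (all sizes and times up,
migration rates down), a paired domestication-branch move (time up,
size down), early-cycle leap grids for the domestication time and the
symmetric contact migration rate, and a Hooke-Jeeves pattern move that
extrapolates each cycle's net displacement.  All evaluations within a
cycle share one simulation seed (common random numbers), refreshed
between cycles so the search cannot lock onto one realization's noise;
search stops early when a cycle improves the log-likelihood by less
than 0.001.  `fitAllModels()` spends the last cycle of the budget on a
cross-pollinated polish (every scenario restarts from the best of its
own optimum and the other scenarios' optima mapped into its parameter
space) and reports, for each scenario, the mean composite
log-likelihood over ten fresh evaluation seeds, so the AIC ranking
(AIC = 2k - 2 lnL, natural log throughout) is not driven by per-fit
Monte-Carlo noise.  Replicate fits can be summarized with
`fitModelReplicates()`, which retains the runs above the 95th
percentile of the likelihood distribution and reports the best,
mirroring the replicate-retention convention of the original workflow.

Default sizes are the full-scale settings (40 cycles, 200,000 simulated
genealogies per evaluation; refinement cycles evaluate at half size).
The package's own validation experiments run a desk scale — 2,000
simulated SNPs of data, 5 cycles, 20,000 genealogies per evaluation,
ten data seeds — at which the flow regime and the fitted parameters are
recovered reliably, while the origin contrast (Jalisco- vs
southern-derived domesticate) sits at the edge of statistical
resolution: on a subset of data realizations the mirrored-origin model
fits within a few log-units of the generating one, and the experiments
report exactly that.

## Selection scans

**F-model scan (environmental covariate).**  Population allele frequencies
are beta-distributed around an ancestral frequency with locus-by-population
precision exp(-eta); eta is a population effect beta_j (prior N(-1, 1.8²))
plus, per locus, nothing (neutral), a locus effect alpha_i ~ N(0,1)
(selection unrelated to the covariate), or g_i·E_j with g_i ~ N(0,2²) and
E_j the wild(0)/domesticated(1) covariate.  Counts are beta-binomial
(ancestral frequencies integrated per-locus by MCMC, not analytically).
Per-locus model indicators move by product-space jumps that propose the
incoming parameter from its prior (so the acceptance ratio is the
likelihood times the model-prior ratio); the neutral model has prior
probability 0.8.  Pilot runs tune the random-walk widths into the 25-45%
acceptance band.  Two independent chains run; convergence of the
population effects is checked with the Gelman-Rubin statistic (flagged,
never silently passed).  The q-value of a locus is the mean posterior
error probability (1 - posterior probability of the environmental model)
among loci called at or before it.  Defaults are the full-scale MCMC
(20 pilots of 10,000, burn-in and sampling 100,000, thinning 20); the
package's calibration experiments use short chains (3-5 pilots of 150-200,
burn-in 400-800, sampling 800-3,000) that mix well for the hundreds-of-SNPs
fixtures they run on.

**PCA outlier scan.**  Scaled dosages are regressed on the first K = 2
principal-component scores; the K z-scores give a Mahalanobis distance,
rescaled by the genomic inflation factor (median D² over the chi-squared
median) and referred to chi-squared K; Bonferroni < 0.05 flags candidates.
The covariance of the z-scores is robustified by trimming the 5% most
outlying loci before recomputing the moments.  Sites with minor-allele
frequency below 5% are excluded from the test (the genome-scan default):
their z-scores are far from the chi-squared reference and would otherwise
dominate the tail.

**Latent-factor scan.**  K = 6 latent factors are estimated from the SVD
of the genotypes projected off the covariate (ridge-regularized projection,
penalty 1e-5); effect sizes come from regressing the residualized
genotypes on the covariate, with z-scores calibrated by the median
chi-squared inflation factor and converted to Benjamini-Hochberg q-values.
With K = 0 and no penalty this reduces exactly to per-SNP least squares.
The covariate enters per population in the F-model but per sample here;
samples inherit their population's status.

**Consensus.**  A SNP is a candidate when flagged by at least two tests at
their own cutoffs (q < 0.05, Bonferroni p < 0.05, q < 0.05) — the
false-positive-reduction rule of the original analysis.

## Introgression

Patterson's D uses frequency-weighted ABBA/BABA site counts over
(((P1 wild, P2 domesticate), P3 moschata), outgroup); single genomes enter
as frequencies in {0, 1/2, 1}.  Significance is a delete-one block
jackknife over contiguous equal-SNP blocks (two-sided normal p).  The
admixture fraction f_G splits P3's sampled alleles per site into random
halves (seeded hypergeometric draws), using one half as the donor proxy.
Local D is computed in 500-SNP windows with step 250.  Candidate SNPs are
classified by outgroup-polarized derived frequencies: derived (nearly)
fixed only in the domesticate or only in the wild subspecies marks the
selection direction; sharing with moschata marks ABBA/BABA (which take
precedence); everything else — including sites whose two outgroup calls
disagree — is unknown.  The 0.8/0.2 frequency thresholds are analysis
conventions exposed as parameters, not study-fixed values.  The default
quartet geometry places the P3 split half a coalescent unit beyond the
P1/P2 split so incomplete lineage sorting supplies the ABBA/BABA site
classes that the statistics rest on.

## Structural variants

Two call sets (a whole-genome-alignment caller and a long-read caller,
consumed as files) are intersected with the ±100 bp endpoint rule per
chromosome and type; matching is one-to-one, greedy by smallest total
endpoint offset with leftmost tie-break, and translocations must satisfy
the rule at both loci.  "Unaligned region" records bypass matching (they
exist only on the alignment side) and flow to gene assignment directly.
Genes are assigned by any-overlap for inversions and translocations but
full containment for CNVs and unaligned regions; term enrichment is a
one-sided Fisher exact test per term at p < 0.05 (classic per-term
testing; the original's graph-decorrelated variant is out of scope).
Read-based records below 6 supporting reads are dropped at read time.

## Pipeline

`runPipeline()` drives the stages in the study's order from a single YAML
config whose defaults are the study-standard thresholds; every threshold
lives in the config so sensitivity re-runs (for example, repeating the
demographic fits without the HWE filter) touch nothing else.  A single
global seed fans out to per-stage seeds through a documented splitter, so
stages are individually reproducible.  Each stage writes a TSV plus a JSON
metrics sidecar and the run ends with a human-readable `summary.md`.

## Numerical notes and known limitations

* Dosage validity, strictly increasing positions, and the
  divergence-order constraint are enforced by S4 validity methods.
* The HWE test, WC F_ST, D/jackknife/f_G, Fisher enrichment and the SV
  consensus rule are each checked against independent brute-force oracles
  to 1e-12 in the test suite; the simulator is checked against closed-form
  coalescent expectations and an independent coalescent implementation.
* Composite-likelihood fits inherit the identifiability limits discussed
  above: scenario ranking is reliable at desk scale, absolute
  domestication-branch parameters are not.
* The F-model scan's calibration is validated for the low-F_ST regime the
  study system lives in; under much stronger background differentiation
  drift outliers bleed into all three tests, which is a property of the
  methods, not of this implementation.
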