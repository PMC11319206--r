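---
title: "Models and methods behind mtmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmosaic)
```

# The scientific problem

A human cell carries hundreds to thousands of mitochondrial DNA (mtDNA)
copies, so a newly acquired mtDNA mutation starts on a single molecule at a
heteroplasmy level of roughly 1/n.  Whole-genome sequencing of clonal
expansions of single cells (colonic crypts, fibroblast clones, HSPC
colonies) turns intracellular heteroplasmy into a measurable quantity: the
variant allele frequency within a clone (clone-VAF) approximates the
heteroplasmy level of the clone's founder cell.

mtmosaic implements the computational machinery needed to work with such
data: noise-aware calling of low-frequency heteroplasmies, classification
of variants into fertilized-egg heteroplasmies (Het_FE) versus postzygotic
mutations (PZ_simple, and PZ_recurrent at hypermutable sites), drift
summary statistics, forward simulation of mtDNA turnover, and
simulation-based (MSE-rejection) inference of two fundamental rates: the
mtDNA turnover rate per year and the mutation rate per base pair per
replication.

# Variant quality control

`apply_read_filters()` applies per-variant read-support criteria with
strict inequalities exactly as printed in the underlying methodology: mean
mapping quality < 25, mean base quality < 15, mean relative position of
the variant base outside 15--85%, forward-strand support outside 10--90%,
five or more mismatches in supporting reads, broken mate pairing
(NUMT-aware: both mates on mtDNA, non-chimeric, correctly oriented),
homopolymer/misalignment blacklists (rCRS 302--315, 513--525,
3,105--3,109, 16,182--16,187), and for InDels a >50% rate of additional
InDels in supporting reads plus the noisy loci m.567/955/5,894.  Boundary
values therefore pass (mapq 25, baseq 15, fractions 0.15/0.85 and
0.10/0.90) while 5 mismatches fails.  Whether quality cutoffs apply to
means or minima over supporting reads is not fixed by the source; the
summaries are means computed upstream, and the thresholds object
(`mt_filter_thresholds()`) is exposed so either convention can be fed in.

# The locus-specific background-noise panel

Sequencing error on mtDNA is strongly locus-specific.  `build_noise_panel()`
collects, for every (position, alternate allele), the VAF of every panel
clone (zeros included) and derives two thresholds:

* a one-sided 95% bound `mean + 1.645 sd` (normal approximation; the
  source states only "one-sided 95% confidence interval");
* a *relative-gap* threshold (`gap_threshold()`): VAFs inside the working
  window 0.05%--15% are sorted; among adjacent pairs whose relative gap
  `(VAF' - VAF)/VAF` is at least 0.33, the pair with the largest absolute
  gap is the noise/signal boundary, and the threshold is
  `min(mean(VAF, VAF'), 1.33 VAF)`.  "Largest gap" is read as the largest
  absolute difference: a relative-gap maximum would always sit at the
  near-zero end of the window, making the rule vacuous, so the 0.33
  relative floor acts as the qualifier and the absolute gap selects among
  qualifiers.

`reconcile_calls()` removes called variants at or below the effective
threshold (gap threshold when present, CI bound otherwise — the two rules
are stated "in parallel" without precedence, so the choice is a
configurable argument) and rescues uncalled measurements above it.  Two
deliberate numerical choices:

* Rescue additionally requires the measured VAF to exceed a practical
  detection floor (default 0.003, the ~0.3% heteroplasmy resolvable at
  several-thousand-fold depth).  Without it, a site whose background is
  almost entirely zero yields a near-zero threshold and "rescues" clones
  supported by one or two error reads.
* The panel includes the clone being evaluated, mirroring a panel built
  from all normal clones.  In cohorts of thousands of clones the
  contamination of a site's panel by a donor-confined true variant is
  negligible; in small cohorts it is not, which is why the inference
  functions read the observed clone-VAF distribution from raw
  measurements rather than from reconciled calls (see below).

Reconciliation is idempotent: removed calls stay below threshold and
rescued calls stay above it on a second pass.

# Classifying variant origin

`classify_variants()` assigns every (variant, donor) pair one class, in
precedence order: cross-donor recurrence (two or more donors with two or
more mutant clones each, or presence in a cohort-size-scaled number of
individuals — 10 out of the reference 86, never fewer than 3) makes a site
PZ_recurrent; exclusive sharing restricted to a late-branched subtree
(ancestor with at least 100 nuclear mutations before diverging, measured
root-to-MRCA on the donor phylogeny) is PZ_simple; exclusive sharing by
two or more clones of exactly one donor is Het_FE; sharing with sporadic
carriers elsewhere is decided by a binomial test — the spontaneous rate is
the maximum-likelihood estimate `x_exp/n` from the rest of the cohort and
the upper tail `P(X >= x_obs)` is compared with 0.01; singletons present
in matched bulk tissue at VAF >= 0.005 are Het_FE; everything else is
PZ_simple.  The precedence (recurrence first, then the late-branch
override) follows the reading that recurrence and late-branching are
corrections to naive sharing; variants that satisfy both the Het_FE
pattern and the cohort-wide recurrence rule are classified recurrent and
carry their `rule_fired` label for audit.

A deliberately simple consequence of the rules: at a genuinely noisy site
that escapes the panel, carriers appear in many donors and the site is
absorbed into PZ_recurrent — the same bucket real hypermutable sites
occupy.

`detect_tissue_recurrent()` flags within-tissue hotspots whose carrier
donors are older than non-carriers (one-sided Wilcoxon rank-sum, default
alpha 0.05 — no threshold is stated in the source) and which recur in at
least two donors of the tissue.

# Drift metrics

* `cavaf()` — the clone-averaged VAF, a zero-inclusive mean across all
  donor clones.  Because the per-turnover drift is a martingale, caVAF is
  an unbiased estimator of the fertilized-egg heteroplasmy level; the
  tests verify |bias| < 3 SE on simulated cohorts.
* `fst_index()` — Wright's fixation index
  `sigma_S^2 / (P(1-P))` with the *population* variance in the numerator
  (the denominator is the population Bernoulli variance, so a sample
  variance would mix conventions).  Computed only when caVAF > 0.01.
* `compute_svaf()` — the per-clone sum of PZ_simple clone-VAFs, the
  clock-like aging readout; Het_FE and PZ_recurrent calls are excluded.
* `strand_spectrum()` — pyrimidine-based substitution types split by the
  strand of the mutated pyrimidine and by position relative to the
  heavy-strand replication origin (m.16,197-191, wrapping the coordinate
  origin), with log2 heavy/light ratios (optional 0.5 pseudocount, off by
  default) and a Pearson chi-squared comparison across tissues.  The rCRS
  reference sequence is C-rich and is treated as the light strand, so a
  pyrimidine reference allele means the mutated pyrimidine lies on the
  light strand.

# The two turnover models

Both models keep the basal copy number n constant per completed turnover
and assume selective neutrality.

**Mitotic turnover** — the pool of n molecules grows by n sequential
random replications, each copying a molecule chosen uniformly from the
*current* pool (a Pólya urn: fresh copies are immediately eligible
templates, which is the natural reading of "increase one by one through
random replication"), and mitosis then retains a uniform subset of n of
the 2n molecules.  The Pólya-urn reading makes an exact sampling shortcut
available: added copies per type follow a Dirichlet-multinomial
(beta-binomial for two types) law and the halving is multivariate
hypergeometric.  The shortcut is validated in the test suite against a
shipped molecule-by-molecule oracle (`drift_step_oracle()`) by chi-squared
equality of one-step distributions at small n.

**Homeostatic turnover** — n Moran replacement events; each event degrades
one uniformly chosen molecule and replicates one uniformly chosen
survivor (degrade first, replicate from the n-1 survivors).  A single
event changes the variant count by ±1 with probability
`k(n-k)/(n(n-1))` each.  The implementation skips no-change events exactly
(geometric waiting times), which the tests validate against naive
per-event simulation.

Per turnover, the homeostatic variance increment of the variant frequency
is twice the mitotic one (2p(1-p)/n versus p(1-p)/n to leading order),
which is why roughly half as many homeostatic rounds reproduce any given
degree of drift — the simulations recover the factor empirically.

One quantitative subtlety the test suite makes explicit: for n = 750 and
an initial frequency of 0.1, the *mean* turnover count to fixation among
fixing cells is ~1,440 under the mitotic model (the diffusion closed form
`-2n (1-p)/p log(1-p)` gives 1,422), and the fixing fraction converges to
the initial frequency (~10% of cells).  At exactly 1,440 turnovers the
fixed fraction is still rising (~6%) and approaches 10% only after ~3,000
turnovers; the acceptance checks therefore test the pair
(mean-fixation-count ~ 1,440, fixation probability ~ 10%) rather than the
fraction at the 1,440-turnover snapshot.

**Mutation acquisition** — every replication event adds
`Poisson(r * 16,569)` new infinite-sites mutations to the newly created
copy; mutations created during the doubling phase face the same halving.
Cells are genotype-class forests in the implementation: each mutation
event creates a child class, a mutation's frequency is its class subtree
size over n, and extinct classes are pruned every turnover.  Per-copy
mutation counts are drawn as Binomial(new copies, 1 - e^-lambda) mutated
copies with zero-truncated Poisson multiplicities, which is exactly the
per-event Poisson model.

Reproducibility: all randomness flows through R's RNG; cells are simulated
sequentially in index order in a single thread, so `set.seed()` makes
every simulation bit-identical.

# Rate inference by MSE rejection

**Turnover rate** (`infer_turnover_rate()`): for every Het_FE variant with
caVAF > 0.005, the observed clone-VAF distribution is reduced to 25
summary statistics (20 bin counts over 0.5–5%, 5–10%, ..., 95–100%; mean;
SD; proportions wild-type < 5%, heteroplasmic 5–90%, homoplasmic > 90%;
VAFs below the 0.5% floor enter only the proportions, the mean and the
SD).  Forward simulations run at the donor's mean mtDNA copy number from
p0 = caVAF; because drift is Markov, a single trajectory recorded at every
candidate turnover count provides all candidates.  Per candidate the
donor's clone count is resampled (without replacement — the source says
only "randomly selected") from the simulated cells 100 times; each
resample yields one candidate draw with its MSE against the observed
statistics.  The estimate is the mean turnover count of the 50 lowest-MSE
draws, divided by donor age; tissues aggregate variant estimates with a
normal-approximation 95% CI.

The observed statistics are computed from raw per-clone measurements at
the site rather than from reconciled calls: at a true variant site the
background error is negligible next to the signal, while reconciliation
zeroes sub-threshold carrier clones and would bias the apparent drift
upward (measurably so in parameter-recovery experiments on small
cohorts).

**Mutation rate** (`infer_mutation_rate()`): log10(r) is drawn uniformly
on (-9, -3); each draw runs the mutation-accumulation simulator for
`g = tissue turnover rate x donor age` turnovers at the donor's copy
number, resamples the donor's clone count ten times, and summarizes each
resample by 22 statistics (20 bins of the per-cell maximum clone-VAF, and
the counts of cells with two and with three homoplasmic mutations).  The
estimate is `10^mean(log10 r)` over the 50 lowest-MSE draws, with the
min–max range.

**MSE normalization** — counts are converted to proportions of the
sampled clone count, after which all statistics share a common scale; the
default is the plain (unstandardized) MSE.  Dividing each statistic by
its across-draw SD is available (`standardize = TRUE`) but overweights
rarely populated bins whose SD is near zero, and degraded parameter
recovery by ~10–30% in the package's own experiments, so it is not the
default.

**Problem sizes** — the methodology at full scale uses on the order of
10^6 simulations per Het_FE variant and 10,000 simulated cells.  The
package defaults and the test suite run deliberately reduced versions
(1,000–2,000 cells and grids of ~60 candidate turnover counts for the
turnover rate; 80–1,000 draws and 60–200 cells for the mutation rate),
chosen so that parameter-recovery experiments on truth-labelled synthetic
cohorts stay within ±25% (turnover rate) and ±0.5 log10 units (mutation
rate).  All sizes are exposed as arguments.

# Selection: dN/dS against a simulated null

`mutation_opportunity()` enumerates every CDS position times three
alternative bases under the vertebrate mitochondrial genetic code
(incomplete, polyadenylation-completed stop codons are padded with A and
treated as stops; stop-gain SNVs and frameshift InDels are truncating).
`simulate_null_dnds()` places exactly the observed number of mutations at
random per iteration — uniformly, or weighted by the strand-resolved
pyrimidine spectrum (the default, since the observed substitution process
is strongly strand-asymmetric; both modes are available because the
source is ambiguous) — and records opportunity-normalized
missense/synonymous and truncating/synonymous ratios.  Iterations without
a synonymous hit are excluded and counted.  `dnds_report()` pools
PZ_simple SNVs per tissue, reports the observed ratios with the null
interquartile range and percentile, and contrasts clone-VAF distributions
of synonymous versus truncating mutations (VAF >= 0.1 only) with a
two-sided Fisher's exact test on the >90%-VAF proportion — the signature
of suppressed expansion of truncating mutations.

At realistic mutation counts the ratio of small counts carries an upward
Jensen bias of order 1/(synonymous count); the package reports null
quartiles rather than relying on the mean being exactly one.

# The synthetic cohort generator

`generate_cohort()` produces fully truth-labelled cohorts so that every
stage of the pipeline, and both inference procedures, can be tested
without access to protected sequencing data.  Its defaults are the study
conditions: tissue turnover rates of 14.3 (colon), 20.8 (fibroblast) and
17.9 (HSPC) mitotic turnovers per year, mutation rate 5e-8 per bp per
replication, 750 mtDNA copies per cell, mean mtDNA depth 6,000x with a
lognormal spread, roughly two fertilized-egg heteroplasmies per donor
(log-uniform egg VAFs), and a small set of hypermutable hotspot loci.
Mechanically:

* Het_FE variants drift per clone for `rate x age` turnovers through the
  same two-allele simulator the inference uses, independently per variant
  (molecular linkage between co-occurring heteroplasmies is not
  modelled);
* PZ_simple mutations accumulate through the molecule-tracking simulator,
  one run per donor with one simulated cell per clone;
* hotspots recur across donors with a configurable per-clone probability
  and stylized Beta-distributed heteroplasmy levels;
* observed alt counts are binomial draws at a lognormal per-clone depth
  from the true frequency plus a per-locus error rate drawn from a
  two-component (mostly near-zero, occasionally elevated) exponential
  mixture — the component structure exercises the gap-threshold
  algorithm.  Elevated error lives on noise-only loci so truth labels
  remain identifiable;
* the "called" flag mimics an upstream caller with a ~0.3% practical
  floor, which the reconciliation step must then clean up and complement;
* donor phylogenies have early-embryonic internal branches (a few nuclear
  mutations per division) and long terminal branches, the geometry that
  makes Het_FE variants converge at early nodes; late-branched clades for
  exercising the late-branch rule are built directly in tests;
* matched bulk ("blood") VAFs are binomial draws around the egg VAF.

A toy circular genome (`generate_toy_genome()`) provides the coordinate
space: random non-overlapping CDS/tRNA/rRNA features on both strands,
valid under the vertebrate mitochondrial code, with wrapped control
regions.  Mutation intensity deliberately uses the rCRS length (16,569)
rather than the toy length, so the per-clone mutation burden matches the
human-mtDNA scale (configurable via `rate_genome_length`).

What passing tests on these cohorts do *not* show about real data: the
generator has no alignment artifacts beyond the stylized error mixture,
no NUMT contamination, no culture-induced VAF shifts, no UV-accelerated
turnover, and no linkage between variants; the filters of
`apply_read_filters()` are exercised by planned-violation fixtures
(`generate_read_support()`), not by simulated reads.

# Degenerate inputs and tie-breaks

`gap_threshold()` returns NA (rule absent) for fewer than two VAFs in the
working window or no qualifying pair; reconciliation then falls back to
the CI bound.  `fst_index()` refuses caVAF <= 0.01.  The binomial
classifier errors on `x_obs = 0` (nothing to classify).  Donors aged 0
are excluded from rate conversion (a rate per year is undefined).  Sites
absent from the noise panel keep their calls with a warning.  Zero counts
in a strand-ratio denominator give NA unless the pseudocount is enabled.

# Known limitations

* Selection on variants, spatial structure and cell death are out of
  scope; the simulators are strictly neutral.
* The early-embryonic bottleneck is not modelled; the generator and the
  inference treat the fertilized-egg VAF as the initial condition of
  lifetime drift, which is the dominant process the data support.
* Rate inference assumes the turnover model (mitotic or homeostatic) is
  given; the two are fit separately and not mixed.
* The background-noise panel is global per cohort; per-tissue or
  leave-one-donor-out panels would be preferable for very small cohorts.
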