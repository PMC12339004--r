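---
title: "Monitoring recurrent target-site resistance evolution from pooled sequencing, bioassays and Sanger haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring recurrent target-site resistance evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitesweep)
```

## The problem

The two-spotted spider mite *Tetranychus urticae* is a haplodiploid crop
pest that evolves resistance to acaricides with remarkable speed.  When a
succinate dehydrogenase inhibitor (SDHi) is deployed at scale, resistance
can arise not from one mutation spreading by migration but from many
independent target-site substitutions in the *sdhB* and *sdhD* subunits of
the pesticide's molecular target, recurring in different genetic
backgrounds.  Detecting and quantifying that process requires several
coordinated analyses:

* **dose-response bioassays** to classify populations as susceptible or
  resistant and quantify resistance levels (probit LC50);
* **pool-seq genome scans** for selective sweeps around the target genes
  (windowed nucleotide diversity, Tajima's D, pairwise FST, and the
  population branch statistic PBS with its genome-wide-corrected form PBE);
* **codon-level cataloguing** of the target-site substitutions and of how
  saturated each residue's mutational neighbourhood is;
* **haplotype analysis** of short Sanger amplicons to distinguish recurrent
  origin from migration and recombination;
* **selection and mutation-supply inference**: selection coefficients from
  allele-frequency trajectories, and the recurrent-mutation rate
  Θ = 3·Ne·μ implied by the number of distinct mutations observed.

`mitesweep` implements each step as a tested, reusable function, plus a
forward simulator that generates every input with known ground truth, so
the whole pipeline can be exercised end-to-end and its operating
characteristics measured.  The numbered scripts under `analysis/` run the
pipeline as a narrative on simulated data.

## The simulator

### Haplodiploid Wright–Fisher model

`simulate_wf()` iterates a single population of `N` diploid females and `N`
haploid males (constant 1:1 census).  Each generation:

1. viability selection weights adults — female genotypes carry fitness
   `1, 1 + h s, 1 + s` and male hemizygotes `1, 1 + s` (selection in males
   can be switched off with `select_males = FALSE`);
2. egg and sperm gamete pools form from the selected adults;
3. recurrent mutation converts wild-type gametes to the resistant allele at
   rate `mu` per gamete per site, and every mutational event is recorded;
4. daughters are random unions of one egg and one sperm; sons develop from
   unfertilized eggs of the same selected egg pool.

Population allele frequency weights females twice and males once, so the
bookkeeping identity `copies = 2·N_females + N_males = 3N` holds every
generation — the same 3 copies per mating pair that give the
mutation-supply relation Θ = 3·Ne·μ its factor of 3.  A mating pair's
expected number of new mutant copies per site per generation is therefore
3·N·μ, which the test suite verifies against the recorded mutation events.

The infinite-N recursion of the same model, `wf_deterministic()`, serves as
the analytic oracle: it defines the expected trajectory shape against which
both the stochastic simulator and the trajectory-regression estimand are
checked.

Dominance is a genuinely open quantity for these resistance alleles; `h` is
a free parameter with default 0.5 (semidominance), which makes the logit
allele frequency grow approximately linearly — the regime the trajectory
regression assumes.

### Genome-scale simulation and the sweep

`simulate_genome()` produces the pooled-sequencing panel: a few thousand
biallelic SNPs on a 0.5-Mb chromosome for several populations that share
ancestral variation and have drifted apart.  Ancestral frequencies are
drawn from a 1/p-shaped spectrum (the neutral equilibrium form) truncated
at `p_min`; each population then drifts `generations` generations by
binomial resampling of its 3N genome copies.  With `generations = 0` the
panel is an equilibrium population — the condition used for the neutral
Tajima's D calibration — while the default 40 generations of separation
produce the moderate background differentiation (window FST of a few
percent) against which a sweep must stand out.

The sweep itself is a forward `simulate_wf()` trajectory for the selected
allele (default `s = 0.5`, starting from an established frequency
`sweep_p0 = 0.05`), combined with a deliberately light-weight hitchhiking
approximation: a neutral site at distance d from the selected locus is
dragged to the founding haplotype's allele with probability
`p_final · exp(-d / (s · hitch_bp))`.  This reproduces the two signatures a
scan keys on — a local trough in diversity and excess focal-branch
differentiation — without simulating recombination explicitly.  It is not a
coalescent-faithful sweep: the footprint shape is exponential by
construction, linkage among the dragged sites is ignored, and soft sweeps
(multiple sweeping haplotypes) are not represented.  Passing scan tests
therefore demonstrate that PBE localizes a hard-sweep-like signal at
realistic pool-seq noise levels, not that the scan's power on real, messier
data equals the measured rates.

### Sampling models

`sample_pool_reads()` emulates pooled resequencing by two-stage binomial
sampling: the pool's 2·`pool_size` chromosomes are drawn from the
population frequency, then reads are drawn from the pool's proportions at
Poisson-distributed depth (the standard shotgun approximation; a fixed
depth is available for variance checks).  Pool sizes of 50–400 individuals
and mean depths near 80 mirror practice.  `generate_bioassay()` draws
binomial kill counts from the probit dose-mortality curve with a baseline
control mortality, and `generate_sanger_genotypes()` draws diploid
individuals from a haplotype pool, recording unphased genotypes and keeping
the true phase as an attribute.  No read-level base errors or PCR artefacts
are modelled; `min_count` exists to make the SNP calls robust to them in
real data, but the simulations cannot measure that robustness.

## Pooled diversity statistics

All estimators work at a uniform depth `b` (default 50): reads are
subsampled without replacement (a multivariate hypergeometric draw;
`subsample_site()` / `subsample_pool()`), sites below `b` are masked, and
a site is a SNP when its minor allele has at least `min_count` reads after
subsampling (default 2, the PoPoolation convention).  Per-site diversity is
the corrected heterozygosity π = b/(b−1)·(1 − Σ p²); windowed π and
Watterson's θ are sums over SNPs divided by the number of covered sites in
the 5-kb window (aligned to the k·5000+1 grid), and Tajima's D uses the
classical constants with sample size n = b — after uniform subsampling the
b reads at a site are exactly a size-b sequence sample.

Two numerical properties of this design are worth stating explicitly
because the test suite is built around them:

* **The singleton filter biases D.**  With `min_count = 2` the rarest read
  class is censored, which inflates π relative to θ and shifts D upward by
  roughly +0.7 on an equilibrium spectrum (the pooled-specific correction
  for this is not implemented).  The defaults keep `min_count = 2` for SNP
  calling and the sweep statistics, where robustness matters more than
  unbiased D; the neutral-expectation calibration of D is run at
  `min_count = 1`, where the classical constants apply exactly and the
  windowed mean falls within the expected band around zero.
* **Window FST sees the pools, not the populations.**  The per-window
  estimator FST = (π_total − π_within)/π_total compares the pooled 2b-read
  sample with the per-pool samples.  Two finite pools drawn from one
  population differ by sampling alone, so the raw estimator's null
  expectation is (2b/(2b−1))/(4·pool_size) — about 0.0025 at 100
  individuals — not zero.  The tests verify this closed form; the default
  output clamps FST to [0, 1] (set `clamp = FALSE` for the raw value).
  Triallelic sites are reduced to their two overall most frequent alleles
  for FST, while π uses all four bases.

## The sweep scan

`branch_length()` maps FST to the additive scale T = −ln(1 − FST)
(clamped just below 1 so fixed differences stay finite), `pbs()` computes
the focal population's branch (T_f1 + T_f2 − T_12)/2, and `pbe()` subtracts
the genome-wide expectation: PBE_w = PBS_w − T_12,w · med, where `med` is
the median of PBS/T_12 over windows with T_12 > 0.  The median, rather than
the mean, keeps the genome-wide ratio insensitive to the very outliers the
scan is meant to find, and makes the identity
median(PBE/T_12) = 0 hold exactly — a property the acceptance tests check
verbatim.  Windows with masked FST in any pair are excluded from both the
median estimation and outlier calling.

Outliers are windows at or above the empirical (1 − q) quantile of PBE.
The default `quantile = 0.01` is the stricter threshold used for
figure-level calls; 0.05 is available, since both thresholds are in common
use and the choice is a sensitivity/specificity trade-off, not a modelling
question.  Ties at the threshold are all flagged; ranks break ties by
genomic order.  A population is called as having a signal at a gene when at
least one outlier window falls within the gene body ±25 kb — a deliberate,
explicit replacement for figure-level judgement.  PBE is computed per 5-kb
window throughout, matching the resolution of the diversity statistics.

## The mutation catalog and codon annotation

The catalog ships as a versioned TSV asset: 15 amino-acid substitutions —
six on five residues of *sdhB* (H146Q, S212I, H258Y, I260T, I260V, A285S)
and nine on three residues of *sdhD* (D116G, D116E, D116N, R119C, R119L,
R119G, R119P, R119H, P120L).  D116E is stored as two rows (wild codons GAC
and GAT, each one nucleotide from GAA) sharing a label and counting once.
Validation on load is strict — codon translations must match the amino
acids (standard nuclear code; these subunits are nuclear-encoded), each
wild/mutant pair must differ at exactly one position, and labels must
reassemble from their parts — because the catalog is treated as ground
truth downstream.  Residue numbering follows the mite protein coordinates.

`annotate_snp()` maps a genomic position through a strand-aware gene model
to its codon and intra-codon offset and reports the amino-acid change in
standard label form; a reference-base mismatch against the model is a hard
error naming the offset.  `accessible_substitutions()` enumerates a codon's
nine single-nucleotide neighbours with stop flags, the raw material of the
saturation argument: at the R119 hotspot (CGT) all three position-2
missense changes and two of the three position-1 changes are already in the
catalog.

For "mutation present in population" the presence threshold is
configurable with default 0 (any detection, by pooled frequency after
`min_count` or by a single Sanger carrier), since any fixed frequency
cut-off would be arbitrary at the detection limits of the two data types.

## Haplotype inference

`resolve_haplotypes()` applies the at-most-one-heterozygous-site rule:
fully homozygous individuals contribute two copies of one haplotype,
single-site heterozygotes contribute the two implied haplotypes, and
individuals with two or more heterozygous sites or any missing panel
genotype are excluded and reported (strictest reading of missing data).
Copy conservation — two copies per retained individual — is exact and
property-tested.  Note the exclusion rule is frequency-dependent: diplotypes
whose two haplotypes differ at ≥2 sites are censored, so resolved
frequencies are unbiased only when such pairs are rare (centre-dominant
pools); the round-trip tests use that regime.

`build_network()` constructs a minimum-spanning network on Hamming
distances — edges added in increasing distance classes, retaining every
co-minimal edge that joins two components as they stood at the start of the
class, so alternative equally short connections are never broken
arbitrarily.  A median-joining network would add inferred intermediate
haplotypes; for short amplicons with unit-step structure the MSN
reproduces the same topology without inventing nodes, which is why it was
chosen.  `classify_ancestral()` labels as ancestral the haplotypes that are
both common (carrier count in the top quartile, configurable) and central
(degree ≥ 2, configurable), mirroring the "common and at the centre"
heuristic, and assigns each derived haplotype its nearest ancestral node.

`enumerate_recombinants()` lists every ordered parent pair and breakpoint
interval by which a single crossover could produce a target haplotype
(double crossovers are deliberately not enumerated: over amplicons tens of
bp wide they would require multiple exchanges within the same few dozen
bases).  `expected_recombinants()` puts the rate argument in numbers:
ρ = 2·c·Ne·r·d crossovers per generation across d bp, with r defaulting to
1e-7 per bp (10 cM/Mb).  The calculator reports its own value from explicit
inputs; published per-individual restatements of this quantity could not be
reproduced from the formula under any parameterization tried, so no attempt
is made to match them.

## Selection and mutation-supply inference

`fit_selection()` regresses allele counts on calendar year with a binomial
logit link, weighting each population-year point by the number of sampled
chromosomes; under logistic allele-frequency growth the year slope is the
per-year selection coefficient, converted to per-generation units via
`gens_per_year` (default 20 generations per year for this mite).  The
joint fit pools alleles with allele-specific intercepts and one shared
slope — fixed effects, not a random-intercept model — giving the collective
selective strength of the resistance alleles.  Alleles observed in fewer
than two distinct years are reported as non-estimable, and trajectories
pinned at 0 or 1 everywhere raise a separation flag rather than a number.
Whether such regressions should weight populations by chromosomes or
equally is not settled; the chromosome-weighted GLM is the documented
default.

`recurrent_mutation_estimate()` converts the mean number of distinct
resistance mutations per population (k̄) accumulated over a known time into
a per-generation mutation supply Θ = k̄/(years × generations/year) and the
effective size that supply implies, Ne = Θ/(c·μ) with c = 3.  With
k̄ = 2.7 over 7 years at 20 generations/year and μ = 2.8e-9, Θ = 0.0193 and
Ne ≈ 2.3 × 10⁶ — the package's worked example, recomputed by the acceptance
script.  (Survey cohorts give slightly different k̄ depending on whether
the 2024 mean is taken as 2.55 or 2.7; both are legitimate inputs and the
function takes k̄ explicitly rather than fixing one.)

`survival_association()` fits ordinary least squares of population survival
at the diagnostic dose on three frequency metrics — predominant-allele
frequency, any-resistant-carrier frequency, homozygous-carrier frequency —
plus one multivariate fit on the individual mutation frequencies.  Survival
at the diagnostic concentration is used directly as the phenotype because
highly resistant populations have no estimable LC50.  `resistance_fst_ibd()`
computes Hudson-style FST from resistance-allele frequencies
(1 − H_within/H_between, ratio of sums over alleles), great-circle
distances, and a one-sided Mantel test with 999 permutations by default.

## Problem sizes and numerical conventions

The test suite and the acceptance script run everything at desk scale,
chosen so each property is measured with useful precision: 500 replicate
bioassays (6 log-spaced doses, 30 mites per dose) for LC50 recovery; 50
sweep replicates plus 20 nulls on a 0.5-Mb, 2000-SNP, 100-window genome
with N = 200 and 40 generations of separation; 60 replicate
selection-inference fits over 30 populations sampled yearly for 6 years at
50 chromosomes each; 100 replicate haplotype genealogies of 250 individuals;
and 400 null Mantel replicates at 199 permutations.  LC50 confidence
intervals use the delta method on −α/β by default (Fieller's interval via
`ci = "fieller"`); doses with 0% or 100% corrected mortality stay in the
likelihood; censored assays (">top dose") are reported with a bound and a
status, never a silent number, and group means over any censored member are
flagged as lower bounds.  Fold ratios are reported from the package's own
estimates; published fold numbers can differ by ±1 in the last integer
digit depending on rounding convention, so exact integer matching is not
forced.

## Limitations

The simulator treats target sites as unlinked, injects sweeps through an
exponential hitchhiking kernel rather than explicit recombination, and
models no sequencing error; the scan statistics are per-window, not
haplotype-based, so soft sweeps distributed over many backgrounds will be
harder to see than the hard-sweep tests suggest; Tajima's D carries the
documented min-count bias at its default settings; and the haplotype
resolution rule censors doubly heterozygous individuals, biasing haplotype
frequencies whenever divergent haplotypes are both common.  These are
properties of the methods themselves, faithfully reproduced, not defects of
the implementation — the package's aim is to make exactly these operating
characteristics measurable.
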