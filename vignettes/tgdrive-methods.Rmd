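---
title: "Models and methods in tgdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tgdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgdrive)
```

`tgdrive` models CRISPR homing gene drives — genetic elements that bias
their own transmission above the Mendelian 50% — with particular attention
to *split* ("trans-complementing") drives, in which the Cas9 cassette and
the tandem-gRNA cassette sit at separate loci and the homing cascade only
fires in individuals carrying both.  This vignette documents the models,
their assumptions, the tunable parameters, and the design choices made
where reasonable alternatives existed.

## The genetic layer: inheritance cubes

Every simulation in the package rests on an *inheritance cube*: an exact
mapping from a (maternal genotype, paternal genotype) pair to a probability
distribution over offspring genotype and sex.  Alleles at each drive locus
take one of four states:

* `W` — wild type, cleavable;
* `T` — the drive transgene (Cas9 cassette, gRNA cassette, or the fused
  full-drive element, depending on the locus role);
* `R` — an in-frame, function-preserving resistant allele created by
  end-joining repair; immune to further cleavage;
* `B` — an out-of-frame, loss-of-function resistant allele, also immune.

Six architectures are built in: full drives at an autosomal (`full_GD`) or
X-linked (`full_GDX`) locus, and split drives with the two cassettes linked
on an autosome (`tGD_linked`), on separate autosomes (`tGDc`), linked on
the X (`tGDX_linked`) or on separate X loci (`tGDXc`).  X-linked males are
hemizygous; they carry a single drive-locus haplotype and a drive-free Y.

The cube composes three exact transforms:

1. **Germline homing.** A wild-type allele is *drive-competent* when the
   genotype carries at least one Cas9 source and one gRNA source and the
   homolog carries the transgene template at that locus.  Each competent
   allele independently: is cleaved with probability $q$; converted to `T`
   by homology-directed repair with probability $c$ given cleavage; and
   otherwise end-joins to `R` with probability $\rho$ or `B` with
   $1-\rho$.  Because a hemizygous male has no homolog, no conversion is
   possible in X-linked male germlines.  The expected transmission of the
   element from a drive-competent heterozygote is the standard
   $\tfrac{1}{2}(1 + qc)$.
2. **Gamete segregation.** Haplotypes segregate at 1/2; two-locus systems
   recombine at the architecture's recombination fraction (0 for linked
   configurations, 1/2 for unlinked); X-linked males transmit X or Y at
   1/2, which sets offspring sex.
3. **Maternal deposition.** A mother carrying both components loads
   Cas9/gRNA ribonucleoprotein into the egg.  Each zygotic `W` at a drive
   locus is cleaved with probability $d$ and repaired by end-joining only
   (`R` with probability $\rho$, else `B`).  Deposition never performs
   homology-directed repair: the empirical signature of coupled maternal
   inheritance — transmission collapsing to ~50% with a single early indel
   per germline — implies no embryonic conversion, so the model forbids
   it.  Deposition depends on the mother's own genotype only; grand-maternal
   carry-over is not modeled.

Cube rows sum to one by construction (products of distributions), never by
renormalization; the test suite checks rows against an independent
brute-force expansion of the whole probability tree to $10^{-12}$.

Design choices worth recording: conversion events at the two loci of a
split drive are independent given competence (no data constrain their
correlation); somatic mosaicism from leaky promoters carries no fitness or
phenotype consequence; genotype codes order haplotypes lexicographically by
state (`W < T < R < B`) so every genotype has a single canonical name
(e.g. `"WA-TB/TA-WB|F"` canonicalizes to `"TA-WB/WA-TB|F"`).

## The fly cross layer: timing structure and resistant alleles

`simulate_cross()` models the classic three-generation scoring experiment:
two transgenic F0 parents produce a transheterozygous F1 whose germline is
scored through the phenotypes of its F2 progeny (one vial per F1).  The
generative model separates two windows in which cleavage can happen:

* **Zygote stage** (only when the F0 mother carried *both* components):
  each zygotic `W` at a drive locus is cleaved with probability $z$ and
  repaired by end-joining, fixing a single indel identity clonally across
  the entire germline.  With $z = 1$ this yields exactly one distinct
  resistant allele per vial and 50% transmission — no conversion substrate
  remains.
* **Germline development**: the germline descends from $k$ primordial
  pole-cell precursors (default $k = 3$, the canonical number set aside in
  the early fly embryo).  Each precursor independently resolves each
  remaining competent `W` (cleave $q_{late}$, convert $c_{late}$, else an
  end-joining indel), so a vial can show at most $k$ distinct late indels
  per locus.  Each F2 offspring samples one precursor uniformly, then a
  gamete.

Observed tallies of up to 4 distinct indels per germline sit slightly above
$k = 3$; whether that reflects more precursors, post-pole-cell editing, or
sampling of residual late events is unresolved, so $k$ is exposed as a
parameter rather than hard-coded.

Indel identities follow an `indel_spectrum()`: a few recurrent labels plus
a *tail* of always-novel singleton identities (at the *white* locus roughly
7% of recovered alleles are singletons; at *yellow* roughly 19%).  Labels
are categorical; no nucleotide-level modeling is attempted.

Phenotypes derive from genotype: DsRed marks the Cas9 cassette, GFP the
gRNA cassette, and the body/eye phenotype columns are mutant only when no
functional allele (`W` or `R`) of the target gene is present.  Mosaicism is
not scored.

## Estimation and tests

`fit_conversion()` maximizes a per-vial binomial likelihood.  Under the
germline-only model the marker-positive probability is
$p = \tfrac{1}{2} + \tfrac{1}{2}qc$, whose MLE is $2\hat p - 1$ constrained
to $[0,1]$; boundary estimates are flagged rather than silently clipped.
The zygotic-mixture model adds the clonal deposition channel: a fraction
$z$ of vials sit at exactly $p = 1/2$, the rest at the germline-only value;
the two-component mixture is fitted by bounded optimization.  Confidence
intervals are percentile bootstrap over vials (vials, not flies, are the
independent units — each F1 germline is one draw).  Parameter recovery on
synthetic tables (20 vials x 50 flies) is unbiased to better than 0.02
across the efficiency range.

The randomization tests permute group labels over pooled values
(difference in means) or pooled Bernoulli outcomes (difference in
proportions) and use the add-one two-sided p-value
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(n_{perm} + 1)$, which
never reports zero; 5000 permutations by default.  Whether the original
analyses were one- or two-sided is not documented; two-sided is
implemented.  An `exact = TRUE` mode enumerates all label assignments for
small groups and is verified against an independent enumeration oracle.

## The population layer

The mosquito model is a single-patch, daily-time-step, genotype-resolved
life-history simulation in the style of the MGDrivE framework family:
egg, larva and pupa stages with fixed durations, adults with constant
mortality, males mating throughout life, females mating exactly once at
emergence and storing the mate's genotype.  Default life-history
parameters for *Aedes aegypti*:

| parameter | meaning | default |
|---|---|---|
| $\beta$ | eggs per female per day | 20 |
| $T_E, T_L, T_P$ | egg / larval / pupal durations (days) | 5, 6, 4 |
| $r$ | daily population growth rate | 1.175 |
| $\mu_M$ | adult daily mortality | 0.090 |
| $N$ | equilibrium adult population size | 10,000 |

Two rates are derived rather than printed.  The common juvenile daily
mortality $\mu_J$ solves the density-independent characteristic equation
$r^{T_J+1} = (1-\mu_M)\,r^{T_J} + \tfrac{\beta}{2}(1-\mu_J)^{T_J}$ with
$T_J = T_E + T_L + T_P$ (root-finding tolerance $10^{-10}$), so that the
linearized daily projection grows at exactly $r$.  Density dependence acts
on larvae through the daily survival multiplier
$\left(\alpha/(\alpha + L)\right)^{1/T_L}$ — the standard Deredec-style
form used by that framework family, fully determined once $\alpha$ is
calibrated so the deterministic equilibrium holds exactly $N$ adults.  The
equilibrium cohort vector returned by `calibrate_life_history()` is an
exact fixed point of the deterministic update (machine precision), and a
365-day deterministic run stays within 1% of $N$.

One reading note: the parameter table labels $N$ an adult *female*
population size, while the release description speaks of an equilibrium of
10,000 adults; the package takes $N$ as total adults.  Only the absolute
scale, not any dynamic, depends on this factor of two.

Stochastic mode uses Poisson clutches (mean $\beta$ per female per day;
the distribution is not documented in the source material, so the maximum-
entropy count model was chosen), multinomial offspring genotypes from the
cube row, binomial survival, and multinomial mate choice weighted by
fitness; all counts stay integers.  Deterministic mode propagates
expectations; the test suite checks the one-step expectation of the
stochastic model against it.  Sex is assigned at the egg via the cube's
sex-resolved offspring distribution, which keeps X-linked genotypes and
sex consistent by construction.  Unmated females (no males present at
emergence) never lay and never remate.  Releases are appended to the adult
male pool on their scheduled day; the default schedule is 5 weekly
releases of 100 drive-homozygous males, starting after a 50-day burn-in
(the burn-in length is a package choice; it only needs to be long enough
that rounding noise has relaxed).

## Replacement and suppression experiments

`replacement_experiment()` scans drive systems against allelic conversion
efficiencies with all other drive parameters at exploratory values
(cleavage 1, end-joining all in-frame and cost-free, no fitness costs) and
reports carrier fraction (adults with at least one transgene copy), its
steady-state time, and allele-class counts.  *Steady state* is the first
day from which the metric's range over a 30-day window falls below 0.001;
the window and threshold are package choices, as the figure being
emulated defines none.

`suppression_experiment()` adds a fertility rule: females with no
functional allele (`W` or `R`) at the target locus are sterile, so drive
homozygotes cannot reproduce.  A *crash* is the day the last adult female
dies, measured from the first release ("within 1.5 years" is interpreted
as 548 days).  With complete conversion the crash is certain; with 99%
conversion, in-frame resistant alleles restore fertility, are immune to
cleavage, and rescue the population before it collapses.  Because the
rescue begins while the population is still large (at $N = 10{,}000$, 1%
of cleavage events is many resistant alleles per day), the dip bottoms out
well above half the equilibrium size; the *rebound* flag therefore
requires a dip below $0.9N$ — beyond the ~2% stochastic fluctuation at the
default population size — followed by recovery above $0.5N$.  A flat
trajectory neither crashes nor rebounds.

## What the synthetic data does and does not emulate

The fixture generators reproduce the statistical structure the analyses
assume: per-vial binomial marker counts with vial-level heterogeneity from
the precursor-cell model, recurrent-plus-singleton indel spectra, and
calibrated miniature populations.  They do not reproduce vial-by-vial
numbers of any real experiment, batch effects, scoring error, viability
differences among phenotypes, or linkage to loci outside the drive.
Passing tests therefore demonstrate internal consistency and correct
inference under the stated model, not agreement with any particular
dataset.

## Problem sizes used in the checks

The bundled tests and the acceptance script run: suppression ensembles of
10–12 stochastic replicates at $N = 10{,}000$ over 3 simulated years;
parameter recovery on 100 replicates x 4 efficiencies of 20-vial x 50-fly
tables; cube-vs-oracle comparisons on 20 random parameter vectors; and
deterministic replacement scans at $N = 500$.  These sizes were chosen so
the full battery completes in minutes on a single core while keeping every
Monte-Carlo tolerance at 3 standard errors or tighter.

## Known limitations

Single patch only — no space, migration, seasonality or temperature
dependence; adults are age-less apart from constant mortality; one mating
per female; no multiplexed-gRNA mechanics (impaired homology arms enter
only as alternative conversion efficiencies per construct); indels are
categorical labels, never sequences; and the deposition model ignores any
asymmetry between loci in zygotic cleavage efficiency unless per-locus
$z$ or $d$ values are supplied explicitly (coupled-maternal data show such
asymmetry between the Cas9 and gRNA markers, which a shared $z$ cannot
produce).
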