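---
title: "Mapping modifiers of a censored onset trait in mutagenised pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping modifiers of a censored onset trait in mutagenised pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ammscreen)
library(dplyr)
```

## The screen this package models

ammscreen analyses forward-genetics modifier screens of the kind run in
NOD mice to find genes whose disruption changes the incidence or age of
onset of autoimmune diabetes. A mutagenised G0 male carries a private load
of random point mutations. His G1 sons each inherit an independent
half-sample of that load and found one pedigree. G1 males are outcrossed
to wild-type females to produce G2 daughters, and each G2 daughter is
backcrossed to her own G1 sire, so that in the resulting G3 daughters any
mutation the pedigree carries can become homozygous. G2 and G3 females are
genotyped at every coding/splice mutation identified in their G1 founder
by exome sequencing, and followed weekly for glycosuria up to 40 weeks of
age; a mouse without onset by then is right-censored. On the
high-incidence genetic background such screens use, about 80% of
unmanipulated females develop diabetes by 40 weeks.

Each mutation is then tested, one locus at a time, for association
between zygosity (REF/HET/VAR) and onset age, under three inheritance
models. The small mutation load per pedigree (a few dozen loci) is the
design's point: an association implicates a specific mutation, not a
broad genomic interval.

## The linkage statistic

For each mutation and model, zygosity is encoded as a numeric dose:
recessive 0/0/1, additive 0/0.5/1, dominant 0/1/1 for REF/HET/VAR. The
association test compares Weibull proportional-hazards fits with and
without the dose, with cumulative hazard

$$H(t \mid x) = (t/\lambda)^k \, e^{\beta x},$$

maximised over $(\lambda, k, \beta)$ on the right-censored weekly onset
data. The statistic is the likelihood ratio $2\{\ell_1 - \ell_0\}$, and
the direction of an effect is the sign of $\hat\beta$ (positive log
hazard ratio = earlier onset = accelerating). This parametric
time-to-event regression is our concrete
reading of a "generalised linear (mixed) model on Kaplan–Meier-analysed
onset" — it handles censoring honestly, nests cleanly for likelihood-ratio
testing, and admits brute-force likelihood oracles in the tests. The
Weibull/AFT equivalence also means `survival::survreg` can serve as an
independent cross-check, which the test suite exercises; the fit itself is
implemented in the package (BFGS with analytic gradients).

The p-value reference deserves a word. A pedigree scan applies a
Bonferroni threshold of roughly $0.05/126$ to tests carrying only a few
dozen events, and in that far tail the first-order $\chi^2_1$
approximation to the likelihood ratio is visibly anti-conservative (in
our null simulations at 54 mice per pedigree, 1.5–2.5× the nominal tail
probability, enough to push the family-wise error of a 42-mutation scan
above its nominal 5%). We therefore refer the statistic to an
$F(1,\,d)$ distribution with $d$ = events − number of estimated
parameters — the same finite-sample calibration normal-theory regression
uses, and the conventional pragmatic adjustment where exact references
are unavailable. It converges to $\chi^2_1$ as events accumulate, costs
nothing, and in the package's simulations restores family-wise error
control (1.6% over 500 null 42-mutation scans) without losing the
planted-effect power the acceptance checks demand.

Two further numerical points deserve note. First, onset times are weekly
ceilings, so the data are heavily tied; the parametric likelihood treats
a week-$w$ onset as exact at $w$ (an interval-censored refinement would
be possible but is not needed for the package's operating
characteristics, and the logrank utility uses the standard tied-data
hypergeometric form). Second, complete separation is routine, not
exceptional: a fully penetrant suppressor leaves every homozygous mutant
censored, the likelihood is then monotone in $\beta$ and its supremum is
approached but never attained. The fitter detects this plateau (restarts
that improve the log-likelihood by less than 10^-6^) and reports the
supremum rather than flagging a convergence failure; the reported LRT is
accurate to well below its printed precision. Fits that fail outright are
flagged `no_convergence` and never support a candidate call.

The mixed variant (`mixed = TRUE`) adds a shared normal random intercept
on the log hazard for each G2 dam's litter, integrated out by 20-node
Gauss–Hermite quadrature, and includes the frailty in both the null and
alternative fits so the LRT still has one degree of freedom. It is the
right scan when litters share unmodelled risk; the fixed-effect scan is
the default.

Multiplicity is handled per pedigree, as each pedigree is an independent
scan: $m$ = (mutations in the pedigree) × (models tested), and
$p_{\mathrm{bonf}} = \min(1, m\,p)$. Whether the original screens'
correction also multiplied by the number of models is not something we
could determine, so the more conservative choice is made; it keeps the
family-wise error of a 42-mutation null scan comfortably inside 5% in
the package's simulations.

## Candidate calling

A mutation is called a candidate modifier when (1) its pedigree has at
least 20 G3 females, (2) at least two homozygous mutants were
phenotypically screened, (3) at least two homozygous reference mice were
screened, and (4) the best model's Bonferroni-adjusted p-value is below
0.05. "Screened" is read as phenotyped, not merely genotyped, since the
criteria concern phenotypic evidence. The best model is the minimum
adjusted p, with deterministic tie-break recessive > additive > dominant;
if the models significant at the threshold disagree on direction the
mutation is flagged for review instead of called. Calls are reported as
accelerating or delaying; the direction classifier additionally
cross-checks the fitted sign against the Kaplan–Meier ordering
(restricted-mean onset-free time) of the affected versus reference
classes and withholds a direction when they disagree.

Small pedigrees are excluded by criterion (1) exactly as in practice,
where pedigrees with ≤14 G3 females are left unscreened.

## Saturation and footprint

Genome saturation is the fraction of annotated autosomal protein-coding
genes carrying damaging and/or null alleles ("probably damaging" or
"probably null" in the damage annotation; the annotation is an input,
never recomputed) screened at least twice in the homozygous state. The
denominator defaults to 20,000 autosomal protein-coding genes and is
configurable, since annotation totals differ between releases. The
genomic footprint of a modifier class extrapolates hits to genome scale:
footprint = hits / saturation, e.g. 7/0.0035 = 2000 genes whose
loss of function would be expected to exacerbate the trait, and
5/0.0035 ≈ 1429 ≈ 1400 (headline figures rounded to the nearest hundred,
halves away from zero; the raw value is always reported alongside).

## What the simulator reproduces, and what it does not

`simulate_screen()` generates the full breeding scheme with Mendelian
transmission: the G1 founder heterozygous at all his mutations, each G2
daughter HET with probability 1/2 per locus, and G3 genotypes drawn from
the G2 × G1 backcross, giving marginal G3 class probabilities
REF:HET:VAR = 3/8 : 1/2 : 1/8. Because screened cohorts mix G2 females
(never VAR) with G3 females from dams of mixed genotype, observed class
counts deliberately do not follow any single Mendelian ratio — matching
the real screens.

Onset times follow a Weibull law parameterised by two interpretable
quantities: the cumulative incidence by week 40 (default 0.80, the
approximate female incidence on the high-incidence background) and the
median onset among affected animals (default 22 weeks — a free parameter
chosen as a plausible mid-monitoring median, as no baseline median is
published for this line). Planted effects multiply the baseline hazard by
`hazard_multiplier^dose`; weekly monitoring is modelled by ceiling onset
to whole weeks and censoring at 40. A configurable dam-level log-normal
frailty (default variance 0) generates litter clustering for exercising
the mixed scan. Mutation positions are uniform over the 19 autosomes with
fixed approximate lengths; missing genotype calls are generated
independently per cell at a configurable rate (default 0).

The simulator does not model ENU dose–response, mutation spectra,
sex-linked loci, male phenotypes, litter-size variation, or epistasis;
pedigree sizes default to 6 G2 dams × 8 G3 per dam as a stand-in for
unpublished per-pedigree counts. Passing tests therefore demonstrate the
pipeline's statistical behaviour under a clean generative model matching
the design's assumptions, not robustness to the full messiness of a real
vivarium.

## Simulation scales used by the test suite

The package's properties are verified at sizes chosen to be informative
while remaining desk-scale: family-wise error over 500 null screens of 42
mutations (the modal pedigree load), detection of a fully penetrant
recessive suppressor (hazard multiplier ~0) over 200 replicate
100-female pedigrees, ten-mouse likelihood toys against grid-search
oracles, 10,000-shuffle permutation references for the logrank test, and
genotype-frequency checks on 600 independently bred G3 daughters.

## Worked example

```{r example, eval = FALSE}
eff <- effect_spec("PED01_M05", "recessive", hazard_multiplier = 0.02)
scr <- simulate_screen(n_pedigrees = 1, n_mutations_per_founder = 42,
                       g2_per_g1 = 10, g3_per_g2 = 9,
                       effects = eff, seed = 77)
res <- amm_scan(scr)
call_candidates(res, scr)
plot_manhattan(manhattan_table(res, scr$mutations))
plot_km_genotype(scr, "PED01_M05")
```

## Known limitations

The F reference for the LRT is a calibration heuristic, not an exact
distribution; with very few homozygotes the far tail of the statistic
remains approximate, which is one reason the candidate criteria demand at
least two screened homozygotes of each class before a call is made. P-values from any specific historical
screen are not expected to be numerically reproduced: per-mouse genotype
and onset data of such screens are not published, and the exact
likelihood of the original mapping software is not restated in the
literature this package draws on; the package's claims are therefore
property-based (error control, power, oracle agreement) rather than
value-based.
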