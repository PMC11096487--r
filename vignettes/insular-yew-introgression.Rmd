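---
title: "Methods: population genetics and cytonuclear introgression dynamics of insular yews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and cytonuclear introgression dynamics of insular yews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yewpop)
```

## The system and the questions

Yews (*Taxus*) are dioecious conifers with paternally inherited chloroplast
DNA. Island lineages in Taiwan and the Philippines are genetically distinct
from each other and from their continental relative *T. mairei*, yet both
island gene pools contain small numbers of foreign-haplogroup sequences:
continental haplotypes in Taiwan and Taiwan-derived haplotypes in the
Philippines. `yewpop` implements the analysis chain used to characterise
this system — within-population diversity, Hardy-Weinberg conformity of the
nuclear ITS marker, hierarchical differentiation, haplotype networks with
introgression counting, a boundary likelihood-ratio test for post-split
migration — together with the package's central model: a deterministic
recursion for the contrast between chloroplast and nuclear introgression
levels under pollen- versus seed-mediated gene flow.

Two markers are assumed throughout: a concatenation of four chloroplast
intergenic spacers treated as one haploid, paternally transmitted,
non-recombining locus, and the nuclear ribosomal ITS treated as a single
biparentally inherited locus whose two phased haplotypes per individual act
as alleles.

## Diversity and Hardy-Weinberg statistics

Per population, `diversity_table()` reports haplotype diversity
$H_d = \frac{n}{n-1}\,(1 - \sum_i p_i^2)$, nucleotide diversity $\pi$
(mean pairwise proportion of differences), and Watterson's
$\theta_W = S / (a_{n-1} L)$ with $a_{n-1} = \sum_{k=1}^{n-1} 1/k$.
Missing-data conventions follow the dominant convention of the standard
desktop tools in this field: $\pi$ uses pairwise deletion (each sequence
pair is compared over the sites where both carry an unambiguous nucleotide,
and the per-pair per-site proportions are averaged), while $S$ and
$\theta_W$ use complete-column deletion. `N` is always missing data; gap
handling is per-statistic. The two conventions coincide on complete data but
can diverge on gappy alignments — a documented risk when comparing against
other software. Reports optionally scale $\pi$ and $\theta_W$ by 1,000, the
presentation used in the study system's summary tables.

Conformity of ITS to single-locus biparental inheritance is tested per
population. `fis()` is the Weir-Cockerham single-population $\hat f$,
combining alleles by summing variance components; it is negative under
heterozygote excess and undefined (reported missing, never 0) for
monomorphic samples. `hwe_exact_test()` computes the conditional exact
p-value: the total probability, given the allele counts, of genotype tables
no more probable than the observed one. When the table universe has at most
`enum_limit` ($10^5$) members the test enumerates it exactly; otherwise a
switch Markov chain swaps single allele copies between random individuals.
Because the conditional table distribution is exactly the one induced by a
uniformly random pairing of the $2n$ gene copies, this random walk needs no
Metropolis correction; the default chain length is $10^6$ steps after
$10^4$ burn-in, and the Monte-Carlo standard error is estimated from 50
batch means (autocorrelation makes this an approximation, which is why
tests compare chain to enumeration at 3 SE with an absolute floor).
Bonferroni correction across populations uses the $\alpha/k$ threshold.

## Differentiation: Phi-statistics, AMOVA, clustering

Molecular distances are counts of differing characters (substitutions plus,
optionally, one character per indel event) with pairwise deletion of
missing states; these counts serve directly as squared Euclidean distances
in the analysis of molecular variance. The hierarchy is taxon / population /
within for the haploid chloroplast marker and taxon / population /
individual / within for phased ITS. Sums of squared deviations per stratum
are computed from subset pair sums, and variance components are solved from
expected-mean-square coefficients computed by a general synthesis rule for
unbalanced nested designs (the three-level case reduces to the classical
closed-form coefficients, which the test suite checks against an
independent brute-force implementation). Negative components are retained
and reported, never floored.

Fixation indices follow the standard nesting:
$\Phi_{CT} = \sigma_a^2/\sigma_T^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2 + \dots)$,
$\Phi_{ST}$ for all among-population structure, and $\Phi_{IS}$ for the
within-individual level of the diploid design. Each index has its own
permutation scheme: whole populations among taxa ($\Phi_{CT}$), units among
populations within taxa ($\Phi_{SC}$), units among all populations
($\Phi_{ST}$), and gene copies among individuals within populations
($\Phi_{IS}$); units are individuals (copies move together) for diploid
data. Permutation p-values use $(\#\{perm \ge obs\} + 1)/(B + 1)$, which
cannot return 0. The study-scale default is $B = 2000$ permutations; the
packaged demo and the test suite use 29–199 permutations and 12–60-sequence
instances, problem sizes chosen so the whole suite runs in about a minute
while still giving binomially meaningful checks.

Population clustering uses neighbour joining on the pairwise $\Phi_{ST}$
matrix (raw values, including small negatives; whether rescaling was used
upstream is not documented, so raw is the default). Labels are sorted
lexicographically before clustering so ties resolve deterministically, and
negative branch lengths are clamped to zero in the output tree only.

## Statistical-parsimony networks and introgression counting

Haplotypes are collapsed from the alignment with indel events recoded by
simple indel coding: each distinct contiguous gap run, identified by its
exact span, becomes one presence/absence character, scored missing for
sequences whose own longer gap strictly subsumes the span. Coordinates are
1-based inclusive in all reports and 0-based half-open internally. For
diversity statistics haplotypes are defined without indel characters
(gap-as-missing); for networks they include them, each indel event counting
as a single mutational step — the paper does not state which convention it
used per marker, so these defaults are documented package choices.

The network joins haplotype pairs in order of increasing mutational
distance, never beyond the connection limit; a $d$-step connection passes
through $d-1$ inferred intermediate nodes so every edge spans exactly one
step, and all pairs tied at the joining distance between two components are
retained (reticulations). Connected components are the separate networks: a
haplotype farther than the limit from everything else stays isolated,
reproducing the two-network behaviour seen with a divergent singleton
haplotype. Intermediates are anonymous per connection; merging of
intermediates across connections is not attempted because implied character
states along a multi-step path are not identifiable without an ordering
assumption.

The probability-of-parsimony limit is computed as
$P(j; L) = ((L-j)/L)^j$, from a two-sequence coalescent argument: the
chance that an observed difference reflects a single mutation is
$1/(1+\theta)$ with the pair-specific per-site $\theta$ estimated as
$j/(L-j)$. The limit is the largest $j$ with $P \ge 0.95$. Published
implementations of this criterion differ in numerical detail, so the limit
can always be fixed explicitly — every packaged fixture and the acceptance
path set `limit = 10` rather than relying on the formula.

Haplogroups are the network components, labelled by the majority taxon of
their sampled sequences (exact ties break by taxon label order with a
warning; user-supplied reference haplotypes can override labels when the
haplogroups of interest are subgraphs of one component, which is the
fallback for delineations within a connected genealogy).
`count_introgressed()` then counts focal-taxon sequences in a donor
haplogroup and reports the percentage to one decimal.

## The cytonuclear introgression model

The package's core model tracks exotic-gene frequencies at a paternal
haploid locus ($x$) and a biparental nuclear locus ($y$), separately in the
male and female adult pools, through discrete non-overlapping generations
(25 years per generation for calendar conversions).

**Pollen mode.** A fraction $p$ of seeds is sired by exotic pollen; mothers
are always local. Chloroplasts come from fathers, so
$x' = p + (1-p)x_M$ for both sexes, while
$y' = \tfrac12\left[y_F + p + (1-p)y_M\right]$. From an uninvaded
population one generation gives $L_{cp}/L_{nuc} = 2$ exactly, and the
closed forms $L_{cp}(t) = 1-(1-p)^t$, $L_{nuc}(t) = 1-(1-p/2)^t$ show that
pollen flow keeps chloroplast introgression ahead of nuclear introgression
forever. Observed levels with $L_{nuc} > L_{cp}$ are therefore
incompatible with pollen-only flow — `introgression_calibrate()` flags such
targets infeasible instead of fitting them.

**Seed mode.** A fraction $s$ of recruits are exotic seeds carrying exotic
states at both loci; local recruits have cp frequency $x_M$ and nuclear
frequency $(y_M+y_F)/2$. A sex-ratio-adjusting mechanism enters through
$\varphi_e$, the probability that an exotic-origin recruit is female
(local: $\varphi_l$, default 0.5); each sex pool is renormalised over its
own recruitment mass, e.g.
$x'_M = \frac{s(1-\varphi_e) + (1-s)(1-\varphi_l)\,x_M}
            {s(1-\varphi_e) + (1-s)(1-\varphi_l)}$.
With $\varphi_e = \varphi_l$ the two loci behave identically; with
$\varphi_e > \varphi_l$ exotic chloroplasts are under-represented in the
transmitting (male) pool and nuclear introgression overtakes chloroplast
introgression — the mechanism proposed for the observed ITS-over-cp excess.
Conditioning is on recruit origin (immigrant versus local), not on locus
ancestry; the alternative reading of the mechanism statements would tie sex
ratios to genotype and is noted here as not implemented. Population-level
levels weight the two adult sex pools equally,
$L = (\cdot_M + \cdot_F)/2$, the simplest convention consistent with an
equal adult sex ratio; weighting by sampled counts is not applied.

These recursions are the infinite-population limit of an explicit
individual-based dioecious simulation (`introgression_forward()`), which
serves as the internal arbiter of the reconstruction: the test suite checks
agreement within three Monte-Carlo standard errors on a 3×3 grid of rates
and sex-ratio parameters at $N = 2000$, $T = 50$, 50 replicates.
`introgression_calibrate()` performs a grid search on $(s, \varphi_e)$
against observed $(L_{cp}, L_{nuc})$ and is validated by parameter recovery
on self-generated targets within one grid cell.

## Migration likelihood-ratio test and unit conversions

Because zero migration lies on the boundary of the isolation-with-migration
parameter space, $-2\log\Lambda$ is referred to a 50:50 mixture of a point
mass at zero and $\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge x)$ and the
$\alpha$-level critical value is the $(1-2\alpha)$ quantile of $\chi^2_1$
(2.71 at $\alpha = 0.05$). The model's scaled estimates convert to
demographic units via a composite yearly mutation rate taken as the
geometric mean of the two locus rates ($1.67\times10^{-6}$ and
$1.24\times10^{-6}$ per locus per year — the convention of the IM software
family, flagged because the study does not restate it), a 25-year
generation time, $N_e = q/(4 u_{gen})$ and $T = t/u_{year}$. Whether $t$ is
scaled by the yearly or per-generation rate is likewise not restated; the
yearly rate is the default, consistent with reporting divergence times
directly in years, and `deconvert_im_estimates()` provides the exact
inverse so conversions round-trip. Inheritance scalars compose a ploidy
factor and a transmitting-sex factor: paternal haploid chloroplast
$\tfrac12 \times \tfrac12 = 0.25$, biparental diploid nuclear 1.

## Synthetic data: what it emulates and what it does not

Two generators are provided.

`simulate_genealogy()` / `sprinkle_mutations()` implement a backward-time
structured coalescent for the three-deme history ((TW, PH), MA) with
exponential waiting times, written in-repo so its expectations are
analytically checkable (pair coalescence time $2N_e$ scaled by the
inheritance scalar; pairwise diversity $4N_e\mu L$ — both verified by
Monte-Carlo tests). Defaults follow the study's modal estimates:
$N_e$ = 16,400 / 6,900 / 2,700 individuals, splits at 1.56 and 4.16 My with
a 25-year generation, population migration rates $2N_eM$ of 0.40 (MA→TW)
and 0.16 (TW→PH). The ancestral insular deme size is not estimated in the
study; it defaults to the Taiwanese size (the inferred source population).
Mutation is infinite-sites over a finite length (site exhaustion is an
error, not silent wrap-around) plus optional short indel events.

`make_fixture()` builds deterministic data sets from membership recipes:
haplogroup centres $2\times$`min_between` substitutions apart, within-group
haplotypes one private substitution from the centre, and exact per-group
copy counts (migrant memberships are injected, never sampled, so
classify-and-count results are exact). Packaged recipes replicate the
study's introgression counts — 16/282 and 2/141 in Taiwan, 19/76 and 2/38
in the Philippines — with the introgressed Taiwanese copies placed in the
largest site and the Philippine incursion copies at Mt. Apo, placements the
published counts do not constrain. Pairing of diploid copies into
individuals is random (Hardy-Weinberg by construction), sequential, or
deliberately heterozygote-excessive to emulate the one strongly
HWE-deviant population ($F_{IS} \approx -0.9$).

Neither generator emulates recombination, selection, substitution-model
heterogeneity, real per-population haplotype frequency spectra (not
printed in the study), or phase-calling error — ITS is emitted pre-phased.
Passing tests therefore demonstrate correctness of the estimators and of
the model algebra under the stated assumptions, not robustness to those
unmodelled features of real data.

## Numerical choices and limitations

* Exact enumeration of Hardy-Weinberg tables is capped at $10^5$ tables;
  beyond that the chain estimate is used and the method is reported.
* Table-probability comparisons use a $10^{-9}$ log-scale tolerance so
  ties in the conditional distribution are counted as "no more probable".
* AMOVA percent-of-variation always sums to 100 (to $10^{-9}$); indices
  whose denominators vanish (e.g. all sequences identical) are `NaN`, and a
  taxon containing a single population triggers a warning that the
  $\Phi_{CT}$ permutation scheme is weak rather than a silent result.
* The parsimony-probability formula is a package reconstruction (see
  above); analyses that must match a specific legacy tool should pass an
  explicit `limit`.
* `run_pipeline()` is deterministic given (config, seed): summaries are
  byte-identical across re-runs, and each report carries a config
  fingerprint. Stage timings are logged to the message stream only.
* The likelihood-ratio statistic is an input here: the package implements
  the boundary test and unit conversions, not the isolation-with-migration
  MCMC that produces $-2\log\Lambda$.
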