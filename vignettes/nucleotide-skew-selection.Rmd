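---
title: "Decomposing nucleotide skews into mutation and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing nucleotide skews into mutation and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the equilibrium
model, the estimators built on it, the two companion simulations, the
design of the synthetic-genome generator, and the numerical and design
choices made where several options were defensible.

## The model

We consider a single genomic site that holds one basepair and can be in two
orientations — A·T vs T·A, or G·C vs C·G — read on a designated strand.
Let $u$ be the mutation rate from the cheap to the expensive base on the
leading strand (C→G for the GC pair, T→A for the AT pair) and $v$ the
reverse rate, and let $s$ be the fitness advantage of the expensive base
(so $s < 0$ when the cheap base is favoured).  Prokaryotic mutation rates
are far below $1/N_e$, so at stationarity each site is essentially fixed
and toggles between the two states via fixation of new mutants.  Balancing
the two fixation fluxes gives the probability of the expensive state, and
hence the expected skew $\gamma$ (fraction expensive minus fraction cheap)
in a large pool of sites:

$$\gamma_{lead} = \frac{\kappa e^S - 1}{\kappa e^S + 1},
  \qquad
  \gamma_{lag} = \frac{e^S/\kappa - 1}{e^S/\kappa + 1},
  \qquad
  \kappa = \frac{v}{u} = \frac{1+\mu}{1-\mu},$$

with $S = 2 N_e s$ and $\mu = (v-u)/(v+u)$.  On the lagging strand the two
rates swap roles.  Only *ratios* of mutation rates enter; neither $N_e$ nor
the raw rates are identifiable, and the package reports only $S$ and $\mu$.
At $S = 0$ the skew reduces to $+\mu$ (leading) and $-\mu$ (lagging) — the
signature of replication alone.

Both strand equations can be inverted jointly and in closed form:

$$S = \tfrac12 \ln\frac{(1+\gamma_{lead})(1+\gamma_{lag})}
                        {(1-\gamma_{lead})(1-\gamma_{lag})},
  \qquad
  \kappa^2 = \frac{(1+\gamma_{lead})(1-\gamma_{lag})}
                  {(1-\gamma_{lead})(1+\gamma_{lag})}.$$

Equivalently $\gamma_{lead(lag)} = \tanh((S \pm \ln\kappa)/2)$, which makes
two antisymmetries obvious and they are enforced by property tests:
relabelling the basepair negates $\mu$, $S$ and the skew together, and
$\gamma_{lead}(\mu, S) = -\gamma_{lag}(\mu, -S)$.

### Site classes and the force ledger

* **Interoperonic** sites (outside every annotated gene, operon, tRNA and
  rRNA) feel replication only: their leading-orientation skew *is* the
  estimate $\hat\mu^{io}$.
* **Fourfold-synonymous (4s)** third codon positions feel replication —
  amplified in transcribed regions by a species-independent factor $\tau$,
  e.g. through replication–transcription collisions — plus selection on
  nucleotide synthesis cost, $S_{RNA}$.
* **Nonsynonymous (NS)** positions additionally feel selection on the cost
  of the encoded amino acid, $S_{AA}$; the two channels are independent and
  additive on the $2N_e s$ scale, $S = S_{RNA} + S_{AA}$.  A fraction
  $1 - f$ of NS sites is frozen by selection on protein function and
  contributes no skew, so the pooled observed NS skew is the model skew
  scaled by $f$; estimation rescales $\gamma_{NS} \to \gamma_{NS}/f$.
* Twofold (2s) and the isoleucine threefold (3s) positions are tallied but
  excluded from estimation: their substitutions are entangled with
  stop-codon adjacency and do not fit the clean two-state model.

### Cross-genome estimators

$\hat\tau$ is the least-squares slope through the origin of $\hat\mu^{4s}$
(from `invert_mu()` on 4s skews) on $\hat\mu^{io}$, fitted separately for
AT and GC pairs, with a normal-theory confidence interval on $n-1$ degrees
of freedom.  $\hat f$ minimises
$\sum_g [\hat\mu(\gamma^{NS}_{lead}/f, \gamma^{NS}_{lag}/f) - \hat\tau\,\hat\mu^{io}_g]^2$
over $f \in (0.01, 1]$ — unweighted least squares was chosen as the
agreement metric, with a bounded scalar minimiser at tolerance $10^{-6}$;
the confidence interval is a bootstrap over genomes (1000 resamples by
default) since no analytic form is available for a plug-in argmin.  Genomes
whose rescaled skew leaves the model domain ($|\gamma|/f \ge 1$) are
excluded from that candidate's objective and reported.  Per genome,
$S_{RNA}$ and $S_{total}$ then come from the single-strand inversion with
$\mu' = \hat\tau \hat\mu^{io}$, and $S_{AA} = S_{total} - S_{RNA}$; the
"mean" strand estimate is the arithmetic mean of the leading and lagging
estimates.  A per-genome mode replaces $\hat\tau\hat\mu^{io}$ with the
genome's own $\hat\mu^{4s}$, which keeps genomes statistically independent
for comparative analyses such as the lifestyle model.

## Genome conventions

Coordinates are 0-based half-open internally; GFF3 and the operon/origin
TSVs (1-based inclusive) are converted on read.  The chromosome is
circular; after rotating the replication origin to coordinate 0 the
terminus is taken to be antipodal at $L/2$, since inputs annotate no
terminus.  A gene is *leading* iff it is on the plus strand in the first
half or on the minus strand in the second half (midpoint rule for features
straddling a boundary — deterministic and affecting a negligible fraction
of genes).  Interoperonic gaps are computed on the circle (the gap spanning
the rotated end is merged before trimming), 60 bp abutting any feature's 5'
end are removed — promoters and 5' UTR-proximal signal are the motivation,
so gaps flanked only by 3' ends are untrimmed — and gaps shorter than
100 bp after trimming are discarded.  Surviving regions are split at the
half boundary and expressed in leading-strand orientation (second-half
regions reverse-complemented).  Multi-chromosome FASTA inputs use only the
largest record; duplicate origin entries use the first.

Coding sequences are taken on the sense strand; the annotated first codon
is always dropped (GTG/TTG alternative starts included) along with a
trailing stop, genes with non-triplet length or internal stops are skipped
with a warning, and codons containing ambiguity codes are skipped rather
than imputed.  Degeneracy classes are derived from the genetic code at
runtime and checked against a frozen packaged copy in the test suite.

## The two defining simulations

**No-selection null.**  Random "genomes" of i.i.d. non-stop codons with
equal A/T and equal G/C frequencies have zero skew by construction at every
basepair — except that excluding the three stop codons (TAA, TAG, TGA)
removes A- and G-rich triplets asymmetrically.  The residual class-specific
skews (medians ≈ 0.018 for NS AT, ≈ 0.081 for NS GC, ≈ 0 at 4s sites)
are the null expectations against which genomic skews must be judged.  The
defaults mirror the reference conditions (1200 genomes, GC equally spaced
on 20–80%, about $10^6$ codons each); the acceptance-scale runs use 240
genomes of $10^5$ codons, which the test suite shows is ample for the
medians (Monte-Carlo SE per genome ≈ 0.002).  An exact enumeration over
the 64-codon product distribution, conditioned on non-stop, serves as the
independent oracle at GC = 0.5.

**Codon-table cost trade-off.**  Random coding sequences with prescribed
GC content and skews are drawn from the maximum-entropy nucleotide model
$P(A) = (1-gc)(1+\gamma_{AT})/2$, etc. — the paper-level parameters fix
only the marginals, and the product form adds no further structure — with
stop codons rejected.  Mean amino-acid cost falls with GC and with skew
while mean nucleotide cost rises: cheap nucleotides encode expensive amino
acids.  One caveat found by exact enumeration and therefore asserted as
such in the tests: when *only* the GC skew is varied, the mean amino-acid
cost is not strictly monotone over skews $-0.8..+0.8$ — it has an interior
minimum near $+0.4$ at every GC level under the packaged amino-acid costs —
though the net trade-off (cost saving across the range, negative
association with nucleotide cost) remains.  The combined- and AT-only
grids are strictly monotone.

### Cost tables

Amino-acid costs ship as the published aerobic-respiration E. coli values
(high-energy phosphate bonds per molecule, de novo).  The nucleotide table
is a constructed, clearly-labelled synthetic stand-in
(`nt_costs_synthetic.tsv`): flux-balance recomputation is out of scope
here, and no table of the reference values was available to package, so the
shipped numbers were chosen once to satisfy every established ordering —
A>U, G>C, C>U, G>A, G+C>A+U — with a mean pairwise difference of a few ATP
units.  Every qualitative conclusion exercised by the tests depends only on
those orderings.  `load_costs()` accepts any conforming TSV, so
lifestyle-specific variants are drop-in replacements.

## The synthetic-genome generator

`generate_synthetic_genome()` is first-class, tested code: it emulates the
statistical structure the model assumes, with every parameter known, so the
whole pipeline (file I/O included, if routed through
`write_synthetic_genome()`) can be validated by parameter recovery.

Operons alternate between plus and minus strands within each replichore,
covering all four strand-by-half combinations; interoperonic gaps separate
them, drawn site-by-site from the equilibrium at $(\mu^{io}, S = 0)$ in
leading orientation.  Coding sequence is built from four codon templates in
balanced blocks of four codons:

| template | pos 1 | pos 2 | pos 3 |
|---|---|---|---|
| `xCz` | drawn NS | invariant C | drawn 4s |
| `G·z` | invariant G | drawn NS | drawn 4s, or invariant C when pos 2 = A |
| `A·z` | invariant A | drawn NS | drawn 4s when pos 2 = C, else invariant C |
| `T·z` | invariant T | drawn NS | drawn 4s when pos 2 = C, else invariant C |

The templates were chosen so that (i) every *drawn* position keeps the same
degeneracy class whatever letter it receives (the prefixes involved are the
fourfold families Thr/Ser/Pro/Ala, Gly/Val/Ala and friends, all verified
stable against the code); (ii) no invariant letter ever lands in a 4s
class — the conditional third-position rules park them in 2s/3s classes,
which estimation ignores; and (iii) the invariant letters that do land in
the NS class arrive in exactly balanced sets {A, T, G, C} per block,
contributing denominators but zero skew.  Those balanced invariants play
the role of part of the functionally frozen $1-f$ fraction.  Writing $a$
for the probability that a drawn site is an AT (rather than GC) pair, a
block contributes $4a$ drawn and 2 invariant AT-pair NS sites, so the
free-draw probability within drawn NS sites is rescaled to
$f' = f\,(4a + 2)/(4a)$ per pair, making the pooled NS skew equal
$f \times$ model skew exactly in expectation.  This requires
$f \le 2a/(2a+1)$ (0.5 at the default $a = 0.5$); the constructor rejects
inconsistent combinations.  4s draws follow
$(\tau\mu^{io}, S_{RNA})$ and free NS draws $(\tau\mu^{io}, S_{RNA}+S_{AA})$
with the strand-appropriate branch.  Genes get an ATG start and TAA stop
(removed again by the classifier) and can contain no in-frame stop by
construction.

Defaults are the validation study conditions: $\mu^{io} = 0.05$,
$\tau = 1.5$, $S_{RNA} = -0.3$, $S_{AA} = +0.8$, $f = 0.35$ for both pairs,
40 single-gene operons of 5000 codons and 2700-bp gaps, giving roughly
$10^5$ sites in each of the interoperonic, 4s and NS classes per genome.
At these sizes the acceptance suite recovers $\tau$ within ±0.1, $f$ within
±0.05, per-genome $\mu$ within ±0.01 and the selection coefficients within
±0.1 with correct signs in >95% of 100 genomes, in about two minutes of
computation.

What the generator does *not* emulate — and hence what passing recovery
tests cannot show about real data: linkage and codon-usage correlations
along genes, heterogeneous gene lengths and operon structure, expression-
dependent $S$, context-dependent mutation, non-equilibrium demography, and
annotation error.  It validates the estimators under the model's own
assumptions, no more.

## Expression and codon-usage components

The tRNA adaptation index follows the reference formulation: per codon,
absolute adaptiveness $W = \sum_j (1-s_j) t_j$ over the Watson–Crick and
wobble-pairing anticodons with the standard constraint vector
(configurable; the prokaryote-specific lysidine reading of AUA by the CAU
anticodon is included), relative $w = W/\max W$, zero values replaced by
the geometric mean of the non-zero ones, and the gene score is the
*geometric* mean of $w$ over codons — the reference implementation's
definition, preferred over a literal arithmetic reading of "average".
Genes are ranked per replication strand and split into five equal bins
(ties broken by stable order) with pooled per-bin skews, GC and mean
amino-acid cost.

Codon bias uses Wright's original effective number of codons (the
background-corrected ENCprime variant is deliberately not reimplemented;
the downstream logic is unchanged), with the isoleucine family in the
$\bar F_3$ term, the usual fallbacks for missing size classes, and
clamping to [20, 61].  Preferred codons are detected per fourfold family as
the strongest significantly negative Spearman correlation between
within-family codon frequency and Nc across genes, at a per-family
Bonferroni threshold $0.05/4$; p-values use the standard t approximation of
the Spearman statistic (adequate at the gene counts involved, and two
orders of magnitude faster than exact enumeration, which matters for the
1000-replicate null calibration in the test suite).  Under a null with no
usage–Nc association the realised family-wise false-positive rate is below
0.05.  The genome-level T-over-A and C-over-G ending preferences are 2×2
Fisher tests.

## Phylogenetic statistics

Independent contrasts are computed by the standard pruning algorithm (via
`ape::pic`, checked in the tests against a brute-force GLS computation on
small trees); trees are expected ultrametric to $10^{-6}$.  Correlations
on contrasts are through the origin with a $t$ test on $n-1$ degrees of
freedom, since contrasts have arbitrary sign.  The lifestyle analysis fits
`S ~ 0 + INTRA * GC * L` on contrasts and removes the least significant
term whose removal respects marginality until all remaining terms are
significant at 0.05; the AIC trace is recorded so the expected monotone
decrease can be verified rather than imposed — gating on AIC can strand
the elimination at a chance-significant interaction, which is why
significance is the operative criterion.

## Numerical and degenerate-input policy

Skews with zero denominators are flagged-undefined (`NA`), never silently
zero; boundary skews ($|\gamma| = 1$) are flagged and poison the affected
genome/pair's global-fit contribution rather than the whole fit.  The f
optimiser's domain guard excludes genomes per candidate value.  Rejection
sampling of codons re-draws in batches and aborts after 50 rounds rather
than looping on pathological frequency vectors.  All randomness flows from
a single user-supplied seed.
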