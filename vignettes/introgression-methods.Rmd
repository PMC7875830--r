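---
title: "Detecting interspecies introgression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interspecies introgression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introkit)
```

## The problem

Two stickleback species from different genera — the three-spined
(*Gasterosteus aculeatus*) and the nine-spined (*Pungitius pungitius*)
stickleback — live side by side in brackish and freshwater habitats of the
White Sea basin. Occasional hybridization followed by backcrossing can move
small blocks of one species' genome into the other (introgression). Finding
such traces in reduced-representation (RAD-seq) genotype data requires a
battery of complementary analyses, each with its own failure modes:
distance-based clustering to confirm the species split, a Bayesian
admixture model to quantify per-individual ancestry fractions, an
outgroup-polarized four-taxon D-statistic to test for excess derived-allele
sharing, an alignment mismatch-rate check to rule out library
contamination, and — for cheap follow-up screening — PCR markers placed on
transposable elements (TEs) present in one species but not the other.

`introkit` implements this battery as reusable, tested R functions, and —
because the interesting claims are statistical — ships a synthetic-data
generator with known truth so that every stage can be validated end to end
without any external download.

## The synthetic study design

`sim_config()` encodes the generative model all tests run against:

* Ancestral derived-allele frequencies $p_\ell \sim \mathrm{Beta}(a, b)$
  (default $a=b=1$) at $L$ biallelic loci (default $10^4$, matching the
  scale of a RAD-seq SNP panel) laid out on 21 chromosomes, the
  three-spined stickleback karyotype.
* Each species' frequency drifts from the ancestor under the
  Balding–Nichols model,
  $f_{s\ell} \sim \mathrm{Beta}\!\big(p_\ell \tfrac{1-F_s}{F_s},
  (1-p_\ell)\tfrac{1-F_s}{F_s}\big)$, so $E[f] = p$ and
  $\mathrm{Var}(f) = F\,p(1-p)$.
* Diploid dosages are Binomial(2, species frequency); the single outgroup
  individual is fixed for the ancestral allele at every site, mirroring
  polarization against a distant reference genome.
* One focal individual of the recipient species carries introgression: at
  a Bernoulli($\alpha$) subset of loci its genotype is drawn from the
  *donor* species' frequency. The realized per-locus mask is the truth
  record, and its mean is the realized ancestry fraction $q_{\text{true}}$.
  An optional tract mode lays the mask down in contiguous runs instead,
  which makes block-jackknife correlation structure realistic.

Default sample sizes are three donor-species individuals, five
recipient-species individuals and one outgroup — the sample layout of the
motivating field study.

**Choice of drift parameters.** The default $F_A = F_B = 0.6$ deserves a
note. The two species are distinct *genera*; empirically, cross-genus read
mapping rates drop by a third relative to within-genus mapping, and most
loci approach complete lineage sorting. A power analysis of the four-taxon
test under this design (a single diploid test individual, $10^4$ sites)
shows that the binomial sampling noise of two allele copies dominates the
jackknife standard error, and the expected Z at $\alpha = 0.05$ scales
roughly linearly with $F$: at $F = 0.2$ the expected Z is below 1 and the
test would be hopeless even with perfect estimation, whereas at $F = 0.6$
the expected Z is $\approx 3.7$, comparable to the sort of signal a real
intergeneric study reports. High drift is both the realistic regime for
this species pair and the regime in which the method is informative. Both
parameters remain exposed.

What the generator does **not** emulate: linkage within loci, RAD locus
dropout and allele-specific bias, coalescent variance along chromosomes,
sequencing-quality artifacts beyond i.i.d. substitutions. Tests passing on
this generator therefore validate the *statistical machinery* (estimators,
their calibration, bookkeeping), not robustness to every real-data
pathology.

## Genotype I/O and the three locus filters

`read_vcf()` parses unphased diploid GT fields to alt-allele dosages
(0/1/2, `NA` for `./.`), keeping QUAL and full allele lists. Three filters
mirror standard practice for this kind of analysis:

* `filter_biallelic()` — drops records with more than one ALT allele
  (downstream containers and statistics assume two alleles);
* `filter_quality(min_qual = 500)` — keeps loci with QUAL **strictly**
  greater than the threshold ("more than 500"); loci with missing QUAL are
  dropped;
* `drop_invariant()` — removes loci whose non-missing dosages are
  identical across samples. Evaluating the rule over non-missing calls
  only is the one well-defined extension to missing data.

Each filter logs (input, output, removed) counts; `write_filter_report()`
emits the audit table. VCF coordinates are 1-based inclusive; all TE/gap
intervals elsewhere in the package are 0-based half-open. Multiallelic
records survive a write/read round trip because raw GT strings are carried
alongside dosages.

## Distances and neighbor joining

`euclidean_distances()` uses raw 0/1/2 dosages without standardization —
the plain "Euclidean distance between genotypes" — with pairwise-complete
handling of missing data: the squared-difference sum over jointly observed
loci is rescaled by $L / L_{\text{complete}}(i,j)$ (this is `stats::dist`'s
convention; a `complete`-cases mode is available). A sample pair sharing no
observed locus is an error, named explicitly.

`neighbor_joining()` is Saitou–Nei NJ (via `ape::nj`, the standard
implementation, which is deterministic and consistent on additive
matrices), followed by one numerical repair: NJ can emit slightly negative
branch lengths on noisy input, and these are clamped to zero with the
deficit transferred to the adjacent branch so path lengths are preserved as
far as possible. On additive input the output reproduces the generating
metric exactly, which is what the tests assert (cophenetic equality to
1e-9, 100/100 topology recovery on random 8-taxon additive matrices).

Newick output quotes labels containing whitespace or metacharacters;
3-taxon trees serialize with the conventional unrooted trifurcation.

## The admixture model

`run_admixture()` implements the admixture-ancestry mixture model with
correlated allele frequencies. Each of individual $i$'s allele copies
originates from one of $K$ clusters with probabilities
$q_i = (q_{i1},\dots,q_{iK})$; a copy from cluster $k$ at locus $\ell$ is
the derived allele with probability $f_{k\ell}$. In the correlated
("F-model") variant the cluster frequencies are tied to a shared ancestral
frequency:
$f_{k\ell} \sim \mathrm{Beta}\!\big(p_{A\ell}\tfrac{1-F_k}{F_k},
(1-p_{A\ell})\tfrac{1-F_k}{F_k}\big)$, with $p_{A\ell}$ uniform and
$F_k \sim \mathrm{Gamma}(2, 0.05)$ a priori. Ancestry rows have a
symmetric Dirichlet($\alpha$) prior, with $\alpha$ either fixed or given a
uniform prior on $(0, 10]$.

Inference is MCMC with one sweep per iteration:

1. every allele copy's origin is resampled,
   $P(z = k) \propto q_{ik} f_{k\ell}$ (derived copies) or
   $q_{ik}(1 - f_{k\ell})$ (ancestral copies), vectorized over all
   (sample, locus) cells;
2. cluster frequencies are updated from their **exact Beta full
   conditionals** — the F-model prior is conjugate to the binomial copy
   counts given $(p_A, F_k)$, so a Gibbs draw replaces a random-walk step
   here; this improves mixing and leaves the stationary distribution
   unchanged;
3. $p_{A\ell}$ (reflected Gaussian proposal) and each $F_k$ (Gaussian
   proposal) are Metropolis–Hastings updates, with step sizes adapted to a
   20–50% acceptance rate during burn-in only;
4. $Q_i \sim \mathrm{Dirichlet}(\alpha + n_{i1}, \dots, \alpha + n_{iK})$;
5. optionally, a Gaussian-step MH update of $\alpha$ (step 0.05).

Missing genotypes contribute no allele copies. Label switching is resolved
per kept sweep by matching cluster-frequency vectors to a running
reference (all $K!$ permutations for $K \le 5$, greedy beyond). The
reported summaries are the posterior mean ancestry matrix and the 90%
equal-tailed (5th–95th percentile) interval per cell; a multi-chain mode
reruns from independent seeds and reports the maximum disagreement in
posterior means as the convergence diagnostic. Defaults are 10,000 burn-in
plus 20,000 kept sweeps — full-analysis settings; the test-suite and the
scaled recovery study below use shorter chains.

**Fixed vs inferred $\alpha$.** For *parameter-recovery simulations* the
package fixes $\alpha = 1$: the generator assigns the focal individual's
ancestry as a fixed fraction, not as a draw from a hierarchical Dirichlet,
and with seven unadmixed individuals the inferred concentration collapses
toward zero and shrinks the one admixed individual's estimate with it.
For exploratory data analysis the inferred-$\alpha$ default of the
original tool is retained.

**A known, measured limitation.** With only four control individuals
anchoring the recipient cluster, the posterior can legitimately explain a
small number of donor alleles in the focal individual as rare
within-cluster variants. Two consequences, both quantified by the
package's own acceptance checks at $q_{\text{true}} = 0.1$, 1,000 loci and
500-sweep chains: the posterior mean is biased downward by roughly 0.02–0.03
(the mean absolute error stays within 0.05), and the 90% intervals —
further narrowed because introgression arrives in two-copy (whole-locus)
units while the likelihood treats copies as independent — cover the truth
in only about half to two-thirds of replicates rather than ~90%. Very long
chains from independent seeds agree to three decimals on such datasets, so
this is a property of the model under this design, not of the sampler.
Practically: treat small admixture fractions from this model as
qualitative evidence (admixed vs not) rather than calibrated estimates,
and corroborate with the D-statistic.

## The four-taxon D-statistic

Sites are polarized against the outgroup: the ancestral allele is the one
the outgroup carries (either a genotyped outgroup sample — sites where it
is heterozygous, polymorphic or missing are dropped — or the reference
allele of the assembly, for data called against a distant reference).
Derived-allele frequencies $p_1, p_2, p_3$ are then computed for the three
ingroup populations of the ordered quadruple (Outgroup, P1, P2, Test),
sites with missing calls in any involved sample or with no derived
variation are dropped, and retained sites are cut into contiguous
equal-count blocks (default 50).

The per-site weights are

$$\text{abba}_s = p_1 (1 - p_2)\, p_3, \qquad
  \text{baba}_s = p_1\, p_2\, (1 - p_3),$$

and $D = \frac{\sum(\text{abba}_s - \text{baba}_s)}
{\sum(\text{abba}_s + \text{baba}_s)}$. This is the frequency-weighted
estimator for the quadruple *in the order given*: with the outgroup fixed
ancestral the numerator reduces to $\sum p_1 (p_3 - p_2)$, i.e. a contrast
of the Test sample's derived-allele sharing with P1 against the control
P2's sharing with P1. The design matters: in this study P2 and Test are
conspecifics (sister samples relative to the distant P1), so the two
weights are the two *discordant* site patterns of the true topology, their
expectations are equal under incomplete lineage sorting alone, and $D$ has
mean zero without gene flow — exactly the exchangeability the null
calibration tests exploit. Positive $D$ means the Test individual shares
excess derived alleles with P1. The alternative pairing of patterns
(contrasting P1-vs-P2 sharing of the Test allele) is *not* mean-zero here,
because P2 and Test share drift that P1 does not; with single-individual
haploid-coded populations the implemented weights reduce to literal
ABBA/BABA pattern counts, which is what the exhaustive-enumeration oracle
asserts. One consequence of the chosen orientation: $D$ is antisymmetric
under swapping P2 with Test (not P1 with P2).

Uncertainty comes from a delete-one-block jackknife over the contiguous
blocks, $\mathrm{SE}^2 = \frac{m-1}{m}\sum_j (D_{(-j)} - \bar D)^2$ with
blocks carrying zero weight skipped, and $Z = D/\mathrm{SE}$. Equal-count
contiguous blocks (default 50) stand in for the LD-aware blocking a
chromosome-scale analysis would use; the count is exposed. Under the null
the package's checks require $|Z| > 3$ in at most 2% of replicates and a
Kolmogorov–Smirnov test cannot distinguish $Z$ from standard normal at the
1% level.

## The contamination check

For each library, the error rate is the ratio of substitution mismatches
to mapped bases: per primary mapped read, NM minus inserted and deleted
bases (so that only substitutions remain, as in `samtools stats`), summed
and divided by the summed M/=/X CIGAR lengths. MD tags are a fallback when
NM is absent; unmapped, secondary, supplementary and duplicate records are
skipped. Cross-sample comparison assigns each library a robust z-score
against the cohort median/MAD and flags rates above median + 5 MAD (a
zero-MAD cohort falls back to flagging anything above twice the median).
The scientific point the simulation reproduces: a genuinely admixed sample
has a *normal* mismatch rate, while a contaminated library — simulated by
spiking 10% of reads from a reference diverged by 5% — stands out, because
contamination inflates mismatches additively
($\approx 0.01 + 0.1 \times 0.05$ at a 1% base error rate).

## TE diagnostic markers

Given a TE consensus and the per-base depth of the *non-target* species'
reads mapped to it, `coverage_gaps()` extracts maximal runs of depth
$\le$ `max_depth` (default 0) of length $\ge$ 250 bp, and
`design_primers()` enumerates primer pairs whose amplicon lies entirely
inside a gap with product length in [200, 500] bp — fragments only the
target species can amplify. Candidate primers must satisfy: length
18–25 nt, GC fraction 0.35–0.65, nearest-neighbor Tm in [51, 66] °C
(SantaLucia unified parameters, 50 mM Na⁺, 25 nM strands; a Wallace-rule
option exists), no homopolymer run of 5+, pairwise |ΔTm| ≤ 3.5 °C; a
3'-G/C clamp is available but off by default. These windows were
calibrated once against the shipped reference panel of 24 published
stickleback TE primers (`inst/extdata/te_primer_panel.tsv`), which spans
lengths 20–23 nt, GC 0.435–0.60, Tm 52.0–59.1 °C and contains pairs with
|ΔTm| up to 3.4 °C and several 3' A/T ends — the constraint check on that
panel is a standing regression test. Ranking is by a transparent score
(|ΔTm|, GC deviation from 0.5, product-length deviation from the window
midpoint), ties broken by coordinates, so output is deterministic.

`screen_primers_in_silico()` dry-runs the PCR: both primers must match in
the correct orientation within a product-length window, allowing up to 2
mismatches each but requiring the 3 terminal bases at the 3' end to match
exactly (a mismatch at the extension end kills amplification). The
end-to-end property — primers found in a planted coverage gap amplify a
TE-bearing sequence and fail on a gap-deleted one — is asserted in the
acceptance suite.

## Numerical and degenerate-input choices

* Beta draws and proposals are clipped to $[10^{-9}, 1-10^{-9}]$; MH
  log-ratios that are not finite are treated as rejections.
* Drift proposals are confined to $(10^{-4}, 1-10^{-4})$ — Beta shape
  parameters explode at the boundary.
* `filter_quality` with every QUAL missing empties the matrix with a
  warning rather than erroring; a zero-record VCF round-trips as a
  header-only file.
* D is an error when no site carries weight; the jackknife requires at
  least two informative blocks, and reports SE = 0 with an infinite,
  flagged Z when all leave-one-out estimates coincide.
* All simulation entry points take a single integer seed and are
  bit-reproducible; the pipeline derives per-stage seeds from its global
  seed, so reruns are byte-identical.

## Problem sizes used by the test and acceptance suites

Chosen to exercise each property at the smallest scale where it is
decisive: D-statistic calibration and power use the full $10^4$-SNP panel
(200 null replicates, 50 per introgression level, 50 jackknife blocks);
the admixture recovery study uses 1,000 loci with 500 burn-in plus 500
kept sweeps, 50 replicates; NJ consistency uses 100 random 8-taxon
additive matrices; oracle-equivalence checks run on ≤20-site toys where
exhaustive enumeration is exact. The full-length 10k + 20k MCMC default is
reserved for real analyses.

## Limitations

* The admixture model's interval calibration for small fractions under
  few reference individuals is the measured limitation described above.
* Equal-count jackknife blocks understate SE if introgression is strongly
  tract-clustered at scales larger than a block; the tract-mode generator
  exists precisely to explore this.
* The primer designer scores thermodynamics only at the level of Tm, GC
  and homopolymers; it does not model dimers, hairpins or multiplexing.
* No genotype-likelihood handling, imputation or phasing; the D-statistic
  uses complete cases per trio.
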