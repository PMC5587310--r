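---
title: "X-linked penetrance models for case-parent triads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{X-linked penetrance models for case-parent triads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtriad)
```

## The scientific setting

Case-parent triads — an affected child plus both parents — support
association inference through transmission distortion: if a variant raises
disease risk, heterozygous parents of affected children transmit it more
often than chance. Because the comparison is within families, allele
frequency differences between unrecognised subpopulations cannot create
spurious signal, which makes the design attractive for traits collected
across heterogeneous populations.

On the X chromosome the design needs special care. Boys are hemizygous
(one maternal X), girls carry two copies of which one is largely silenced
by X-inactivation, and for sexually dimorphic traits the baseline risk
itself differs by sex. `xtriad` makes these choices explicit instead of
borrowing autosomal machinery.

## The penetrance model

A window of 1–4 contiguous SNPs defines $H = 2^{\ell}$ haplotypes with
frequencies $p_h$ (assumed equal in eggs and sperm, random mating) and
single-dose relative risks $r_h$ in girls, with the reference haplotype
fixed at $r = 1$. A phased explanation of a triad is the triple
$(t, u, f)$: maternal transmitted, maternal untransmitted and paternal
haplotype. A boy's X genotype is $t$; a girl's is $\{t, f\}$.

The dose-response in girls is multiplicative: two copies of haplotype $h$
multiply risk by $r_h^2$. Conditioning on an affected child of known sex
gives the cell probabilities

$$
P(t,u,f \mid \text{affected girl}) =
  \frac{p_t\, p_u\, p_f\, r_t\, r_f}{\left(\sum_h p_h r_h\right)^2},
\qquad
P(t,u,f \mid \text{affected boy}) =
  \frac{p_t\, p_u\, p_f\, r^{(m)}_t}{\sum_h p_h r^{(m)}_h},
$$

where the boy coupling $r^{(m)}$ is the modelling choice: under
X-inactivation $r^{(m)}_h = r_h^2$ (a hemizygous boy is like a
double-dose girl, since each of her cells expresses only one copy);
without X-inactivation $r^{(m)}_h = r_h$ (dosage matters; one copy is one
dose). The `males_only` and `females_only` variants fit one sex alone, in
which case the fitted $r$ is that sex's own single-dose risk.

Two consequences are worth noting. First, sex-specific baseline
prevalences cancel: the normalising constants absorb them within sex, so
case-only triads carry no information about baselines and none are
estimated. Second, the couplings are falsifiable: fitting both and
comparing the implied boy risks against a separate male-only fit shows
which coupling the data prefer, and a boy estimate that falls between the
two implied values indicates partial (e.g. escape from) X-inactivation.

## Estimation

**Configurations.** For each family, all $(t,u,f)$ triples compatible with
the observed genotypes are enumerated: the mother's unordered pair must
equal $\{t, u\}$, the father's allele must equal $f$, a boy's allele must
equal $t$ and a girl's pair $\{t, f\}$, at every *observed* marker; a
missing call imposes no constraint. An empty set is a Mendelian
inconsistency and the family is excluded for that window (counted in the
output). Families with identical genotype patterns are grouped and
weighted, which makes chromosome-wide scans fast. A per-family cap
(default 65,536 configurations) guards against pathological missingness.

**Null model (EM).** With all $r \equiv 1$ the complete-data likelihood
is multinomial in haplotype counts, so EM has a closed-form M-step: the
E-step weights each configuration by $p_t p_u p_f$ normalised within
family; the M-step divides expected haplotype counts (three slots per
family) by $3n$. The likelihood is non-decreasing by construction;
iteration stops when the gain drops below $10^{-8}$ or after 1000
iterations, returning a convergence flag rather than an error.

**Pruning.** Haplotypes with null-fitted frequency below `min_freq`
(default 0.01, mirroring the MAF floor used in data cleaning) are removed
before the risk fit: with $2^4 = 16$ haplotypes in 4-SNP windows, rare
haplotypes otherwise produce flat likelihood directions and unstable
intervals. Frequencies are renormalised, configurations referencing pruned
haplotypes are deleted, and stranded families are excluded and counted. A
window keeping fewer than two haplotypes is reported "uninformative" with
a missing p-value. After pruning, the null EM is re-run on the pruned
configuration set so that the null and full fits are nested on *identical*
data — this guarantees a non-negative LRT statistic.

**Full model.** Frequencies are softmax-transformed (first haplotype as
anchor) and risks log-transformed (reference fixed at 0), and the
observed-data log-likelihood is maximised by BFGS from the null solution
(relative tolerance $10^{-14}$). Standard errors come from the inverse of
the numerically differentiated observed information at the optimum; 95%
Wald intervals on $\log r$ are exponentiated, and the double-dose interval
uses $2 \log r \pm 1.96 \cdot 2\,\mathrm{se}$. A singular information
matrix yields missing intervals with a flag, not a failure. Separation (a
haplotype never or always transmitted) is detected as $|\log \hat r| > 15$
and handled by refitting with that bound active and flagging the boundary.

**Testing.** Each window carries one overall LRT, all $r$ free against all
$r = 1$, on $H_{\text{kept}} - 1$ degrees of freedom, with a chi-square
upper-tail p-value. Per-haplotype inference is Wald. The scan ranks
windows by the overall LRT — a single p-value per window matches how
chromosome-wide results are displayed and FDR-corrected; the per-haplotype
intervals remain available for interpreting which haplotype drives a hit.

**Reference haplotype.** Chosen as the most frequent under the null fit,
ties broken by lexicographically smallest label. The choice is a
reparameterisation: switching the reference inverts the relative risks
($r \to 1/r$) and leaves the LRT unchanged, which the test suite asserts.
An explicit `reference` argument overrides the default — useful when a
specific allele is the natural baseline.

A subtlety of the retrospective likelihood is worth recording: for
complete single-SNP data in a sex-stratified fit, the intuitive estimator
is the transmission ratio $T/U$ from heterozygous mothers (the conditional
transmission odds are exactly $r$). The joint MLE, however, also draws
information about $p$ — and hence indirectly $r$ — from the case-enriched
parental genotype distribution, and equals $T/U$ only when that nuisance
information is balanced (for boys, fathers carrying the variant as often
as it was transmitted; for girls, as often as it was *untransmitted*,
because the paternal allele itself contributes a risk dose to an affected
girl). The oracle fixtures in the test suite are constructed this way.

## Multiple testing

Scans replace p-values by Benjamini–Hochberg step-up q-values,
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, computed within one scan (one
model, one sex selection, one window length) over its successful windows;
failed windows are excluded from $m$. Significance is conventionally
declared at $q \le 0.1$, i.e. an expected 10% of declared hits are false.
Only the classical BH construction is implemented; estimators of the null
proportion $\pi_0$ (Storey-type) would sharpen q-values slightly but add a
tuning parameter, and are deliberately left out.

## The simulator

`simulate_triads()` draws each family's phased configuration *directly*
from the normalised case-triad distribution above — for case-only data
this is mathematically identical to prospective simulation with
ascertainment rejection, and orders of magnitude faster. Child sex is
Bernoulli (default 0.5), genotypes are then unphased (mothers and girls
reported as unordered pairs) and masked at a per-call missing rate.
`simulate_snp_panel()` extends this to many markers by drawing each
family's sex once and each SNP independently — i.e. linkage equilibrium.

What the generator emulates: the exact conditional genotype distribution
of ascertained triads, sex-dependent child genotypes, hemizygous fathers
and boys, missing calls, and configurable frequencies, risks and sample
sizes. What it does not: linkage disequilibrium between markers (real
windows are correlated; planted-effect localisation is therefore cleaner
in simulation than in practice), genotyping error, Mendelian
inconsistencies from sample swaps, and population structure. Passing tests
demonstrate correctness of the estimator under the model, not robustness
to these artefacts — which is why the QC filters exist upstream.

## Power studies

`estimate_power()` simulates replicate datasets, fits the matching model
and reports the fraction of window LRT p-values below $\alpha$ (default
0.05), with the binomial Monte-Carlo standard error. For the
sex-stratified models the sample size is halved and only the analysed sex
simulated, reflecting a design in which roughly half the ascertained cases
are of each sex; the default reference design uses 600 combined-sex triads
(300 for a stratified analysis), a single SNP with MAF 0.2, and 1000
replicates. `power_grid()` evaluates the Cartesian product of relative
risks, MAFs, sample sizes and models, with one derived seed per cell so
grids are reproducible and cells independent.

The package's own validation runs use reduced problem sizes chosen to keep
the full suite comfortably interactive: 400 replicates for type-I error
calibration, 500 for bias and coverage of the Wald intervals
(600 triads each), 20 replicate null scans of 200 single-SNP windows at
300 triads for FDR behaviour, and 100 replicates per cell for power
monotonicity. At these sizes the Monte-Carlo standard errors are small
relative to the tolerances asserted.

## Degenerate inputs and numerical conventions

- Monomorphic markers cannot define two haplotype labels and are rejected
  at window construction; the MAF filter removes them in normal use.
- Male genotypes supplied as two distinct alleles are impossible on X;
  they are set to missing with a counted warning rather than aborting,
  since arrays do emit such calls and the EM machinery already handles
  missingness.
- A dataset carrying only one haplotype estimates its frequency as 1 and
  is then caught by the uninformative-window rule.
- Chromosome labels "X" and "23" are accepted as equivalent; the missing
  allele code is "0"; positions are 1-based base pairs reported as-is.
- All tolerances (EM gain $10^{-8}$, optimiser relative tolerance
  $10^{-14}$, separation bound $e^{\pm 15}$, LRT non-negativity slack
  $10^{-8}$) are fixed constants, not user-tunable state.

## Known limitations

The likelihood covers case-parent triads only: control-triad hybrids,
maternal-effect and parent-of-origin terms, and Hardy–Weinberg departure
parameters are out of scope. Confidence intervals are Wald-type on the log
scale; profile-likelihood intervals would behave better at extreme
frequencies but are not provided. Haplotype frequency estimation uses all
three family members jointly through the triad likelihood. Windows are
fixed-length per scan; mixed-length scanning is a loop over scans, each
with its own FDR correction.
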