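---
title: "Animal models for communal-nesting colony data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Animal models for communal-nesting colony data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestQG)
```

## The problem

Estimating the heritability of morphological traits in a wild bird colony
requires two things that field data rarely provide directly: a reliable
pedigree and a variance decomposition that separates additive genetic
variance from the environmental similarity of nest mates. In a
communal-nesting parrot colony, broods share a chamber inside a large
stick nest, extra-pair paternity (EPP) is common (around 40% of breeding
chambers in the population this package targets), and a few percent of
eggs are laid in foreign chambers. Social parentage is therefore an
unreliable guide to genetic parentage, and the pedigree must be
reconstructed from codominant microsatellite genotypes before any
quantitative-genetic model is fitted.

`nestQG` implements that full chain: locus diagnostics and null-allele
adjustment, likelihood-based parentage and full-sib partitioning, the
additive (numerator) relationship matrix **A**, Bayesian "animal models"
fitted by Gibbs sampling, genetic correlations from bivariate fits, DIC
selection among random-effect structures, and a synthetic colony
simulator that makes every stage testable against known truth.

## The model

The univariate animal model is

$$ y = X\beta + Z_a a + Z_m m + Z_n n + e $$

with $a \sim N(0, A\,\sigma^2_A)$ (breeding values, covariance
proportional to pedigree relatedness), $m \sim N(0, I\,\sigma^2_M)$ a
maternal-identity effect, $n \sim N(0, I\,\sigma^2_N)$ a nest effect and
$e \sim N(0, I\,\sigma^2_E)$. Reported ratios are
$h^2 = \sigma^2_A/\sigma^2_P$, $me^2 = \sigma^2_M/\sigma^2_P$,
$ne^2 = \sigma^2_N/\sigma^2_P$ with
$\sigma^2_P = \sigma^2_A + \sigma^2_M + \sigma^2_N + \sigma^2_E$,
computed per MCMC sample so each ratio has a full posterior.

The sampler is a blocked Gibbs scheme: all location effects are drawn
jointly from their multivariate-normal full conditional (the mixed-model
equations with $A^{-1}$), each variance from its scaled-inverse-chi-square
full conditional with prior $(\nu, V)$ — equivalent to an
inverse-gamma$(\nu/2, \nu V/2)$ — and, in bivariate models, each 2×2
covariance block from an inverse-Wishart full conditional with prior
IW$(\nu, \nu V)$. Fixed effects carry an improper flat prior. Defaults
mirror common practice for this study design: $V = 0.05\,\mathrm{var}(y)$
and $\nu = 1$ per variance term (univariate), $V = \mathrm{diag}(2)$ and
$\nu = 1.002$ (bivariate).

Two exact computational shortcuts keep fits fast without changing the
posterior:

* Unphenotyped pedigree members are dropped from the location vector.
  Their breeding values only enter the model through the prior, so the
  phenotyped subvector has the exact marginal prior
  $N(0, \sigma^2_A\,A_{obs})$ with $A_{obs}$ the corresponding submatrix
  of A.
* When the only random term is the additive one and each individual has a
  single record, the data are rotated by the eigenvectors of $A_{obs}$.
  In that basis the breeding values are independent
  ($\tilde a_i \sim N(0, d_i \sigma^2_A)$) and one iteration costs
  $O(n)$ instead of a dense factorization. Long-chain comparisons against
  the dense sampler agree to within Monte-Carlo error.

### Posterior summaries

"Posterior mode" is the argmax of a Gaussian kernel density estimate
(Silverman's rule-of-thumb bandwidth on a 512-point grid spanning the
sample range); credible intervals are highest-posterior-density intervals
(narrowest contiguous window of sorted samples). Both follow the common
reporting convention for these models. A genetic correlation is flagged
significant when its 95% HPD interval excludes zero.

### Schedules

`model_schedule("paper")` reproduces the reference run lengths
(univariate: 10^6 iterations, burn-in 10^5, thinning 100, i.e. 9,000
retained samples; bivariate: 4×10^6 / 4×10^5 / 1000 = 3,600 samples).
`"fast"` (15,000 / 5,000 / 10) is the default for interactive use; the
test suite uses a further-scaled 6,000 / 2,000 / 4 so that eighty
parameter-recovery fits stay within a desk-scale budget. Pilot runs showed
the same coverage behaviour at the longer schedules.

## DIC and the choice of likelihood focus

Random-effect structures (additive; +maternal; +nest; +both) are compared
by DIC with the retention rule ΔDIC < 7. DIC in hierarchical models
depends on the likelihood "focus", and the choice matters more than is
usually acknowledged. With the *conditional* (lowest-level) focus
$D(\theta) = -2\log N(y \mid X\beta + Zu, \sigma^2_E I)$, the additive
term — which carries one effect per individual — can absorb any
brood-level variance into individual breeding values, driving the
conditional deviance down regardless of what generated the data. In our
simulations the conditional-focus DIC preferred the additive-only model
even when 50% of the phenotypic variance was maternal, which would make
the model search vacuous.

`compute_dic()` therefore defaults to a *marginal* focus for univariate
fits: location effects are integrated out and
$D(\theta) = -2\log N(y \mid X\beta,\; \sum_t \sigma^2_t Z_t K_t Z_t' +
\sigma^2_E I)$ is evaluated per retained sample, with the plug-in at
posterior means. This focus scores the variance structure itself; in
simulations it cleanly separates models when maternal variance dominates
(ΔDIC of 25–50 at $me^2 = 0.8$) and treats them as equivalent
(ΔDIC < 7) when maternal variance is absent — the qualitative behaviour
the ΔDIC < 7 rule is meant to exploit. The conditional focus remains
available (`focus = "conditional"`), and the per-iteration conditional
deviance is stored with the samples.

A related fidelity note: when maternal variance is moderate
(around half of $\sigma^2_P$) and broods are mostly full sibs, the
additive-only model's marginal covariance ($0.5\sigma^2_A$ within broods)
can imitate a maternal structure almost perfectly at a colony scale of
~150 nestlings; no DIC variant separates the models there. Separation is
driven by EPP half-sib contrast and by maternal fractions well above one
half — which is exactly the regime reported for the maternal-dominated
traits (wing, bill, tail) that motivate the comparison.

## Microsatellite machinery

* **Locus summaries.** Allele frequencies by counting; unbiased expected
  heterozygosity $(2n/(2n-1))(1-\sum p^2)$; exact test for Hardy-Weinberg
  proportions conditional on allele counts (complete enumeration of
  genotype tables when the locus has ≤ 4 alleles and the table count fits
  a budget, otherwise Monte-Carlo with 10^5 permutations, add-one
  corrected).
* **Null alleles.** A single-null-allele EM: apparent homozygotes are a
  mixture of true homozygotes and visible/null heterozygotes, and the
  unobserved null-homozygote class is imputed with its expected count so
  the likelihood is properly conditioned on amplification. Visible
  frequencies are renormalized so all frequencies plus $p_{null}$ sum
  to 1; $p_{null}$ is clipped to [0, 0.5]. A monomorphic visible locus
  has a flat likelihood in $p_{null}$ and returns 0 by convention.
* **Exclusion probabilities.** Q1 (random non-father excluded given a
  known mother) and Q2 (random pair excluded) by exact enumeration over
  Hardy-Weinberg genotype triples, with the inner sums reduced to
  carrier probabilities for speed; loci combine as $1-\prod(1-Q_l)$.
* **Pairwise likelihoods.** $P(g_1,g_2\mid k) = k_0 P(g_1)P(g_2) + k_1
  P(g_1) T(g_2|g_1) + k_2 P(g_1)[g_1{=}g_2]$ with the usual Cotterman
  coefficients for U/HS/FS/PO; loci multiply; when a positive null-allele
  frequency is modeled, apparent homozygotes are marginalized over the
  hidden null-carrier state. Classification ties break toward the less
  related category (U > HS > FS > PO), keeping the reconstructed pedigree
  conservative.
* **Parentage.** Candidates with Mendelian mismatches (zero transmission
  likelihood) at more than `max_mismatch` loci (default 0) are excluded;
  null-compatible apparent-homozygote mismatches are not counted when
  null modeling is on. Posteriors are likelihoods normalized over the
  surviving candidates plus an "unsampled random parent" alternative;
  assignment requires posterior ≥ 0.99.
* **Sibship.** Greedy agglomeration on pairwise FS-vs-U log-likelihood
  gains, refusing merges that would put a U-classified pair in one group.
  This replaces a joint-likelihood MCMC over sibship configurations; it
  is deterministic and testable, but it is a documented fidelity gap —
  with 7 loci × 8 alleles two true clutches occasionally cannot be
  separated, and the clutch-recovery unit test uses 10 loci × 12 alleles.

## The synthetic colony

`sim_config()` states the simulated world; defaults are the study
conditions: 28 nests (21 single-chamber, 6 double, 1 quadruple), one
breeding pair per chamber, truncated-Poisson(4) clutches on [1, 8]
(clutch size is not published; Poisson(4) matches typical clutch sizes
for the species), EPP in 40% of chambers (extra-pair sires drawn from
other resident males), intra-brood parasitism in 3% of chambers, 7 loci
with 8 equifrequent alleles, and six traits with nestling-scale means and
standard deviations. True (co)variance components G, M, N, R are free
parameters; the default decomposition h² = 0.3, me² = 0.2, ne² = 0.1 per
trait is an arbitrary but realistic mid-range choice and is returned as
truth alongside every simulated phenotype table.

Gene dropping follows the standard recursion: founders are MVN(0, G),
offspring receive the parental mean plus a Mendelian-sampling deviate
with covariance $(1 - k_d(1+F_d)/4 - k_s(1+F_s)/4)\,G$, where $k$ flags a
known parent and F its inbreeding coefficient. Null alleles are simulated
mechanistically (null homozygote → missing cell, null heterozygote →
apparent visible homozygote).

What the simulator does *not* emulate: overlapping generations, spatial
structure between localities, age-dependent trait means within the
nestling class (the real wing-length SD of 33.67 mm implies mixed-age
nestlings), genotyping error, and allelic dropout other than via null
alleles. A green recovery test therefore establishes that the estimators
work when the model matches the generative process — not that the
published point estimates are correct.

## Numerical choices and degenerate inputs

* Unknown parents are accepted as "", "0" or "NA" and written as "0";
  referenced-but-unlisted parents are auto-added as founders (candidate
  parent lists from field trapping are incomplete by nature).
* A is stored dense and inverted by dense Cholesky; fine at colony scale
  (hundreds of individuals), a known limit for large pedigrees.
* Individuals with an unknown dam each get their own maternal level, so
  the maternal design stays full rank without discarding records.
* The HWE Monte-Carlo p-value uses the add-one correction
  $(1+\#\{P \le P_{obs}\})/(1+B)$, so it is never exactly zero.
* A zero-variance response, a maternal term with no known dams, fewer
  than 10 phenotyped individuals, or a non-PSD covariance input all stop
  with informative errors rather than producing output.
* The 82 g fledging filter is applied to all model inputs by default
  (configurable), since the source analysis pools adults and
  fledging-weight nestlings for all traits.

## Known limitations

Single-trait maternal and nest effects are identity-covariance (no
maternal genetic effects); no repeated measures; no genotyping-error
model in parentage (a mismatch budget is the only knob); DIC focus
differences mean absolute DIC values are not comparable across software,
only Δ values within one focus; and the greedy sibship partition can
split a true clutch when loci are weakly informative.
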