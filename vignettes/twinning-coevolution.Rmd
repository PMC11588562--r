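---
title: "Modelling the gene–culture coevolution of human twinning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the gene–culture coevolution of human twinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geminicoev)
```

Dizygotic twinning is an evolutionary puzzle: twin births carry real
survival and maternal costs, primates are modally monotocous, and yet human
populations keep producing twins at appreciable — and widely varying —
rates, with the highest rates found in comparatively poor economies rather
than rich ones. `geminicoev` implements three small formal models that
together frame one candidate resolution: ecological selection on ovulation
strategies, the demography that makes twin-maternity a salient communal
risk, and a gene–culture feedback in which community institutions that
materially support mothers of twins (*geminophilous* norms) blunt selection
against polyovulation — and can even reverse it.

This vignette records the models as implemented, the choices made where a
design was genuinely open, and what the stochastic machinery does and does
not emulate.

## 1. Selection on ovulation strategies

Two genotypes compete: double-ovulation $P$ and mono-ovulation $S$. A
mother's resource endowment $E \in (0,1)$ sets both the embryo/foetal
mortality of each fertilised ovum,

$$m(E) = d - cE, \qquad c > 0,\; c < d \le 1,$$

and the reproductive value of a twin birth, $R_t(E) = aE + b$, against a
constant singleton value $R_s$. Each of the double-ovulator's two embryos
survives gestation independently, so

$$W_P(E) = R_t(E)\,(1-m)^2 + R_s\, 2m(1-m), \qquad
  W_S(E) = R_s\,(1-m).$$

There are no trade-offs between current and future reproduction and no
prenatal/postnatal allocation trade-offs; the model compares fixed
genotypes and deliberately does not evolve plasticity itself.

Collecting terms of $W_P > W_S$ gives a concave parabola
$q(E) = \alpha E^2 + \beta E + \gamma$ with

$$\alpha = -ac, \qquad \beta = a(d-1) + c(2R_s - b), \qquad
  \gamma = R_s(1-2d) + b(d-1),$$

and the implementation rests on the exact algebraic identity

$$W_P(E) - W_S(E) = -(1 - m(E))\, q(E),$$

so wherever any embryo can survive ($m < 1$), double ovulation is favoured
*iff* $q(E) < 0$, i.e. outside the root interval $[E_1, E_2]$. Because the
identity is exact, the sign orientation is not a numerical convention: it
is verified against direct fitness comparison on dense grids in the test
suite, across randomly drawn valid ecologies.

`partition_resource_space()` cuts $(0,1)$ at
$\{E_1, E_2, E^*\} \cap (0,1)$, where $E^* = (R_s-b)/a$ is the threshold
above which a twin birth outvalues a singleton outright, and labels each
interval by *twinning adaptive* ($E \ge E^*$) and *double ovulation
favoured* ($q < 0$). With both roots inside $(0, E^*)$ the canonical
four-region layout appears — double ovulation pays at **both** ends of the
resource gradient:

```{r four-region}
eco <- ovulation_ecology(a = 1.1, b = 0.02, c = 0.5, d = 0.55, Rs = 1)
partition_resource_space(eco)
```

This ecology is the package's reference four-region parameterisation; it
was found analytically by requiring a positive discriminant with both roots
below $E^*$. Complex or out-of-interval roots collapse the partition to
fewer regions, which the same code path handles.

Numerical choices, all deliberate:

* **Strict validation.** Parameter sets allowing $m(E) \notin [0,1]$
  anywhere on $(0,1)$ are rejected at construction rather than clamped:
  clamping would silently change the model. Likewise $a > 0$, $R_s > b$.
* **Open interval.** $E$ is validated to lie strictly inside $(0,1)$; grid
  evaluations use a $10^{-6}$ endpoint margin.
* **Root tolerance.** A discriminant within $\pm 10^{-12}$ of zero is
  treated as a double root — a tangency with no sign change.
* **Degenerate regions.** Partition intervals narrower than `tol`
  (default $10^{-8}$) are dropped so coinciding boundaries cannot produce
  zero-width regions.
* **$E^* \ge 1$.** Nothing special happens: the partition is simply
  truncated at 1 and the twinning-adaptive region is absent.

## 2. How common are mothers of twins?

With a constant per-pregnancy twinning probability $x$ and $P$ successful
pregnancies — twinning assumed not to reduce future pregnancies, $x$
constant over age and parity — the probability of ever mothering twins is
the complement of a run of failures:

$$T = 1 - (1 - x)^P.$$

The formula is elementary but its magnitudes are not widely appreciated:

```{r prevalence}
# modern low-fertility regime at the global average twinning rate
round(100 * mother_of_twins_probability(0.013, 2), 1)
# high-fertility regime at a Yoruba-like twinning rate
round(100 * mother_of_twins_probability(0.045, 10))
# modern Benin: standardised rate, completed fertility
round(100 * mother_of_twins_probability(0.028, 5), 1)
```

In a pre-demographic-transition fertility regime, becoming a mother of
twins is not a rare private misfortune but a risk faced by a third of
all mothers — exactly the regime in which a communal insurance institution
can arise. The closed form is cross-checked in the tests against
brute-force Bernoulli careers ($10^6$ simulated reproductive histories per
query) and obeys complement multiplicativity,
$T(x, P_1 + P_2) = 1 - (1 - T(x,P_1))(1 - T(x,P_2))$.

## 3. Geminophilous redistribution and culture-led selection

Two genotypes (low-twinning $Q$ with twin-birth probability $\beta$;
mutant $\tilde Q$ with $\beta + \delta$, the increment taken as additive)
cross two cultural types ($G$: member of the twin-support network; $A$:
not), giving four types. Everyone holds $M$ resource units and produces one
birth per generation. Survival of an offspring is a monotone increasing
function $S(\cdot)$ of the resources invested in it; the packaged default
is the exponential CDF $S(r) = 1 - e^{-\lambda r}$.

* $A$-types: a singleton gets $M$; each twin gets $M/2$, so
  $W_A(\beta) = (1-\beta) S(M) + \beta\, 2 S(M/2)$.
* $G$-types pay the fixed membership cost $\gamma$. Those who produce a
  singleton also contribute the variable share $\alpha(M-\gamma)$ to the
  community pool — twinners do **not** pay the variable share. The pool
  $\kappa = \alpha(M-\gamma) \times (\text{number of } G\text{-type
  singleton producers})$ is split equally among the $T_G$ $G$-type
  twinners, so each $G$ twin offspring gets
  $(M - \gamma + \kappa/T_G)/2$ and a contributing singleton's offspring
  gets $(1-\alpha)(M-\gamma)$.

Twinning is maladaptive without institutions when $S(M) > 2S(M/2)$. This
is a *shape* condition on $S$: any concave survival function through the
origin — including the exponential default, for every $M$ and $\lambda$ —
violates it, because halving the investment never halves concave survival.
The package therefore treats $S$ as pluggable everywhere (`surv_fn`
arguments) and *reports* whether the condition holds for the configured
$S$ (`twinning_maladaptive()`) instead of assuming it; analyses that need
costly twinning use a convex or threshold-like survival such as
$S(r) = \min(r,1)^2$, which the test suite adopts for its
direction-of-selection checks.

`expected_fitness_G()` computes the expected surviving offspring of a
focal $G$-type individual, taking the expectation over the twin/singleton
Bernoulli draws of **all** $G$-types — the focal draw and the binomial twin
counts of the others, which jointly determine $\kappa$ and $T_G$. The
focal individual's own outcome is included in the counts, matching the
simulation's accounting (the analytic invasion condition below is
unaffected by this interpretation, since it fixes every outcome). Exact
enumeration of the joint binomial outcomes is used up to a configurable
$G$-population cap (default 20, beyond which the sum is long and Monte
Carlo with its reported standard error is the better tool).

### Invasion and the conservative norm strength

In an all-$G$ population of size $N$ with non-twinning residents
($\beta = 0$), a lone mutant who twins is the sole claimant of the pool,
$\kappa = \alpha(M-\gamma)(N-1)$, so it out-reproduces residents when

$$2\,S\!\left(\frac{(M-\gamma)\,(1 + \alpha(N-1))}{2}\right) >
  S\big((1-\alpha)(M-\gamma)\big).$$

Since $S$ is monotone, comparing the *arguments* gives a sufficient
condition independent of the shape of $S$:
$(1+\alpha(N-1))/2 \ge 1-\alpha \iff \alpha \ge 1/(N+1)$, returned by
`conservative_alpha()`. The bound is tight in both directions: at
$\alpha = 1/(N+1)$ the arguments coincide and the factor of two decides
for every strictly increasing $S$, while for any $\alpha$ below it there
is a survival function (one rising steeply between the two arguments) that
blocks invasion. A community norm as mild as "everyone gives about
$1/N_G$ of their net wealth" — 1% each among 100 twin-supporters —
therefore suffices, and the per-capita cost of the insurance vanishes as
the community grows.

```{r invasion}
invasion_condition(N = 100, M = 1, gamma_cost = 0.1, alpha_share = 1/99,
                   lambda_surv = 2)
conservative_alpha(100)
```

### The stochastic simulation

`simulate_geneculture()` runs the full generation-by-generation dynamics
that the analytic pieces only bound. Per generation: every individual
draws twin/singleton (Bernoulli at its genotype's rate); the pool is
filled by the realised $G$ singleton producers and split among the
realised $G$ twinners; every offspring survives independently at $S$ of
its resource share; and the next generation of constant size $N$ is formed
by multinomial resampling of parents weighted by their realised
surviving-offspring counts (Wright–Fisher regulation), offspring
inheriting genotype and cultural type clonally.

Design choices a maintainer should know:

* **Fixed $N$, not a branching process.** The fitness reasoning is
  relative, and fixed-$N$ regulation makes the neutral baseline exact: a
  neutral mutant lineage fixes with probability equal to its initial
  frequency ($1/N$ from one copy), which anchors the selection tests.
* **Type-count implementation.** Individuals within a type ×
  birth-outcome class are exchangeable, so the per-individual Bernoulli
  draws are realised as binomial draws per class and the resampling as a
  multinomial over types. This is distribution-identical to the
  individual-level description and costs $O(1)$ per generation, which is
  what makes replicate counts in the hundreds of thousands practical.
* **Clonal transmission, no mutation.** Polyovulation is treated as if
  controlled by a single haploid locus (the phenotypic gambit); mutants
  are introduced explicitly in initial conditions. Cultural type is
  vertically inherited; there is no conformity or cultural mutation rule,
  so mixed-culture populations are supported as initial conditions only.
* **Independent twin survival.** The two offspring of a twin birth
  survive independently, consistent with the squared survival term in the
  ovulation model.
* **Zero twinners.** Contributions are still collected and discarded,
  because contributing-singleton fitness uses $(1-\alpha)(M-\gamma)$
  unconditionally.
* **Extinction.** A generation with no surviving offspring truncates the
  trajectory with an explicit flag rather than resampling from nothing.
* **Seeds.** Every stochastic entry point takes an explicit seed;
  `simulate_replicates()` derives per-replicate child seeds
  deterministically from one root seed, so trajectories are reproducible
  byte for byte.

```{r sim}
scn <- gemino_scenario(M = 1, gamma_cost = 0.1, alpha_share = 0.05,
                       lambda_surv = 2, beta = 0, delta = 1,
                       N_GQ = 99, N_GQt = 1)
traj <- simulate_geneculture(scn, generations = 30, seed = 11)
tail(as.data.frame(traj)[, c("generation", "N_GQ", "N_GQt", "kappa")], 3)
```

## What the tests do and do not show

The suite validates the models at these problem sizes, chosen to give the
statistical checks real power while keeping a default run fast: 1,000
random ecologies × 100-point grids for the quadratic/fitness consistency
oracle; $10^5$ one-generation replicates for simulation-vs-analytic
agreement (within 3 Monte Carlo standard errors per type); 20 random small
support networks for exact-vs-Monte-Carlo cross-validation; 500
replicates × 30 generations for neutrality of $\delta = 0$; 200
replicates for the decline of a high-twinning mutant among $A$-types under
convex survival; and 1,000 replicates for the fixation probability of a
lone always-twinning mutant in a supportive community exceeding the
neutral $1/N$. Monte Carlo assertions use a 3-standard-error band with a
single confirmation re-draw on a borderline exceedance, so a sampling
fluke does not masquerade as a disagreement while genuine bias would
replicate and fail.

All of this exercises the models *on their own terms*. It does not show
that real twinning demography follows them: there is no age or parity
structure, no plastic ovulation response, no prestige or mate-choice
pathway, no cultural transmission dynamics, no diploid genetics, no
spatial structure, and the survival and mortality functions are stylised
(linear mortality in resources; memoryless exponential survival). The
package's claims are about the internal logic of culture-led selection on
twinning propensity — under which conditions a support norm flips the
direction of selection — not about fitted parameters for any population.
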