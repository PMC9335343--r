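---
title: "Polygenic adaptation to an optimum shift: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic adaptation to an optimum shift: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r setup}
library(polyadapt)
```

## The model and its assumptions

polyadapt simulates a quantitative trait controlled by $L$ unlinked,
additive, biallelic loci in a haploid Wright–Fisher population of census
size $n$. The "+" allele at locus $i$ has effect $\gamma_i > 0$ and
population frequency $p_i$; under the default centered convention the
trait is $z = \sum_i \gamma_i (x_i - \tfrac12)$, the mean is
$\bar z = \sum_i \gamma_i (p_i - \tfrac12)$, and the genetic variance is
$V_g = \sum_i \gamma_i^2 p_i q_i$. Fitness is Gaussian stabilizing,
$w(z) \propto \exp[-(z - z_{opt})^2 / (2 V_s)]$, around an optimum that
can shift instantaneously. The model assumes:

* **additivity** — no dominance (the population is haploid), no epistasis,
  no pleiotropy;
* **linkage equilibrium** — loci are unlinked and the frequency engine
  treats them as independent given the trait moments;
* **heritability one** — no environmental variance; the phenotype is the
  breeding value;
* **symmetric mutation** — each allele mutates to the other at rate $\mu$,
  so the stationary allele-frequency distribution at a neutral locus is
  symmetric Beta$(\theta,\theta)$ with $\theta = 2 n \mu$.

The centered convention matters: it makes the mutation–selection–drift
equilibrium symmetric around $\bar z = 0$, so an optimum at 0 is typical
of equilibrium and a shift to 10 is a well-posed displacement of about 13
genetic standard deviations. The raw convention
($z = \sum \gamma_i x_i$) is kept as an option for sensitivity checks;
with all effects positive it pins the equilibrium against the low-frequency
boundary and is not the regime the package targets.

## The two engines

**Frequency engine** (`wf_run()`): each generation applies selection,
then mutation, then drift, to the frequency vector. The selection update
needs the expected allelic fitness ratio at each locus. Conditioning on
the allele at locus $i$ shifts the mean of the (approximately Gaussian)
trait distribution to $\bar z + \gamma_i q_i$ or $\bar z - \gamma_i p_i$;
integrating the Gaussian fitness over the background gives

$$\log \frac{w_+}{w_-} =
  \frac{\gamma_i (z_{opt} - \bar z) + \gamma_i^2 (p_i - \tfrac12)}
       {V_s + V_{-i}},$$

where $V_{-i}$ is the genetic variance excluding locus $i$. This
closed-form Gaussian-background closure is the default
(`sel_method = "gaussian"`); expanding to first order in $1/V_s$ gives the
per-locus selection coefficient
$s_i = [\gamma_i(z_{opt} - \bar z) + \gamma_i^2(p_i - \tfrac12)]/V_s$
and $\Delta p_i = p_i q_i s_i$ (`sel_method = "first_order"`), which is
faster and is the form the stationary diffusion theory uses. At a single
locus the Gaussian closure is the exact two-genotype selection map, which
is how the engine is unit-tested. The first term is directional selection
toward the optimum; the second acts against heterozygosity once the mean
is near the optimum, pushing common alleles to fixation and rare ones out.

Mutation is applied deterministically to expected frequencies,
$p' = p + \mu(1 - 2p)$. At the default $n\mu = 0.25$ expected mutation
events per locus per generation this choice matters only at the absorbing
boundaries, and it is validated by the neutral closed form below. Drift is
one binomial draw of $n$ trials per locus per generation.

**Individual engine** (`wf_run_individual()`): an explicit $n \times L$
genotype matrix. Each offspring samples two parents with probability
proportional to fitness (selfing allowed), inherits every locus from
either parent with probability $\tfrac12$ (free recombination), and
mutates each copy with probability $\mu$. This engine carries real linkage
disequilibrium and non-Gaussian trait distributions, and is the oracle
against which the mean-field closure is cross-validated at desk scale
($n = 200$, $L = 20$ in the test suite), where both engines agree on the
equilibrium variance and the post-shift mean trajectory within Monte-Carlo
error.

Because the mean-field engine ignores the negative linkage
disequilibrium that stabilizing selection builds (the Bulmer effect), it
slightly *understates* the equilibrium genetic variance relative to the
individual-based dynamics; the discrepancy is a few percent at
$V_g/V_s \approx 0.03$ and is visible in the cross-validation if pushed to
much stronger scaled selection.

## Parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `L` | number of loci | — | 1000 | study conditions |
| `mean_effect` | mean of exponential effect sizes | trait units | 0.12 | study conditions |
| `n` | haploid census = drift size | individuals | 10\^4 | study conditions |
| `mu` | symmetric per-locus mutation rate | /generation | 2.5e-5 | $\theta = 0.5$ |
| `Vs` | stabilizing-selection width | trait units² | 20 | study conditions |
| `shift_to` | post-shift optimum | trait units | 10 | ~13 genetic SDs |
| `burn_in_generations` | pre-shift equilibration | generations | 10\^4 | study protocol |
| `fix_threshold` | "substituted" final frequency | — | 0.99 | see below |
| `return_threshold` | "returned" final frequency | — | 0.05 | see below |

The substitution thresholds are stated defaults, not derived quantities:
"substituted" means final frequency $\ge 0.99$ (a locus ending exactly at
1 is always substituted), "returned to low frequency" means an excursion
above $\tfrac12$ that ends below 0.05. The time-to-optimum tolerance
defaults to one equilibrium genetic standard deviation
$\sqrt{V_g^{eq}}$, since "reaching the optimum" is otherwise arbitrary
for a mean that fluctuates around it. Contribution splits are reported at
the checkpoints: the shift generation, 100 generations after it, and the
final generation.

## The synthetic-architecture generator

There is no empirical input anywhere: the generator *is* the study
system. `sample_architecture()` draws i.i.d. exponential effects (mean
0.12); `initial_state()` starts each locus fixed at 0 or 1 with equal
probability (`near_fixed_random`), which is close to the stationary
distribution when $\theta < 1$ and equilibrates fastest; the `half` mode
(all $p = \tfrac12$) is kept for variance-decay experiments. Fresh effect
draws per replicate are the default, so replicate averages integrate over
architectures; a fixed-architecture mode reproduces single-realization
behavior.

What the generator deliberately does **not** emulate: linkage maps and
hitchhiking, dominance and epistasis, pleiotropic constraint,
environmental variance, distributions of effects other than the
exponential, and any demography beyond constant $n$. Passing tests
therefore show that the engines and theory are self-consistent under the
stated generative model — not that real traits behave this way.

## Diffusion prediction of the equilibrium variance

With the mean at the optimum, the per-locus stationary density follows
from the engine's own forces (drift variance $pq/n$, mutation
$\mu(1-2p)$, selection $\Delta p = pq\,\gamma^2(p-\tfrac12)/V_s$) via the
standard stationary-density construction:

$$\psi(p) \propto (pq)^{\theta - 1}
  \exp\!\left(-\frac{n \gamma^2 pq}{V_s}\right).$$

`expected_locus_variance()` computes $E[pq]$ under $\psi$ and
`predict_equilibrium_vg()` sums $\gamma^2 E[pq \mid \gamma]$ over a
concrete architecture or integrates over the exponential effect
distribution. The haploid convention ($n$, not $2n$, in the exponent) is
fixed throughout and validated against the simulation engine rather than
against any published notation: at the study conditions the prediction
(0.635) agrees with the simulated replicate-mean equilibrium variance
within a few percent, which is the consistency the package enforces in its
acceptance suite. Note that the simulated value measured at the end of a
$10^4$-generation burn-in from the near-fixed start still carries a small
upward-relaxing transient (the slowest loci equilibrate on the
$\sim 1/(1/n + 4\mu)$ = 5,000-generation timescale), so it sits a few
percent below the stationary prediction.

**Numerics.** At $\theta = \tfrac12$ the density has integrable
$p^{-1/2}$ endpoint singularities. The substitution $p = \sin^2(\phi/2)$
turns $\psi(p)\,dp$ into a bounded integrand
$\propto \sin(\phi)^{2\theta - 1}$ on $(0, \pi)$; adaptive quadrature on
that scale is the primary route, and an open-grid midpoint rule on the
same scale is the independent cross-check (they agree to six significant
digits in the tests).

## Limits to selection

`fixation_probability()` implements the haploid diffusion result
$u(p) = (1 - e^{-2Nsp})/(1 - e^{-2Ns})$, computed with `expm1` for
stability and with the neutral limit $u = p$ taken explicitly below
$|2Ns| < 10^{-8}$. It is validated against exact absorption probabilities
of the finite Wright–Fisher chain (transition-matrix linear solve, $N \le
50$) rather than by convention argument.

**The factor of two.** Robertson's bound states that the total response
equals $2 N_e$ times the first-generation response. In a haploid
Wright–Fisher population heterozygosity decays by $1/n$ per generation,
so the cumulative directional response is $n R_1$ — the classical factor
2 appears once $N_e$ is read in the diploid-standard inbreeding sense,
$1/n = 1/(2 N_e)$, i.e. $N_e = n/2$ for a haploid census of $n$. The
package adopts this correspondence everywhere it reports a Robertson
ratio: `robertson_experiment()` with $n = 200$ haploids is an
$N_e = 100$ experiment, and the bias-sum identity
$\sum_i \gamma_i (u_i - p_{0i}) \to n\beta \sum_i \gamma_i^2 p_0 q_0 =
2 N_e R_1$ holds exactly in the weak-selection limit. Without this
reading, a haploid engine cannot produce the factor 2 at all.

**Measuring $R_1$.** At $N_e = 100$ the realized first-generation change
in the mean has drift standard deviation $\sqrt{V_g/n}$, about seven
times the expected response itself, so a per-replicate realized $R_1$ is
statistically useless. The experiment therefore uses the deterministic
expected first-generation response (the selection update applied to
$p_0 = \tfrac12$ before drift), which the realized change equals in
expectation. Loci are dropped from the resampling once fixed (absorbing,
since $\mu = 0$ here), and runs are capped at $20n$ generations, by which
point the expected unrealized response is a factor $e^{-40}$ of the
total.

`efficiency_scan()` makes the efficiency argument quantitative: holding
the total variance in relative fitness fixed at $V_w$ and splitting it
over $L$ equal loci gives $s = \sqrt{V_w/(L p_0 q_0)}$ per locus, and the
expected excess of substitutions $L[u(p_0) - p_0]$ *grows* with $L$
(asymptotically like $\sqrt{L}$) even as each locus sinks into the
drift-dominated regime $N_e s < 1$ — adaptation is most efficient in the
infinitesimal limit.

## Design decisions that were genuinely open

* **Default selection closure.** The Gaussian-background integral is the
  default because it is exact at a single locus and closest to the
  individual-based oracle in cross-validation; the first-order form is
  what the diffusion theory linearizes, so both are first-class and every
  analytic test states which it uses. The two closures differ by the
  $V_s + V_{-i}$ versus $V_s$ denominator, about 3% in equilibrium
  variance at the study conditions.
* **Burn-in initialization.** `near_fixed_random` rather than `half`:
  with $\theta = \tfrac12$ the stationary density is boundary-
  concentrated, so starting at the boundaries converges from below on the
  drift timescale instead of overshooting from the variance-maximizing
  interior state.
* **Update order** selection → mutation → drift, one binomial draw per
  locus per generation; a single seeded RNG stream per run, vectorized
  draws, never re-seeded per locus. Experiment-level replicate seeds are
  drawn once from the master seed.
* **Shift timing.** "Time zero" is the generation after burn-in; the
  post-shift phase defaults to $10^4$ generations (the acceptance
  experiments use 5,000, past the point where the variance has returned
  to equilibrium).
* **Fitness exponent sign.** Stabilizing selection requires the negative
  exponent $\exp[-(z - z_{opt})^2/(2V_s)]$; the package never exposes the
  disruptive sign.

## Problem sizes used by the tests

The unit suite runs scaled systems chosen to preserve the two scaled
parameters that control the dynamics — $\theta = 2n\mu = 0.5$ and
$n\gamma^2/V_s$ — at a fraction of the cost: $n = 1000$, $L = 100$,
$V_s = 2$ for shift experiments (burn-ins of several relaxation times so
the pre-shift variance is fully stationary), $n = 200$, $L = 20$ for
engine cross-validation, and $n = 100$ for neutral closed-form checks.
The acceptance suite runs the full study conditions: five fresh-draw
replicates of the $10^4$-generation burn-in plus 5,000 post-shift
generations, and 200 directional replicates at $N_e = 100$, $L = 2000$.

## Known limitations

* The frequency engine is a linkage-equilibrium mean field; it omits the
  (negative) selection-generated linkage disequilibrium and so slightly
  understates equilibrium variance relative to the individual-based
  dynamics.
* Equilibrium quantities measured "at the end of burn-in" carry a small
  transient unless the burn-in spans several relaxation times; the
  full-scale protocol inherits this by construction.
* Single-realization counts (how many large-effect alleles substitute,
  their summed contribution) vary strongly across architecture draws;
  the package reports replicate means with Monte-Carlo standard errors
  and makes no claim about any particular realization.
* The diffusion module is equilibrium-only; no transient solutions.
* Nothing here addresses dominance, epistasis, linkage, pleiotropy,
  environmental variance, or changing population size.
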