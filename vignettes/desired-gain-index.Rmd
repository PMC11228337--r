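---
title: "Iterative desired-gain selection indices: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative desired-gain selection indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgindex)
```

## The problem

Breeding programmes almost always improve several traits at once. The
classical Smith–Hazel index needs economic weights per trait, which are
often unavailable. Desired-gain indices side-step economic weights: the
breeder states how much gain is wanted per trait, and the index weights
are solved from

$$ b = P^{-1} G \, (G P^{-1} G)^{-1} d $$

where $P$ is the phenotypic (co)variance matrix — in this package, by
default, the correlation matrix of the reference population's genomic
estimated breeding values (GEBVs) — $G$ is the genetic
variance–covariance matrix, and $d$ is the desired-gain vector. The
construction guarantees the *expected* gain identity $G b = d$
(`expected_gains()` exposes it as a diagnostic; `dg_weights()` verifies
it to 1e-8 relative error).

The catch is that $d$ is only a direction-setting input. When the index
$I_i = \sum_j b_j\,\mathrm{GEBV}_{ij}$ is used for truncation selection —
keep the top $N_{sel}$ of $m$ lines — the *realised* standardized
response

$$ g_j = \frac{\overline{\mathrm{GEBV}}_{j,\text{sel}} -
               \overline{\mathrm{GEBV}}_{j,\text{all}}}
              {\mathrm{SD}(\mathrm{GEBV}_{j,\text{all}})} $$

generally does not equal $d$, nor any simple rescaling of it. `dgi()`
therefore treats $d$ as a free parameter and searches for the $d$ whose
*realised* response best matches a user-specified target response
$d_g$ (in population-SD units, sign = desired direction).

## The optimiser

Each iteration: (1) propose $d^\*_j \sim N(d^{acc}_j,\,\sigma_p)$
independently per trait, centred on the most recently accepted $d$;
(2) compute $b(d^\*)$; (3) rank the reference population, select the top
$N_{sel}$, measure $g$; (4) score the proposal with the penalty

$$ \theta = \sum_j \frac{gof^{max}_j - gof_j}{gof^{max}_j}, $$

and (5) accept iff $\theta$ strictly decreased. The search starts at
$d^{acc} = d_g$, so the final fit can never be worse (in $\theta$) than
the classical single-pass method, which `dgi_baseline()` reproduces and
every report carries as its `Response_NoIteration` column.

Defaults: 1,000 iterations, proposal SD $\sigma_p = 0.5$ (desired-gain
units), $N_{sel} = 100$, and 20 replicates in `dgi_replicates()`, whose
consistency statistic is the mean pairwise Pearson correlation of the
replicates' *candidate score vectors*. Scores, not $b$ vectors, are
correlated because scores are what determine selections and are free of
the scale ambiguity of $b$ (scaling $d$ scales $b$ without changing any
ranking — which is also why a target of $8 d_g$ selects exactly the
individuals of $d_g$ in a baseline run). Replicate $k$ runs with seed
$\texttt{seed} + k$, making the whole campaign reproducible yet the
replicates mutually independent.

## The goodness-of-fit curve

Per trait, with the response ratio $r = g/d_g$ ($r = 1$: target hit;
$r \le 0$: wrong direction):

* $r \ge 1/e$: $gof = \ln(x)/x$ with $x = e\,r$ — the unimodal
  $\ln(x)/x$ curve with its maximum $1/e$ exactly at $g = d_g$. Its
  asymmetry is deliberate: overshoot decays slowly, undershoot steeply.
* $0 < r < 1/e$: the linear ramp $gof = -1/e + r$. Continuing
  $\ln(x)/x$ here would send $gof \to -\infty$ as $r \to 0^+$, making a
  tiny correct-direction response score *below* a wrong-direction one
  and handing the optimiser an inverted preference near the origin. The
  ramp joins $\ln(x)/x$ continuously at $x = 1$, stays strictly
  increasing, and keeps every correct-direction response strictly above
  $-1/e$.
* $r \le 0$: $gof = -(1/e)(1 + |r|)$, strictly below $-1/e$, so any
  wrong-direction response scores below every correct-direction one and
  worse the further it goes. This is what makes $\theta$-descent push
  all traits toward their desired directions.

$\theta \ge 0$ always, and $\theta = 0$ exactly when $g = d_g$
componentwise. A published variant of the curve,
$\log_{base}(base^2|g|)/(base^2|g|)$ with $base = |e\,d_g|$, is kept
behind `gof(..., form = "literal")` for comparison; it neither peaks at
$g = d_g$ nor sees the sign of $g$, so it is not used for fitting.

## What the simulator emulates — and what it does not

`simulate_gebv()` draws true breeding values from
$N(0, \Sigma_g)$ with $\Sigma_g = D R_g D$, $D = diag(\sqrt{h^2})$
(phenotypic variance normalised to 1, so $\sigma^2_g = h^2$ and all
responses are naturally in population-SD units), then builds GEBVs with
the standard predictor property
$\mathrm{gebv} = r^2\,\mathrm{tbv} + \varepsilon$,
$\varepsilon \sim N(0,\, r^2(1-r^2)h^2)$, giving
$\mathrm{var(gebv)} = r^2 h^2$ and $\mathrm{cor(gebv, tbv)} = r$.
`wheat_params()` packages a realistic seven-trait bread-wheat setting
(h² 0.21–0.59, accuracies 0.29–0.47, mostly weak genetic correlations,
TKW–Screen at −0.61; 3,331 reference lines and 3,005 double-haploid
candidates), and `wheat_targets()` the three matching target scenarios
(equal ±0.5; yield-dominant +2/±0.5; "maximal" ±4, effectively
unconstrained).

The prediction noise is independent **across traits**: cross-trait GEBV
correlations derive from the breeding-value structure alone and are
therefore the genetic correlations shrunk by $r_j r_k \approx$
0.09–0.22. This is the simplest model consistent with per-trait
accuracies, but it is a known limitation: real multi-trait genomic
predictions share a training set and a kinship structure, so real GEBV
correlations track the genetic correlations much more closely. The
candidate population is drawn from the same distribution as the
reference (exchangeability instead of an explicit crossing model).

This matters for interpreting optimisation results on simulated data.
For multivariate-normal GEBVs, *any* linear index selecting the top
fraction $p$ realises a response vector on the shell
$\lVert g \rVert_{P^{-1}} \approx i(p)$, where $i(p) = \phi(\Phi^{-1}(1-p))/p$
is the selection intensity — $i \approx 2.27$ at $p = 100/3331$. With the
near-diagonal $P$ of the independent-noise simulator, the equal-weight
target ($\lVert d_g \rVert \approx 1.32$) lies strictly *inside* that
shell: no index can realise it, the optimiser's $\theta$ bottoms out
above zero, responses overshoot (typically concentrating the excess
intensity on one or two traits), and — because many points of the shell
fit almost equally well — independently seeded replicates can settle on
visibly different solutions, depressing the replicate-consistency
correlation. The yield-dominant target ($\lVert d_g \rVert \approx 2.35$)
sits almost exactly on the shell and is recovered closely and
consistently. On real data with strongly correlated GEBVs the reachable
shell is oriented differently and an equal-weight target can be much
closer to attainable; passing or failing the equal-weight recovery on
simulated data therefore says more about this geometry than about the
optimiser.

## Numerical choices

* Eq. 1 is evaluated with two linear solves ($PX = G$, then
  $(G'X)y = d$, $b = Xy$), never explicit inverses.
* Matrices with 2-norm condition number above 1e12 are refused with the
  condition number in the message; `jitter = TRUE` adds 1e-8 to the
  diagonal instead. Symmetry is required to 1e-10 (relative) on input
  matrices, 1e-8 on files.
* Standardization uses the sample SD ($m-1$); at $m \approx 3000$ the
  difference from $m$ is negligible, but the convention is fixed.
* Ties at the selection cutoff are broken by input order (stable radix
  ranking), so runs are deterministic for any score vector.
* Acceptance is strict ($\theta_{new} < \theta_{best}$); an equal
  $\theta$ is rejected. On a single trait, where every $d > 0$ induces
  the same ranking, the trajectory is therefore exactly flat.
* Responses are measured on each population's own mean/SD: the
  reference population inside the optimisation loop, the candidates'
  own statistics in `predict()`. $G$ is used on whatever scale it is
  supplied (it is typically a REML estimate; only the induced ranking
  matters, and re-standardizing $G$ only reparameterizes $d$).
* Targets of exactly 0 are rejected ($base = |e \cdot d_g|$ would
  vanish); leave a trait effectively unconstrained with a
  large-magnitude target such as ±4 instead.

## Worked example sizes

The examples in the documentation use a few hundred simulated lines and
tens of iterations so they run in moments; the study-scale configuration
(3,331/3,005 lines, 100 selected, 1,000 iterations, 20 replicates) is
exercised by the test suite and by `scripts/acceptance.R`, and a single
such fit takes well under a second of CPU.

## Known limitations

* The simulator's independent prediction noise (above) understates
  cross-trait GEBV correlation; do not read simulated equal-weight
  recovery quantitatively onto real data.
* The optimiser is a greedy stochastic descent: it cannot escape a
  basin once $\theta$ improvements become rare, and with an
  unreachable target different seeds may end in different basins. If
  replicate consistency matters, inspect `dgi_replicates()$mean_cor`
  and the per-replicate responses before committing to an index.
* The method measures alignment with the target response only; the
  correlation between the index and net genetic merit is not assessed.
* Multi-cycle breeding (recurrent selection, crossing plans) is out of
  scope; the package scores one selection decision at a time.
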