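---
title: "Open Markov chains: model, moment engines, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open Markov chains: model, moment engines, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openmarkov)
```

## The model

An open Markov chain is a population of non-interacting particles on a
finite state space. Three ingredients define it:

* a **jump matrix** `Q` — nonnegative, row sums at most 1 — whose entry
  `q_ij` is the probability that a particle at state *i* moves to state *j*
  in one step;
* the implied **escape probabilities** `e_i = 1 - sum_j q_ij`, with which a
  particle leaves the system for the reservoir; and
* an **arrival protocol**, the law of the random vector `J^t` of particles
  immigrating at each step, with mean `eps` and covariance `Delta`.

One step proceeds in two stages. Every particle at state *i* independently
chooses among the `S + 1` options `(q_i1, ..., q_iS, e_i)`, so the vector of
destination counts out of state *i* is multinomial with `N_i` trials; the
redistributed total `R^t` is the sum of these independent multinomials. The
new arrivals are then added: `N^{t+1} = J^t + R^t`. Particle number is
conserved pathwise: departures plus retained particles always add up to the
previous total, and `simulate_chain()` asserts this identity at every step.

The key standing assumption is `rho(Q) < 1` (strict sub-stochasticity in
spectral radius). It guarantees that the expected number of visits a particle
makes before escaping, `(I - Q)^{-1} = sum_k Q^k`, is finite, and hence that
a stationary regime exists under any stationary arrival protocol.
Irreducibility and aperiodicity of `Q` are *not* required by any formula in
the package; `open_chain()` warns about them (they matter for some classical
interpretations) but does not error. The ring example below is a case where
the internal cycle structure can be periodic while every result still holds.

## Two independent routes to the moments

The package deliberately implements the same quantities twice, by different
mathematics, and the test suite requires the routes to agree.

**Route 1 — m.g.f. transport.** The occupancy m.g.f. satisfies
`G_{t+1}(a) = F(a) * G_t(H(a))` where `F` is the arrival m.g.f. and
`H_i(a) = log(e_i + sum_j q_ij e^{a_j})`. Unrolling gives a finite product
for `G_t` and, as `t -> Inf`, the stationary infinite product
`G_stat(a) = prod_r F(H^(r)(a))`. The iterates have the closed form
`H^(r)(a)_i = log(1 - sum_j (Q^r)_ij + sum_j (Q^r)_ij e^{a_j})`, which
`h_iterate()` uses by default: it runs through matrix powers instead of `r`
nested `log`/`exp` evaluations and so does not accumulate transcendental
round-off. Naive composition is retained as an independent check and the
suite verifies the two agree to `1e-12` on random chains.

**Route 2 — cumulant recursions.** Differentiating the m.g.f. recursion at
zero yields `mu_{t+1} = eps + mu_t Q` and
`Sigma_{t+1} = Delta + Lambda_t + t(Q) Sigma_t Q`, with
`Lambda = diag(mu Q) - t(Q) diag(mu) Q` the covariance injected by the
multinomial redistribution itself (it is positive semidefinite, vanishing
with `mu`). The index in the sum defining `Lambda` runs over the source
states `k = 1 ... S`. Stationary solutions are `mu_bar = eps (I - Q)^{-1}`
and the discrete Lyapunov (Stein) equation
`Sigma_bar = (Delta + Lambda_bar) + t(Q) Sigma_bar Q`.

`stationary_variance()` solves the Stein equation as an `S^2 x S^2` linear
system via `vec(Sigma) = (I - t(Q) %x% t(Q))^{-1} vec(M)`. The equivalent
series `sum_k (t(Q))^k M Q^k` is implemented as
`stationary_variance_series()` and kept as a cross-check only: the direct
solve is exact up to solver tolerance and does not degrade as `rho -> 1`,
where the series needs `O(log(tol) / log(rho))` terms.

Worth singling out, because the algebra is easy to get wrong: the
one-vertex chain with Bernoulli(`p`) arrivals and retention `q` has
stationary variance `p/(1-q) - p^2/(1-q^2)` — with a **minus** sign, since
the stationary occupancy is a convolution of independent Bernoulli(`p q^r`)
variables and each contributes `p q^r (1 - p q^r)`. The same sign propagates
to the outflow variance `p - p^2 (1-q)^2 / (1-q^2)`. Both are confirmed
three independent ways in the tests (direct summation, Stein solve, exact
enumeration); at `p = q = 1/2` the variance is `2/3`, not `4/3`.

## Outflow and correlations

Departures from state *i* are a binomial thinning `Binom(N_i, e_i)`, so the
outflow m.g.f. is the occupancy m.g.f. composed with
`C_i(a) = log(1 - e_i + e_i e^{a_i})`. First and second moments follow as
`E[U] = mu E`, `Var(U) = E Sigma E + diag(mu e (1 - e))`, and for the total
outflow `E[O] = mu e'`, `Var(O) = e Sigma e' + mu (I - E) e'`. At
stationarity `mu_bar e' = sum(eps)` exactly — the flux balance — and
`flux_balance()` errors if the identity fails beyond `1e-10`, since that can
only signal an inconsistent input.

In simulation, the outflow is read from the exit cell of the same
multinomial draw that redistributes the particles, not re-thinned
independently: the two laws coincide marginally (multinomial lumping), and
reusing the draw preserves conservation realization by realization.

The two-time covariance is `Cov(N^t, N^{t+s}) = Sigma_t Q^s`: only the jump
matrix propagates correlation forward, so at stationarity the decay is
geometric at rate `rho` and — notably — completely independent of any
autocorrelation in the arrival sequence. For this reason the built-in
arrival families are i.i.d. across time; nothing in the implemented
covariance theory would change for a dependent stationary arrival sequence
with the same one-step marginal.

## Arrival protocols

Built-ins: `arrival_constant()`, `arrival_bernoulli()` (independent
per-state Bernoulli), `arrival_poisson()` (independent Poisson — under it
the stationary occupancy is product-Poisson and `Sigma_bar = diag(mu_bar)`
identically, which the suite asserts to `1e-12`), `arrival_pmf()` (any
finite joint table; moments by enumeration, sampling by inverse CDF), and
`arrival_coupled_bernoulli(p)` — three states where states 1 and 2 receive a
dependent Bernoulli(1/2) pair (`Cov(J1, J2) = (2p - 1)/4`) and state 3 an
independent Bernoulli(1/2). The coupling parameter lets one study how
arrival correlation does (spatially) and does not (temporally) propagate
into the occupancy field.

## The exact enumeration oracle

For tiny systems the transition kernel `K(k, n) = P(J + R = n | N = k)` can
be enumerated outright: per-state multinomial outcome tables are convolved
destination-wise, then convolved with the arrival support. `evolve_pmf()`
pushes a dense probability table over the box `[0, n_max]^S` (guarded at
`(n_max + 1)^S <= 1e6` cells) forward in time; `stationary_pmf()` iterates
to a total-variation fixed point (default `1e-12`). Mass that leaves the box
is never silently renormalized: it accumulates in `truncation_mass`, and
results should be trusted only when that mass is negligible (the suite
works at caps where it is below `1e-12`).

The oracle closes the validation triangle: simulator vs recursions vs
m.g.f. products are all checked against enumerated ground truth on one- and
two-state chains, including a brute-force confirmation of
`Cov(N^t, N^{t+s}) = Sigma_bar Q^s` that never uses that formula.

## Numerical choices

* **Validation margins.** Row sums may exceed 1 by at most `1e-12`, and the
  spectral radius must stay below `1 - 1e-12`: the stationary theory
  degrades continuously as `rho -> 1` (means scale like `1/(1 - rho)`), so
  near-critical inputs fail fast rather than returning fragile numbers.
* **Stationary product truncation.** `stationary_mgf()` multiplies factors
  until `max(abs(H^(r)(a))) < tol` (default `1e-12`). The omitted tail
  biases `log G` by about `tol * sum(eps) / (1 - rho)`.
* **Cumulant extraction.** `mgf_cumulants()` uses central differences of
  `log(mgf)` with one Richardson step, default `h = 1e-2`. The coarse step
  is deliberate: Richardson makes the differencing truncation `O(h^4)`
  (harmless for count distributions with moderate higher cumulants), while
  any evaluation noise — round-off, or the product-truncation bias above —
  enters the Hessian divided by `h^2`. At `h = 1e-4` that amplification is
  `1e8` and visibly corrupts the covariance of the `rho = 0.9` example;
  at `h = 1e-2` both error sources sit near `1e-7`. When comparing the two
  moment routes to `1e-5`, the product tolerance is tightened to `1e-15`.
* **Burn-in.** `default_burn_in()` returns
  `max(1000, ceiling(50 / (1 - rho)))` steps: the occupancy relaxes
  geometrically at rate `rho`, so this is ≥ 50 relaxation times.
* **Monte-Carlo error bars.** Stationary single-run estimates are
  autocorrelated; standard errors in `validate_report()` and in the
  stochastic tests use non-overlapping batch means (default 50 blocks),
  with comparisons at 4 standard errors. With a fixed seed the suite is
  deterministic; at fresh seeds a 4-sigma band keeps the false-alarm
  probability per table far below 1%.
* **Integer safety.** Occupancies are doubles holding exact integers; the
  simulator errors beyond `2^53`.

## What the bundled examples emulate

The fixtures are idealized study systems, not data: a one-vertex chain
(everything in closed form), a ring of `L` states open only at state 0
(mean profile `sum_{r<t} p Q^r[0, ]`; its internal cycle can make `Q`
periodic, which is why periodicity is a warning), the symmetric three-state
chain `Q = q(J - I)` with coupled arrivals (spectral radius `2q`, flat
stationary mean `1/(2 - 4q)`, closed-form matrix powers), and a three-state
chain with two arrival sources and one closed state. Passing tests on these
systems demonstrates the internal consistency and exactness of the engines
under the model's assumptions — independent particles, time-homogeneous
`Q`, stationary arrivals. They say nothing about whether a given real
system *satisfies* those assumptions: interacting particles, time-varying
rates, or non-stationary inflow are outside the model class.

Problem sizes in the suite were chosen to make the statistical checks sharp
at small cost: replicate ensembles of 2000 runs for the transient
recursions, single runs of `2e5`–`1e6` steps for stationary estimates, and
a `5e5`-step run of the three-state system for the correlation comparisons
(matching the scale at which the spatial and temporal correlation curves
have standard errors of a few times `1e-3`).

## Design notes on open corners

* For the ring, the stay probability at the open state 0 is taken as zero:
  a particle there jumps to 1, to `L - 1`, or exits with `1 - a - b`.
* Time-dependent arrival moments are accepted by `mean_step()` /
  `var_step()` (the recursions hold verbatim); the stationary solvers
  require time-invariant protocols by construction.
* The closed-form expressions for the three-state stationary covariance and
  correlations as explicit rational functions of `(p, q)` are unwieldy and
  easy to mistranscribe; the package computes `kappa` numerically from the
  Stein solve and validates it against simulation instead.

## Limitations

Cumulants above order 2 are not propagated (the m.g.f. route could in
principle deliver them, but no closed recursion is provided). The exact
oracle is exponential in `S` and practical only for `S <= 3` with small
caps. Continuous-time chains, interacting particles, and time-varying jump
matrices are out of scope.
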