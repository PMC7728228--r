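---
title: "Maximum Caliber network inference: models, approximations, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum Caliber network inference: models, approximations, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maxcalnet)
```

## The model

The data are discrete-time activity trajectories at the nodes of an unknown
network: spins $v_i(t) \in \{-1,+1\}$ (a neuron firing or silent per tick)
or nonnegative copy numbers (proteins per cell).  Maximum Caliber selects
the distribution over whole trajectories that maximizes path entropy subject
to reproducing the observed first moments $M_i(t)$ and second moments
$\chi_{ij}(t,s)$.  The maximizer is the exponential family

$$P_\Gamma = \frac{1}{Z}\exp\Big[\sum_{i,t} h_i(t)\,v_i(t)
  + \tfrac12 \sum_{i,t,j,s} K_{ij}(t,s)\, v_i(t)\, v_j(s)\Big],$$

with biases $h$ and couplings $K$ as Lagrange multipliers.  Everything in
this package is organized around recovering $(h, K)$ from moments.

**Coupling convention.**  $K$ is stored symmetric under
$(i,t)\leftrightarrow(j,s)$, with the $\tfrac12$ in the exponent, so each
unordered site pair contributes $K\,v\,v$ once.  Under this convention the
linear-response identity $K' = -C^{-1}$ (off-diagonal) and the Gaussian
closed form $K = -C^{-1}$ hold without factor bookkeeping; the exact oracle
tests confirm there is no residual factor-of-two anywhere in the chain.
For spins, the zero-lag self-coupling $K_{ii}(t,t)$ multiplies $v^2 = 1$ and
is degenerate with the normalizer; it is gauge-fixed to 0.

**Stationary form.**  Time-translation-invariant systems use
$K_{ij}(\tau)$ with $\tau = |t-s|$, and constraints averaged over all valid
$(t, t+\tau)$ windows and samples jointly.  Windows at the trajectory edges
simply contribute the lags they contain (valid-window averaging).

## Exact solver (the oracle)

For $NT \le 20$ binary sites the trajectory space is enumerated
($2^{NT}$ states; routine tests stay at $NT \le 12$).  The inverse problem
is the convex dual of moment matching: minimize
$\log Z(\theta) - \theta^\top m^\ast$, whose gradient is (model moments $-$
target moments) and whose Hessian is the feature covariance.  The solver is
a damped Newton iteration with step halving on the dual objective;
convergence is declared when the largest moment residual falls below
`tol = 1e-10` and a fit is rejected as infeasible when the residual stays
above $\sqrt{\texttt{tol}}$ or any multiplier exceeds 10 in magnitude (a
multiplier of 10 already pins a spin moment within $5\times10^{-9}$ of its
boundary, so larger values indicate deterministic, non-realizable targets).

## The two approximations

**Uncoupled.**  Force all cross-couplings to zero and fit each node's
$(\tilde h_i, \tilde K_{ii})$ so the single-node model reproduces that
node's own moments exactly.  This is the forward-KL optimum; the residual of
the per-node moment match is driven below $10^{-8}$ by construction.  The
neglected interactions are absorbed into the effective fields (the
reverse-KL/mean-field view), which is what makes the biases correctable
afterwards.  For stationary problems each node is a
$(\tau_{\max}+1)$-consecutive-spin window problem — four spins at the
default lag range — with a uniform bias and lag couplings, solved by
enumeration.  A finite window has edge spins with fewer lag neighbours than
an infinite chain, so the fitted $\tilde h$ absorbs a small edge deficit;
this is visible when re-simulating an uncoupled model as a long chain (its
mean activity sits slightly below the data's) and is documented as a known
systematic of the four-spin construction.

**Linear Coupling.**  Cross-couplings from linear response,
$K'_{ij}(t,s) = -(C^{-1})_{ij}(t,s)$ for $i \ne j$ (within-node entries come
from the Uncoupled stage, never from $C^{-1}$), then the one-pass mean-field
bias correction
$h'_i = \tilde h_i - \sum_{j \ne i}\sum_s K'_{ij}(t,s) M_j(s)$ using the
empirical means — no self-consistent iteration, since the correction is a
direct formula.  For stationary problems the sum over $s$ runs over both
signs of the lag: $h'_i = \tilde h_i - \sum_{j\ne i}\,[K'_{ij}(0) +
2\sum_{\tau\ge1} K'_{ij}(\tau)]\, M_j$.

**Covariance assembly and the inversion window.**  Stationary covariances
are assembled as an $(NW)\times(NW)$ block-Toeplitz matrix over a window of
$W$ time slices and inverted; equal-lag blocks of the inverse are averaged
and symmetrized in $(i,j)$ (`linear_coupling_K`, default
$W = \tau_{\max}+1$).  A coupled chain's correlations do not terminate at
the coupling range, so inverting a window only as wide as that range folds
out-of-window correlation into the retained couplings — a small positive
inflation that is independent of sample size and gets amplified by the
$N-1$ terms of the mean-field bias correction.  `infer_network` therefore
estimates constraints out to $2(\tau_{\max}+1)-1$ lags, inverts over the
full available window, reads couplings from central blocks only (edge
blocks are dropped via the `margin` argument), and truncates the reported
couplings to the coupling range.  Conditioning: a reciprocal condition
number below $10^{-10}$ raises an error suggesting more samples or the
optional ridge term (off by default; recorded in the result's attributes
when used).

## The Gaussian benchmark

Two stationary, jointly Gaussian agents with auto-covariance blocks $C_A$
and cross-covariance $C_C$ are exactly solvable ($K = -C^{-1}$,
$h = -KM$), which makes the error of Linear Coupling computable in closed
form.  With $B = C_A^{-1} C_C$, the reconstructed covariance is
$C' = -(K')^{-1}$ and the first-order reconstruction error
$\lVert B^2 C\rVert / \lVert C\rVert$ is bounded by $\alpha = \lVert
B\rVert^2$.  Two definitional choices deserve note:

* The norm is the matrix 2-norm (largest **singular** value).  $B$ is not
  symmetric in general, so its largest eigenvalue magnitude can be smaller;
  the singular-value norm is the one for which the submultiplicative bound
  is actually a theorem, and it is conservative with respect to the
  eigenvalue reading.
* The closed form $C' = (I - B^2)^{-1} C$ is exact only when $C_A$ and
  $C_C$ commute (e.g. both diagonal); for generic blocks $-(K')^{-1}$ is
  symmetric while $(I-B^2)^{-1}C$ is not, and they agree to $O(B^2)$.
  The function reports both `err_linear` $= \lVert B^2C\rVert/\lVert
  C\rVert$ (the bounded quantity, always $\le \alpha$) and `err_exact`
  $= \lVert C'-C\rVert/\lVert C\rVert$, which carries an extra factor
  $\lVert(I-B^2)^{-1}\rVert$ and can slightly exceed $\alpha$ at large
  $\lVert B\rVert$.

`gaussian_instance` constructs seeded instances with a prescribed
$\lVert B\rVert$; positive definiteness of the block covariance is
automatic because $\lVert B\rVert < 1$ implies $C_A \pm C_C \succ 0$.
Instances become invalid at spectral radius $\ge 1$ (outside the
perturbative regime) and are refused.

## The genetic toggle switch

Two genes, each producing a protein that represses the other.  Per interval
$\delta t$: at most one new protein per gene ($l_\alpha, l_\beta \in
\{0,1\}$), and each existing protein survives or degrades (binomial
multiplicity), with step law
$P \propto \binom{N_A}{l_A}\binom{N_B}{l_B}
e^{h_P[l_\alpha+l_\beta] + h_S[l_A+l_B] + K[l_A l_\beta + l_B l_\alpha]}$.
The exact sampler uses the algebraic factorization of this law into
independent $(l_A, l_\beta)$ and $(l_B, l_\alpha)$ pairs (production from
its exact marginal, then survivors binomial with logistic success
probability), which is identical to enumerating the full event space but
costs $O(1)$ per step and vectorizes across chains.

The Uncoupled analysis gives effective fields $\tilde h_{S,A} = h_S +
K\langle l_\beta\rangle$, $\tilde h_{P,A} = h_P + K\langle l_B\rangle$,
stationary points $N_A = \Lambda e^{K N_B}$, $N_B = \Lambda e^{K N_A}$ with
$\Lambda = e^{h_P + h_S}$, and the critical repression
$K_c = -e^{1-h_P-h_S}$.  These closed forms are the **short-interval
limit**: they assume at most one event per tick dominates the partition
function, i.e. $h_P \ll 0 \ll h_S$ at fixed $\Lambda$.  The package's
canonical demonstration fields are $h_P = -6$, $h_S = 10$
(`toggle_example_params`): production probability $\sim e^{-6}$ per tick,
degradation $\sim e^{-10}$ per molecule per tick, $\Lambda = e^4 \approx 55$
proteins — copy numbers typical of a strongly expressed bacterial circuit —
where the finite-interval correction to the fixed points,
$(1+e^{-h_S})/(1+e^{-h_P}) - 1$, is below 0.3%.

**Stability.**  The force field is $F_A = \Lambda e^{K N_B} - N_A$ (and
symmetrically $F_B$); its Jacobian at a fixed point has eigenvalues
$-1 \pm K\sqrt{N_A N_B}$, so a point is stable iff $K^2 N_A N_B < 1$.
Long simulations confirm the convention: started at the asymmetric points
of a subcritical switch, trajectories stay; started at the symmetric point,
they break symmetry and leave.  (Reading the scalar derivative
$dF_A/dN_A = K^2 N_B N_A - 1$ with the usual "stable when negative" rule
gives the same classification; the two-dimensional eigenvalue argument is
the one the package trusts and tests.)

**Fixed-point finding.**  The symmetric point is the unique root of
$N = \Lambda e^{KN}$ on the diagonal (monotone bracketing).  Asymmetric
points reduce to the scalar composed map $N = \Lambda\exp(K\Lambda e^{KN})$,
which is increasing; below the symmetric point there is at most one root,
detected by minimizing the residual with `optimize` and bracketing when the
minimum is negative.  The numerical bifurcation detector
(`toggle_bifurcation_K`) bisects $K$ on the predicate "slope of the composed
map at the symmetric point exceeds one", with the slope from central finite
differences — deliberately independent of the closed form it is tested
against.

**Occupancy.**  The Uncoupled stationary distribution is Poisson at a
stable fixed point; subcritical switches get an equal-weight two-Poisson
mixture for the per-protein marginal (equal weights are forced by the
A/B exchange symmetry).  Near the critical point
($|K^2 N_0^2 - 1| < 0.05$) the prediction is returned flagged
`known_inaccurate`: there the occupancy is broad and non-Poissonian and the
factorized theory fails by construction.  Two quantitative cautions,
verified by simulation against the exact sampler:

* The mixture is accurate **deep** in the bistable regime.  At $K$ only
  modestly below $K_c$ (e.g. $1.5 K_c$) the per-basin occupancy is visibly
  over-dispersed relative to Poisson, because each gene's effective field
  fluctuates adiabatically with the opposing copy number; the extra
  variance ratio scales like $(fe)^2 e^{-fe}$ at $K = f K_c$ and is
  essentially independent of $\Lambda$.  The canonical subcritical point is
  therefore $K = 3K_c$, where this effect is at the percent level.
* Mixture weights in a finite simulation reflect basin occupancy; chains
  are slow to switch deep in the bistable regime, so occupancy comparisons
  pool both protein marginals (the exchange symmetry then enforces the
  ½/½ weights exactly) and split initial conditions across both basins.

## The synthetic neural network

The ground truth (`neural_ground_truth`) is a stationary dynamic Ising
model of $N = 40$ neurons: uniform bias $h_0 = -0.1$ (neurons tend to
silence), pair couplings drawn once per unordered pair per lag from
$\mathcal N(K_0 a^{-\tau}, (K_\delta a^{-\tau})^2)$ with
$K_0 = K_\delta = 0.015$ and $a = 4$, strong self-couplings
$K_{ii}(\tau) = 20 K_0 a^{-\tau}$ for $\tau \ge 1$ (zero at $\tau = 0$ by
the spin gauge), couplings beyond $\tau_{\max} = 3$ set to zero, and a
global inverse temperature $\beta$ scaling all multipliers.  At $\beta = 1$
the summed coupling per site is slightly above the mean-field critical
value, so the network sits near criticality: mostly silent, with weak
pairwise correlations that occasionally sum into avalanches — transient
positive spikes of the synchrony $s(t) = \sum_i v_i(t)/N$.

**What the generator emulates, and what it does not.**  It reproduces the
statistical skeleton of cortical population recordings — silence-dominated
activity, weak heterogeneous couplings, short coupling memory, avalanche
bursts — but it is a time-translation-invariant equilibrium model on a
fixed lattice of length $T$: no non-stationarity, no external stimulus, no
refractory dynamics, no spatial structure.  Passing tests on it shows the
inference machinery is correct and well-calibrated for weakly coupled
near-critical spin systems; it does not certify performance on recorded
spike trains.

**Sampling.**  `sample_network` draws whole space-time configurations from
$P_\Gamma$ with single-site Metropolis flips (compiled; one sweep $= NT$
random-site flip attempts; proposals accepted with probability
$\min(1, e^{\Delta})$ on the log-weight).  Defaults retain one
configuration every 2–4 sweeps after a burn-in of a few hundred sweeps; the
production runs behind the package's quantitative checks use trajectory
lengths $T = 256$–$1000$ and 150–250 retained configurations, i.e. on the
order of $10^7$–$10^8$ elementary flips — sized so that doubling the chain
length leaves the measured moments unchanged within their Monte-Carlo
error.  The sampler is validated against exact enumeration on small systems
(moments within three Monte-Carlo standard errors).  The default initial
configuration is all-silent, which is adjacent to the dominant activity
branch; random initializations converge to the same moments but need longer
burn-in because the early transient carries inflated pairwise correlations.
That transient matters for one reported quantity: the mean pairwise
equal-time correlation of the ground truth at $\beta = 1$ is
protocol-dependent under short budgets (drifting from $\approx 0.03$ after
two sweeps from a random start down to its equilibrium value
$\approx 0.012$), so the package always reports the equilibrated value.

**Inference pipeline.**  `infer_network` chains the per-neuron four-spin
Uncoupled solves, the wide-window covariance inversion with central-block
readout, and the mean-field bias correction; couplings beyond
$\tau_{\max} = 3$ are zeroed (at lag 4 the ground-truth couplings are
$a^4 = 256$-fold weaker than at lag 0 and are safely neglected).  Because
the method is first-order in the couplings, reconstruction near $\beta = 1$
(the critical point, the worst case) carries small systematic offsets:
inferred cross-couplings are slightly inflated and the reconstructed biases
land within a fraction of their cross-neuron scatter of $h_0$ rather than
exactly on it.  Both effects shrink quadratically as $\beta$ decreases —
the package's property tests check exactly this decay against the
enumeration oracle.

**Synchrony.**  `synchrony_analysis` histograms $s(t)$ on its native
discrete support (multiples of $2/N$; no smoothing), and `beta_sweep` runs
the full loop — scale truth, sample, infer both approximations, re-simulate
each inferred model — recording mean, variance and spike frequency of $s$.
The scientific content: all three models track the mean synchrony, but only
the Linearly Coupled model tracks its variance (the avalanche
fluctuations), at every $\beta$ visited.  "Tracks the mean" is asserted at
5% of the $[-1,1]$ range of $s$ rather than at Monte-Carlo error, because
the re-simulated approximate models have small systematic offsets in
$\langle s\rangle$ (the four-spin window edge bias for the Uncoupled model,
residual coupling inflation for the Linearly Coupled one) that any
sufficiently long chain resolves.

## Numerical choices, degenerate inputs, RNG

* Exponential-family fits: damped Newton from $\theta = 0$, ridge
  $10^{-12}$ on the Hessian solve, step halving (factor 2, floor
  $10^{-12}$); tolerance $10^{-10}$ on the maximum moment residual.
* Ties in toggle basin attribution ($N_A = N_B$) occur on a measure-zero
  set of the pooled comparisons and are irrelevant to the pooled-marginal
  occupancy used throughout.
* Degenerate constraints: perfectly correlated covariances are refused at
  reciprocal condition number $10^{-10}$; boundary moments (e.g.
  $|M| = 1$) are refused as infeasible rather than returned as divergent
  multipliers.
* All stochastic operations take a single integer seed and are reproducible
  bit-for-bit (`set.seed` drives both the R-level samplers and the compiled
  Metropolis kernel, which consumes R's own RNG stream).
* Problem sizes in the routine test suite are deliberately desk-scale:
  enumerations at $NT \le 12$, toggle runs of $10^5$–$3\times10^5$ steps
  across 40 chains, neural chains of $T = 256$–$1000$ with a few hundred
  retained configurations.

## Known limitations

* First-order theory: no TAP/Plefka second-order corrections, no Bethe
  approximation, no variational schemes beyond the factorized family.
* Binary spins and toggle-style count processes only; no general
  multi-state alphabets, and no continuous-time master-equation inference.
* The Gaussian error bound is specific to the two-agent block structure;
  there is no general-$N$ bound.
* The four-spin Uncoupled window inherits edge effects (quantified above);
  reconstructed biases at strong coupling are accurate to the cross-node
  mean-field scale, not to Monte-Carlo precision.
* Empirical covariances from short ensembles can be ill-conditioned; the
  ridge option trades a documented bias for invertibility and is off by
  default.
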