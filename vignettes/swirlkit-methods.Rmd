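---
title: "swirlkit: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{swirlkit: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

swirlkit is an agent-based simulator of collective animal motion under
severely limited perception, with behaviour *learned* by policy-gradient
reinforcement learning rather than prescribed by interaction forces. This
vignette records the models it implements, the assumptions behind them,
the tunable parameters and their defaults, and the numerical and design
choices made where the problem statement left the design open. It states
no empirical result that the package's tests and acceptance script do not
themselves compute.

## The behavioural model

Agents are point-like animals in the plane. An agent never observes
coordinates, distances or speeds as numbers. Its world is summarised by a
handful of binary indicators — "am I inside my comfort zone?", "am I
getting closer?" — plus unit direction vectors (its own heading, its
nearest neighbour's heading, the group's mean heading) and the force it
exerted at the previous step. Behaviour is a stochastic policy
$\pi_\theta(\mathbf a \mid \mathbf s)$: a diagonal Gaussian over 2-D
actions whose mean $\mu_\theta(\mathbf s)$ and standard deviation
$\sigma_\theta(\mathbf s)$ are produced by a three-layer fully connected
network (hidden width 128, ELU activations, exponential activation on the
$\sigma$ head so that $\sigma > 0$ always).

Learning is EPISODIC REINFORCE: run $n$ episodes of length $T$, compute
discounted returns with $\gamma = 0.9$, and ascend
$\theta_{k+1} = \theta_k + \eta\, \nabla_\theta \langle R \rangle_k$ with
the score-function estimator. We use the discounted *reward-to-go* $G_t$
as the per-transition weight and subtract, by default, the across-episode
mean of $G_t$ at each time step (a control variate; it changes the
variance of the estimator but not its mean — one of the test suite's
property checks). Setting `baseline = FALSE` recovers the literal
estimator.

### Escort (one leader, one follower)

The follower must keep its distance to an independently moving leader
inside the band $d_t \pm e_t$, knowing only the band indicator $S_d$, the
approach indicator $S_a$, the two heading vectors and its own last force
— an 8-component state. Three control regimes are implemented: direct
velocity control (A), velocity control with an acceleration cap (B), and
force-only control with a force cap (C, the realistic one, reused by all
swarm tasks). Rewards: $r_{\mathrm{target}}$ inside the band, else
$r_{\mathrm{pursuit}}$ when approaching, else $r_{\mathrm{recede}}$.

### Swarm motion and swirling

$N$ identical agents each escort the *group centre*: the state
(12 components) carries the comfort-zone indicator w.r.t. the nearest
neighbour, the approach indicators for neighbour and centre, the
centre-zone indicator, and the heading vectors of neighbour, self and
group. The reward is the escort reward w.r.t. the group centre plus an
additive penalty $r_{\mathrm{intrude}} < 0$ whenever the nearest
neighbour sits inside the agent's comfort zone. All agents learn
simultaneously; every agent is rewarded individually and no information
is exchanged beyond what the observation encodes.

Swirling (milling) is quantified by the mean angular velocity
$$\Omega = \frac1N \sum_i \left(\mathbf v_i - \mathbf v_{gc}\right)
  \times \frac{\mathbf x_i - \mathbf x_{gc}}
              {\lVert \mathbf x_i - \mathbf x_{gc} \rVert^2},$$
where $\times$ is the scalar 2-D cross product taken in the operand order
written here, so a *counterclockwise* rigid rotation at rate $\omega$
gives $\Omega = -\omega$; the magnitude $|\Omega|$ is the reported swirl
strength. $\Omega$ vanishes for rigid translation and is Galilean
invariant and parity-odd (all property-tested).

### External perturbation

A force of fixed random direction (per episode) and stretched-exponential
magnitude
$$P(f \mid f_0, \beta) = \frac{1}{f_0}\frac{\beta}{\Gamma(1/\beta)}
  e^{-(f/f_0)^\beta}$$
pushes every agent; the magnitude is re-drawn every `modulation_period`
steps (default 50 — the modulation periodicity is not specified in the
source material). Sampling is exact via the gamma transform
$f = f_0 G^{1/\beta}$, $G \sim \Gamma(1/\beta, 1)$, verified against
numerical quadrature of the density. The resistance experiment compares
the swarm-centre shift along the force direction between a swarm trained
*with the field active* (direction re-randomised each episode) and an
untrained swarm (freshly initialised policies, whose broad Gaussian head
approximates state-independent random action).

### Locomotion in viscous fluid

Spherical agents of radius $a$ at low Reynolds number interact through
the Rotne–Prager mobility tensor; motion is overdamped, so
$\mathbf v_i = -\sum_j \hat\zeta_{ij} \mathbf F^e_j$ with
$\hat\zeta_{ii} = \hat I/(6\pi\eta a)$ and the standard far-field pair
block, restricted to its in-plane $2\times2$ part because all motion is
planar. The power dissipated by a rigidly translating swarm is
$P = (6\pi\eta a)^{-1} \sum_i \lVert \mathbf F_i^a \rVert^2$, reported in
units of the solo power $6\pi\eta a \lVert v \rVert^2$ ("specific
dissipation", 1 for a lone agent). Two routes to the optimal formation
are implemented: direct multi-start minimisation of $P$ over positions,
and an RL task in which followers trail a constant-velocity leader and
pay an energy penalty $c_E \lVert \mathbf F \rVert^2$ once settled.

## Parameters, units and defaults

Lengths, times and forces are dimensionless; agents have unit mass, so
force and acceleration coincide.

| parameter | meaning | default | why |
|---|---|---|---|
| `dt` | Euler step | 0.1 | resolves orbits of radius $\sim d_t$ at the available force scale |
| `T_steps` | episode length | 500 | several orbital periods at the defaults |
| `gamma` | discount | 0.9 | stated by the model; horizon $\sim 10$ steps |
| `d_t` | target radius / band centre | 1 | sets the length unit |
| `e_t` | escort band half-width | 0.2 | perceptibly narrow but reachable |
| `d_cz` | comfort-zone radius | 0.15–0.3 | see crowding note below |
| `F_max` | force bound | 1 | orbit of radius $d_t$ at unit speed is marginally feasible |
| `v0` | max initial speed | 0.5 | below the orbital speed scale |
| `lr` | learning rate $\eta$ | $10^{-3}$ | largest value stable without capping on the bandit |
| `n` | episodes per update | 16 | variance/cost compromise |
| `r_target, r_pursuit, r_recede, r_intrude` | reward constants | $1, 0.1, -0.1, -0.5$ | only the ordering is mandated; magnitudes are package choices |
| `c_energy` | energy penalty | 0.1 | makes the dissipation term a perceptible fraction of $r_{\mathrm{target}}$ |
| `a`, `eta_fluid` | agent radius, viscosity | $1, 1/(6\pi)$ | makes the Stokes drag coefficient 1 |

Crowding: with $N$ agents asked to stay within radius $d_t$ of their
centre while defending private disks of radius $d_{cz}$, the area ratio
$N d_{cz}^2 / (2 d_t)^2$ controls how much the comfort zones compete for
room inside the target disk. The regime depicted for milling swarms has
visibly packed comfort zones; configurations in that regime use
$d_{cz} \approx 2 d_t \sqrt{\phi / N}$ with packing fraction
$\phi \sim 0.7$ (about $0.3$ for $N = 25$, $d_t = 1$).

## Numerical choices

* **Integrator.** Semi-implicit Euler, velocity before position; fixed
  and documented so trajectories are bitwise reproducible.
* **Boundary convention.** $H(0) = 1$ everywhere: a zone boundary counts
  as inside. Approach indicators are backward differences over one step
  and are 0 at the first step and on ties.
* **Zero-velocity headings.** The unit direction of a (near-)zero vector
  is the $(0,0)$ sentinel, keeping the observation map deterministic.
* **Bounded actions.** Sampled actions are norm-clipped to the physical
  bound; the log-density in the estimator is evaluated at the *raw*
  Gaussian draw, which keeps the estimator unbiased for the pre-clip
  distribution. (The exact bounded-normal construction used by the
  original study is not printed; post-hoc clipping is our documented
  approximation.)
* **$\sigma$ guard rails.** The $\sigma$-head pre-activation is clamped
  to $[\log 0.02, \log 50]$ and its gradient zeroed at the rails. An
  unguarded exponential head collapses ($\sigma \to 0$ makes the score
  function explode) — observed, not hypothetical.
* **Gradient cap.** Training applies plain gradient ascent with a global
  gradient-norm cap (default 10, direction-preserving) purely as a
  divergence guard; `policy_update()` itself defaults to the uncapped
  printed rule.
* **Optimizer.** Plain ascent is the default everywhere; `make_optimizer`
  also provides Adam (`optimizer = "adam"`, lr `3e-4` recommended) as the
  configurable alternative. At desk-scale budgets plain ascent on the
  swarm task is seed-fragile — some seeds never reach a cohesive swarm —
  while Adam does so reliably; the acceptance experiments therefore use
  Adam and say so. Even then some seeds fail to converge, so the
  resistance experiment trains up to two candidate policies (derived
  seeds) and keeps the one whose *force-free* evaluation episode has the
  smaller final extent, stopping early when the extent is bounded
  (below 3 target radii -- an untrained swarm disperses to 10-30).
  Selection looks only at this training-success check, never at the
  measured shift ratio, which is computed afterwards on fresh paired
  trial seeds.
* **Group centre under finite perception.** With perception radius
  $R_p < \infty$, "group centre" means the centroid of the perceived
  subset (self plus agents within $R_p$), which reduces to the global
  centroid when $R_p = \infty$. How the original model treats partially
  perceived groups is not specified; this is one consistent reading.
* **Minimum separation $2a$** is enforced in the hydrodynamic optimiser
  (the far-field tensor is invalid below contact and the optimum would
  otherwise degenerate), via a smooth quadratic penalty with increasing
  stiffness and a derivative-free polish. The RL locomotion environment
  instead clamps sub-contact separations inside the tensors
  (direction-preserving) so that an exploring policy cannot crash the
  linear solve; the optimiser-vs-RL comparison uses the comfort-zone
  radius as the optimiser's separation floor, since that is the distance
  the reward actually defends.
* **Counting optima.** Minima within a relative specific-power tolerance
  of the best are clustered modulo translation and agent relabelling;
  mirror images about the motion axis are counted as distinct (the
  triplet's two realisations).

## Design decisions on open points

* **Shared vs per-agent networks.** Both are implemented. The package
  default for swarm experiments is a *single shared* policy updated from
  every agent's individually rewarded transitions: the agents are stated
  to be identical and to follow the same action policy, and sharing
  multiplies the effective batch per update by $N$, which matters at desk
  scale. `shared = FALSE` gives each agent its own network trained only
  on its own rewards (the strictest reading of "independently"); an
  isolation contract test guarantees no gradient crosses agents.
* **Reward-to-go vs whole-episode return.** The weight on
  $\nabla \log \pi(a_t \mid s_t)$ is $G_t$ from $t$ onward. Whether the
  original uses $G_t$ or the whole-episode $R$ for every $t$ is not
  printed; reward-to-go is the lower-variance unbiased variant.
* **Intrusion penalty is additive** to the centre-escort base term (one
  consistent reading of "penalised if someone breaks into its comfort
  zone").
* **Rewards are functions of the pre-action state** $r_t = r(s_t)$,
  matching the printed description of computing $r(\mathbf s_0), \ldots,
  r(\mathbf s_T)$ along a trajectory.
* **Initial conditions.** Positions uniform in a disk of radius
  $2 d_t$; speeds uniform on $[0, v_0]$ with uniform heading. The source
  states only "random"; these are the package's fixed choices.

## What the synthetic world does and does not establish

Everything here is simulation: the package generates its own data, and a
green test establishes properties *of the model*, not of any animal
system. The desk-scale training budgets (tens of minutes of one CPU)
are far below the original experiments (hundreds of agents,
thousands of updates); the acceptance suite therefore checks reduced
surrogates — ordering and emergence properties at small $N$ and short
training — and the full-scale headline numbers (e.g. the
hundred-fold resistance ratio) are explicitly *not* reproduced at desk
scale. Quantities with exact oracles (Rotne–Prager algebra, the
stretched-exponential sampler, discounted returns, the gradient
estimator) are tested tightly; training outcomes are tested as
stochastic properties with fixed seeds.

## Known limitations

* REINFORCE without a learned baseline or trust region is sample-hungry;
  desk-scale swarm policies are under-converged relative to the source
  experiments. Concretely: trained swarms become cohesive (bounded extent
  while an untrained control disperses) and an order of magnitude more
  resistant to mid-range external forces, but coherent milling — a
  time-averaged $|\Omega|$ well above the untrained noise floor in nearly
  every seed — did not emerge within any configuration we could afford
  (up to $\sim$4x the shipped training budget, two optimizers, several
  learning rates and crowding regimes). The corresponding emergence
  assertion in the acceptance suite is deliberately left failing rather
  than weakened; the source experiments used roughly 45x more
  simulation.
* No 3-D motion, no visual-cone perception, no topological neighbours.
* The Rotne–Prager far field has no lubrication correction; results
  within a diameter of contact are regularised, not physical.
* A single global RNG stream drives each run; reproducibility is
  guaranteed for a fixed configuration, not across changes of $N$ or
  episode count.
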