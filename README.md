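# mnler — mixed neural likelihood estimation for decision-making models

`mnler` performs simulation-based Bayesian inference for cognitive
decision-making models whose observations mix a discrete choice with a
continuous reaction time — the drift-diffusion model (DDM) being the
canonical example. Such models are easy to *simulate* but, beyond the
simplest variant, their likelihood cannot be evaluated, which blocks
standard Bayesian inference.

The package trains a **mixed neural likelihood estimator (MNLE)** on
simulated parameter/data pairs: the joint likelihood of a trial
`x = (c, rt)` given parameters `θ = (v, a, w, τ[, γ])` is factorized as

    q(c, rt | θ) = q(c | θ) · q(rt | c, θ)

with a Bernoulli choice network for the discrete part and a conditional
rational-quadratic spline flow over log reaction times for the continuous
part. Both are trained by maximum likelihood on the *same* `N` simulations
(one trial per prior draw; the reference budget is `N = 1e5`). The trained
estimator is exactly normalized, can be sampled as an *emulator* of the
simulator, and plugs into slice-sampling MCMC through the i.i.d. joint
potential

    p(θ | X) ∝ Π_i q(c_i, rt_i | θ) · p(θ),

so one training run amortizes over observations with any number of trials.
For the constant-bound DDM the package also implements the analytic Wiener
first-passage-time (WFPT) likelihood, giving reference posteriors against
which the learned ones are validated; for the collapsing-bound DDM (no
tractable likelihood) MNLE is the only route, validated by calibration and
posterior-predictive checks.

The neural components are implemented from first principles (vectorized
forward/backward passes, analytic spline gradients verified against finite
differences, Adam), with compiled (C++) forward passes for the MCMC hot
path and a compiled Euler–Maruyama DDM simulator with Brownian-bridge
boundary correction.

## Worked example

```r
library(mnler)

prior <- ddm_prior()                                   # v, a, w, tau box prior
ts    <- generate_training_set(prior, 20000, seed = 1) # simulate training data
est   <- train_mnle(ts$theta, ts$trials, prior = prior, seed = 1)

# an "observed" session: 100 trials from known parameters
truth <- c(v = 0.8, a = 1.3, w = 0.45, tau = 0.5)
obs   <- simulate_ddm(truth, 100, seed = 2)

cfg  <- mcmc_config(n_chains = 4, n_samples = 400, burn_in = 150, thin = 2)
post <- ddm_posterior(obs, prior, backend = "mnle", est = est,
                      config = cfg, seed = 3)
ref  <- ddm_posterior(obs, prior, backend = "analytic",
                      config = cfg, seed = 3)
print(post)
posterior_metrics(post, ref, true_params = truth)$c2st
```

Output of this exact script:

```
Posterior samples: 400 draws, 4 chains (mnle backend)
          v      a      w    tau
mean 0.8520 1.2432 0.4545 0.5271
sd   0.2607 0.0814 0.0368 0.0191
[1] 0.91375
```

The learned-likelihood posterior recovers the generating parameters
(`v = 0.8, a = 1.3, w = 0.45, tau = 0.5`) with honest uncertainty. The
classifier two-sample test (C2ST) against the reference posterior reads
0.5 when the two are indistinguishable and 1.0 when completely separable:
at this deliberately small training budget (2 x 10^4 simulations, chosen so
the example runs in about a minute) the posteriors are still clearly
distinguishable (0.91). At the reference budget of 10^5 simulations the
mean C2ST over prior-sampled observations drops to about 0.70, which is
what `scripts/acceptance.R` measures.

Every user-facing step has a command-line equivalent (`inst/cli/mnler`):

```sh
mnler simulate --model ddm --n 100000 --seed 1 --out-dir data/
mnler train    --params data/params.csv --trials data/trials.csv --out est.json
mnler infer    --obs session.csv --checkpoint est.json --out posterior.csv
mnler diagnose c2st --a posterior.csv --b reference.csv
```

## Diagnostics included

* `likelihood_accuracy()` — Huber/MSE of learned vs analytic
  (log-)likelihoods under the fixed-observation × 1000-prior-draws
  protocol;
* `c2st()` — cross-validated classifier two-sample test between posterior
  sample sets;
* `sbc()` — simulation-based calibration with rank-uniformity KS tests;
* `posterior_metrics()` — normalized mean/variance differences, recovery
  MSE, C2ST;
* `predictive_check()` — observed vs prior-/posterior-predictive choice
  fractions and reaction-time quantiles.

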