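# rmsorn

Reward-modulated self-organizing recurrent networks (RM-SORN) in R.

Reservoir networks of binary threshold neurons can learn temporal
structure purely through local plasticity. This package simulates a
two-layer model in which a sparse excitatory reservoir (with an
inhibitory pool, 5:1 ratio) self-organizes through three interacting
rules — intrinsic plasticity (IP), synaptic normalization (SN) and
spike-timing-dependent plasticity (STDP) — and a winner-take-all readout
learns from a scalar reward instead of a supervised error signal.
It is aimed at computational-neuroscience work on the interaction of
homeostatic and reward-driven plasticity: IP serves as a *deterministic*
exploration drive, replacing the noise used by most reward-modulated
models.

The dynamics are

```
x(t+1) = Θ( W_EE x(t) − W_EI y(t) + u(t) − T_E(t) )     reservoir, binary
y(t+1) = Θ( W_IE x(t) − T_I )                            inhibitory pool
o(t+1) = a( W_OE x(t) − T_O(t) )                         readout (WTA / Θ)
```

with plasticity

```
ΔT_E  = η_IP (x − μ_IP)                                  intrinsic plasticity
Δw_EE = m_r η_STDP ( x_j(t−1) x_i(t) − x_j(t) x_i(t−1) ) recurrent STDP
Δw_OE = m_o η_STDP   x_j(t−1) o_i(t)                     readout STDP
w_ij ← w_ij / Σ_j w_ij                                   synaptic normalization
```

where the modulation `m` is the reward (`m0` strategy) or a
reward-prediction error, reward minus the moving average of the previous
`k` rewards (`mk` strategy). Negative modulation inverts STDP
(anti-STDP under punishment).

Included: seeded generators and scoring rules for eight symbolic
benchmarks (counting, motion prediction, occluder, memory capacity,
Markov-85, parity, motion generation, pattern recognition), the
two-phase snapshot-selection training protocol, SORN / static / random
comparison baselines (the SORN readout is fitted by non-negative least
squares), a bit-flip-noise exploration mode, parameter grid search,
replicated experiment tables, and neuron-selectivity analysis.

## A worked example

```r
library(rmsorn)

# counting task: predict the next letter of random "abbbbc"/"eddddf" words;
# the last letter requires counting the b's/d's
fit <- train_rmsorn(task_spec("counting", n = 4), n_excitatory = 100, seed = 1)
fit
#> RM-SORN fit: task counting (n = 4), N = 100
#>   test performance: 1.0000
#>   counting performance: 1.0000
```

`test performance` is the fraction of correctly predicted, predictable
letters in a fresh 10,000-step test stream (word-initial letters are
unpredictable and excluded); `counting performance` restricts scoring to
the word-final letters, which can only be predicted by counting — here
the trained network predicts both perfectly. Replicated experiments and
baselines:

```r
res <- run_experiment("counting", n = 4, n_excitatory = 100,
                      variant = "rmsorn", datasets = 5, networks = 2,
                      seed_base = 1)
summarize_experiment(res)
```

A thin command-line front end ships in `inst/scripts/rmsorn`:

```sh
Rscript inst/scripts/rmsorn run --task counting --n 8 --size 100 --seed 3
Rscript inst/scripts/rmsorn baseline --kind sorn --task counting --n 8 --size 100
Rscript inst/scripts/rmsorn sweep --config grid.yaml
```

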