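# synitl — synergistic information-theoretic learning for small neural networks

`synitl` trains feedforward and fully recurrent neural networks with a pair
of information-theoretic plasticity rules and studies how they interact:

* **Synaptic rule — minimization of error entropy (MEE).** Instead of the
  mean squared error, training maximizes the quadratic information
  potential of the prediction errors,

      V(e) = (1/N²) Σᵢ Σⱼ G_{σ√2}(eⱼ − eᵢ),

  the Parzen-window estimate of ∫p(e)²de, so that the whole error
  distribution — not just its first two moments — is squeezed toward a
  delta function. Weights follow steepest ascent on V (equivalently,
  descent on the Renyi quadratic entropy H₂ = −log V), epochwise, with
  exact backpropagated error-weight derivatives for the feedforward
  network and real-time recurrent learning (RTRL) sensitivities for the
  recurrent one. Because entropy is blind to the error mean, a final
  additive output bias cancels the mean training error.

* **Intrinsic rule — batch infomax plasticity (IP).** Every neuron has an
  adaptive tanh activation y = tanh(a·x + b). Once per epoch its gain and
  bias ascend the neuron's input-output mutual information
  (E[log|dy/dx|]):

      Δa = η_IP (1/a − 2·Ê[xy]),   Δb = −2 η_IP Ê[y],

  which centres the activation on its input distribution and matches its
  steep region to the input mass.

Run together ("synergistic" training), the intrinsic rule accelerates MEE
convergence and improves the final error on the Mackey-Glass chaotic
prediction benchmark, for both architectures. The package ships the full
experimental harness: a Mackey-Glass generator (RK4 integration of the
delay differential equation), normalization and delay embedding, paired
with/without-IP comparisons over seeded runs, IP-rate and network-size
sweeps, kernel-density distribution diagnostics, JSON/CSV export, and a
command-line runner (`exec/synitl`).

## Worked example

Ten paired runs (same data, same initial weights per seed) of the 5-hidden-
neuron feedforward network on Mackey-Glass, 1000 epochs, with and without
intrinsic plasticity:

```r
library(synitl)

data <- make_benchmark_split(n_train = 300, n_test = 10000, seed = 1)
cmp  <- run_comparison("fnn", data = data, n_runs = 10, base_seed = 1)
cmp
#> Paired MEE comparison (FNN, 10 runs)
#>  condition train_V train_mse test_V  test_mse
#>      no_ip  2.2674 0.0057284 2.2988 0.0053572
#>    with_ip  2.3770 0.0043431 2.4016 0.0041509
#> MSE improvement with IP: 24.18% (train), 22.52% (test)
```

Reading the table: `train_V` is the quadratic information potential of the
training errors (its ceiling at σ = 0.1 is 1/(2σ√π) ≈ 2.82; higher is
better), `train_mse` the mean squared training error after bias
correction, and the improvement row is (MSE_noIP − MSE_IP)/MSE_noIP. The
synergistic condition ends with a visibly higher potential and lower MSE
on training and held-out data alike. The same protocol for the 2-neuron
fully recurrent network (`run_comparison("rnn", ...)`) shows the same
ordering with a larger relative gain.

Single runs, sweeps and diagnostics:

```r
cfg  <- do.call(train_config, default_schedule("fnn"))
cfg$seed <- 42
net  <- init_fnn(5, 4, cfg)
fit  <- train_fnn(net, data$train$inputs, data$train$targets, cfg)
head(fit$curves)                    # epoch, V, mse, mean_gain
evaluate_fnn(fit$net, data$test$inputs, data$test$targets)

sweep_ip_rate(c(0, 5e-4, 1e-3), "fnn", data = data)   # rate comparison
sweep_size(3:8, "fnn", data = data)                   # size comparison
distribution_report(fit)            # Parzen densities, initial vs final
```

Or from the shell:

```sh
exec/synitl compare --model fnn --n-runs 10 --out results/fnn
exec/synitl sweep-ip --model rnn --rates 0,5e-4,1e-3
exec/synitl generate-data --n 2000 --file mg.txt
```

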