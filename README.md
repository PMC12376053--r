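# pod12risk

Risk scoring and chaotic time-series forecasting of early progression
(POD12) in diffuse large B-cell lymphoma (DLBCL).

## The problem

Roughly half of DLBCL patients who progress or relapse within 12 months of
diagnosis (POD12) respond poorly to salvage therapy, so identifying them
*before* first-line treatment is the clinically useful moment. This package
implements a complete, testable POD12 analysis in two halves:

**Cohort half — a points-based clinical score.** Six dichotomized risk
factors (LDH ≥ 250 IU/L, β2-microglobulin ≥ 3 µmol/L, Ann Arbor stage
III–IV, ECOG ≥ 2, NLR ≥ 1.73, SII ≥ 304.2) form the score

    S = 2·[β2-MG] + [LDH] + [stage] + [ECOG] + [NLR] + [SII]  ∈ {0,…,7},

with `S ≥ 4` flagging high risk. Validation uses the 2×2 diagnostic
machinery — sensitivity, specificity, PPV, NPV, accuracy = (TP+TN)/n,
positive likelihood ratio, and the cross-product odds ratio with Wald CI
exp(ln OR ± 1.96·√(1/TP+1/FP+1/FN+1/TN)) — plus Youden-index cut-off
selection (J = sens + spec − 1), adjusted logistic regression tables in the
β/SE/Wald/OR/CI/p layout, a three-level two-factor model (model B), the
NCCN-IPI comparator, and a single-proportion power check.

**Forecasting half — chaos-theory monitoring.** The six factors monitored
over time are treated as a chaotic multivariate series. Each variable is
delay-embedded (delay τ from the first minimum of mutual information;
dimension m from false nearest neighbours), a CNN-LSTM (1-D convolution →
ReLU → max-pool → LSTM(100) → linear head, loss ‖y−ŷ‖² + λ‖W‖², Adam)
predicts the next state, a comprehensive risk index

    W_i(t) = ||x(t)| − x̄₀| / (x_max − x̄₀)   (clipped to [0,1]),
    W_z(t) = Σ W_i(t)·p_i(t),

is classified into four levels (risk / subsidiary risk / subsidiary safe /
safe), and a general regression neural network with PSO-selected smoothing
factor maps variable states to the risk value. Forecast quality is measured
by MAPE and a deviation-scaled MASE with the standard accuracy bands.

Patient-level data of this kind are private; the package ships synthetic
cohort and monitoring-series generators that reproduce the statistical
structure the analysis assumes, so everything is exercisable end to end.

## Worked example

```r
library(pod12risk)

# --- cohort half -------------------------------------------------------
co <- simulate_cohort(default_cohort_spec(n = 1000, seed = 7))
mean(co$pod12)
#> [1] 0.464                       # generator calibrated to 46% incidence

evaluate_model(co, "A", adjust_for = "rituximab")$metrics
#> sens 0.6810  spec 0.7966  PPV 0.7435  NPV 0.7426  accuracy 0.7430
#> OR 8.364 (95.0% CI 6.278-11.144)

youden_cutoff(co$b2mg_value, co$pod12)[c("cutoff", "youden_j")]
#> $cutoff   [1] 3.000036         # recovers the 3 umol/L dichotomy
#> $youden_j [1] 0.4084507

# --- forecasting half --------------------------------------------------
pan <- simulate_series(series_spec("sine", n_points = 300,
                                   variables = c("ldh", "b2mg", "stage"),
                                   seed = 7, missing_rate = 0.02))
out <- run_forecast_pipeline(pan, forecast_config(seed = 7),
                             max_lag = 25, max_m = 4)
out$embedding
#> ldh      tau = 9, m = 2
#> b2mg     tau = 9, m = 4
#> stage    tau = 9, m = 2
#> total state dimension: 8

out$evaluation[c("variable", "mape", "band")]
#>   variable      mape            band
#> 1      ldh 1.9461828 highly accurate
#> 2     b2mg 1.9185673 highly accurate
#> 3    stage 0.5373405 highly accurate

out$future
#> predicted state at t+1:
#>    ldh   b2mg  stage
#> 2.9891 0.9990 1.9463
#> W_z (index) 0.6437 | W_z (GRNN) 0.6486 | level: subsidiary risk
```

The periodic panel is imputed (before/after mean), stabilized (µ = 0.85 on
imputed entries), embedded per variable, forecast one step ahead by the
CNN-LSTM (validation MAPE per variable, all in the "highly accurate" band
here), scored by the comprehensive risk index, and the PSO-GRNN regresses
the composite risk of the predicted t+1 state — 0.649, which classifies as
*subsidiary risk* under the default 0.75/0.5/0.25 thresholds.

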