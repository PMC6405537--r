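# kiwidetect

Hierarchical Bayesian detection modelling for bioacoustic broadcast
calibration experiments: do autonomous recording units (ARUs) hear what
human observers hear?

In a broadcast calibration experiment, known bird calls (brown and little
spotted kiwi, ruru) are played from speakers at surveyed positions while
human observers and ARUs listen from fixed stations, so every broadcast is
a Bernoulli trial with known ground truth. `kiwidetect` implements the
complete analysis for ecologists running such experiments:

- **geometry** — great-circle (Haversine, R = 6,371 km) distances,
  listener-to-speaker bearings, 45° direction sectors, relative altitude,
  line-of-sight flags;
- **assembly** — expansion of the experiment design into the broadcast
  schedule, scoring of observer sheets / ARU annotations into binary
  detection records, unit exclusion and replication rules, covariate
  standardization;
- **model** — Bernoulli likelihood with sigmoid link over
  `esp_i = int + b_st + b_t + b_dis*dis_z + b_a*alt_z + b_il + b_ca + b_dir
  + b_unit + eps_i`, every effect per unit class (human/ARU), human unit
  contributions hierarchically modelled by a person-level linear model in
  expertise, experience, gender and age, ARU contributions around a common
  sample mean, all with zero-mean normal priors of precision 1e-4;
- **inference** — adaptive Metropolis-within-Gibbs MCMC (compiled kernel),
  the published run protocol (70,000 burn-in, 7 chains × 200,000
  iterations, thin 20) plus a desk-scale preset, effective sample size with
  initial-positive-sequence truncation, split-chain R-hat, and posterior
  sign classification of effects;
- **validation** — tenfold cross-validation of held-out predictive
  accuracy, detection tallies by unit kind, and a parameter-recovery
  harness;
- **synthetic data** — a generator that replays the published experiment
  design (7 trials × 6 speakers × 5 calls; 13 observers rotating through 7
  stations; 14 ARUs) from configurable generative truth, so the entire
  pipeline is testable without any field recordings.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 2
simulates a full field night and tallies detections:

```r
library(kiwidetect)
cfg <- simulation_config()                      # published design + layout
ds  <- simulate_detections(cfg, seed = 20260923)
paired <- apply_unit_rules(ds$records, rawhiti_unit_rules())
tally(paired)$by_kind
#>   kind detected total  percent
#>    ARU     1797  2940 61.12245
#>  human     1384  2520 54.92063
```

ARUs detect a larger share of broadcasts than human observers under the
default generative truth, mirroring the field pattern. Step 3 fits the
detection model to the 4,830-row model dataset (12 observers + 11 working
ARUs × 210 events) and classifies effects by posterior sign:

```r
model <- model_config(priors = prior_spec(overdispersion_precision = 4))
fit <- sample_posterior(records, rawhiti_units(), model,
                        mcmc_config("desk"), seed = 20260924)
summ <- summarize_posterior(fit, level = 0.95)
summ[summ$significant != "none" & !grepl("^b_unit", summ$parameter), ]
#>     parameter       mean      lower      upper significant
#>  b_dis[human] -0.8226062 -1.1301661 -0.5025877    negative
#>    b_dis[ARU] -1.3606658 -1.7971955 -0.9473195    negative
#>    b_alt[ARU] -0.6039981 -0.7813992 -0.4325252    negative
```

Detection probability falls with distance for both listening methods and
more steeply for ARUs, and relative altitude affects ARUs but not people —
the qualitative structure the generator plants and the fit recovers. Step
4 cross-validates (in one run of `analysis/04_cross_validate.R`: 71.5% of
1,260 held-out points correctly classified), and step 5 runs the recovery
study (slope signs recovered in 100% of replicate-slope pairs; 90%
intervals covered true contrasts 92% of the time).

Because the model fits one effect per class level with no reference level
(as published), individual class effects are only interpretable relative
to each other; `contrast_set()` enumerates the identifiable contrasts, and
low effective sample sizes on single class effects are expected and
flagged. See the vignette (`vignettes/detection-modelling.Rmd`) for the
model, its priors, and every design decision.

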