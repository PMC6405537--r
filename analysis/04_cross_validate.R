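#!/usr/bin/env Rscript
# Step 4: tenfold cross-validation of predictive accuracy. Holds out each
# random tenth of a desk-scale synthetic dataset, refits, and scores the
# held-out posterior-mean detection probabilities at the 0.5 threshold.

library(kiwidetect)
dir.create("results", showWarnings = FALSE)
seed <- 20260925

units <- subset_units(rawhiti_units(),
                      c("obs1", "obs2", "obs3", "NE1", "NE2", "NE3"))
cfg <- simulation_config(units = units, truth = default_truth(units))
ds <- simulate_detections(cfg, seed = seed)
model <- model_config(priors = prior_spec(overdispersion_precision = 4))

cv <- tenfold_cv(ds$records, units, model, mcmc_config("desk"),
                 seed = seed + 1)

cat("Cross-validated", cv$n_total, "observations in 10 folds of",
    paste(unique(lengths(cv$folds)), collapse = "/"), "\n")
cat("Fold accuracies (%):",
    paste(round(100 * cv$fold_accuracies, 1), collapse = " "), "\n")
cat(sprintf("Overall: %.3f%% of held-out points correctly classified\n",
            cv$overall_percent_correct))
cat(sprintf("Held-out log-loss: %.4f\n", cv$log_loss))
if (length(cv$single_class_folds))
  cat("Folds with a single outcome class:",
      paste(cv$single_class_folds, collapse = ", "), "\n")

out <- data.frame(fold = 1:10, size = lengths(cv$folds),
                  accuracy = cv$fold_accuracies)
write.table(out, "results/cv_folds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/cv_folds.tsv\n")
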