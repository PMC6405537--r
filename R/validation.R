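#' Randomised fold assignment for k-fold cross-validation
#'
#' Permutes the observation indices and deals them into k disjoint folds of
#' size floor(n/k), distributing any remainder one per fold. When n is a
#' multiple of k the assignment is also returned as an (n/k) x k index
#' matrix, mirroring the randomized index-matrix construction of the
#' original analysis.
#'
#' @param n number of observations.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list with `folds` (list of k index vectors) and `matrix`
#'   ((n/k) x k, or NULL when n is not a multiple of k).
#' @export
cv_fold_matrix <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("need at least k observations", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  base <- n %/% k
  rem <- n - base * k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(f) sort(perm[starts[f]:ends[f]]))
  mat <- if (rem == 0L) matrix(perm, nrow = base, ncol = k) else NULL
  list(folds = folds, matrix = mat)
}

#' Tenfold cross-validation of predictive accuracy
#'
#' Sequentially holds out each random tenth of the dataset, refits the
#' model on the remaining nine tenths, predicts the held-out detection
#' probabilities (posterior mean, overdispersion at its prior mean), and
#' classifies each held-out point as detected when p >= `threshold`. The
#' overall figure is the percentage of held-out points classified
#' correctly; held-out log-loss is reported alongside. Folds are purely
#' random (no stratification); folds containing a single outcome class are
#' allowed and logged.
#'
#' @param records assembled detection data.frame with `y`.
#' @param units `listening_units` roster.
#' @param model a [model_config()].
#' @param mcmc an [mcmc_config()] used for each refit.
#' @param seed integer seed (drives fold assignment and each refit).
#' @param threshold classification threshold on the posterior-mean
#'   probability (default 0.5).
#' @return a `cv_result` list: `fold_accuracies`, `overall_percent_correct`,
#'   `n_total`, `fold_index_matrix`, `log_loss`, `single_class_folds`.
#' @export
tenfold_cv <- function(records, units = NULL, model = model_config(),
                       mcmc = mcmc_config(), seed = 1L, threshold = 0.5) {
  n <- nrow(records)
  if (n < 20) stop("need at least 20 observations", call. = FALSE)
  fm <- cv_fold_matrix(n, 10L, seed)
  frame <- model_frame(records, units, model)
  correct <- 0L
  ll <- 0
  fold_acc <- numeric(10)
  single <- integer(0)
  for (f in seq_along(fm$folds)) {
    held <- fm$folds[[f]]
    if (length(unique(records$y[held])) == 1L) single <- c(single, f)
    fit <- sample_posterior(frame, mcmc = mcmc, seed = seed + f,
                            subset = setdiff(seq_len(n), held))
    p <- predict_detection(fit, rows = held)
    yhat <- as.integer(p >= threshold)
    y <- records$y[held]
    fold_acc[f] <- mean(yhat == y)
    correct <- correct + sum(yhat == y)
    pc <- pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)
    ll <- ll - sum(y * log(pc) + (1 - y) * log(1 - pc))
  }
  structure(list(
    fold_accuracies = fold_acc,
    overall_percent_correct = 100 * correct / n,
    n_total = n,
    fold_index_matrix = fm$matrix,
    folds = fm$folds,
    log_loss = ll / n,
    single_class_folds = single,
    threshold = threshold), class = "cv_result")
}

#' Detection tallies by unit kind and by unit
#'
#' Counts of broadcast events detected (y = 1) out of events in scope, as
#' totals, per unit kind (human vs ARU) and per individual unit, with
#' percentages. An empty dataset yields zero counts and absent (NA)
#' percentages.
#'
#' @param records detection data.frame with `unit_id`, `kind`, `y`.
#' @return a `tally_report` list with `by_kind` and `by_unit` data.frames.
#' @export
tally <- function(records) {
  pct <- function(d, t) ifelse(t > 0, 100 * d / t, NA_real_)
  if (!nrow(records)) {
    by_kind <- data.frame(kind = character(0), detected = integer(0),
                          total = integer(0), percent = numeric(0))
    by_unit <- data.frame(unit_id = character(0), kind = character(0),
                          detected = integer(0), total = integer(0),
                          percent = numeric(0))
  } else {
    by_kind <- aggregate(list(detected = records$y),
                         list(kind = records$kind), sum)
    by_kind$total <- aggregate(list(n = records$y),
                               list(kind = records$kind), length)$n
    by_kind$percent <- pct(by_kind$detected, by_kind$total)
    by_unit <- aggregate(list(detected = records$y),
                         list(unit_id = records$unit_id,
                              kind = records$kind), sum)
    by_unit$total <- aggregate(list(n = records$y),
                               list(unit_id = records$unit_id,
                                    kind = records$kind), length)$n
    by_unit$percent <- pct(by_unit$detected, by_unit$total)
  }
  structure(list(by_kind = by_kind, by_unit = by_unit), class = "tally_report")
}

# flatten structured truth onto a frame's parameter layout
flatten_params <- function(frame, params, aru_mean = 0) {
  b <- frame$blocks
  theta <- setNames(numeric(frame$n_par), frame$par_names)
  val <- function(row) {
    comp <- params[[row$block]]
    if (row$block == "intercept") return(params$intercept)
    if (is.null(comp)) return(0)
    switch(row$block,
      station = comp["human", as.integer(row$level)],
      trial = comp[row$class, as.integer(row$level)],
      distance = comp[[row$class]],
      altitude = comp[[row$class]],
      los = comp[row$class, match(row$level, LOS_LEVELS)],
      call = comp[row$class, match(row$level, CALL_LEVELS)],
      direction = comp[row$class, as.integer(row$level)],
      unit = if (row$level %in% names(comp)) comp[[row$level]] else 0)
  }
  for (r in seq_len(nrow(b)))
    theta[b$idx[r]] <- val(b[r, , drop = FALSE])
  theta
}

#' Identifiable contrasts of the detection model
#'
#' Because every class block carries one effect per class with no reference
#' level (regularised only by the weak priors), individual class effects
#' are interpretable only relative to each other. The identifiable
#' quantities are the slope coefficients (distance, altitude, per unit
#' class) and within-block differences between class levels; this helper
#' enumerates them over a frame (each level against the block's first
#' level, per unit class).
#'
#' @param frame a [model_frame()].
#' @return data.frame with columns `name`, `a`, `b` (parameter names;
#'   `b` NA for plain coefficients).
#' @export
contrast_set <- function(frame) {
  b <- frame$blocks
  res <- data.frame(name = character(0), a = character(0), b = character(0),
                    stringsAsFactors = FALSE)
  for (bl in c("distance", "altitude")) {
    rows <- b[b$block == bl, , drop = FALSE]
    nm <- frame$par_names[rows$idx]
    res <- rbind(res, data.frame(name = nm, a = nm, b = NA_character_))
  }
  for (bl in c("station", "trial", "los", "call", "direction")) {
    rows <- b[b$block == bl, , drop = FALSE]
    if (!nrow(rows)) next
    for (cl in unique(rows$class)) {
      rc <- rows[rows$class == cl, , drop = FALSE]
      if (nrow(rc) < 2) next
      ref <- frame$par_names[rc$idx[1]]
      for (r in 2:nrow(rc)) {
        nm <- frame$par_names[rc$idx[r]]
        res <- rbind(res, data.frame(
          name = paste0(nm, " - ", ref), a = nm, b = ref))
      }
    }
  }
  rownames(res) <- NULL
  res
}

contrast_values <- function(contrasts, theta) {
  a <- theta[contrasts$a]
  b <- ifelse(is.na(contrasts$b), 0, theta[contrasts$b])
  setNames(as.numeric(a) - as.numeric(b), contrasts$name)
}

#' Parameter-recovery study on synthetic data
#'
#' Repeatedly simulates an experiment from known truth, refits the model,
#' and scores recovery of the identifiable quantities: bias and RMSE of the
#' posterior-mean contrasts, coverage of central credible intervals at
#' `level`, and the rate at which the signs of the distance/altitude slopes
#' are recovered. Replicates whose fits trip the convergence warning are
#' reported, never dropped.
#'
#' @param sim_config a [simulation_config()] carrying the truth.
#' @param model a [model_config()].
#' @param mcmc an [mcmc_config()].
#' @param n_replicates number of simulate-fit replicates.
#' @param seed integer seed.
#' @param level credible level for coverage (default 0.9).
#' @return a `recovery_report` list: `per_contrast` (bias, rmse, coverage),
#'   `slope_sign_rate`, `coverage_overall`, `n_warnings`, `replicates`.
#' @export
recover_parameters <- function(sim_config, model = model_config(),
                               mcmc = mcmc_config(), n_replicates = 20L,
                               seed = 1L, level = 0.9) {
  alpha <- (1 - level) / 2
  reps <- vector("list", n_replicates)
  n_warn <- 0L
  for (r in seq_len(n_replicates)) {
    ds <- simulate_detections(sim_config, seed = seed + 1000L * r)
    frame <- model_frame(ds$records, sim_config$units, model)
    truth_theta <- flatten_params(frame, sim_config$truth$params,
                                  sim_config$truth$aru_mean)
    contrasts <- contrast_set(frame)
    truth_c <- contrast_values(contrasts, truth_theta)
    fit <- sample_posterior(frame, mcmc = mcmc, seed = seed + 1000L * r + 1L)
    D <- pooled_draws(fit)
    ca <- D[, contrasts$a, drop = FALSE]
    cb <- matrix(0, nrow(D), nrow(contrasts))
    has_b <- !is.na(contrasts$b)
    cb[, has_b] <- D[, contrasts$b[has_b], drop = FALSE]
    cd <- ca - cb
    lo <- apply(cd, 2, quantile, alpha)
    hi <- apply(cd, 2, quantile, 1 - alpha)
    mn <- colMeans(cd)
    rh <- vapply(contrasts$a, function(pn)
      split_rhat(lapply(fit$chains, function(m) m[, pn])), 0.0)
    warned <- any(is.finite(rh) & rh > 1.05)
    n_warn <- n_warn + warned
    reps[[r]] <- data.frame(
      replicate = r, contrast = contrasts$name, truth = as.numeric(truth_c),
      mean = mn, lower = lo, upper = hi,
      covered = truth_c >= lo & truth_c <= hi,
      convergence_warning = warned, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, reps)
  per <- do.call(rbind, lapply(split(all, all$contrast), function(d)
    data.frame(contrast = d$contrast[1],
               truth = d$truth[1],
               bias = mean(d$mean - d$truth),
               rmse = sqrt(mean((d$mean - d$truth)^2)),
               coverage = mean(d$covered))))
  rownames(per) <- NULL
  slopes <- grepl("^b_(dis|alt)\\[", all$contrast)
  sign_ok <- sign(all$mean[slopes]) == sign(all$truth[slopes])
  structure(list(
    per_contrast = per,
    slope_sign_rate = mean(sign_ok),
    coverage_overall = mean(all$covered),
    n_warnings = n_warn,
    level = level,
    replicates = all), class = "recovery_report")
}
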