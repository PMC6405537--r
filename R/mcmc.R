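#' MCMC run protocols
#'
#' Two presets: `"desk"` (1,000 burn-in, 4 chains, 5,000 post-burn-in
#' iterations, thin 5) sized for routine refits, tests and cross-validation;
#' `"paper"` is the full published protocol (70,000 burn-in, 7 chains,
#' 200,000 iterations, thin 20, i.e. 70,000 pooled retained draws). Any
#' field can be overridden.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param burn_in,n_chains,n_iterations,thin overrides of the preset values;
#'   `n_iterations` counts post-burn-in iterations per chain.
#' @param init_jitter half-width of the uniform jitter around zero used to
#'   initialise every parameter of every chain.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(preset = c("desk", "paper"), burn_in = NULL,
                        n_chains = NULL, n_iterations = NULL, thin = NULL,
                        init_jitter = 0.1) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(burn_in = 1000L, n_chains = 4L, n_iterations = 5000L,
                thin = 5L),
    paper = list(burn_in = 70000L, n_chains = 7L, n_iterations = 200000L,
                 thin = 20L))
  out <- list(
    preset = preset,
    burn_in = as.integer(burn_in %||% base$burn_in),
    n_chains = as.integer(n_chains %||% base$n_chains),
    n_iterations = as.integer(n_iterations %||% base$n_iterations),
    thin = as.integer(thin %||% base$thin),
    init_jitter = init_jitter)
  if (out$thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(out, class = "mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname mcmc_config
#' @param config an `mcmc_config`.
#' @return `retained_draws`: total pooled retained draws,
#'   chains x (iterations / thin).
#' @export
retained_draws <- function(config) {
  config$n_chains * (config$n_iterations %/% config$thin)
}

#' Sample the posterior of the detection model
#'
#' Runs independent adaptive Metropolis-within-Gibbs chains (compiled
#' kernel) against the configured model. Each chain initialises every
#' parameter at zero plus a uniform jitter and adapts its proposal scales
#' during burn-in only; retained draws are the post-burn-in iterations at
#' the thinning interval. All randomness flows from `seed` through R's RNG,
#' so the same seed reproduces the draws exactly.
#'
#' @param records assembled detection data.frame with `y`, or a prebuilt
#'   [model_frame()].
#' @param units `listening_units` roster (required when human units enter
#'   the model).
#' @param model a [model_config()].
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed.
#' @param subset optional integer vector of record rows to fit on (the
#'   frame keeps the full layout; used by cross-validation).
#' @return a `kiwi_fit`: draws per chain (matrix, retained x parameters),
#'   parameter names, the frame, configs, seed, and per-chain final states.
#' @export
sample_posterior <- function(records, units = NULL, model = model_config(),
                             mcmc = mcmc_config(), seed = 1L,
                             subset = NULL) {
  frame <- if (inherits(records, "model_frame")) records
           else model_frame(records, units, model)
  rows <- subset %||% seq_len(frame$n)
  set.seed(seed)
  has_aru <- length(frame$aru_unit_par) > 0
  par_names <- c(frame$par_names, frame$gamma_names,
                 if (has_aru) "aru_mean")
  chains <- vector("list", mcmc$n_chains)
  finals <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    res <- run_chain_cpp(
      y = frame$y[rows],
      obs_par = frame$obs_par[rows, , drop = FALSE],
      obs_w = frame$obs_w[rows, , drop = FALSE],
      n_par = frame$n_par,
      prior_prec = frame$prior_prec, prior_mean0 = frame$prior_mean0,
      prior_type = frame$prior_type, human_of_par = frame$human_of_par,
      Z = frame$Z, gamma_prec = frame$gamma_prec,
      human_unit_par = frame$human_unit_par,
      aru_unit_par = frame$aru_unit_par,
      hyper_prec = frame$config$priors$hyper_precision,
      include_eps = frame$include_eps,
      eps_prec = frame$config$priors$overdispersion_precision,
      burn_in = mcmc$burn_in, n_iter = mcmc$n_iterations, thin = mcmc$thin,
      init_jitter = mcmc$init_jitter)
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    finals[[ch]] <- res[c("theta_final", "gamma_final", "m_final",
                          "eps_final", "logpost_final")]
  }
  structure(list(chains = chains, par_names = par_names, frame = frame,
                 model = frame$config, mcmc = mcmc, seed = seed,
                 rows = rows, finals = finals),
            class = "kiwi_fit")
}

#' Pool the retained draws of a fit
#'
#' @param fit a `kiwi_fit`.
#' @return matrix, (chains x retained) rows by parameters.
#' @export
pooled_draws <- function(fit) {
  do.call(rbind, fit$chains)
}

#' Posterior detection probabilities for records of the fitted frame
#'
#' For each requested record, averages the sigmoid of the linear predictor
#' over the pooled posterior draws. The per-observation overdispersion term
#' is observation-specific and unavailable for held-out points, so it is
#' set to its prior mean (zero).
#'
#' @param fit a `kiwi_fit`.
#' @param rows record rows of the frame to predict (default: all).
#' @return vector of posterior-mean detection probabilities.
#' @export
predict_detection <- function(fit, rows = NULL) {
  rows <- rows %||% seq_len(fit$frame$n)
  X <- frame_design_matrix(fit$frame)[rows, , drop = FALSE]
  D <- pooled_draws(fit)[, seq_len(fit$frame$n_par), drop = FALSE]
  p <- matrix(0, length(rows), 1)
  # chunk over draws to bound memory
  step <- max(1L, floor(2e7 / max(1, length(rows))))
  idx <- seq_len(nrow(D))
  acc <- numeric(length(rows))
  for (start in seq(1L, nrow(D), by = step)) {
    block <- idx[start:min(start + step - 1L, nrow(D))]
    esp <- X %*% t(D[block, , drop = FALSE])
    acc <- acc + rowSums(plogis(esp))
  }
  acc / nrow(D)
}

#' Effective sample size of a chain of draws
#'
#' Estimates the number of independent draws a correlated chain is worth:
#' n / (1 + 2 * sum(rho_k)), the autocorrelation sum truncated by the
#' initial-positive-sequence rule (summing over pairs of consecutive lags
#' while their sum stays positive). A constant chain returns 0.
#'
#' @param draws numeric vector (one parameter's chain), length >= 10, or a
#'   list of such vectors (one per chain, ESS summed across chains).
#' @return estimated effective sample size.
#' @export
effective_sample_size <- function(draws) {
  if (is.list(draws)) return(sum(vapply(draws, effective_sample_size, 0.0)))
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws", call. = FALSE)
  if (stats::var(draws) == 0) return(0)
  max_lag <- min(n - 1L, 2000L)
  rho <- as.numeric(acf(draws, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  s <- 0
  k <- 1L
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  ess <- n / (1 + 2 * s)
  min(max(ess, 0), n * 1.5)
}

# split-chain potential scale reduction (each chain halved)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0.0)
  vars <- vapply(halves, stats::var, 0.0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarise a fit: intervals, sign classification, ESS
#'
#' Per parameter: posterior mean, a central credible interval at `level`,
#' a significance flag by posterior sign (`positive` when the whole interval
#' is above zero, `negative` when below, else `none`), effective sample
#' size (summed over chains), and split-chain R-hat. A convergence warning
#' flag is set when R-hat exceeds 1.05 or ESS falls below 400.
#'
#' @param fit a `kiwi_fit`.
#' @param level credible level of the central interval (default 0.95).
#' @param parameters optional character vector restricting the summary.
#' @return data.frame of class `posterior_summary`.
#' @export
summarize_posterior <- function(fit, level = 0.95, parameters = NULL) {
  pars <- parameters %||% fit$par_names
  alpha <- (1 - level) / 2
  rows <- lapply(pars, function(pn) {
    per_chain <- lapply(fit$chains, function(m) m[, pn])
    x <- unlist(per_chain)
    qs <- unname(quantile(x, c(alpha, 1 - alpha)))
    ess <- effective_sample_size(per_chain)
    rh <- split_rhat(per_chain)
    data.frame(parameter = pn, mean = mean(x), lower = qs[1], upper = qs[2],
               significant = if (qs[1] > 0) "positive"
                             else if (qs[2] < 0) "negative" else "none",
               ess = ess, rhat = rh,
               convergence_warning = (is.finite(rh) && rh > 1.05) || ess < 400,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
summary.kiwi_fit <- function(object, level = 0.95, ...) {
  summarize_posterior(object, level = level)
}

#' @export
print.kiwi_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical detection-model fit: %d observations, %d parameters,\n%d chains x %d retained draws (preset '%s', seed %d)\n",
    length(x$rows), length(x$par_names), x$mcmc$n_chains,
    x$mcmc$n_iterations %/% x$mcmc$thin, x$mcmc$preset, x$seed))
  invisible(x)
}
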