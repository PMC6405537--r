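UNIT_CLASSES <- c("human", "ARU")
LOS_LEVELS <- c("in", "out")

#' Prior specification for the hierarchical detection model
#'
#' All hierarchical covariate effects get proper normal priors with zero
#' mean and a very small precision; the one precision printed for the model
#' (0.0001 on the person-level hierarchy) is the default everywhere it is
#' otherwise unspecified. The per-observation overdispersion precision is
#' genuinely unspecified in the source model and is deliberately exposed:
#' 0.0001 reproduces the original prior, while desk-scale analyses in this
#' package use a much larger value (see the package vignette).
#'
#' @param default_precision precision of the zero-mean priors on all
#'   covariate-class effects and person-level regression terms.
#' @param person_precision precision of the human individual-contribution
#'   hierarchy (around each person's linear-model mean).
#' @param aru_precision precision of the ARU individual-contribution
#'   hierarchy (around the ARU sample mean).
#' @param hyper_precision precision of the prior on the ARU sample mean.
#' @param overdispersion_precision precision of the per-observation noise.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(default_precision = 1e-4,
                       person_precision = 1e-4,
                       aru_precision = 1e-4,
                       hyper_precision = 1e-4,
                       overdispersion_precision = 1e-4) {
  p <- list(default_precision = default_precision,
            person_precision = person_precision,
            aru_precision = aru_precision,
            hyper_precision = hyper_precision,
            overdispersion_precision = overdispersion_precision)
  if (any(unlist(p) <= 0)) stop("precisions must be > 0", call. = FALSE)
  structure(p, class = "prior_spec")
}

#' Configure the detection model
#'
#' Switches select which covariate blocks enter the linear predictor; the
#' full model uses all of them. Experience covariates (five-minute bird
#' counts, kiwi call surveys, other surveys) enter the person-level model as
#' categorical class effects by default, or linearly in standardized years.
#'
#' @param include character vector of covariate blocks; any subset of
#'   `station`, `trial`, `distance`, `altitude`, `los`, `call`, `direction`,
#'   `unit`, `overdispersion`.
#' @param priors a [prior_spec()].
#' @param experience `"categorical"` or `"linear"` encoding of the
#'   experience covariates.
#' @return a `model_config` list.
#' @export
model_config <- function(include = c("station", "trial", "distance",
                                     "altitude", "los", "call", "direction",
                                     "unit", "overdispersion"),
                         priors = prior_spec(),
                         experience = c("categorical", "linear")) {
  all_blocks <- c("station", "trial", "distance", "altitude", "los", "call",
                  "direction", "unit", "overdispersion")
  include <- if (length(include)) match.arg(include, all_blocks,
                                            several.ok = TRUE)
             else character(0)
  structure(list(include = include, priors = priors,
                 experience = match.arg(experience)),
            class = "model_config")
}

#' Construct a full set of detection-model parameters
#'
#' Container for every symbol of the observation-level linear predictor.
#' Class-effect components are matrices with one row per unit class
#' (`human`, `ARU`); the ARU row of the station matrix must be zero because
#' ARUs never change station. Missing (`NULL`) components are treated as
#' zero, which is how reduced models are expressed.
#'
#' @param intercept global intercept.
#' @param station 2 x n_stations matrix (ARU row all zero).
#' @param trial 2 x n_trials matrix.
#' @param distance,altitude length-2 vectors of slopes on the standardized
#'   covariate, named by unit class.
#' @param los 2 x 2 matrix, columns `in`/`out` (mutually exclusive pair).
#' @param call 2 x 5 matrix, columns BKF, BKM, LSKF, LSKM, RR.
#' @param direction 2 x 8 matrix over direction sectors.
#' @param unit named vector of individual contributions, one per unit.
#' @param eps per-observation overdispersion values (length n or NULL).
#' @param aru_mean hyper-mean of the ARU contributions.
#' @return a `model_parameters` list.
#' @export
model_parameters <- function(intercept = 0, station = NULL, trial = NULL,
                             distance = NULL, altitude = NULL, los = NULL,
                             call = NULL, direction = NULL, unit = NULL,
                             eps = NULL, aru_mean = 0) {
  if (!is.null(station) && any(station["ARU", ] != 0))
    stop("ARU station effects are fixed at zero (ARUs do not move)",
         call. = FALSE)
  structure(list(intercept = intercept, station = station, trial = trial,
                 distance = distance, altitude = altitude, los = los,
                 call = call, direction = direction, unit = unit, eps = eps,
                 aru_mean = aru_mean),
            class = "model_parameters")
}

# class-effect matrix helper: 2 x k, rows human/ARU
class_matrix <- function(human, aru, colnames = NULL) {
  m <- rbind(human = human, ARU = aru)
  if (!is.null(colnames)) base::colnames(m) <- colnames
  m
}

#' Person-level parameters of the observer sub-model
#'
#' The mean of each human observer's individual contribution is its own
#' linear model in expertise vote, experience counts, gender and
#' standardized age.
#'
#' @param intercept person-level intercept.
#' @param vote length-5 vector named `vote0`..`vote4`.
#' @param fmc,kcs,os named vectors of class effects (names are the observed
#'   year counts as characters) or single slopes under the linear encoding.
#' @param gender length-2 vector named `female`, `male`.
#' @param age_coef slope on standardized age.
#' @return a `person_parameters` list.
#' @export
person_parameters <- function(intercept = 0,
                              vote = setNames(numeric(5), paste0("vote", 0:4)),
                              fmc = numeric(0), kcs = numeric(0),
                              os = numeric(0),
                              gender = c(female = 0, male = 0),
                              age_coef = 0) {
  structure(list(intercept = intercept, vote = vote, fmc = fmc, kcs = kcs,
                 os = os, gender = gender, age_coef = age_coef),
            class = "person_parameters")
}

lookup_level <- function(table, level, what) {
  idx <- match(as.character(level), names(table))
  if (anyNA(idx))
    stop("unknown ", what, " level: ",
         paste(unique(level[is.na(idx)]), collapse = ", "), call. = FALSE)
  unname(table[idx])
}

#' Person-level mean of an observer's individual contribution
#'
#' @param profile one or more observer profiles with columns
#'   `expertise_vote`, `fmc_years`, `kcs_years`, `other_surveys`, `gender`
#'   and `age_z` (age standardized across the human roster).
#' @param pparams a [person_parameters()] object.
#' @param experience `"categorical"` or `"linear"` (must match how
#'   `pparams` was built).
#' @return numeric vector of means, one per profile row.
#' @export
person_mean <- function(profile, pparams, experience = "categorical") {
  if (is.null(profile$age_z))
    stop("profile must carry age_z (age standardized across the roster)",
         call. = FALSE)
  exper <- if (experience == "categorical") {
    lookup_level(pparams$fmc, profile$fmc_years, "fmc") +
      lookup_level(pparams$kcs, profile$kcs_years, "kcs") +
      lookup_level(pparams$os, profile$other_surveys, "os")
  } else {
    pparams$fmc * profile$fmc_years + pparams$kcs * profile$kcs_years +
      pparams$os * profile$other_surveys
  }
  pparams$intercept +
    lookup_level(pparams$vote, paste0("vote", profile$expertise_vote), "vote") +
    exper +
    lookup_level(pparams$gender, profile$gender, "gender") +
    pparams$age_coef * profile$age_z
}

#' Linear predictor of the detection model
#'
#' For observation i, the log-odds of detection is the sum of the global
#' intercept, the station effect of the unit's class (zero for ARUs), the
#' trial effect, distance and relative-altitude slopes times the
#' standardized covariates, the line-of-sight pair, the call effect, the
#' direction-sector effect, the unit's individual contribution, and the
#' per-observation overdispersion term. `NULL` parameter components
#' contribute zero.
#'
#' @param records detection data.frame (columns `kind`, `station`, `trial`,
#'   `distance_z`, `altitude_z`, `line_of_sight`, `call`, `sector`,
#'   `unit_id`).
#' @param params a [model_parameters()] object.
#' @return numeric vector of linear predictors (one per record).
#' @export
linear_predictor <- function(records, params) {
  stopifnot(inherits(params, "model_parameters"))
  n <- nrow(records)
  esp <- rep(params$intercept, n)
  kind <- records$kind
  if (!all(kind %in% UNIT_CLASSES))
    stop("unit kind must be human or ARU", call. = FALSE)
  pick <- function(m, col, what) {
    if (max(col) > ncol(m)) stop(what, " index out of range", call. = FALSE)
    m[cbind(match(kind, rownames(m)), col)]
  }
  if (!is.null(params$station)) {
    hu <- kind == "human"
    if (any(records$station[hu] > ncol(params$station)))
      stop("station index out of range", call. = FALSE)
    esp[hu] <- esp[hu] + params$station["human", records$station[hu]]
  }
  if (!is.null(params$trial))
    esp <- esp + pick(params$trial, records$trial, "trial")
  if (!is.null(params$distance))
    esp <- esp + params$distance[kind] * records$distance_z
  if (!is.null(params$altitude))
    esp <- esp + params$altitude[kind] * records$altitude_z
  if (!is.null(params$los))
    esp <- esp + params$los[cbind(match(kind, rownames(params$los)),
                                  ifelse(records$line_of_sight, 1L, 2L))]
  if (!is.null(params$call))
    esp <- esp + pick(params$call, match(records$call, CALL_LEVELS), "call")
  if (!is.null(params$direction))
    esp <- esp + pick(params$direction, records$sector, "direction sector")
  if (!is.null(params$unit))
    esp <- esp + lookup_level(params$unit, records$unit_id, "unit")
  if (!is.null(params$eps)) {
    if (length(params$eps) != n)
      stop("eps must have one value per observation", call. = FALSE)
    esp <- esp + params$eps
  }
  unname(esp)
}

#' Detection probability from the linear predictor
#'
#' The sigmoid (inverse-logit) link: p = 1 / (1 + exp(-esp)), computed
#' stably for large |esp|.
#'
#' @param esp linear predictor value(s).
#' @return probabilities in (0, 1).
#' @export
detection_probability <- function(esp) {
  if (!all(is.finite(esp))) stop("esp must be finite", call. = FALSE)
  plogis(esp)
}

PROB_CLAMP <- 1e-12

bernoulli_loglik <- function(y, esp) {
  p <- pmin(pmax(plogis(esp), PROB_CLAMP), 1 - PROB_CLAMP)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Log posterior density of the hierarchical detection model
#'
#' Bernoulli log-likelihood of the observed detections plus all normal
#' log-prior terms: zero-mean priors on every free covariate-class effect
#' and person-level term, the person hierarchy on human contributions
#' (normal around each person's linear-model mean), the ARU hierarchy
#' (normal around the ARU sample mean, itself normal around zero), and the
#' zero-mean overdispersion terms. Probabilities inside logs are clamped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' This plain-R implementation is the reference density; the MCMC sampler
#' maintains the same quantity incrementally in compiled code and the two
#' are cross-checked in the package tests.
#'
#' @param records detection data.frame with outcome `y`.
#' @param params a [model_parameters()] (with `unit` and `eps` as used).
#' @param pparams a [person_parameters()] (required when human units are
#'   present and `params$unit` is in the model).
#' @param profiles observer profiles with `age_z`, rownames/ids matching the
#'   human entries of `params$unit` via `unit_id` column.
#' @param priors a [prior_spec()].
#' @param experience experience encoding, as in [model_config()].
#' @return scalar log posterior (unnormalised).
#' @export
log_posterior <- function(records, params, pparams = NULL, profiles = NULL,
                          priors = prior_spec(), experience = "categorical") {
  esp <- linear_predictor(records, params)
  lp <- bernoulli_loglik(records$y, esp)
  sd0 <- 1 / sqrt(priors$default_precision)
  prior0 <- function(x) if (is.null(x)) 0 else sum(dnorm(x, 0, sd0, log = TRUE))
  lp <- lp + prior0(params$intercept)
  if (!is.null(params$station))          # ARU row fixed at zero: not a free term
    lp <- lp + prior0(params$station["human", ])
  lp <- lp + prior0(params$trial) + prior0(params$distance) +
    prior0(params$altitude) + prior0(params$los) + prior0(params$call) +
    prior0(params$direction)
  if (!is.null(params$unit)) {
    ids <- names(params$unit)
    kinds <- ifelse(ids %in% records$unit_id,
                    records$kind[match(ids, records$unit_id)], NA)
    hum <- which(kinds == "human"); aru <- which(kinds == "ARU")
    if (length(hum)) {
      if (is.null(pparams) || is.null(profiles))
        stop("human units require pparams and profiles", call. = FALSE)
      pid <- match(ids[hum], profiles$unit_id)
      mu <- person_mean(profiles[pid, , drop = FALSE], pparams, experience)
      lp <- lp + sum(dnorm(params$unit[hum], mu,
                           1 / sqrt(priors$person_precision), log = TRUE))
      for (comp in c("intercept", "vote", "fmc", "kcs", "os", "gender",
                     "age_coef"))
        lp <- lp + prior0(pparams[[comp]])
    }
    if (length(aru)) {
      lp <- lp + sum(dnorm(params$unit[aru], params$aru_mean,
                           1 / sqrt(priors$aru_precision), log = TRUE)) +
        dnorm(params$aru_mean, 0, 1 / sqrt(priors$hyper_precision), log = TRUE)
    }
  }
  if (!is.null(params$eps))
    lp <- lp + sum(dnorm(params$eps, 0,
                         1 / sqrt(priors$overdispersion_precision),
                         log = TRUE))
  lp
}
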