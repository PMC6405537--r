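#' Default generative truth for synthetic experiments
#'
#' Fixed-effect values that mirror, qualitatively, what the field experiment
#' found — detection falls with distance (more steeply for ARUs), relative
#' altitude matters more for ARUs, human detection is depressed at station 6
#' and elevated at 1, 2 and 4, ARUs favour brown-kiwi-male over
#' brown-kiwi-female and ruru calls — so that simulated outputs look like
#' plausible field data. The numeric values themselves are arbitrary
#' synthetic choices, not estimates.
#'
#' @param units roster used to enumerate the experience-covariate levels of
#'   the person sub-model (default the Rawhiti roster).
#' @return a `sim_truth` list: `params` ([model_parameters()], unit and
#'   overdispersion terms absent — drawn at simulation time), `pparams`
#'   ([person_parameters()]), `aru_mean`, and the generative spreads
#'   `person_sd`, `aru_sd`, `overdispersion_sd`.
#' @export
default_truth <- function(units = rawhiti_units()) {
  obs <- units$observers
  lev <- function(x) setNames(numeric(length(unique(x))),
                              sort(unique(x)))
  pparams <- person_parameters(
    intercept = 0,
    vote = setNames(c(0, 0, 0, 0.1, 0.1), paste0("vote", 0:4)),
    fmc = lev(obs$fmc_years), kcs = lev(obs$kcs_years),
    os = lev(obs$other_surveys),
    gender = c(female = 0, male = 0),
    age_coef = -0.1)
  params <- model_parameters(
    intercept = 0,
    station = class_matrix(c(0.35, 0.28, 0, 0.42, 0, -0.84, 0), numeric(7)),
    trial = class_matrix(numeric(7), numeric(7)),
    distance = c(human = -0.9, ARU = -1.3),
    altitude = c(human = -0.2, ARU = -0.6),
    los = class_matrix(c(0.2, -0.2), c(0.5, -0.5), LOS_LEVELS),
    call = class_matrix(numeric(5),
                        c(-0.6, 0.6, 0.1, 0.2, -0.4), CALL_LEVELS),
    direction = class_matrix(c(0, 0, 0, 0, 0.3, 0, 0, 0), numeric(8)))
  structure(list(params = params, pparams = pparams, aru_mean = 0.55,
                 person_sd = 0.3, aru_sd = 0.8, overdispersion_sd = 0.5),
            class = "sim_truth")
}

#' Strong-signal truth for parameter-recovery studies
#'
#' Same structure as [default_truth()] but with unit-magnitude slopes and
#' well-separated class contrasts, the regime where sign and coverage
#' properties of the sampler are checked.
#'
#' @inheritParams default_truth
#' @return a `sim_truth` list.
#' @export
recovery_truth <- function(units = rawhiti_units()) {
  truth <- default_truth(units)
  truth$params$distance <- c(human = -1, ARU = -1)
  truth$params$altitude <- c(human = 1, ARU = -1)
  truth$params$call["ARU", ] <- c(-0.8, 0.8, 0, 0, -0.5)
  truth$params$station["human", ] <- c(0.8, 0, 0, 0.5, 0, -1.2, 0)
  truth
}

#' Configure a synthetic broadcast experiment
#'
#' Bundles the geometry, design, roster and generative truth that define a
#' simulated run of the experiment. Defaults reproduce the published layout
#' and design.
#'
#' @param layout a `geometry_table` (default [rawhiti_geometry()]).
#' @param design an [experiment_design()] (default [rawhiti_design()]).
#' @param units a `listening_units` roster (default [rawhiti_units()]).
#' @param truth a `sim_truth` (default [default_truth()]).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(layout = rawhiti_geometry(),
                              design = rawhiti_design(),
                              units = rawhiti_units(),
                              truth = default_truth(units)) {
  structure(list(layout = validate_geometry_table(layout), design = design,
                 units = units, truth = truth),
            class = "simulation_config")
}

#' Generate a geometry table for a simulation
#'
#' Either validates a directly supplied geometry table, or computes one from
#' raw station/speaker coordinates (distances by the Haversine formula,
#' bearings from listener to speaker, 45-degree sectors).
#'
#' @param table a geometry table to validate, or `NULL`.
#' @param stations,speakers `geo_point` tables (used when `table` is NULL).
#' @param line_of_sight passed to [build_geometry_table()].
#' @return a validated `geometry_table`.
#' @export
generate_layout <- function(table = NULL, stations = NULL, speakers = NULL,
                            line_of_sight = TRUE) {
  if (!is.null(table)) return(validate_geometry_table(table))
  if (is.null(stations) || is.null(speakers))
    stop("supply either a geometry table or station and speaker coordinates",
         call. = FALSE)
  build_geometry_table(stations, speakers, line_of_sight)
}

#' Subset a listening-unit roster
#'
#' @param units a `listening_units` object.
#' @param unit_ids ids to keep.
#' @return the reduced roster.
#' @export
subset_units <- function(units, unit_ids) {
  keep <- units$table$unit_id %in% unit_ids
  structure(list(
    table = units$table[keep, , drop = FALSE],
    station_by_trial = units$station_by_trial[
      units$table$unit_id[keep], , drop = FALSE],
    observers = units$observers[
      paste0("obs", units$observers$observer_id) %in% unit_ids, ,
      drop = FALSE]
  ), class = "listening_units")
}

#' A reduced roster for desk-scale studies
#'
#' Five human observers and five ARUs from the full roster, giving about
#' 2,000 Bernoulli trials per simulated experiment — large enough to
#' identify the model's contrasts, small enough for replicated refits.
#'
#' @return a `listening_units` roster.
#' @export
desk_units <- function() {
  subset_units(rawhiti_units(),
               c(paste0("obs", 1:5), paste0("NE", 1:5)))
}

#' Simulate detections from the generative model
#'
#' Runs the detection model forward over every (unit, broadcast event)
#' pair: builds covariates from the layout and design, computes each human
#' observer's person-level mean and draws the individual contributions
#' (once per unit), draws per-observation overdispersion noise, and draws
#' the Bernoulli outcomes from the sigmoid of the linear predictor.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; regenerating with the same config and seed
#'   reproduces the dataset exactly.
#' @return a `synthetic_dataset`: `records` (assembled detection
#'   data.frame with `y`), `truth` echo, drawn `unit_effects` and `eps`,
#'   and a manifest.
#' @export
simulate_detections <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  schedule <- build_broadcast_schedule(config$design)
  records <- assemble_detections(
    unit_event_frame(config$units, schedule, config$layout))
  truth <- config$truth

  tab <- config$units$table
  u <- numeric(nrow(tab))
  names(u) <- tab$unit_id
  hum <- tab$kind == "human"
  if (any(hum)) {
    prof <- config$units$observers
    prof$age_z <- zscore_safe(prof$age_years)
    pid <- match(tab$observer_id[hum], prof$observer_id)
    mu <- person_mean(prof[pid, , drop = FALSE], truth$pparams)
    u[hum] <- rnorm(sum(hum), mu, truth$person_sd)
  }
  if (any(!hum))
    u[!hum] <- rnorm(sum(!hum), truth$aru_mean, truth$aru_sd)

  eps <- rnorm(nrow(records), 0, truth$overdispersion_sd)
  params <- truth$params
  params$unit <- u
  params$eps <- eps
  esp <- linear_predictor(records, params)
  records$y <- rbinom(nrow(records), 1L, detection_probability(esp))

  structure(list(
    records = records, truth = truth, unit_effects = u, eps = eps,
    manifest = list(seed = seed,
                    n_records = nrow(records),
                    n_units = nrow(tab),
                    n_events = nrow(schedule))),
    class = "synthetic_dataset")
}

#' Sheet-noise settings for simulated observer sheets
#'
#' @param p_omit_time probability a human record has no time written.
#' @param p_omit_species probability the species label is blank.
#' @param jitter_sd_s standard deviation (s) of the clock-time error.
#' @return a `sheet_noise` list.
#' @export
sheet_noise <- function(p_omit_time = 0.1, p_omit_species = 0.05,
                        jitter_sd_s = 10) {
  structure(list(p_omit_time = p_omit_time, p_omit_species = p_omit_species,
                 jitter_sd_s = jitter_sd_s), class = "sheet_noise")
}

#' Emulate raw observer sheets and ARU annotations
#'
#' For each detected event (y = 1): human units produce a survey-sheet row
#' with a jittered clock time and possibly missing fields (some observers
#' wrote no time or species); ARUs produce exact annotation rows. The
#' output feeds [score_records()] for round-trip testing of the matcher.
#'
#' @param dataset a `synthetic_dataset`.
#' @param noise a [sheet_noise()] configuration.
#' @param seed integer seed.
#' @return raw-records data.frame with columns `unit_id`, `trial`,
#'   `clock_time_s`, `species`, `direction_deg`, `distance_est_m`.
#' @export
simulate_observer_sheets <- function(dataset, noise = sheet_noise(),
                                     seed = 1L) {
  set.seed(seed)
  hits <- dataset$records[dataset$records$y == 1L, , drop = FALSE]
  n <- nrow(hits)
  if (!n)
    return(data.frame(unit_id = character(0), trial = integer(0),
                      clock_time_s = numeric(0), species = character(0),
                      direction_deg = numeric(0),
                      distance_est_m = numeric(0)))
  human <- hits$kind == "human"
  mid <- (hits$start_s + hits$end_s) / 2
  time <- mid
  time[human] <- mid[human] + rnorm(sum(human), 0, noise$jitter_sd_s)
  time[human][runif(sum(human)) < noise$p_omit_time] <- NA
  species <- hits$call
  species[human][runif(sum(human)) < noise$p_omit_species] <- NA
  data.frame(
    unit_id = hits$unit_id, trial = hits$trial,
    clock_time_s = time, species = species,
    direction_deg = ((hits$sector - 0.5) * 45) %% 360,
    distance_est_m = round(hits$distance_m / 10) * 10,
    stringsAsFactors = FALSE)
}
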