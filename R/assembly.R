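#' Define and validate a broadcast-experiment design
#'
#' The design fixes everything that was decided before the field night:
#' how many trials ran, the order in which each speaker played the five
#' calls, the order in which speakers fired within each trial, and the
#' station each observer listened from in each trial.
#'
#' @param n_trials number of trials.
#' @param speaker_call_sequences character matrix, 5 rows x speakers columns;
#'   column s is the call order of speaker s (a permutation of
#'   BKF, BKM, LSKF, LSKM, RR).
#' @param trial_speaker_orders integer matrix, speakers x trials; column t is
#'   the firing order of speakers within trial t (a permutation of speakers).
#' @param observer_station_orders integer matrix, observers x trials; row o
#'   is the station observer o occupied in each trial (a permutation of
#'   stations).
#' @param call_duration_s seconds of broadcast per call segment (default 88).
#' @return an `experiment_design` list.
#' @export
experiment_design <- function(n_trials, speaker_call_sequences,
                              trial_speaker_orders, observer_station_orders,
                              call_duration_s = 88) {
  n_speakers <- ncol(speaker_call_sequences)
  for (s in seq_len(n_speakers)) {
    if (!setequal(speaker_call_sequences[, s], CALL_LEVELS) ||
        anyDuplicated(speaker_call_sequences[, s]))
      stop("speaker ", s, " call sequence is not a permutation of the five calls",
           call. = FALSE)
  }
  if (ncol(trial_speaker_orders) != n_trials)
    stop("trial_speaker_orders must have one column per trial", call. = FALSE)
  for (t in seq_len(n_trials)) {
    if (!setequal(trial_speaker_orders[, t], seq_len(n_speakers)))
      stop("trial ", t, " speaker order is not a permutation of speakers",
           call. = FALSE)
  }
  n_stations <- max(observer_station_orders)
  for (o in seq_len(nrow(observer_station_orders))) {
    if (!setequal(observer_station_orders[o, ], seq_len(n_stations)))
      stop("observer ", o, " station order is not a permutation of stations",
           call. = FALSE)
  }
  structure(list(
    n_trials = as.integer(n_trials),
    n_speakers = as.integer(n_speakers),
    n_stations = as.integer(n_stations),
    speaker_call_sequences = speaker_call_sequences,
    trial_speaker_orders = trial_speaker_orders,
    observer_station_orders = observer_station_orders,
    call_duration_s = call_duration_s
  ), class = "experiment_design")
}

#' Expand a design into the full broadcast schedule
#'
#' One row per broadcast event (trial x speaker x call), the experimental
#' unit of the whole analysis. Within a trial, speakers fire in the trial's
#' configured order, each playing its own call sequence; nominal start times
#' place consecutive speaker sequences back to back, each call segment
#' lasting `call_duration_s` seconds.
#'
#' @param design an [experiment_design()].
#' @return data.frame with columns `event_id`, `trial`, `slot`, `speaker_id`,
#'   `sequence_position`, `call`, `start_s`, `end_s` (times within trial).
#' @export
build_broadcast_schedule <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  rows <- vector("list", design$n_trials)
  seq_len_s <- 5 * design$call_duration_s
  for (t in seq_len(design$n_trials)) {
    speakers <- design$trial_speaker_orders[, t]
    trial <- data.frame(
      trial = t,
      slot = rep(seq_along(speakers), each = 5L),
      speaker_id = rep(speakers, each = 5L),
      sequence_position = rep(1:5, times = length(speakers))
    )
    trial$call <- design$speaker_call_sequences[
      cbind(trial$sequence_position, trial$speaker_id)]
    trial$start_s <- (trial$slot - 1) * seq_len_s +
      (trial$sequence_position - 1) * design$call_duration_s
    trial$end_s <- trial$start_s + design$call_duration_s
    rows[[t]] <- trial
  }
  out <- do.call(rbind, rows)
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Build the listening-unit roster
#'
#' Combines human observers (who rotate through stations trial by trial)
#' with ARUs (fixed at one station for the whole experiment) into a single
#' roster with a station-by-trial lookup.
#'
#' @param observers observer profile data.frame in the [rawhiti_observers()]
#'   layout (ids, expertise vote, experience counts, age, gender, and
#'   `station_t*` columns).
#' @param aru_stations named integer vector: station of each ARU, names are
#'   unit ids.
#' @return a `listening_units` object: `$table` (unit_id, kind, observer_id),
#'   `$station_by_trial` (units x trials), `$observers` (profiles).
#' @export
make_units <- function(observers, aru_stations) {
  st_cols <- grep("^station_t", names(observers), value = TRUE)
  n_trials <- length(st_cols)
  human_ids <- paste0("obs", observers$observer_id)
  aru_ids <- names(aru_stations)
  if (is.null(aru_ids) || any(aru_ids == ""))
    stop("aru_stations must be a named vector", call. = FALSE)
  sbt <- rbind(
    as.matrix(observers[st_cols]),
    matrix(rep(as.integer(aru_stations), n_trials), ncol = n_trials,
           dimnames = list(aru_ids, NULL))
  )
  rownames(sbt) <- c(human_ids, aru_ids)
  colnames(sbt) <- paste0("t", seq_len(n_trials))
  structure(list(
    table = data.frame(
      unit_id = c(human_ids, aru_ids),
      kind = rep(c("human", "ARU"), c(length(human_ids), length(aru_ids))),
      observer_id = c(observers$observer_id, rep(NA_integer_, length(aru_ids))),
      stringsAsFactors = FALSE),
    station_by_trial = sbt,
    observers = observers
  ), class = "listening_units")
}

# Cross every retained unit with every event of the schedule and attach the
# spatial covariates for the unit's station in that trial.
unit_event_frame <- function(units, schedule, geometry) {
  stopifnot(inherits(units, "listening_units"))
  tab <- units$table
  n_e <- nrow(schedule)
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    df <- schedule
    df$unit_id <- tab$unit_id[i]
    df$kind <- tab$kind[i]
    df$station <- units$station_by_trial[tab$unit_id[i], df$trial]
    df
  }))
  geo <- geometry_lookup(geometry, out$station, out$speaker_id)
  out$distance_m <- geo$distance_m
  out$relative_altitude_m <- geo$relative_altitude_m
  out$line_of_sight <- geo$line_of_sight
  out$sector <- geo$sector
  rownames(out) <- NULL
  out
}

#' Score raw field records against the broadcast schedule
#'
#' Turns observer sheets / ARU annotations into one Bernoulli trial per
#' (unit, broadcast event): y = 1 when a raw record matches the event, else
#' y = 0. Matching uses trial, the species label when present, and the
#' record's clock time against the event's broadcast window (within
#' `tolerance_s`); records without a usable time fall back to
#' species-plus-order matching (earliest unmatched event of that species in
#' the trial), and every fallback is logged.
#'
#' @param raw data.frame of raw records with columns `unit_id`, `trial`,
#'   `clock_time_s`, `species` (optional columns may be NA/blank).
#' @param schedule output of [build_broadcast_schedule()].
#' @param units a `listening_units` roster.
#' @param geometry a `geometry_table` for the layout.
#' @param tolerance_s matching tolerance around the broadcast window
#'   (default 60 s).
#' @return detection data.frame (one row per unit x event) with outcome `y`
#'   and attributes `match_log` (character) and `n_fallbacks`.
#' @export
score_records <- function(raw, schedule, units, geometry, tolerance_s = 60) {
  frame <- unit_event_frame(units, schedule, geometry)
  frame$y <- 0L
  log_lines <- character(0)
  n_fallback <- 0L
  if (nrow(raw)) {
    bad_unit <- setdiff(unique(raw$unit_id), units$table$unit_id)
    bad_trial <- setdiff(unique(raw$trial), unique(schedule$trial))
    if (length(bad_unit) || length(bad_trial))
      stop("raw records reference unknown units/trials: ",
           paste(c(bad_unit, bad_trial), collapse = ", "), call. = FALSE)
    key <- paste(frame$unit_id, frame$event_id)
    for (r in seq_len(nrow(raw))) {
      uid <- raw$unit_id[r]; tr <- raw$trial[r]
      cand <- schedule[schedule$trial == tr, , drop = FALSE]
      sp <- if ("species" %in% names(raw)) raw$species[r] else NA
      if (!is.na(sp) && nzchar(sp))
        cand <- cand[cand$call == sp, , drop = FALSE]
      tm <- if ("clock_time_s" %in% names(raw)) raw$clock_time_s[r] else NA
      if (!is.na(tm)) {
        gap <- pmax(0, cand$start_s - tm, tm - cand$end_s)
        cand <- cand[gap <= tolerance_s, , drop = FALSE]
        gap <- gap[gap <= tolerance_s]
        if (!nrow(cand)) {
          log_lines <- c(log_lines, sprintf(
            "record %d (unit %s, trial %d): no event within %gs", r, uid, tr,
            tolerance_s))
          next
        }
        # nearest window; ties break toward the earlier event
        cand <- cand[order(gap, cand$start_s), , drop = FALSE]
        hit <- cand$event_id[1]
      } else {
        # fallback: no time written; earliest still-undetected matching event
        n_fallback <- n_fallback + 1L
        taken <- frame$y[match(paste(uid, cand$event_id), key)] == 1L
        cand <- cand[!taken, , drop = FALSE]
        if (!nrow(cand)) {
          log_lines <- c(log_lines, sprintf(
            "record %d (unit %s, trial %d): fallback found no free event",
            r, uid, tr))
          next
        }
        hit <- cand$event_id[order(cand$start_s)][1]
        log_lines <- c(log_lines, sprintf(
          "record %d (unit %s, trial %d): time missing, fallback match to event %d",
          r, uid, tr, hit))
      }
      frame$y[match(paste(uid, hit), key)] <- 1L
    }
  }
  attr(frame, "match_log") <- log_lines
  attr(frame, "n_fallbacks") <- n_fallback
  frame
}

#' Drop and replicate listening-unit data streams
#'
#' Field realities: some ARUs fail and their co-located working twin's data
#' is replicated under the failed unit's id so station-level comparisons
#' with human observers stay paired, and observers who did not follow the
#' protocol are excluded.
#'
#' @param records detection data.frame (must contain `unit_id` and `y`).
#' @param rules list with `drop` (unit ids to remove) and `clone`
#'   (named character vector `failed_id = source_id`).
#' @param keep_clones keep the replicated streams (`TRUE`, the paired-tally
#'   dataset) or only unique streams (`FALSE`, the model dataset).
#' @return filtered (and possibly augmented) records.
#' @export
apply_unit_rules <- function(records, rules, keep_clones = TRUE) {
  out <- records[!(records$unit_id %in% rules$drop), , drop = FALSE]
  if (keep_clones && length(rules$clone)) {
    missing <- setdiff(unname(rules$clone), unique(out$unit_id))
    if (length(missing))
      stop("replication source units absent: ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (failed in names(rules$clone)) {
      src <- out[out$unit_id == rules$clone[[failed]], , drop = FALSE]
      src$unit_id <- failed
      out <- rbind(out, src)
    }
  }
  rownames(out) <- NULL
  out
}

#' Standardize a covariate to z-scores
#'
#' Centre and scale to mean 0, spread 1 using the population standard
#' deviation (denominator n). The centre/scale used are kept as attributes
#' so the transform is invertible with [destandardize()].
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return z-scores with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("cannot standardize a constant covariate", call. = FALSE)
  structure((x - mu) / sigma, center = mu, scale = sigma)
}

#' @rdname standardize
#' @param z output of [standardize()].
#' @export
destandardize <- function(z) {
  as.numeric(z) * attr(z, "scale") + attr(z, "center")
}

# population z-scores, degenerate vectors (length 1 or constant) map to zero
zscore_safe <- function(x) {
  if (length(x) < 2 || sqrt(mean((x - mean(x))^2)) == 0)
    return(rep(0, length(x)))
  as.numeric(standardize(x))
}

#' Attach standardized covariates to a detection dataset
#'
#' Adds `distance_z` and `altitude_z`, standardized once over the whole
#' assembled dataset (all units, all events), which is the covariate scale
#' the detection model is fit on.
#'
#' @param records detection data.frame with `distance_m` and
#'   `relative_altitude_m`.
#' @return the records with `distance_z`/`altitude_z` columns.
#' @export
assemble_detections <- function(records) {
  records$distance_z <- as.numeric(standardize(records$distance_m))
  records$altitude_z <- as.numeric(standardize(records$relative_altitude_m))
  records
}
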