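#' The Rawhiti acoustic experiment design
#'
#' Printed design of the broadcast experiment run at Rawhiti, Northland,
#' New Zealand: 7 trials, 6 broadcast speakers each playing the same 5 calls
#' (two brown kiwi, two little spotted kiwi, one ruru) in a fixed per-speaker
#' random order, heard from 7 listening stations. These fixtures reproduce
#' the published tables cell-for-cell and are the default layout of the
#' synthetic-experiment generator.
#'
#' @name rawhiti
NULL

#' @describeIn rawhiti observer roster: self-assessed expertise vote (0-4),
#'   years of five-minute bird counts (`fmc_years`), kiwi call surveys
#'   (`kcs_years`), other surveys, age, gender, and the station visited in
#'   each of the 7 trials (`station_t1`..`station_t7`).
#' @export
rawhiti_observers <- function() {
  df <- read.delim(text = "
observer_id\texpertise_vote\tfmc_years\tkcs_years\tother_surveys\tage_years\tgender\tstation_t1\tstation_t2\tstation_t3\tstation_t4\tstation_t5\tstation_t6\tstation_t7
1\t2\t0\t10\t3\t66\tfemale\t1\t3\t5\t7\t6\t4\t2
2\t4\t0\t0\t0\t28\tmale\t1\t3\t5\t7\t6\t4\t2
3\t3\t0\t3\t1\t61\tfemale\t2\t1\t3\t5\t7\t6\t4
4\t2\t2\t4\t0\t42\tmale\t3\t5\t7\t6\t4\t2\t1
5\t1\t1\t7\t0\t73\tfemale\t3\t5\t7\t6\t4\t2\t1
7\t0\t0\t0\t0\t47\tfemale\t4\t2\t1\t3\t5\t7\t6
6\t3\t0\t4\t0\t74\tmale\t4\t2\t1\t3\t5\t7\t6
8\t3\t0\t0\t3\t54\tfemale\t5\t7\t6\t4\t2\t1\t3
9\t0\t0\t0\t1\t40\tfemale\t5\t7\t6\t4\t2\t1\t3
10\t4\t0\t0\t0\t25\tmale\t6\t4\t2\t1\t3\t5\t7
11\t1\t0\t1\t3\t45\tmale\t7\t6\t4\t2\t1\t3\t5
12\t2\t0\t0\t0\t30\tfemale\t7\t6\t4\t2\t1\t3\t5
13\t3\t0\t0\t0\t37\tfemale\t6\t4\t2\t1\t3\t5\t7
", stringsAsFactors = FALSE)
  df
}

# Call labels: brown kiwi female/male, little spotted kiwi female/male, ruru.
CALL_LEVELS <- c("BKF", "BKM", "LSKF", "LSKM", "RR")

#' @describeIn rawhiti per-speaker call sequences: a 5 x 6 character matrix,
#'   column s giving the order in which speaker s played the five calls.
#' @export
rawhiti_call_sequences <- function() {
  m <- matrix(c(
    "BKF",  "BKF",  "LSKF", "BKM",  "BKM",  "LSKF",
    "LSKF", "RR",   "BKF",  "BKF",  "LSKF", "RR",
    "LSKM", "BKM",  "LSKM", "RR",   "BKF",  "BKM",
    "RR",   "LSKM", "RR",   "LSKM", "RR",   "BKF",
    "BKM",  "LSKF", "BKM",  "LSKF", "LSKM", "LSKM"
  ), nrow = 5, byrow = TRUE,
  dimnames = list(position = 1:5, speaker = 1:6))
  m
}

#' @describeIn rawhiti per-trial speaker firing orders: a 6 x 7 integer
#'   matrix, column t giving the order in which the six speakers broadcast
#'   during trial t.
#' @export
rawhiti_speaker_orders <- function() {
  matrix(c(
    1L, 6L, 5L, 1L, 2L, 3L, 6L,
    6L, 2L, 4L, 3L, 5L, 5L, 5L,
    4L, 4L, 2L, 5L, 4L, 4L, 4L,
    2L, 3L, 1L, 6L, 1L, 1L, 2L,
    5L, 5L, 6L, 4L, 6L, 6L, 3L,
    3L, 1L, 3L, 2L, 3L, 2L, 1L
  ), nrow = 6, byrow = TRUE,
  dimnames = list(slot = 1:6, trial = 1:7))
}

#' @describeIn rawhiti station-by-speaker distances (m) and relative
#'   altitudes (m, station minus speaker) as published; bearings, direction
#'   sectors and line-of-sight flags were not published and are synthetic:
#'   deterministic stand-in values so the layout is complete for simulation
#'   (bearing from a fixed arithmetic rule; line of sight true for pairs
#'   closer than 150 m).
#' @export
rawhiti_geometry <- function() {
  distance <- matrix(c(
    84.6, 136.7, 267.5,  30.4, 167.9, 264.4,
    55.8, 184.3, 314.4, 115.0, 193.0, 281.3,
    61.5,  78.2, 209.1,  80.2,  95.9, 191.5,
    113.5,  57.3, 154.1, 149.7,  25.3, 116.7,
    172.5,  51.0,  90.8, 176.9,  41.7,  93.5,
    235.8, 112.8,  36.1, 237.8,  98.7,  76.2,
    260.6, 158.2,  83.8, 283.5, 124.7,  43.0
  ), nrow = 7, byrow = TRUE)
  rel_alt <- matrix(c(
    22,  -2,   3,  -2,  -4,   1,
    5, -19, -14, -19, -21, -16,
    16,  -8,  -3,  -8, -10,  -5,
    25,   1,   6,   1,  -1,   4,
    30,   6,  11,   6,   4,   9,
    17,  -7,  -2,  -7,  -9,  -4,
    27,   3,   8,   3,   1,   6
  ), nrow = 7, byrow = TRUE)
  grid <- expand.grid(station_id = 1:7, speaker_id = 1:6)
  # synthetic bearing: fixed arithmetic spread over the compass, deterministic
  bearing <- (grid$station_id * 97 + grid$speaker_id * 151) %% 360
  out <- data.frame(
    station_id = grid$station_id,
    speaker_id = grid$speaker_id,
    distance_m = distance[cbind(grid$station_id, grid$speaker_id)],
    relative_altitude_m = rel_alt[cbind(grid$station_id, grid$speaker_id)],
    line_of_sight = distance[cbind(grid$station_id, grid$speaker_id)] < 150,
    bearing_deg = as.numeric(bearing)
  )
  out$sector <- direction_sector(out$bearing_deg)
  validate_geometry_table(out)
}

#' @describeIn rawhiti the complete experiment design: trials, call
#'   sequences, speaker orders, observer station rotations and the 88-second
#'   call-segment duration.
#' @export
rawhiti_design <- function() {
  experiment_design(
    n_trials = 7L,
    speaker_call_sequences = rawhiti_call_sequences(),
    trial_speaker_orders = rawhiti_speaker_orders(),
    observer_station_orders = as.matrix(
      rawhiti_observers()[paste0("station_t", 1:7)]),
    call_duration_s = 88
  )
}

#' @describeIn rawhiti the listening-unit roster of the experiment: 13 human
#'   observers rotating stations per the published order, plus 14 ARUs (two
#'   per station, named `NE1..NE7` and `Ex1..Ex7`), fixed at their stations.
#' @export
rawhiti_units <- function() {
  make_units(rawhiti_observers(),
             aru_stations = c(setNames(1:7, paste0("NE", 1:7)),
                              setNames(1:7, paste0("Ex", 1:7))))
}

#' @describeIn rawhiti the record-exclusion and replication rules applied to
#'   the experiment's data streams: three failed ARUs (NE3, NE4, Ex2) are
#'   replaced by clones of the co-located working units (Ex3, Ex4, NE2), and
#'   one human observer is excluded. The published account does not name the
#'   excluded observer; observer 6 stands in.
#' @export
rawhiti_unit_rules <- function() {
  list(drop = c("obs6", "NE3", "NE4", "Ex2"),
       clone = c(NE3 = "Ex3", NE4 = "Ex4", Ex2 = "NE2"))
}
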