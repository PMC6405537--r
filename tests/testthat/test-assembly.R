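test_that("schedule expansion yields 7 x 6 x 5 events in the designed order", {
  design <- rawhiti_design()
  sched <- build_broadcast_schedule(design)
  expect_equal(nrow(sched), 210)
  expect_equal(anyDuplicated(sched[c("trial", "speaker_id",
                                     "sequence_position")]), 0)
  # speaker 1 opens with the brown kiwi female call
  first_sp1 <- sched[sched$speaker_id == 1 & sched$sequence_position == 1, ]
  expect_true(all(first_sp1$call == "BKF"))
  # trial 1 fires speakers in the published order
  t1 <- sched[sched$trial == 1, ]
  expect_identical(unique(t1$speaker_id[order(t1$start_s)]),
                   c(1L, 6L, 4L, 2L, 5L, 3L))
  # deterministic and idempotent
  expect_identical(sched, build_broadcast_schedule(design))
  # malformed designs are rejected
  bad <- rawhiti_speaker_orders(); bad[1, 1] <- 6L
  expect_error(experiment_design(7, rawhiti_call_sequences(), bad,
                                 as.matrix(rawhiti_observers()[
                                   paste0("station_t", 1:7)])),
               "permutation")
})

test_that("scoring produces exactly one record per unit-event pair", {
  design <- rawhiti_design()
  sched <- build_broadcast_schedule(design)
  units <- subset_units(rawhiti_units(), c("obs1", "obs2", "NE1"))
  geo <- rawhiti_geometry()
  empty <- data.frame(unit_id = character(0), trial = integer(0),
                      clock_time_s = numeric(0), species = character(0))
  rec <- score_records(empty, sched, units, geo)
  expect_equal(nrow(rec), 3 * 210)
  expect_true(all(rec$y == 0))
  expect_equal(anyDuplicated(rec[c("unit_id", "event_id")]), 0)
  expect_setequal(paste(rec$unit_id, rec$event_id),
                  as.vector(outer(c("obs1", "obs2", "NE1"), 1:210, paste)))
  # sheets exactly mirroring the schedule score all ones
  mirror <- do.call(rbind, lapply(c("obs1", "obs2", "NE1"), function(u)
    data.frame(unit_id = u, trial = sched$trial,
               clock_time_s = (sched$start_s + sched$end_s) / 2,
               species = sched$call, stringsAsFactors = FALSE)))
  rec1 <- score_records(mirror, sched, units, geo)
  expect_true(all(rec1$y == 1))
  # unknown units are an error
  bad <- data.frame(unit_id = "ghost", trial = 1L, clock_time_s = 10,
                    species = "BKF")
  expect_error(score_records(bad, sched, units, geo), "unknown")
})

test_that("scoring recovers a planted detection set exactly", {
  design <- rawhiti_design()
  sched <- build_broadcast_schedule(design)
  units <- subset_units(rawhiti_units(), c("obs1", "NE1"))
  geo <- rawhiti_geometry()
  set.seed(99)
  grid <- expand.grid(unit_id = c("obs1", "NE1"), event = 1:210,
                      stringsAsFactors = FALSE)
  planted <- grid[runif(nrow(grid)) < 0.4, ]
  sheets <- data.frame(
    unit_id = planted$unit_id,
    trial = sched$trial[planted$event],
    clock_time_s = (sched$start_s + sched$end_s)[planted$event] / 2,
    species = sched$call[planted$event], stringsAsFactors = FALSE)
  rec <- score_records(sheets, sched, units, geo)
  got <- paste(rec$unit_id, rec$event_id)[rec$y == 1]
  want <- paste(planted$unit_id, planted$event)
  expect_setequal(got, want)
})

test_that("unit rules drop, clone and preserve stream counts", {
  set.seed(5)
  records <- data.frame(
    unit_id = rep(c("obs1", "obs2", "Ex3", "NE3"), each = 10),
    y = rbinom(40, 1, 0.5), event_id = rep(1:10, 4),
    stringsAsFactors = FALSE)
  dropped <- apply_unit_rules(records, list(drop = "obs2", clone = NULL))
  expect_equal(nrow(dropped), 30)
  cloned <- apply_unit_rules(records, list(drop = "NE3",
                                           clone = c(NE3 = "Ex3")))
  expect_equal(nrow(cloned), 40)
  expect_identical(cloned$y[cloned$unit_id == "NE3"],
                   cloned$y[cloned$unit_id == "Ex3"])
  expect_error(apply_unit_rules(records, list(drop = c("NE3", "Ex3"),
                                              clone = c(NE3 = "Ex3"))),
               "absent")
})

test_that("the published exclusion rules leave 12 human and 11 unique ARU streams", {
  cfg <- simulation_config()
  ds <- simulate_detections(cfg, seed = 3)
  with_clones <- apply_unit_rules(ds$records, rawhiti_unit_rules())
  ids <- unique(with_clones$unit_id)
  expect_equal(sum(grepl("^obs", ids)), 12)
  aru_ids <- setdiff(ids, grep("^obs", ids, value = TRUE))
  expect_equal(length(aru_ids), 14)
  # the three replicated streams equal their sources element-wise
  key <- function(u) {
    d <- with_clones[with_clones$unit_id == u, ]
    d$y[order(d$trial, d$event_id)]
  }
  expect_identical(key("NE3"), key("Ex3"))
  expect_identical(key("NE4"), key("Ex4"))
  expect_identical(key("Ex2"), key("NE2"))
  # 11 distinct ARU data streams among the 14 retained ids
  streams <- vapply(aru_ids, function(u) paste(key(u), collapse = ""), "")
  expect_equal(length(unique(streams)), 11)
  # the model dataset keeps unique streams only
  model_ds <- apply_unit_rules(ds$records, rawhiti_unit_rules(),
                               keep_clones = FALSE)
  expect_equal(length(unique(model_ds$unit_id)), 23)
  expect_equal(nrow(model_ds), 23 * 210)
})

test_that("standardization is a population z-score and inverts exactly", {
  z <- standardize(c(-1, 1))
  expect_equal(as.numeric(z), c(-1, 1))
  set.seed(8)
  x <- rnorm(100, 50, 9)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sqrt(mean(as.numeric(z)^2)), 1, tolerance = 1e-12)
  expect_equal(destandardize(z), x, tolerance = 1e-9)
  expect_error(standardize(rep(3, 5)), "constant")
  # station 1 distances of the published layout against a direct computation
  d <- c(84.6, 136.7, 267.5, 30.4, 167.9, 264.4)
  mu <- sum(d) / 6
  sigma <- sqrt(sum((d - mu)^2) / 6)
  expect_equal(as.numeric(standardize(d)), (d - mu) / sigma,
               tolerance = 1e-12)
})

test_that("assembled covariates are standardized over the whole dataset", {
  cfg <- simulation_config(units = desk_units())
  ds <- simulate_detections(cfg, seed = 2)
  expect_lt(abs(mean(ds$records$distance_z)), 1e-10)
  expect_equal(sqrt(mean(ds$records$distance_z^2)), 1, tolerance = 1e-9)
  expect_lt(abs(mean(ds$records$altitude_z)), 1e-10)
})
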