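zero_truth <- function(units) {
  truth <- default_truth(units)
  truth$params <- model_parameters()
  truth$pparams <- person_parameters(
    fmc = truth$pparams$fmc * 0, kcs = truth$pparams$kcs * 0,
    os = truth$pparams$os * 0)
  truth$aru_mean <- 0
  truth$person_sd <- 1e-8
  truth$aru_sd <- 1e-8
  truth$overdispersion_sd <- 1e-8
  truth
}

test_that("a zero truth simulates fair coins", {
  cfg <- simulation_config(truth = zero_truth(rawhiti_units()))
  y <- unlist(lapply(1:2, function(s)
    simulate_detections(cfg, seed = s)$records$y))
  expect_gt(length(y), 10000)
  expect_lt(abs(mean(y) - 0.5), 0.015)
})

test_that("a strong negative distance effect makes detection fall across quartiles", {
  truth <- zero_truth(rawhiti_units())
  truth$params$distance <- c(human = -2, ARU = -2)
  cfg <- simulation_config(truth = truth)
  ds <- simulate_detections(cfg, seed = 23)
  q <- cut(ds$records$distance_z,
           quantile(ds$records$distance_z, 0:4 / 4), include.lowest = TRUE)
  rates <- tapply(ds$records$y, q, mean)
  expect_true(all(diff(rates) < 0))
})

test_that("simulation is reproducible and seed-sensitive", {
  cfg <- simulation_config(units = desk_units())
  d1 <- simulate_detections(cfg, seed = 24)
  d2 <- simulate_detections(cfg, seed = 24)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$unit_effects, d2$unit_effects)
  d3 <- simulate_detections(cfg, seed = 25)
  expect_false(identical(d1$records$y, d3$records$y))
})

test_that("overdispersion spreads per-unit detection rates", {
  # with a high baseline, extra per-observation noise pushes probabilities
  # toward one half, inflating the replicate-to-replicate spread of each
  # unit's detection rate
  spread <- function(od_sd, seeds) {
    truth <- zero_truth(rawhiti_units())
    truth$params$intercept <- 2
    truth$overdispersion_sd <- od_sd
    cfg <- simulation_config(truth = truth)
    rates <- unlist(lapply(seeds, function(s) {
      ds <- simulate_detections(cfg, seed = s)
      tapply(ds$records$y, ds$records$unit_id, mean)
    }))
    stats::var(rates)
  }
  expect_gt(spread(4, 1:5), spread(0.01, 1:5))
})

test_that("sheets round-trip exactly with zero noise", {
  cfg <- simulation_config(units = subset_units(
    rawhiti_units(), c("obs1", "obs3", "NE1", "Ex5")))
  ds <- simulate_detections(cfg, seed = 26)
  sheets <- simulate_observer_sheets(
    ds, sheet_noise(p_omit_time = 0, p_omit_species = 0, jitter_sd_s = 0),
    seed = 27)
  sched <- build_broadcast_schedule(cfg$design)
  rec <- score_records(sheets, sched, cfg$units, cfg$layout)
  key <- function(d) d[order(d$unit_id, d$event_id), c("unit_id", "event_id", "y")]
  expect_equal(key(rec)$y, key(ds$records)$y)
  expect_equal(attr(rec, "n_fallbacks"), 0)
})

test_that("missing times force the fallback matcher and are all logged", {
  cfg <- simulation_config(units = subset_units(rawhiti_units(),
                                                c("obs1", "obs2")))
  ds <- simulate_detections(cfg, seed = 28)
  sheets <- simulate_observer_sheets(
    ds, sheet_noise(p_omit_time = 1, p_omit_species = 0, jitter_sd_s = 0),
    seed = 29)
  expect_true(all(is.na(sheets$clock_time_s)))
  sched <- build_broadcast_schedule(cfg$design)
  rec <- score_records(sheets, sched, cfg$units, cfg$layout)
  expect_equal(attr(rec, "n_fallbacks"), nrow(sheets))
  expect_gte(length(attr(rec, "match_log")), nrow(sheets))
  # fallback preserves per-(unit, trial, species) detection counts
  agg <- function(d) tapply(d$y, list(d$unit_id, d$trial, d$call), sum)
  expect_equal(agg(rec), agg(ds$records))
})

test_that("modest clock jitter inside the tolerance barely costs recovery", {
  cfg <- simulation_config(units = subset_units(
    rawhiti_units(), c("obs1", "obs4", "NE2", "Ex6")))
  ds <- simulate_detections(cfg, seed = 30)
  sheets <- simulate_observer_sheets(
    ds, sheet_noise(p_omit_time = 0, p_omit_species = 0, jitter_sd_s = 10),
    seed = 31)
  sched <- build_broadcast_schedule(cfg$design)
  rec <- score_records(sheets, sched, cfg$units, cfg$layout, tolerance_s = 60)
  key <- function(d) d[order(d$unit_id, d$event_id), "y"]
  expect_gte(mean(key(rec) == key(ds$records)), 0.99)
})

test_that("layouts generate from coordinates and pass through validated", {
  set.seed(32)
  st <- geo_point(runif(7, -35.4, -35.2), runif(7, 174.2, 174.4),
                  runif(7, 0, 100))
  sp <- geo_point(runif(6, -35.4, -35.2), runif(6, 174.2, 174.4),
                  runif(6, 0, 100))
  g <- generate_layout(stations = st, speakers = sp)
  expect_equal(nrow(g), 42)
  # independent recomputation of one random pair
  i <- sample(nrow(g), 1)
  p1 <- geo_point(st$lat[g$station_id[i]], st$lon[g$station_id[i]],
                  st$alt[g$station_id[i]])
  p2 <- geo_point(sp$lat[g$speaker_id[i]], sp$lon[g$speaker_id[i]],
                  sp$alt[g$speaker_id[i]])
  expect_equal(g$distance_m[i], haversine_distance(p1, p2))
  expect_equal(g$relative_altitude_m[i], p1$alt - p2$alt)
  # fixture table passes through unchanged
  expect_identical(generate_layout(table = rawhiti_geometry()),
                   rawhiti_geometry())
  expect_error(generate_layout(), "supply either")
  # the published fixture row used downstream: station 5, speaker 3
  expect_equal(rawhiti_geometry()$distance_m[
    rawhiti_geometry()$station_id == 5 & rawhiti_geometry()$speaker_id == 3],
    90.8)
})
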