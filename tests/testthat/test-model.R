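test_that("linear predictor reduces correctly in degenerate cases", {
  rec <- tiny_records(10)
  expect_equal(linear_predictor(rec, model_parameters()), rep(0, 10))
  expect_equal(linear_predictor(rec, model_parameters(intercept = 1.5)),
               rep(1.5, 10))
})

test_that("linear predictor equals an independent term-by-term sum", {
  # hand-constructed record: human, station 4, trial 2, standardized
  # distance 0.5, altitude -1, in line of sight, BKM call, sector 5
  rec <- data.frame(unit_id = "obs2", kind = "human", trial = 2L,
                    station = 4L, distance_z = 0.5, altitude_z = -1,
                    line_of_sight = TRUE, call = "BKM", sector = 5L,
                    stringsAsFactors = FALSE)
  params <- tiny_params(c("obs1", "obs2", "NE1"))
  hand <- unname(0.4 + 0 + (-0.1) + (-0.7 * 0.5) + (0.2 * -1) + 0.3 +
    0.2 + params$direction["human", 5] + (-0.25))
  expect_equal(linear_predictor(rec, params), hand, tolerance = 1e-12)
  # every record of a random dataset, against a slow loop
  recs <- tiny_records(40, seed = 4)
  params$eps <- seq(-0.5, 0.5, length.out = 40)
  slow <- vapply(seq_len(40), function(i) {
    r <- recs[i, ]
    params$intercept +
      (if (r$kind == "human") params$station["human", r$station] else 0) +
      params$trial[r$kind, r$trial] +
      params$distance[[r$kind]] * r$distance_z +
      params$altitude[[r$kind]] * r$altitude_z +
      params$los[r$kind, if (r$line_of_sight) 1 else 2] +
      params$call[r$kind, match(r$call, CALL_LEVELS_T)] +
      params$direction[r$kind, r$sector] +
      params$unit[[r$unit_id]] + params$eps[i]
  }, 0.0)
  expect_equal(linear_predictor(recs, params), slow, tolerance = 1e-12)
  expect_error(linear_predictor(transform(recs, station = 9L), params),
               "out of range")
})

test_that("the sigmoid link behaves and never overflows", {
  expect_equal(detection_probability(0), 0.5)
  expect_equal(detection_probability(log(3)), 0.75)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(detection_probability(-x), 1 - detection_probability(x))
  expect_true(all(diff(detection_probability(x)) > 0))
  # extreme linear predictors saturate cleanly instead of overflowing
  expect_equal(detection_probability(800), 1)
  expect_equal(detection_probability(-800), 0)
  expect_false(any(is.nan(detection_probability(c(-1e6, 1e6)))))
})

test_that("raising an effect with a positive covariate raises the probability", {
  rec <- tiny_records(20, seed = 6)
  rec$distance_z <- abs(rec$distance_z)
  params <- tiny_params(c("obs1", "obs2", "NE1"))
  p0 <- detection_probability(linear_predictor(rec, params))
  params$distance <- params$distance + 0.5
  p1 <- detection_probability(linear_predictor(rec, params))
  expect_true(all(p1 > p0))
})

test_that("with only an intercept the model is flat at sigmoid(int)", {
  rec <- tiny_records(30, seed = 7)
  p <- detection_probability(linear_predictor(
    rec, model_parameters(intercept = -0.8)))
  expect_equal(p, rep(plogis(-0.8), 30))
})

test_that("person-level means reduce and match a hand computation", {
  prof <- data.frame(expertise_vote = 4L, fmc_years = 0L, kcs_years = 0L,
                     other_surveys = 0L, gender = "male", age_z = -0.62,
                     stringsAsFactors = FALSE)
  zero <- person_parameters(fmc = c("0" = 0), kcs = c("0" = 0),
                            os = c("0" = 0))
  expect_equal(person_mean(prof, zero), 0)
  zero$intercept <- 0.3
  expect_equal(person_mean(prof, zero), 0.3)
  pp <- tiny_pparams()
  hand <- pp$intercept + pp$vote[["vote4"]] + pp$fmc[["0"]] + pp$kcs[["0"]] +
    pp$os[["0"]] + pp$gender[["male"]] + pp$age_coef * -0.62
  expect_equal(person_mean(prof, pp), hand, tolerance = 1e-12)
  expect_error(person_mean(transform(prof, expertise_vote = 9L), pp),
               "unknown vote")
})

test_that("log posterior has the right degenerate values and additivity", {
  rec1 <- data.frame(unit_id = "u", kind = "human", trial = 1L, station = 1L,
                     distance_z = 0, altitude_z = 0, line_of_sight = TRUE,
                     call = "BKF", sector = 1L, y = 1L,
                     stringsAsFactors = FALSE)
  # intercept-only model at 0: likelihood term is -log 2; remove the prior
  # by evaluating the prior density at zero and subtracting
  pr <- prior_spec()
  base <- log_posterior(rec1, model_parameters(), priors = pr)
  prior_at_zero <- dnorm(0, 0, 1 / sqrt(pr$default_precision), log = TRUE)
  expect_equal(base - prior_at_zero, -log(2), tolerance = 1e-12)
  rec2 <- rbind(rec1, rec1)
  expect_equal(log_posterior(rec2, model_parameters(), priors = pr) -
                 prior_at_zero, -2 * log(2), tolerance = 1e-12)
})

test_that("log posterior equals a brute-force oracle on random small datasets", {
  prof2 <- data.frame(unit_id = c("obs1", "obs2"),
                      expertise_vote = c(2L, 4L), fmc_years = c(0L, 1L),
                      kcs_years = c(3L, 0L), other_surveys = c(0L, 2L),
                      gender = c("female", "male"), age_z = c(-1, 1),
                      stringsAsFactors = FALSE)
  for (s in 1:10) {
    rec <- tiny_records(15, seed = s)
    set.seed(100 + s)
    params <- tiny_params(c("obs1", "obs2", "NE1"), n_eps = 15)
    params$unit <- params$unit + rnorm(3, 0, 0.2)
    pp <- tiny_pparams(seed = 200 + s)
    pr <- prior_spec(overdispersion_precision = 2)
    got <- log_posterior(rec, params, pp, prof2, pr)
    want <- brute_log_posterior(rec, params, pp, prof2, pr)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("the parameter graph keeps person terms and the ARU mean in their branches", {
  cfg <- simulation_config(units = desk_units())
  ds <- simulate_detections(cfg, seed = 9)
  # ARU-only data: no person-level parameters anywhere
  aru <- ds$records[ds$records$kind == "ARU", ]
  f_aru <- model_frame(aru, cfg$units, model_config())
  expect_length(f_aru$gamma_names, 0)
  expect_true(length(f_aru$aru_unit_par) > 0)
  # human-only data: person level present, no ARU sample mean
  hum <- ds$records[ds$records$kind == "human", ]
  f_hum <- model_frame(hum, cfg$units, model_config())
  expect_gt(length(f_hum$gamma_names), 0)
  expect_length(f_hum$aru_unit_par, 0)
  fit <- sample_posterior(f_hum, mcmc = mcmc_config(
    burn_in = 50, n_chains = 1, n_iterations = 100, thin = 5), seed = 1)
  expect_false("aru_mean" %in% fit$par_names)
})

test_that("flattened draws reproduce the structured linear predictor", {
  cfg <- simulation_config(units = desk_units())
  ds <- simulate_detections(cfg, seed = 10)
  frame <- model_frame(ds$records, cfg$units, model_config())
  set.seed(11)
  draw <- setNames(rnorm(length(frame$par_names) + length(frame$gamma_names)
                         + 1, 0, 0.5),
                   c(frame$par_names, frame$gamma_names, "aru_mean"))
  X <- kiwidetect:::frame_design_matrix(frame)
  esp_flat <- as.numeric(X %*% draw[frame$par_names])
  st <- params_from_draw(frame, draw)
  esp_struct <- linear_predictor(ds$records, st$params)
  expect_equal(esp_flat, esp_struct, tolerance = 1e-10)
})

test_that("the compiled sampler targets the reference log posterior", {
  cfg <- simulation_config(units = subset_units(rawhiti_units(),
                                                c("obs1", "obs2", "NE1")))
  ds <- simulate_detections(cfg, seed = 12)
  mc <- model_config(priors = prior_spec(overdispersion_precision = 4))
  frame <- model_frame(ds$records, cfg$units, mc)
  fit <- sample_posterior(frame, mcmc = mcmc_config(
    burn_in = 100, n_chains = 2, n_iterations = 200, thin = 10), seed = 13)
  for (ch in 1:2) {
    fin <- fit$finals[[ch]]
    draw <- setNames(c(fin$theta_final, fin$gamma_final, fin$m_final),
                     fit$par_names)
    st <- params_from_draw(frame, draw, eps = fin$eps_final)
    ref <- log_posterior(ds$records, st$params, st$pparams,
                         frame$profiles, mc$priors)
    expect_equal(fin$logpost_final, ref, tolerance = 1e-8)
  }
})
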