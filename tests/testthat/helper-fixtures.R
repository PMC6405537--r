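# Shared builders for the test suite. Everything is generated in code.

# random geo_points, well away from the poles
random_points <- function(n, lat_range = c(-60, 60)) {
  geo_point(runif(n, lat_range[1], lat_range[2]), runif(n, -180, 180),
            runif(n, 0, 500))
}

# independently coded spherical law of cosines (oracle for the Haversine path)
slc_distance <- function(p1, p2, R = 6371000) {
  phi1 <- p1$lat * pi / 180; phi2 <- p2$lat * pi / 180
  dl <- (p2$lon - p1$lon) * pi / 180
  ca <- sin(phi1) * sin(phi2) + cos(phi1) * cos(phi2) * cos(dl)
  R * acos(pmin(pmax(ca, -1), 1))
}

# independently coded planar small-separation bearing (equirectangular)
planar_bearing <- function(p1, p2) {
  dx <- (p2$lon - p1$lon) * cos((p1$lat + p2$lat) / 2 * pi / 180)
  dy <- p2$lat - p1$lat
  (atan2(dx, dy) * 180 / pi) %% 360
}

# a tiny assembled detection dataset with arbitrary but valid covariates
tiny_records <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    unit_id = rep(c("obs1", "obs2", "NE1"), length.out = n),
    kind = NA_character_, trial = sample(1:3, n, TRUE),
    station = sample(1:4, n, TRUE),
    distance_z = rnorm(n), altitude_z = rnorm(n),
    line_of_sight = runif(n) > 0.5,
    call = sample(CALL_LEVELS_T, n, TRUE),
    sector = sample(1:8, n, TRUE),
    y = rbinom(n, 1, 0.5), stringsAsFactors = FALSE
  ) -> df
  df$kind <- ifelse(grepl("^obs", df$unit_id), "human", "ARU")
  df
}

CALL_LEVELS_T <- c("BKF", "BKM", "LSKF", "LSKM", "RR")

# a two-human, one-ARU roster with simple profiles
tiny_units <- function() {
  obs <- data.frame(
    observer_id = 1:2, expertise_vote = c(2L, 4L), fmc_years = c(0L, 1L),
    kcs_years = c(3L, 0L), other_surveys = c(0L, 2L),
    age_years = c(30L, 55L), gender = c("female", "male"),
    station_t1 = c(1L, 2L), station_t2 = c(2L, 3L), station_t3 = c(3L, 1L),
    stringsAsFactors = FALSE)
  # pad to permutations of 1..3 over 3 trials
  make_units(obs, aru_stations = c(NE1 = 2L))
}

# arbitrary small full parameter set over the tiny dataset's dimensions
tiny_params <- function(unit_ids, n_eps = NULL) {
  model_parameters(
    intercept = 0.4,
    station = rbind(human = c(0.1, -0.2, 0.3, 0), ARU = rep(0, 4)),
    trial = rbind(human = c(0.05, -0.1, 0.2), ARU = c(0.1, 0, -0.3)),
    distance = c(human = -0.7, ARU = -1.1),
    altitude = c(human = 0.2, ARU = -0.4),
    los = rbind(human = c(0.3, -0.3), ARU = c(0.5, -0.5)),
    call = rbind(human = c(0.1, 0.2, -0.1, 0, 0.05),
                 ARU = c(-0.4, 0.5, 0, 0.1, -0.2)),
    direction = rbind(human = seq(-0.2, 0.5, length.out = 8),
                      ARU = seq(0.3, -0.4, length.out = 8)),
    unit = setNames(c(0.15, -0.25, 0.6), unit_ids),
    eps = if (!is.null(n_eps)) seq(-0.1, 0.1, length.out = n_eps),
    aru_mean = 0.2)
}

# brute-force log posterior: plain loops, independent of the package's
# vectorised implementation
brute_log_posterior <- function(records, params, pparams, profiles, priors,
                                experience = "categorical") {
  lp <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    esp <- params$intercept
    if (!is.null(params$station) && r$kind == "human")
      esp <- esp + params$station["human", r$station]
    if (!is.null(params$trial)) esp <- esp + params$trial[r$kind, r$trial]
    if (!is.null(params$distance))
      esp <- esp + params$distance[[r$kind]] * r$distance_z
    if (!is.null(params$altitude))
      esp <- esp + params$altitude[[r$kind]] * r$altitude_z
    if (!is.null(params$los))
      esp <- esp + params$los[r$kind, if (r$line_of_sight) 1 else 2]
    if (!is.null(params$call))
      esp <- esp + params$call[r$kind, match(r$call, CALL_LEVELS_T)]
    if (!is.null(params$direction))
      esp <- esp + params$direction[r$kind, r$sector]
    if (!is.null(params$unit)) esp <- esp + params$unit[[r$unit_id]]
    if (!is.null(params$eps)) esp <- esp + params$eps[i]
    p <- 1 / (1 + exp(-esp))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    lp <- lp + if (r$y == 1) log(p) else log(1 - p)
  }
  sd0 <- 1 / sqrt(priors$default_precision)
  pr0 <- function(x) if (is.null(x)) 0 else sum(dnorm(x, 0, sd0, log = TRUE))
  lp <- lp + pr0(params$intercept) +
    (if (is.null(params$station)) 0 else pr0(params$station["human", ])) +
    pr0(params$trial) + pr0(params$distance) + pr0(params$altitude) +
    pr0(params$los) + pr0(params$call) + pr0(params$direction)
  if (!is.null(params$unit)) {
    for (id in names(params$unit)) {
      kind <- records$kind[match(id, records$unit_id)]
      if (kind == "human") {
        pr <- profiles[profiles$unit_id == id, ]
        mu <- pparams$intercept +
          pparams$vote[[paste0("vote", pr$expertise_vote)]] +
          pparams$fmc[[as.character(pr$fmc_years)]] +
          pparams$kcs[[as.character(pr$kcs_years)]] +
          pparams$os[[as.character(pr$other_surveys)]] +
          pparams$gender[[pr$gender]] + pparams$age_coef * pr$age_z
        lp <- lp + dnorm(params$unit[[id]], mu,
                         1 / sqrt(priors$person_precision), log = TRUE)
      } else {
        lp <- lp + dnorm(params$unit[[id]], params$aru_mean,
                         1 / sqrt(priors$aru_precision), log = TRUE)
      }
    }
    if (any(records$kind == "human"))
      for (comp in c("intercept", "vote", "fmc", "kcs", "os", "gender",
                     "age_coef"))
        lp <- lp + pr0(pparams[[comp]])
    if (any(records$kind == "ARU"))
      lp <- lp + dnorm(params$aru_mean, 0, 1 / sqrt(priors$hyper_precision),
                       log = TRUE)
  }
  if (!is.null(params$eps))
    lp <- lp + sum(dnorm(params$eps, 0,
                         1 / sqrt(priors$overdispersion_precision),
                         log = TRUE))
  lp
}

# random person-level parameter set over the tiny roster's levels
tiny_pparams <- function(seed = 1) {
  set.seed(seed)
  person_parameters(
    intercept = rnorm(1, 0, 0.3),
    vote = setNames(rnorm(5, 0, 0.3), paste0("vote", 0:4)),
    fmc = setNames(rnorm(2, 0, 0.3), c("0", "1")),
    kcs = setNames(rnorm(2, 0, 0.3), c("0", "3")),
    os = setNames(rnorm(2, 0, 0.3), c("0", "2")),
    gender = c(female = rnorm(1, 0, 0.3), male = rnorm(1, 0, 0.3)),
    age_coef = rnorm(1, 0, 0.3))
}
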