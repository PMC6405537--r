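# Internal bridge between an assembled detection dataset and the sampler:
# flattens the model's parameter blocks into one vector with a name, a prior
# and an (observation, weight) incidence structure per element.

#' Build the model frame for a detection dataset
#'
#' Lays out every free parameter of the configured model over the assembled
#' dataset: covariate-class effects per unit class, slopes on the
#' standardized covariates, individual unit contributions with their
#' hierarchical priors, the person-level design matrix for human observers,
#' and the overdispersion switch. The frame is what the MCMC sampler,
#' predictions and summaries all share.
#'
#' @param records assembled detection data.frame (see
#'   [assemble_detections()]) with outcome `y`.
#' @param units `listening_units` roster covering every unit in `records`
#'   (needed for human profiles; may be `NULL` for ARU-only or unit-free
#'   models).
#' @param config a [model_config()].
#' @return a `model_frame` list; see the source for fields.
#' @export
model_frame <- function(records, units = NULL, config = model_config()) {
  inc <- config$include
  n <- nrow(records)
  if (n < 1) stop("cannot build a model frame from zero observations",
                  call. = FALSE)
  if (!all(records$y %in% 0:1)) stop("y must be binary", call. = FALSE)
  classes <- intersect(UNIT_CLASSES, unique(records$kind))
  pr <- config$priors

  par_names <- character(0)
  prior_prec <- prior_mean0 <- numeric(0)
  prior_type <- human_of_par <- integer(0)
  obs_par <- list(); obs_w <- list()
  blocks <- list()

  add_block <- function(block, class_of, level_of, idx_obs, w_obs, names,
                        prec, type = 0L, hop = 0L) {
    off <- length(par_names)
    par_names <<- c(par_names, names)
    prior_prec <<- c(prior_prec, rep_len(prec, length(names)))
    prior_mean0 <<- c(prior_mean0, numeric(length(names)))
    prior_type <<- c(prior_type, rep_len(type, length(names)))
    human_of_par <<- c(human_of_par, rep_len(hop, length(names)))
    obs_par[[length(obs_par) + 1L]] <<- ifelse(idx_obs > 0L, idx_obs + off, 0L)
    obs_w[[length(obs_w) + 1L]] <<- w_obs
    blocks[[length(blocks) + 1L]] <<- data.frame(
      block = block, class = class_of, level = level_of,
      idx = off + seq_along(names), stringsAsFactors = FALSE)
    invisible(NULL)
  }
  class_block <- function(block, short, level_obs, levels) {
    # one effect per (unit class x level)
    kmat <- expand.grid(level = levels, class = classes,
                        stringsAsFactors = FALSE)[2:1]
    idx <- match(paste(records$kind, level_obs),
                 paste(kmat$class, kmat$level))
    add_block(block, kmat$class, as.character(kmat$level), idx, rep(1, n),
              sprintf("b_%s[%s,%s]", short, kmat$class, kmat$level),
              pr$default_precision)
  }

  add_block("intercept", "both", "int", rep(1L, n), rep(1, n), "int",
            pr$default_precision)
  if ("station" %in% inc && "human" %in% classes) {
    stations <- seq_len(max(records$station))
    idx <- ifelse(records$kind == "human", records$station, 0L)
    add_block("station", "human", as.character(stations), idx, rep(1, n),
              sprintf("b_st[human,%d]", stations), pr$default_precision)
  }
  if ("trial" %in% inc)
    class_block("trial", "t", records$trial,
                seq_len(max(records$trial)))
  if ("distance" %in% inc) {
    idx <- match(records$kind, classes)
    add_block("distance", classes, "dis", idx, records$distance_z,
              sprintf("b_dis[%s]", classes), pr$default_precision)
  }
  if ("altitude" %in% inc) {
    idx <- match(records$kind, classes)
    add_block("altitude", classes, "alt", idx, records$altitude_z,
              sprintf("b_alt[%s]", classes), pr$default_precision)
  }
  if ("los" %in% inc)
    class_block("los", "los", ifelse(records$line_of_sight, "in", "out"),
                LOS_LEVELS)
  if ("call" %in% inc)
    class_block("call", "ca", records$call, CALL_LEVELS)
  if ("direction" %in% inc)
    class_block("direction", "dir", records$sector, 1:8)

  # unit contributions with hierarchical prior means
  human_ids <- aru_ids <- character(0)
  Z <- matrix(0, 0, 0); gamma_names <- character(0)
  profiles <- NULL
  if ("unit" %in% inc) {
    ids <- unique(records$unit_id)
    kind_of <- records$kind[match(ids, records$unit_id)]
    human_ids <- ids[kind_of == "human"]
    aru_ids <- ids[kind_of == "ARU"]
    idx <- match(records$unit_id, c(human_ids, aru_ids))
    if (length(human_ids)) {
      if (is.null(units))
        stop("units roster required when human units are in the model",
             call. = FALSE)
      prof <- units$observers
      prof$unit_id <- paste0("obs", prof$observer_id)
      prof <- prof[match(human_ids, prof$unit_id), , drop = FALSE]
      if (anyNA(prof$observer_id))
        stop("profiles missing for some human units", call. = FALSE)
      prof$age_z <- zscore_safe(prof$age_years)
      pd <- person_design(prof, config$experience)
      Z <- pd$Z; gamma_names <- pd$names
      profiles <- prof
    }
    add_block("unit", kind_of[match(c(human_ids, aru_ids), ids)],
              c(human_ids, aru_ids), idx, rep(1, n),
              sprintf("b_unit[%s]", c(human_ids, aru_ids)),
              c(rep(pr$person_precision, length(human_ids)),
                rep(pr$aru_precision, length(aru_ids))),
              type = rep(c(1L, 2L), c(length(human_ids), length(aru_ids))),
              hop = c(seq_along(human_ids), rep(0L, length(aru_ids))))
  }

  blocks <- do.call(rbind, blocks)
  n_par <- length(par_names)
  unit_par <- blocks$idx[blocks$block == "unit"]
  human_unit_par <- unit_par[seq_along(human_ids)]
  aru_unit_par <- unit_par[length(human_ids) + seq_along(aru_ids)]

  structure(list(
    y = as.integer(records$y), n = n, records = records,
    classes = classes, blocks = blocks,
    par_names = par_names, n_par = n_par,
    obs_par = matrix(unlist(obs_par), nrow = n),
    obs_w = matrix(unlist(obs_w), nrow = n),
    prior_prec = prior_prec, prior_mean0 = prior_mean0,
    prior_type = prior_type, human_of_par = human_of_par,
    Z = Z, gamma_names = gamma_names,
    gamma_prec = rep(pr$default_precision, length(gamma_names)),
    human_unit_par = as.integer(human_unit_par),
    aru_unit_par = as.integer(aru_unit_par),
    profiles = profiles,
    include_eps = "overdispersion" %in% inc,
    config = config
  ), class = "model_frame")
}

# person-level design matrix: intercept, the five vote classes, experience
# classes (or linear years), the gender pair, standardized age
person_design <- function(prof, experience) {
  H <- nrow(prof)
  cols <- list(p_int = rep(1, H))
  for (v in 0:4) cols[[paste0("p_vote", v)]] <- as.numeric(prof$expertise_vote == v)
  if (experience == "categorical") {
    for (nm in c("fmc_years", "kcs_years", "other_surveys")) {
      short <- c(fmc_years = "fmc", kcs_years = "kcs", other_surveys = "os")[[nm]]
      for (lv in sort(unique(prof[[nm]])))
        cols[[paste0("p_", short, lv)]] <- as.numeric(prof[[nm]] == lv)
    }
  } else {
    cols$p_fmc <- prof$fmc_years
    cols$p_kcs <- prof$kcs_years
    cols$p_os <- prof$other_surveys
  }
  cols$p_gen_female <- as.numeric(prof$gender == "female")
  cols$p_gen_male <- as.numeric(prof$gender == "male")
  cols$p_age <- prof$age_z
  list(Z = matrix(unlist(cols), nrow = H), names = names(cols))
}

# dense n x n_par model matrix for predictions (eps excluded)
frame_design_matrix <- function(frame) {
  obs_par <- frame$obs_par; obs_w <- frame$obs_w; n <- frame$n
  X <- matrix(0, n, frame$n_par, dimnames = list(NULL, frame$par_names))
  for (k in seq_len(ncol(obs_par))) {
    j <- obs_par[, k]
    keep <- j > 0L
    X[cbind(which(keep), j[keep])] <-
      X[cbind(which(keep), j[keep])] + obs_w[keep, k]
  }
  X
}

#' Reconstruct structured parameters from a flat draw
#'
#' Inverse of the frame's flattening: turns one row of the posterior draw
#' matrix back into [model_parameters()] / [person_parameters()] objects so
#' the structured operations ([linear_predictor()], [log_posterior()]) can
#' be evaluated at sampled values.
#'
#' @param frame a [model_frame()].
#' @param draw named numeric vector over `frame$par_names`,
#'   `frame$gamma_names` and (if present) `aru_mean`.
#' @param eps optional per-observation overdispersion vector.
#' @return list with `params` and (when humans are present) `pparams`.
#' @export
params_from_draw <- function(frame, draw, eps = NULL) {
  b <- frame$blocks
  take <- function(block) b[b$block == block, , drop = FALSE]
  getm <- function(block) {
    rows <- take(block)
    if (!nrow(rows)) return(NULL)
    levels <- unique(rows$level)
    m <- matrix(0, 2, length(levels),
                dimnames = list(UNIT_CLASSES, levels))
    m[cbind(rows$class, rows$level)] <- draw[rows$idx]
    m
  }
  getv <- function(block) {
    rows <- take(block)
    if (!nrow(rows)) return(NULL)
    out <- setNames(rep(0, 2), UNIT_CLASSES)
    out[rows$class] <- draw[rows$idx]
    out
  }
  st <- NULL
  if (nrow(take("station"))) {
    rows <- take("station")
    st <- matrix(0, 2, nrow(rows),
                 dimnames = list(UNIT_CLASSES, rows$level))
    st["human", ] <- draw[rows$idx]
  }
  unit <- NULL
  if (nrow(take("unit"))) {
    rows <- take("unit")
    unit <- setNames(draw[rows$idx], rows$level)
  }
  params <- model_parameters(
    intercept = unname(draw[take("intercept")$idx]),
    station = st,
    trial = getm("trial"),
    distance = getv("distance"), altitude = getv("altitude"),
    los = getm("los"), call = getm("call"),
    direction = getm("direction"),
    unit = unit, eps = eps,
    aru_mean = if ("aru_mean" %in% names(draw)) unname(draw[["aru_mean"]]) else 0)
  pparams <- NULL
  if (length(frame$gamma_names)) {
    g <- draw[frame$gamma_names]
    pick <- function(prefix) {
      nm <- grep(paste0("^p_", prefix), frame$gamma_names, value = TRUE)
      setNames(unname(g[nm]), sub(paste0("^p_", prefix), "", nm))
    }
    if (frame$config$experience == "categorical") {
      pparams <- person_parameters(
        intercept = unname(g[["p_int"]]),
        vote = setNames(unname(g[paste0("p_vote", 0:4)]), paste0("vote", 0:4)),
        fmc = pick("fmc"), kcs = pick("kcs"), os = pick("os"),
        gender = c(female = unname(g[["p_gen_female"]]),
                   male = unname(g[["p_gen_male"]])),
        age_coef = unname(g[["p_age"]]))
    } else {
      pparams <- person_parameters(
        intercept = unname(g[["p_int"]]),
        vote = setNames(unname(g[paste0("p_vote", 0:4)]), paste0("vote", 0:4)),
        fmc = unname(g[["p_fmc"]]), kcs = unname(g[["p_kcs"]]),
        os = unname(g[["p_os"]]),
        gender = c(female = unname(g[["p_gen_female"]]),
                   male = unname(g[["p_gen_male"]])),
        age_coef = unname(g[["p_age"]]))
    }
  }
  list(params = params, pparams = pparams)
}
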