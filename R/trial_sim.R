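# Clinical-trial simulator: population sampling, 3-weekly dose titration
# among the PED2.5/5/7.5/10 levels, sparse PK sampling windows, observation
# generation with assay-limit (LLOQ) censoring. Ships presets emulating a
# 12-week placebo-controlled OAB titration trial ("lion"), two 52-week
# open-label NDO titration trials ("monkey", "marmoset"), and a richly
# sampled single-dose OAB trial at 3x the weight-adjusted dose ("giraffe").

.PED_LEVELS <- c(2.5, 5, 7.5, 10)

#' Trial design configuration
#'
#' Loads one of the shipped trial presets (`"lion"`, `"monkey"`,
#' `"marmoset"`, `"giraffe"`) or a custom YAML design file. The returned
#' list can be edited field-wise (e.g. stratum sizes) before simulation.
#'
#' @param preset Preset name, or a path to a YAML trial design.
#' @return A validated list of class `trial_config`.
#' @seealso [read_trial_config()] for the schema.
#' @export
trial_config <- function(preset = "lion") {
  path <- if (file.exists(preset)) preset else
    system.file("extdata", "configs", paste0(preset, ".yaml"), package = "pedpk")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown trial preset or missing file: ", preset)
  }
  read_trial_config(path)
}

.TRIAL_KEYS <- c("name", "population", "strata", "agp", "titration_weeks",
                 "max_titration_week", "pk_weeks", "duration_weeks",
                 "windows", "lloq", "uloq", "single_dose", "dose_multiple",
                 "rich_grid", "formulation")

#' Read and validate a trial design file
#'
#' YAML schema: `name`, `population` (OAB/NDO), `strata` (list of
#' `label`, `age_min`, `age_max`, `n_subjects`, and either `weight_mean`/`weight_sd`
#' or `weight_by_age: true` with `weight_cv`), `agp` (`meanlog`, `sdlog`),
#' `titration_weeks`, `max_titration_week`, `pk_weeks`, `duration_weeks`,
#' `windows` (list of `label`, `lo`, `hi` hours relative to the visit dose,
#' optional `final_only`), `lloq`, `uloq`, `formulation`, and for
#' single-dose designs `single_dose: true`, `dose_multiple`, `rich_grid`.
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A list of class `trial_config`.
#' @export
read_trial_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .TRIAL_KEYS)
  if (length(unknown)) {
    stop("unknown trial config keys: ", paste(unknown, collapse = ", "))
  }
  need <- c("name", "population", "strata", "agp", "pk_weeks",
            "duration_weeks", "windows", "lloq", "uloq")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("trial config missing keys: ", paste(miss, collapse = ", "))
  if (is.null(cfg$single_dose)) cfg$single_dose <- FALSE
  if (is.null(cfg$formulation)) cfg$formulation <- "A"
  if (is.null(cfg$titration_weeks)) cfg$titration_weeks <- numeric(0)
  if (is.null(cfg$max_titration_week)) cfg$max_titration_week <- 0
  for (st in cfg$strata) {
    if (st$n_subjects < 0 || st$age_min >= st$age_max) stop("invalid stratum in trial config")
  }
  if (!length(cfg$windows) && !cfg$single_dose) stop("sampling windows must be non-empty")
  if (is.unsorted(cfg$titration_weeks)) stop("titration weeks must be ordered")
  if (any(cfg$pk_weeks > cfg$duration_weeks)) {
    stop("PK sampling visit after trial end")
  }
  if (cfg$lloq <= 0 || cfg$uloq <= cfg$lloq) stop("invalid assay limits")
  class(cfg) <- "trial_config"
  cfg
}

# piecewise-linear age -> weight default for the infant/young-child design
.WT_BY_AGE <- list(age = c(0.5, 1, 2, 3, 4, 5),
                   wt  = c(7.6, 9.6, 12.2, 14.3, 16.4, 18.3))

.rtruncnorm <- function(n, mean, sd) {
  # truncated at +/-2.5 SD with a 3rd-percentile lower floor
  lo <- mean + stats::qnorm(0.03) * sd
  hi <- mean + 2.5 * sd
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample a trial population
#'
#' Draws subjects per age stratum: ages uniform over the stratum range,
#' weights normal (stratum mean/SD, truncated at 2.5 SD and floored at the
#' 3rd percentile) or from a piecewise-linear age-weight curve with
#' log-normal scatter for the youngest design, AGP log-normal, and fat-free
#' mass from [ffm_from_weight()]. Deterministic under a fixed seed.
#'
#' @param cfg A [trial_config].
#' @return A data frame with one row per subject (`id`, `stratum`, `age`,
#'   `weight`, `ffm`, `agp`, `age_group`, `population`, `formulation`).
#' @export
sample_population <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  out <- list()
  idx <- 0L
  for (st in cfg$strata) {
    n <- st$n_subjects
    if (n == 0L) next
    age <- stats::runif(n, st$age_min, st$age_max)
    if (isTRUE(st$weight_by_age)) {
      cv <- if (is.null(st$weight_cv)) 0.12 else st$weight_cv
      wt <- stats::approx(.WT_BY_AGE$age, .WT_BY_AGE$wt, xout = age,
                          rule = 2)$y * exp(stats::rnorm(n, 0, cv))
    } else {
      wt <- .rtruncnorm(n, st$weight_mean, st$weight_sd)
    }
    agp <- stats::rlnorm(n, cfg$agp$meanlog, cfg$agp$sdlog)
    out[[length(out) + 1L]] <- data.frame(
      id = idx + seq_len(n), stratum = st$label, age = age, weight = wt,
      ffm = ffm_from_weight(wt, age), agp = agp,
      age_group = as.character(age_group(age)),
      population = cfg$population, formulation = cfg$formulation,
      stringsAsFactors = FALSE)
    idx <- idx + n
  }
  if (!length(out)) {
    return(data.frame(id = integer(0), stratum = character(0), age = numeric(0),
                      weight = numeric(0), ffm = numeric(0), agp = numeric(0),
                      age_group = character(0), population = character(0),
                      formulation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.row_subject <- function(row) {
  subject(id = row$id, age = row$age, weight = row$weight, agp = row$agp,
          ffm = row$ffm, population = row$population,
          formulation = row$formulation)
}

#' Dose-titration decision rules
#'
#' Titration is driven by a latent per-subject optimal level (the smallest
#' PED level at which the subject is "dry" without bothersome events), drawn
#' from `optimum_probs`. At each titration visit a subject below its optimum
#' is not dry and up-titrates with probability `p_up`; a subject above its
#' optimum experiences a bothersome event and down-titrates with probability
#' `p_down`; otherwise the level is kept. Defaults are calibrated so that
#' about 70\% of subjects are on PED10 when titration closes.
#'
#' @param p_up Probability of up-titration given not dry.
#' @param p_down Probability of down-titration given a bothersome event.
#' @param optimum_probs Named probabilities over the PED levels
#'   (`"2.5"`, `"5"`, `"7.5"`, `"10"`), summing to 1.
#' @return A list of class `titration_rules`.
#' @export
titration_rules <- function(p_up = 0.95, p_down = 0.9,
                            optimum_probs = c("2.5" = 0.02, "5" = 0.10,
                                              "7.5" = 0.18, "10" = 0.70)) {
  if (p_up < 0 || p_up > 1 || p_down < 0 || p_down > 1) {
    stop("titration probabilities must lie in [0, 1]")
  }
  if (length(optimum_probs) != 4L || abs(sum(optimum_probs) - 1) > 1e-8) {
    stop("'optimum_probs' must be 4 probabilities summing to 1")
  }
  structure(list(p_up = p_up, p_down = p_down, optimum_probs = optimum_probs),
            class = "titration_rules")
}

#' Simulate one subject's dose-titration path
#'
#' Starts at PED5 (PED2.5 for subjects under 2 years), takes one decision at
#' each titration visit (moving at most one level, clamped to the PED
#' range), and fixes the level after the last titration week.
#'
#' @param s A [subject] (or a row of [sample_population()] output).
#' @param rules A [titration_rules].
#' @param cfg A [trial_config].
#' @return A data frame (`week`, `level`) giving the level in force from
#'   each decision week onward (week 0 = starting dose).
#' @export
simulate_titration <- function(s, rules = titration_rules(), cfg) {
  stopifnot(inherits(rules, "titration_rules"), inherits(cfg, "trial_config"))
  age <- if (inherits(s, "subject")) s$age else s$age
  start <- if (age < 2) 2.5 else 5
  optimum <- .PED_LEVELS[sample.int(4L, 1L, prob = rules$optimum_probs)]
  weeks <- cfg$titration_weeks[cfg$titration_weeks <= cfg$max_titration_week]
  level <- start
  path <- data.frame(week = 0, level = start)
  for (w in weeks) {
    i <- match(level, .PED_LEVELS)
    if (level < optimum && stats::runif(1) < rules$p_up) {
      level <- .PED_LEVELS[min(i + 1L, 4L)]
    } else if (level > optimum && stats::runif(1) < rules$p_down) {
      level <- .PED_LEVELS[max(i - 1L, 1L)]
    }
    path <- rbind(path, data.frame(week = w, level = level))
  }
  path
}

#' Draw PK sampling times for one visit
#'
#' One uniform draw per sampling window, as offsets (h) relative to the
#' visit-day dose: pre-dose windows give negative offsets in `[-3, 0)`;
#' windows marked `final_only` (the 2-3 day washout sample) are drawn only
#' at the trial-end visit.
#'
#' @param cfg A [trial_config].
#' @param visit_week Week of the visit.
#' @return A data frame (`label`, `offset`).
#' @export
draw_sampling_times <- function(cfg, visit_week) {
  stopifnot(inherits(cfg, "trial_config"))
  out <- lapply(cfg$windows, function(w) {
    if (isTRUE(w$final_only) && visit_week < cfg$duration_weeks) return(NULL)
    data.frame(label = w$label, offset = stats::runif(1, w$lo, w$hi))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.level_at_week <- function(path, week) {
  path$level[max(which(path$week <= week))]
}

#' Simulate a full trial
#'
#' End-to-end synthetic dataset generation: sample the population, titrate
#' each subject's once-daily weight-adjusted dose, realize individual
#' parameters, evaluate concentrations by full superposition over the dose
#' history at the drawn sampling times, apply residual error, and censor
#' observations below the assay LLOQ (M1-style: flagged, value withheld).
#' Single-dose mode (rich-sampling preset) gives one dose at `dose_multiple`
#' times the weight-adjusted PED with a fixed rich time grid.
#'
#' One seed governs all randomness through per-stage substreams, so a fixed
#' seed yields a byte-identical dataset.
#'
#' @param cfg A [trial_config].
#' @param coeffs A [covariate_coeffs] population model.
#' @param omega An [omega_spec] (inter-individual variability).
#' @param sigma A [sigma_spec] (residual error); use zero SDs for noise-free
#'   output.
#' @param rules A [titration_rules].
#' @param seed Integer seed.
#' @param censor Apply LLOQ censoring (default `TRUE`).
#' @return A `pk_dataset`: a data frame in rectangular event format with
#'   columns `ID, TIME, TAD, AMT, DV, EVID, MDV, BLQ, PED, WEEK, AGE, WT,
#'   FFM, AGP, STUDY, FORM` (dose rows `EVID = 1`, observations `EVID = 0`).
#' @export
simulate_trial <- function(cfg, coeffs = covariate_coeffs(),
                           omega = omega_spec(), sigma = sigma_spec(),
                           rules = titration_rules(), seed = 1L,
                           censor = TRUE) {
  stopifnot(inherits(cfg, "trial_config"))
  set.seed(sub_seed(seed, "population"))
  pop <- sample_population(cfg)
  rows <- vector("list", nrow(pop))
  set.seed(sub_seed(seed, "subjects"))
  for (i in seq_len(nrow(pop))) {
    srow <- pop[i, ]
    s <- .row_subject(srow)
    ind <- realize_individual(typical_params(s, coeffs), omega)
    if (isTRUE(cfg$single_dose)) {
      level <- sample(c(2.5, 5, 10), 1L)
      amt <- cfg$dose_multiple * ped_dose(level, s)
      obs_t <- unlist(cfg$rich_grid)
      dose_t <- 0
      dose_amt <- amt
      dose_lvl <- level
      obs_lvl <- rep(level, length(obs_t))
      obs_week <- rep(0, length(obs_t))
      tad <- obs_t
    } else {
      path <- simulate_titration(s, rules, cfg)
      visit_week <- if (length(cfg$pk_weeks) == 1L) cfg$pk_weeks else
        cfg$pk_weeks[sample.int(length(cfg$pk_weeks), 1L)]
      visit_day <- visit_week * 7L
      days <- 0:visit_day
      dose_t <- 24 * days
      lvls <- vapply(floor(days / 7), function(w) .level_at_week(path, w),
                     numeric(1))
      dose_amt <- vapply(seq_along(days), function(j)
        ped_dose(lvls[j], s), numeric(1))
      draws <- draw_sampling_times(cfg, visit_week)
      obs_t <- visit_week * 168 + draws$offset
      last_dose <- vapply(obs_t, function(tt) max(dose_t[dose_t <= tt]),
                          numeric(1))
      tad <- obs_t - last_dose
      obs_lvl <- rep(lvls[length(lvls)], length(obs_t))
      obs_week <- rep(visit_week, length(obs_t))
      dose_lvl <- lvls
    }
    reg <- dose_regimen(dose_t, dose_amt)
    conc <- conc_regimen(obs_t, reg, ind)
    dv <- apply_residual(conc, sigma)
    blq <- censor & (dv < cfg$lloq)
    sub_rows <- rbind(
      data.frame(ID = srow$id, TIME = dose_t, TAD = 0, AMT = dose_amt,
                 DV = NA_real_, EVID = 1L, MDV = 1L, BLQ = 0L, PED = dose_lvl,
                 WEEK = floor(dose_t / 168)),
      data.frame(ID = srow$id, TIME = obs_t, TAD = tad, AMT = NA_real_,
                 DV = ifelse(blq, NA_real_, as.numeric(dv)), EVID = 0L,
                 MDV = as.integer(blq), BLQ = as.integer(blq), PED = obs_lvl,
                 WEEK = obs_week)
    )
    sub_rows <- sub_rows[order(sub_rows$TIME, sub_rows$EVID), ]
    sub_rows$AGE <- srow$age; sub_rows$WT <- srow$weight
    sub_rows$FFM <- srow$ffm; sub_rows$AGP <- srow$agp
    sub_rows$STUDY <- cfg$name; sub_rows$FORM <- srow$formulation
    rows[[i]] <- sub_rows
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  structure(ds, class = c("pk_dataset", "data.frame"),
            seed = seed, trial = cfg$name)
}
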