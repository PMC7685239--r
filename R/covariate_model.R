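# Covariate model: maps subject covariates (fat-free mass, alpha-1-acid
# glycoprotein, age) to individual typical parameters, realizes log-normal
# inter-individual variability, applies residual error, and computes
# weight-adjusted pediatric equivalent doses (PED).

#' Subject covariate record
#'
#' @param id Subject identifier.
#' @param age Age (years), positive.
#' @param weight Body weight (kg), positive.
#' @param agp Alpha-1-acid glycoprotein level, in the same units as the model
#'   reference (it only ever enters as the ratio `agp / agp_ref`).
#' @param ffm Fat-free mass (kg), `0 < ffm <= weight`. Defaults to
#'   [ffm_from_weight()].
#' @param population `"OAB"` or `"NDO"`.
#' @param formulation `"A"` (reference) or `"B"` (alternate, carries the
#'   relative bioavailability parameter).
#' @return A list of class `subject` with a derived `age_group` label.
#' @export
subject <- function(id, age, weight, agp, ffm = NULL,
                    population = c("OAB", "NDO"),
                    formulation = c("A", "B")) {
  population <- match.arg(population)
  formulation <- match.arg(formulation)
  if (!is.numeric(age) || age <= 0) stop("'age' must be positive")
  if (!is.numeric(weight) || weight <= 0) stop("'weight' must be positive")
  if (!is.numeric(agp) || agp <= 0) stop("'agp' must be positive")
  if (is.null(ffm)) ffm <- ffm_from_weight(weight, age)
  if (!is.numeric(ffm) || ffm <= 0 || ffm > weight) {
    stop("'ffm' must satisfy 0 < ffm <= weight")
  }
  structure(list(id = id, age = age, weight = weight, ffm = ffm, agp = agp,
                 age_group = age_group(age), population = population,
                 formulation = formulation),
            class = "subject")
}

#' Pediatric age-group label
#'
#' Labels ages by the trial strata: infants (0.5 to <2 y), young children
#' (2 to <5 y), children (5 to <12 y), adolescents (12 to <18 y), adults
#' (18 y and over).
#'
#' @param age Age in years (vectorized).
#' @return Character vector of group labels.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(0, 2, 5, 12, 18, Inf), right = FALSE,
      labels = c("infant", "young_child", "child", "adolescent", "adult"))
}

#' Default fat-free mass imputation
#'
#' Simple pediatric FFM default used by the trial simulator when a dataset
#' does not carry measured fat-free mass:
#' `ffm = weight * (0.85 - 0.003 * max(age - 5, 0))`.
#' Real datasets should supply FFM explicitly.
#'
#' @param weight Body weight (kg).
#' @param age Age (years).
#' @return Fat-free mass (kg).
#' @export
ffm_from_weight <- function(weight, age) {
  weight * (0.85 - 0.003 * pmax(age - 5, 0))
}

#' CYP3A4 ontogeny configuration
#'
#' Hill-type maturation of CYP3A4 activity with postnatal age. The default
#' half-maximal age (`tm50 = 0.3` y) and sigmoidicity (`hill = 2`) give
#' near-complete maturation (about 98\%) by age 2.
#'
#' @param tm50 Age (years) at half-maximal activity.
#' @param hill Sigmoidicity exponent.
#' @return A list of class `ontogeny_config`.
#' @export
ontogeny_config <- function(tm50 = 0.3, hill = 2) {
  if (tm50 <= 0 || hill <= 0) stop("'tm50' and 'hill' must be positive")
  structure(list(tm50 = tm50, hill = hill), class = "ontogeny_config")
}

#' CYP3A4 maturation fraction
#'
#' Hill function of postnatal age:
#' \eqn{age^{hill} / (age^{hill} + tm50^{hill})}, monotone increasing in age
#' and approaching 1 in older children.
#'
#' @param age Age (years), positive (vectorized).
#' @param cfg An [ontogeny_config].
#' @return Maturation fraction in (0, 1].
#' @export
cyp3a4_maturation <- function(age, cfg = ontogeny_config()) {
  stopifnot(inherits(cfg, "ontogeny_config"))
  if (any(age <= 0)) stop("'age' must be positive")
  age^cfg$hill / (age^cfg$hill + cfg$tm50^cfg$hill)
}

#' Covariate coefficients of a population model
#'
#' Holds the typical values (theta) of the structural parameters together
#' with the covariate model: allometric fat-free-mass exponents on clearance
#' and volumes, AGP power exponents on clearance and central volume, the
#' covariate reference values, and an optional CYP3A4 ontogeny term on the
#' CYP3A4-mediated fraction of clearance.
#'
#' Defaults are the final two-compartment population estimates for the
#' school-age OAB population (typical subject: FFM 24 kg, AGP 67).
#'
#' @param theta Named list of typical values: `cl_f`, `v2_f`, `ka`, `alag`
#'   and, for two-compartment models, `q_f`, `v3_f`; optionally `f1`
#'   (relative bioavailability of formulation B).
#' @param ffm_exp Named allometric exponents for `cl_f`, `v2_f`, `v3_f`.
#' @param agp_exp Named power exponents for `cl_f`, `v2_f`.
#' @param ffm_ref,agp_ref Reference covariate values at which theta applies.
#' @param ontogeny_enabled Apply the CYP3A4 ontogeny term to clearance?
#' @param cyp3a4_fraction Fraction of clearance mediated by CYP3A4 (0-1).
#' @param ontogeny An [ontogeny_config].
#' @return A list of class `covariate_coeffs`.
#' @export
covariate_coeffs <- function(theta = list(cl_f = 8.81, v2_f = 162, q_f = 98.1,
                                          v3_f = 174, ka = 0.742,
                                          alag = 0.834, f1 = 1.12),
                             ffm_exp = c(cl_f = 0.652, v2_f = 1.18, v3_f = 1.07),
                             agp_exp = c(cl_f = -0.649, v2_f = -1.06),
                             ffm_ref = 24, agp_ref = 67,
                             ontogeny_enabled = FALSE,
                             cyp3a4_fraction = 0.8,
                             ontogeny = ontogeny_config()) {
  if (ffm_ref <= 0 || agp_ref <= 0) stop("covariate references must be positive")
  if (cyp3a4_fraction < 0 || cyp3a4_fraction > 1) {
    stop("'cyp3a4_fraction' must lie in [0, 1]")
  }
  need <- c("cl_f", "v2_f", "ka")
  miss <- setdiff(need, names(theta))
  if (length(miss)) stop("theta is missing: ", paste(miss, collapse = ", "))
  if (is.null(theta$alag)) theta$alag <- 0
  structure(list(theta = theta, ffm_exp = ffm_exp, agp_exp = agp_exp,
                 ffm_ref = ffm_ref, agp_ref = agp_ref,
                 ontogeny_enabled = ontogeny_enabled,
                 cyp3a4_fraction = cyp3a4_fraction, ontogeny = ontogeny),
            class = "covariate_coeffs")
}

.exp_or_zero <- function(v, nm) if (nm %in% names(v)) unname(v[nm]) else 0

#' Individual typical parameters from covariates
#'
#' Applies the covariate model to a subject:
#' \deqn{CL/F = \theta_{CL} (FFM/FFM_{ref})^{0.652} (AGP/AGP_{ref})^{-0.649}
#'       [1 - f_{CYP}(1 - mat(age))]}
#' (the ontogeny bracket only when enabled), with analogous power terms on
#' the volumes; `ka`, `alag` and `q_f` carry no covariates, and `f_rel` is
#' theta `f1` for formulation B, 1 otherwise.
#'
#' @param s A [subject].
#' @param c A [covariate_coeffs].
#' @return A [structural_params] object (the individual's typical values,
#'   before inter-individual variability).
#' @export
typical_params <- function(s, c = covariate_coeffs()) {
  stopifnot(inherits(s, "subject"), inherits(c, "covariate_coeffs"))
  for (field in c("ffm", "agp", "age")) {
    if (is.null(s[[field]]) || !is.finite(s[[field]])) {
      stop(sprintf("subject '%s' is missing covariate '%s'", s$id, field))
    }
  }
  fr <- s$ffm / c$ffm_ref
  ar <- s$agp / c$agp_ref
  th <- c$theta
  cl <- th$cl_f * fr^.exp_or_zero(c$ffm_exp, "cl_f") *
    ar^.exp_or_zero(c$agp_exp, "cl_f")
  if (isTRUE(c$ontogeny_enabled)) {
    mat <- cyp3a4_maturation(s$age, c$ontogeny)
    cl <- cl * (1 - c$cyp3a4_fraction * (1 - mat))
  }
  v2 <- th$v2_f * fr^.exp_or_zero(c$ffm_exp, "v2_f") *
    ar^.exp_or_zero(c$agp_exp, "v2_f")
  v3 <- if (!is.null(th$v3_f)) th$v3_f * fr^.exp_or_zero(c$ffm_exp, "v3_f") else NULL
  f_rel <- if (identical(s$formulation, "B") && !is.null(th$f1)) th$f1 else 1
  structural_params(cl_f = cl, v2_f = v2, ka = th$ka,
                    q_f = th$q_f, v3_f = v3,
                    alag = th$alag, f_rel = f_rel)
}

#' Inter-individual variability specification
#'
#' Log-normal random-effect standard deviations (omega, log scale) for a
#' subset of `cl_f`, `v2_f`, `ka`, with an optional correlation matrix.
#'
#' @param sd Named non-negative log-scale SDs, e.g.
#'   `c(cl_f = 0.35, v2_f = 0.45, ka = 0.5)`.
#' @param corr Optional correlation matrix (same dimension/order as `sd`);
#'   must be positive semi-definite.
#' @return A list of class `omega_spec`.
#' @export
omega_spec <- function(sd = c(cl_f = 0.35, v2_f = 0.45, ka = 0.5), corr = NULL) {
  if (is.null(names(sd)) || any(!nzchar(names(sd)))) stop("'sd' must be named")
  if (any(sd < 0)) stop("omega SDs must be non-negative")
  if (!is.null(corr)) {
    if (!is.matrix(corr) || nrow(corr) != length(sd) || ncol(corr) != length(sd)) {
      stop("'corr' must be a square matrix matching length(sd)")
    }
    if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("'corr' must be positive semi-definite")
    }
  }
  structure(list(sd = sd, corr = corr), class = "omega_spec")
}

#' Draw one individual's parameters
#'
#' Multiplies each affected typical parameter by `exp(eta)` with
#' `eta ~ N(0, omega^2)` (jointly normal when a correlation is specified).
#' Uses R's global random number generator; seed upstream for
#' reproducibility.
#'
#' @param typ Typical [structural_params] for the subject.
#' @param omega An [omega_spec].
#' @return A [structural_params] object with realized variability; the draw
#'   is attached as attribute `"eta"`.
#' @export
realize_individual <- function(typ, omega = omega_spec()) {
  stopifnot(inherits(typ, "structural_params"), inherits(omega, "omega_spec"))
  d <- length(omega$sd)
  if (is.null(omega$corr)) {
    eta <- stats::rnorm(d, 0, omega$sd)
  } else {
    cov <- diag(omega$sd, d) %*% omega$corr %*% diag(omega$sd, d)
    eta <- as.numeric(MASS::mvrnorm(1, rep(0, d), cov))
  }
  names(eta) <- names(omega$sd)
  out <- typ
  for (nm in names(eta)) {
    if (!is.null(out[[nm]])) out[[nm]] <- out[[nm]] * exp(eta[[nm]])
  }
  attr(out, "eta") <- eta
  out
}

#' Residual error specification
#'
#' Combined proportional plus additive residual error; at least one
#' component must be positive for a non-degenerate model (both zero is
#' allowed for noise-free simulation).
#'
#' @param prop Proportional SD (fraction of the prediction).
#' @param add Additive SD (ng/mL).
#' @param study Optional study label for per-study residual models.
#' @return A list of class `sigma_spec`.
#' @export
sigma_spec <- function(prop = 0.2, add = 0.05, study = NULL) {
  if (prop < 0 || add < 0) stop("residual SDs must be non-negative")
  structure(list(prop = prop, add = add, study = study), class = "sigma_spec")
}

#' Apply residual error to simulated concentrations
#'
#' `y = conc * (1 + eps_prop) + eps_add` with independent normal errors;
#' negative results are floored at 0 and flagged in the `"floored"`
#' attribute.
#'
#' @param conc Non-negative concentrations (ng/mL).
#' @param sigma A [sigma_spec].
#' @return Perturbed concentrations with a logical `"floored"` attribute.
#' @export
apply_residual <- function(conc, sigma = sigma_spec()) {
  stopifnot(inherits(sigma, "sigma_spec"))
  if (any(conc < 0)) stop("'conc' must be non-negative")
  n <- length(conc)
  y <- conc * (1 + stats::rnorm(n, 0, sigma$prop)) + stats::rnorm(n, 0, sigma$add)
  floored <- y < 0
  y[floored] <- 0
  attr(y, "floored") <- floored
  y
}

#' Weight-adjusted pediatric equivalent dose
#'
#' Computes the once-daily dose for a PED level (2.5, 5, 7.5 or 10 mg adult
#' equivalent). The default rule scales the adult dose by the clearance
#' allometric exponent, `level * (ffm / ffm_adult_ref)^0.652`, so the typical
#' steady-state exposure is size-independent, then rounds to the suspension
#' granularity (0.5 mg for a 1 mg/mL suspension). A custom dose table
#' (data frame with columns `level`, `min_size`, `max_size`, `dose_mg`,
#' sizes in kg FFM) overrides the rule.
#'
#' @param level One of 2.5, 5, 7.5, 10.
#' @param s A [subject].
#' @param table Optional dose-table data frame (see above).
#' @param ffm_adult_ref Adult reference FFM (kg) for the default rule.
#' @param granularity Rounding granularity (mg).
#' @return Dose in mg.
#' @export
ped_dose <- function(level, s, table = NULL, ffm_adult_ref = 52,
                     granularity = 0.5) {
  if (!level %in% c(2.5, 5, 7.5, 10)) stop("'level' must be one of 2.5, 5, 7.5, 10")
  stopifnot(inherits(s, "subject"))
  if (!is.null(table)) {
    need <- c("level", "min_size", "max_size", "dose_mg")
    if (!all(need %in% names(table))) {
      stop("dose table must have columns: ", paste(need, collapse = ", "))
    }
    rows <- table[table$level == level, , drop = FALSE]
    if (!nrow(rows)) stop("dose table has no rows for level ", level)
    if (s$ffm < min(rows$min_size)) {
      stop(sprintf("subject '%s' (FFM %.1f kg) is below the dose table minimum",
                   s$id, s$ffm))
    }
    hit <- rows$min_size <= s$ffm & s$ffm < rows$max_size
    if (!any(hit)) hit <- which.max(rows$max_size)  # above top band: largest band
    return(rows$dose_mg[which(hit)[1]])
  }
  raw <- level * (s$ffm / ffm_adult_ref)^0.652
  max(granularity, round(raw / granularity) * granularity)
}

#' Read a PED dose table from CSV
#'
#' Columns: `level`, `min_size`, `max_size`, `dose_mg` (sizes in kg).
#' Doses must be monotone non-decreasing in level and in body size.
#'
#' @param path CSV file path.
#' @return A validated data frame usable as the `table` of [ped_dose()].
#' @export
read_dose_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level", "min_size", "max_size", "dose_mg")
  if (!all(need %in% names(tab))) {
    stop("dose table must have columns: ", paste(need, collapse = ", "))
  }
  for (lv in unique(tab$level)) {
    rows <- tab[tab$level == lv, ]
    rows <- rows[order(rows$min_size), ]
    if (is.unsorted(rows$dose_mg)) stop("doses must be non-decreasing in body size")
  }
  agg <- tapply(tab$dose_mg, tab$level, max)
  if (is.unsorted(agg[order(as.numeric(names(agg)))])) {
    stop("doses must be non-decreasing in PED level")
  }
  tab
}
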