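# Closed-form concentration-time solutions for one- and two-compartment
# disposition with first-order oral absorption and an absorption lag time.
# Units throughout: dose mg, time h, volumes L, clearances L/h,
# concentrations ng/mL (the mg/L -> ng/mL factor 1000 is applied once here).

#' Structural pharmacokinetic parameters of one subject
#'
#' Container for the apparent (oral) parameters of a one- or two-compartment
#' model with first-order absorption and lag time. Two-compartment models
#' carry an intercompartmental clearance `q_f` and peripheral volume `v3_f`;
#' one-compartment models omit both.
#'
#' @param cl_f Apparent clearance CL/F (L/h).
#' @param v2_f Apparent central volume V2/F (L).
#' @param ka First-order absorption rate constant (1/h).
#' @param q_f Apparent intercompartmental clearance Q/F (L/h), or `NULL` for a
#'   one-compartment model.
#' @param v3_f Apparent peripheral volume V3/F (L), or `NULL` for a
#'   one-compartment model. Must be present exactly when `q_f` is.
#' @param alag Absorption lag time (h), non-negative.
#' @param f_rel Relative bioavailability (1 for the reference formulation).
#' @return An object of class `structural_params`.
#' @examples
#' p <- structural_params(cl_f = 8.81, v2_f = 162, q_f = 98.1, v3_f = 174,
#'                        ka = 0.742, alag = 0.834)
#' micro_constants(p)
#' @export
structural_params <- function(cl_f, v2_f, ka, q_f = NULL, v3_f = NULL,
                              alag = 0, f_rel = 1) {
  if (is.null(q_f) != is.null(v3_f)) {
    stop("q_f and v3_f must be jointly present (2-compartment) or jointly absent")
  }
  for (nm in c("cl_f", "v2_f", "ka", "f_rel")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm))
    }
  }
  if (!is.numeric(alag) || length(alag) != 1L || !is.finite(alag) || alag < 0) {
    stop("'alag' must be a single non-negative finite number")
  }
  if (!is.null(q_f)) {
    for (nm in c("q_f", "v3_f")) {
      val <- get(nm)
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
        stop(sprintf("'%s' must be a single positive finite number", nm))
      }
    }
  }
  structure(
    list(cl_f = cl_f, v2_f = v2_f, q_f = q_f, v3_f = v3_f,
         ka = ka, alag = alag, f_rel = f_rel),
    class = "structural_params"
  )
}

#' @export
print.structural_params <- function(x, ...) {
  kind <- if (is.null(x$q_f)) "one-compartment" else "two-compartment"
  cat(sprintf("<structural_params> %s oral model with lag\n", kind))
  vals <- unlist(x[!vapply(x, is.null, logical(1))])
  print(signif(vals, 4))
  invisible(x)
}

is_two_cpt <- function(p) !is.null(p$q_f)

#' First-order micro rate constants
#'
#' Re-parameterizes apparent clearances/volumes into the first-order rate
#' constants k10 = CL/V2, k12 = Q/V2, k21 = Q/V3 (the latter two only for
#' two-compartment models).
#'
#' @param p A [structural_params] object.
#' @return A list of class `micro_constants` with `k10`, `k12`, `k21`, `ka`
#'   (`k12`/`k21` `NULL` for one-compartment models).
#' @export
micro_constants <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  out <- list(k10 = p$cl_f / p$v2_f, k12 = NULL, k21 = NULL, ka = p$ka)
  if (is_two_cpt(p)) {
    out$k12 <- p$q_f / p$v2_f
    out$k21 <- p$q_f / p$v3_f
  }
  class(out) <- "micro_constants"
  out
}

#' Hybrid disposition rate constants
#'
#' The eigenvalue rates of the disposition system: for a two-compartment
#' model, `lambda1` (fast) and `lambda_z` (terminal) are the roots of
#' \eqn{\lambda^2 - (k10 + k12 + k21)\lambda + k10 k21 = 0}; for a
#' one-compartment model both equal `k10`. `lambda_z` sets the terminal
#' half-life \eqn{t_{1/2} = \ln 2 / \lambda_z}.
#'
#' @param m A [micro_constants] object.
#' @return A list of class `hybrid_rates` with `lambda1 >= lambda_z > 0`.
#' @export
hybrid_rates <- function(m) {
  stopifnot(inherits(m, "micro_constants"))
  if (is.null(m$k12)) {
    lam <- c(m$k10, m$k10)
  } else {
    s <- m$k10 + m$k12 + m$k21
    prod <- m$k10 * m$k21
    disc <- sqrt(max(s^2 - 4 * prod, 0))
    lam <- c((s + disc) / 2, (s - disc) / 2)
  }
  structure(list(lambda1 = lam[1], lambda_z = lam[2]), class = "hybrid_rates")
}

# Relative tolerance below which ka is merged with a disposition rate and the
# limiting t*exp(-lambda*t) form is used (avoids catastrophic cancellation).
.DEGENERATE_TOL <- 1e-8

# Exponential-term decomposition of the single-dose profile:
# conc(u) = sum_i coef_i * u^tpow_i * exp(-rate_i * u), u = t - alag (u > 0).
# Returns list(coef, rate, tpow); plain vectors, this sits in the
# estimator's innermost loop. Scale includes mg/L -> ng/mL.
.exp_terms <- function(dose, p) {
  ka <- p$ka
  k10 <- p$cl_f / p$v2_f
  scale <- 1000 * p$f_rel * dose / p$v2_f
  if (is.null(p$q_f)) {
    if (abs(ka - k10) < .DEGENERATE_TOL * k10) {
      return(list(coef = scale * ka, rate = k10, tpow = 1))
    }
    a <- scale * ka / (ka - k10)
    return(list(coef = c(a, -a), rate = c(k10, ka), tpow = c(0, 0)))
  }
  k12 <- p$q_f / p$v2_f
  k21 <- p$q_f / p$v3_f
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  l1 <- (s + disc) / 2
  lz <- (s - disc) / 2
  deg1 <- abs(ka - l1) < .DEGENERATE_TOL * l1
  degz <- abs(ka - lz) < .DEGENERATE_TOL * lz
  if (deg1 || degz) {
    # double pole at the matching disposition rate
    lam <- if (deg1) l1 else lz       # merged rate
    oth <- if (deg1) lz else l1       # remaining simple pole
    list(
      coef = scale * ka * c((k21 - oth) / (lam - oth)^2,
                            (oth - k21) / (oth - lam)^2,
                            (k21 - lam) / (oth - lam)),
      rate = c(oth, lam, lam),
      tpow = c(0, 0, 1)
    )
  } else {
    list(
      coef = scale * ka * c((k21 - l1) / ((ka - l1) * (lz - l1)),
                            (k21 - lz) / ((ka - lz) * (l1 - lz)),
                            (k21 - ka) / ((l1 - ka) * (lz - ka))),
      rate = c(l1, lz, ka),
      tpow = c(0, 0, 0)
    )
  }
}

# Evaluate term decomposition at shifted times u (vector); u <= 0 -> 0.
.eval_terms <- function(terms, u) {
  out <- numeric(length(u))
  pos <- u > 0
  if (!any(pos)) return(out)
  up <- u[pos]
  acc <- 0
  for (i in seq_along(terms$coef)) {
    e <- exp(-terms$rate[i] * up)
    acc <- acc + terms$coef[i] * (if (terms$tpow[i] == 1) up * e else e)
  }
  out[pos] <- acc
  pmax(out, 0)
}

# Steady-state profile under repeated dosing every tau h: infinite
# superposition summed per exponential term (geometric accumulation).
# tss = time since one steady-state dose, any value >= 0.
.eval_terms_ss <- function(terms, tss, tau, alag) {
  u <- tss - alag
  # shift each time to the most recent dose whose absorption has started
  shift <- ifelse(u <= 0, ceiling(-u / tau + 1e-12) * tau, 0)
  shift[u + shift <= 0] <- shift[u + shift <= 0] + tau
  u <- u + shift
  acc <- 0
  for (i in seq_along(terms$coef)) {
    r <- terms$rate[i]
    E <- exp(-r * tau)
    e0 <- exp(-r * u)
    one <- 1 - E
    if (terms$tpow[i] == 1) {
      acc <- acc + terms$coef[i] * e0 * (u / one + tau * E / one^2)
    } else {
      acc <- acc + terms$coef[i] * e0 / one
    }
  }
  pmax(acc, 0)
}

#' Concentration after a single oral dose
#'
#' Closed-form plasma concentration at times `t` after one oral dose given at
#' time 0: zero up to the lag time, then the Bateman (one-compartment) or
#' tri-exponential (two-compartment) solution in shifted time `t - alag`.
#' Linear in dose. When `ka` coincides with a disposition rate (within
#' relative 1e-8), the limiting `t*exp(-lambda*t)` form is used.
#'
#' @param t Numeric vector of times (h) since the dose, `>= 0` (earlier times
#'   return 0).
#' @param dose Dose amount (mg), positive.
#' @param p A [structural_params] object.
#' @return Concentrations (ng/mL), same length as `t`.
#' @export
conc_single_dose <- function(t, dose, p) {
  stopifnot(inherits(p, "structural_params"))
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0) {
    stop("'dose' must be a single positive number")
  }
  terms <- .exp_terms(dose, p)
  .eval_terms(terms, t - p$alag)
}

#' Dosing regimen
#'
#' A sequence of oral doses, optionally with a dosing interval `tau` to
#' request the steady-state shortcut in [conc_regimen()] and
#' [secondary_params()].
#'
#' @param times Dose times (h), non-decreasing.
#' @param amounts Dose amounts (mg), positive; recycled to `length(times)`.
#' @param tau Dosing interval (h) for steady-state evaluation, or `NULL`.
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(times = 0, amounts, tau = NULL) {
  if (length(times) == 0L) stop("regimen must contain at least one dose event")
  amounts <- rep_len(amounts, length(times))
  if (any(!is.finite(times)) || is.unsorted(times)) {
    stop("dose times must be finite and non-decreasing")
  }
  if (any(!is.finite(amounts) | amounts <= 0)) stop("dose amounts must be positive")
  if (!is.null(tau) && (!is.numeric(tau) || length(tau) != 1L || tau <= 0)) {
    stop("'tau' must be a single positive number")
  }
  structure(list(times = as.numeric(times), amounts = as.numeric(amounts),
                 tau = tau), class = "dose_regimen")
}

#' Concentration under a dosing regimen
#'
#' Superposition of [conc_single_dose()] over all doses of the regimen. If
#' the regimen carries a dosing interval `tau`, the steady-state shortcut is
#' used instead: `times` are then interpreted as time since one steady-state
#' dose (of the regimen's last amount), and the profile equals the infinite
#' superposition limit via per-exponential geometric accumulation factors.
#'
#' @param times Observation times (h). Absolute trial time in superposition
#'   mode; time since a steady-state dose in steady-state mode.
#' @param regimen A [dose_regimen].
#' @param p A [structural_params] object.
#' @return Concentrations (ng/mL).
#' @export
conc_regimen <- function(times, regimen, p) {
  stopifnot(inherits(regimen, "dose_regimen"), inherits(p, "structural_params"))
  if (!is.null(regimen$tau)) {
    amt <- regimen$amounts[length(regimen$amounts)]
    terms <- .exp_terms(amt, p)
    return(.eval_terms_ss(terms, times, regimen$tau, p$alag))
  }
  out <- numeric(length(times))
  for (i in seq_along(regimen$times)) {
    terms <- .exp_terms(regimen$amounts[i], p)
    out <- out + .eval_terms(terms, times - regimen$times[i] - p$alag)
  }
  out
}

#' Secondary (derived) pharmacokinetic parameters at steady state
#'
#' Derives the terminal half-life, terminal-phase volume, dose-normalized
#' AUC, and the steady-state Cmax/tmax/Ctrough of a once-every-`tau` regimen:
#' \itemize{
#'   \item `t_half = ln(2) / lambda_z`
#'   \item `vz_f = cl_f / lambda_z`
#'   \item `auc_inf_per_dose = 1000 * f_rel / cl_f` (ng·h/mL per mg dosed;
#'     for linear kinetics this equals the steady-state AUC over a dosing
#'     interval divided by the dose)
#'   \item `cmax`/`tmax` from bounded scalar maximization of the
#'     steady-state profile on `(alag, tau]`
#'   \item `ctrough` = steady-state concentration at the pre-dose time
#' }
#'
#' @param p A [structural_params] object.
#' @param regimen A [dose_regimen] with `tau` set.
#' @return A list of class `secondary_params`.
#' @export
secondary_params <- function(p, regimen) {
  stopifnot(inherits(p, "structural_params"), inherits(regimen, "dose_regimen"))
  if (is.null(regimen$tau)) stop("secondary_params requires a regimen with 'tau' set")
  tau <- regimen$tau
  if (p$alag >= tau) stop("lag time must be shorter than the dosing interval")
  lz <- hybrid_rates(micro_constants(p))$lambda_z
  amt <- regimen$amounts[length(regimen$amounts)]
  terms <- .exp_terms(amt, p)
  f_ss <- function(tt) .eval_terms_ss(terms, tt, tau, p$alag)
  opt <- stats::optimize(f_ss, lower = p$alag + 1e-9, upper = tau,
                         maximum = TRUE, tol = 1e-6)
  if (!is.finite(opt$objective) || opt$objective <= 0) {
    stop("steady-state maximization failed to locate a positive peak")
  }
  structure(
    list(t_half = log(2) / lz,
         vz_f = p$cl_f / lz,
         auc_inf_per_dose = 1000 * p$f_rel / p$cl_f,
         cmax = opt$objective,
         tmax = opt$maximum,
         ctrough = f_ss(tau),
         dose = amt, tau = tau),
    class = "secondary_params"
  )
}

#' @export
print.secondary_params <- function(x, ...) {
  cat("<secondary_params> steady-state metrics\n")
  print(signif(unlist(x), 4))
  invisible(x)
}
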