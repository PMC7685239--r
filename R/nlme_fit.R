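# Nonlinear mixed-effects estimation by the Laplace approximation at the
# per-subject conditional mode of the random effects (FOCE-with-interaction
# flavour: the residual variance is evaluated at the individual prediction).
# Fixed effects, variance components, standard errors, and empirical-Bayes
# individual estimates.

# finite-difference constants (documented numerical choices)
.FD_REL <- 1e-4       # relative step for Hessians
.INNER_TOL <- 1e-8    # inner eta-optimization tolerance
.VAR_FLOOR <- 1e-12   # residual-variance floor

# central-difference Hessian with relative steps
.fd_hessian <- function(f, x, rel = .FD_REL) {
  d <- length(x)
  h <- rel * (abs(x) + rel)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h[i]
    fp <- f(x + ei); fm <- f(x - ei)
    H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- numeric(d); ej[j] <- h[j]
      fpp <- f(x + ei + ej); fpm <- f(x + ei - ej)
      fmp <- f(x - ei + ej); fmm <- f(x - ei - ej)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Laplace-approximate -2 log marginal likelihood for one subject
#'
#' The estimation core, exposed for direct use and testing. Given
#' observations `y`, a prediction function of the random effects, log-normal
#' random-effect SDs `omega_sd`, and a combined residual-error model, the
#' inner optimization locates the conditional mode `eta*` of the joint
#' density and the marginal likelihood integral is approximated by a
#' second-order expansion there:
#' \deqn{-2\ell \approx 2h(\eta^*) + \log|\Omega| + \log|\nabla^2 h(\eta^*)|}
#' where \eqn{h(\eta) = -\log p(y|\eta) + \tfrac12 \eta'\Omega^{-1}\eta}.
#' Residual variance is `(prop * f)^2 + add^2` at the individual prediction
#' (interaction). Dimensions with `omega_sd = 0` are fixed at zero; with all
#' SDs zero the result is the extended-least-squares deviance of the fixed
#' effects. Exact for models linear in `eta` with additive normal error.
#'
#' @param y Observation vector.
#' @param fpred Function `eta -> predictions` (same length as `y`); `eta`
#'   has `length(omega_sd)` elements.
#' @param omega_sd Non-negative random-effect SDs (log scale).
#' @param sigma Numeric `c(prop, add)` residual SDs.
#' @param eta_init Warm start for the inner optimization.
#' @return The approximate -2 log marginal likelihood, with the conditional
#'   mode in attribute `"eta"`; `+Inf` (with attribute `"failed"`) if the
#'   inner optimization fails.
#' @export
laplace_neg2ll <- function(y, fpred, omega_sd, sigma,
                           eta_init = rep(0, length(omega_sd))) {
  n <- length(y)
  prop <- sigma[[1]]; add <- sigma[[2]]
  free <- which(omega_sd > 0)
  d <- length(free)
  eta_full <- numeric(length(omega_sd))
  nll <- function(eta) {
    f <- fpred(eta)
    v <- pmax((prop * f)^2 + add^2, .VAR_FLOOR)
    0.5 * sum(log(2 * pi * v) + (y - f)^2 / v)
  }
  if (d == 0L) {
    val <- 2 * nll(eta_full)
    attr(val, "eta") <- eta_full
    return(val)
  }
  w2 <- omega_sd[free]^2
  h <- function(ef) {
    eta_full[free] <- ef
    nll(eta_full) + 0.5 * sum(ef^2 / w2)
  }
  opt <- tryCatch(
    stats::nlminb(eta_init[free], h,
                  control = list(abs.tol = .INNER_TOL, rel.tol = .INNER_TOL,
                                 x.tol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    val <- Inf
    attr(val, "failed") <- TRUE
    return(val)
  }
  H <- .fd_hessian(h, opt$par)
  detH <- det(as.matrix(H))
  if (!is.finite(detH) || detH <= 0) {
    # fall back to the prior curvature on the offending directions
    H <- H + diag(1e-8, d)
    detH <- det(as.matrix(H))
    if (!is.finite(detH) || detH <= 0) {
      val <- Inf
      attr(val, "failed") <- TRUE
      return(val)
    }
  }
  val <- 2 * opt$objective + sum(log(w2)) + log(detH)
  eta_full[free] <- opt$par
  attr(val, "eta") <- eta_full
  val
}

#' Population model specification
#'
#' Declares the structural model, covariate model (with initial/fixed theta
#' values), variability structure, residual-error structure, and which
#' components are estimated. Parameters kept out of `estimate_theta` stay
#' fixed at their `coeffs` values (covariate exponents are always fixed:
#' they were pre-specified, not searched).
#'
#' @param structural `"2cpt"` or `"1cpt"`.
#' @param coeffs A [covariate_coeffs] carrying the theta initial values.
#' @param omega Named initial log-scale SDs for the random effects (subset
#'   of `cl_f`, `v2_f`, `ka`).
#' @param sigma Data frame with columns `study`, `prop`, `add`; one row per
#'   residual-error model (`study = NA` matches any study).
#' @param estimate_theta Names of theta components to estimate.
#' @param estimate_omega Names of omega components to estimate.
#' @param estimate_sigma Components (`"prop"`, `"add"`) estimated in every
#'   sigma row.
#' @param tau Dosing interval (h) assumed by the steady-state shortcut.
#' @param ss Use the steady-state shortcut for prediction (`NULL` = auto:
#'   on for subjects with long once-daily dose histories).
#' @return A list of class `pop_model_spec`.
#' @export
pop_model_spec <- function(structural = c("2cpt", "1cpt"),
                           coeffs = covariate_coeffs(),
                           omega = c(cl_f = 0.35, v2_f = 0.45, ka = 0.5),
                           sigma = data.frame(study = NA, prop = 0.2, add = 0.05),
                           estimate_theta = c("cl_f", "v2_f", "ka"),
                           estimate_omega = names(omega),
                           estimate_sigma = "prop",
                           tau = 24, ss = NULL) {
  structural <- match.arg(structural)
  stopifnot(inherits(coeffs, "covariate_coeffs"))
  if (structural == "2cpt" &&
      (is.null(coeffs$theta$q_f) || is.null(coeffs$theta$v3_f))) {
    stop("a 2-compartment spec requires q_f and v3_f in theta")
  }
  if (structural == "1cpt") {
    coeffs$theta$q_f <- NULL
    coeffs$theta$v3_f <- NULL
  }
  bad <- setdiff(estimate_theta, names(coeffs$theta))
  if (length(bad)) stop("estimate_theta not in theta: ", paste(bad, collapse = ", "))
  for (nm in estimate_theta) {
    if (coeffs$theta[[nm]] <= 0) stop("initial value for '", nm, "' must be positive")
  }
  bad <- setdiff(estimate_omega, names(omega))
  if (length(bad)) stop("estimate_omega not in omega: ", paste(bad, collapse = ", "))
  stopifnot(all(c("study", "prop", "add") %in% names(sigma)))
  for (comp in estimate_sigma) {
    if (!comp %in% c("prop", "add")) stop("estimate_sigma must be 'prop'/'add'")
    if (any(sigma[[comp]] <= 0)) {
      stop("estimated sigma components need positive initial values")
    }
  }
  structure(list(structural = structural, coeffs = coeffs, omega = omega,
                 sigma = sigma, estimate_theta = estimate_theta,
                 estimate_omega = estimate_omega,
                 estimate_sigma = estimate_sigma, tau = tau, ss = ss),
            class = "pop_model_spec")
}

# ---- parameter packing (all estimated components on the log scale) ----

.pack_params <- function(spec) {
  x <- c()
  for (nm in spec$estimate_theta) {
    x[paste0("theta.", nm)] <- log(spec$coeffs$theta[[nm]])
  }
  for (nm in spec$estimate_omega) {
    x[paste0("omega.", nm)] <- log(spec$omega[[nm]])
  }
  for (r in seq_len(nrow(spec$sigma))) {
    lab <- spec$sigma$study[r]
    lab <- if (is.na(lab)) "all" else lab
    for (comp in spec$estimate_sigma) {
      x[paste0("sigma.", lab, ".", comp)] <- log(spec$sigma[[comp]][r])
    }
  }
  x
}

.unpack_params <- function(x, spec) {
  theta <- spec$coeffs$theta
  omega <- spec$omega
  sigma <- spec$sigma
  for (nm in spec$estimate_theta) theta[[nm]] <- exp(x[[paste0("theta.", nm)]])
  for (nm in spec$estimate_omega) omega[[nm]] <- exp(x[[paste0("omega.", nm)]])
  for (r in seq_len(nrow(sigma))) {
    lab <- sigma$study[r]
    lab <- if (is.na(lab)) "all" else lab
    for (comp in spec$estimate_sigma) {
      sigma[[comp]][r] <- exp(x[[paste0("sigma.", lab, ".", comp)]])
    }
  }
  list(theta = theta, omega = omega, sigma = sigma)
}

# ---- data preparation ----

# Split a pk_dataset into per-subject fitting units. BLQ and missing-DV
# rows are excluded (M1 handling); subjects left without observations are
# dropped with a message.
.prep_subjects <- function(data, spec) {
  need <- c("ID", "TIME", "TAD", "AMT", "DV", "EVID", "MDV", "BLQ",
            "AGE", "FFM", "AGP", "STUDY", "FORM")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("dataset is missing required columns: ", paste(miss, collapse = ", "))
  }
  out <- list()
  dropped <- c()
  for (id in unique(data$ID)) {
    d <- data[data$ID == id, ]
    doses <- d[d$EVID == 1L, ]
    obs <- d[d$EVID == 0L & d$BLQ == 0L & !is.na(d$DV), ]
    if (!nrow(obs)) { dropped <- c(dropped, id); next }
    first <- d[1, ]
    covs <- subject(id = id, age = first$AGE,
                    weight = if ("WT" %in% names(d)) first$WT else first$FFM / 0.85,
                    agp = first$AGP, ffm = first$FFM,
                    population = if ("STUDY" %in% names(d) &&
                                     tolower(first$STUDY) %in% c("monkey", "marmoset"))
                      "NDO" else "OAB",
                    formulation = first$FORM)
    amt_last <- vapply(obs$TIME, function(tt) {
      prior <- doses$AMT[doses$TIME <= tt]
      prior[length(prior)]
    }, numeric(1))
    out[[as.character(id)]] <- list(
      id = id, covs = covs, study = tolower(as.character(first$STUDY)),
      y = obs$DV, t = obs$TIME, tad = obs$TAD, amt_last = amt_last,
      dose_t = doses$TIME, dose_amt = doses$AMT)
  }
  if (length(dropped)) {
    message("excluded ", length(dropped),
            " subject(s) with no quantifiable observations: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  }
  if (!length(out)) stop("no subjects with quantifiable observations")
  out
}

.sigma_for_study <- function(sigma, study) {
  r <- which(tolower(as.character(sigma$study)) == study)
  if (!length(r)) r <- which(is.na(sigma$study))
  if (!length(r)) r <- 1L
  c(sigma$prop[r[1]], sigma$add[r[1]])
}

# fast unvalidated parameter object for the inner loop
.fast_params <- function(cl, v2, q, v3, ka, alag, f_rel) {
  structure(list(cl_f = cl, v2_f = v2, q_f = q, v3_f = v3, ka = ka,
                 alag = alag, f_rel = f_rel), class = "structural_params")
}

# Prediction closure for one subject given its typical params. The time
# grids do not depend on eta (no variability on the lag time), so shifted
# times, dose weights and steady-state wrapping are precomputed once; the
# closure then evaluates the tri-/bi-exponential solution with inlined
# arithmetic. Near-degenerate ka (within relative 1e-8 of a disposition
# rate) falls back to the generic limiting-form path.
.make_fpred <- function(sub, typ, eta_names, use_ss, tau) {
  q <- typ$q_f; v3 <- typ$v3_f; two <- !is.null(q)
  alag <- typ$alag; frel <- typ$f_rel
  i_cl <- match("cl_f", eta_names)
  i_v2 <- match("v2_f", eta_names)
  i_ka <- match("ka", eta_names)
  generic <- function(cl, v2, ka) {
    p <- .fast_params(cl, v2, q, v3, ka, alag, frel)
    if (use_ss) {
      out <- numeric(length(sub$tad))
      for (amt in unique(sub$amt_last)) {
        sel <- sub$amt_last == amt
        out[sel] <- .eval_terms_ss(.exp_terms(amt, p), sub$tad[sel], tau, alag)
      }
      out
    } else {
      out <- numeric(length(sub$t))
      for (j in seq_along(sub$dose_t)) {
        out <- out + .eval_terms(.exp_terms(sub$dose_amt[j], p),
                                 sub$t - sub$dose_t[j] - alag)
      }
      out
    }
  }
  if (use_ss) {
    u0 <- sub$tad - alag
    shift <- ifelse(u0 <= 0, ceiling(-u0 / tau + 1e-12) * tau, 0)
    u <- u0 + shift
    w <- sub$amt_last
    nobs <- length(u)
    ridx <- seq_len(nobs)
    acc <- TRUE      # apply steady-state accumulation factors
  } else {
    U <- outer(sub$t, sub$dose_t, "-") - alag
    keep <- U > 0
    u <- U[keep]
    w <- matrix(sub$dose_amt, nrow = length(sub$t), ncol = length(sub$dose_t),
                byrow = TRUE)[keep]
    ridx <- row(U)[keep]
    nobs <- length(sub$t)
    acc <- FALSE
  }
  function(eta) {
    cl <- typ$cl_f; v2 <- typ$v2_f; ka <- typ$ka
    if (!is.na(i_cl)) cl <- cl * exp(eta[i_cl])
    if (!is.na(i_v2)) v2 <- v2 * exp(eta[i_v2])
    if (!is.na(i_ka)) ka <- ka * exp(eta[i_ka])
    k10 <- cl / v2
    base <- 1000 * frel * ka / v2
    if (two) {
      k12 <- q / v2; k21 <- q / v3
      s <- k10 + k12 + k21
      disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
      l1 <- (s + disc) / 2; lz <- (s - disc) / 2
      if (abs(ka - l1) < 1e-7 * l1 || abs(ka - lz) < 1e-7 * lz) {
        return(generic(cl, v2, ka))
      }
      a1 <- (k21 - l1) / ((ka - l1) * (lz - l1))
      a2 <- (k21 - lz) / ((ka - lz) * (l1 - lz))
      a3 <- (k21 - ka) / ((l1 - ka) * (lz - ka))
      if (acc) {
        v <- a1 * exp(-l1 * u) / (1 - exp(-l1 * tau)) +
          a2 * exp(-lz * u) / (1 - exp(-lz * tau)) +
          a3 * exp(-ka * u) / (1 - exp(-ka * tau))
      } else {
        v <- a1 * exp(-l1 * u) + a2 * exp(-lz * u) + a3 * exp(-ka * u)
      }
    } else {
      if (abs(ka - k10) < 1e-7 * k10) return(generic(cl, v2, ka))
      a <- 1 / (ka - k10)
      if (acc) {
        v <- a * (exp(-k10 * u) / (1 - exp(-k10 * tau)) -
                    exp(-ka * u) / (1 - exp(-ka * tau)))
      } else {
        v <- a * (exp(-k10 * u) - exp(-ka * u))
      }
    }
    contrib <- base * w * v
    if (length(contrib) == nobs && identical(ridx, seq_len(nobs))) {
      return(pmax(contrib, 0))
    }
    out <- numeric(nobs)
    rs <- rowsum(contrib, ridx)
    out[as.integer(rownames(rs))] <- rs
    pmax(out, 0)
  }
}

.use_ss <- function(sub, spec) {
  if (!is.null(spec$ss)) return(isTRUE(spec$ss))
  length(sub$dose_t) > 20L
}

#' Conditional (Laplace) -2 log likelihood of a population model
#'
#' Sums [laplace_neg2ll()] over the subjects of a dataset under given
#' population parameters. Below-quantification-limit rows are excluded
#' (M1 handling). Deterministic given data and parameters.
#'
#' @param data A `pk_dataset` (see [simulate_trial()], [read_pk_dataset()]).
#' @param spec A [pop_model_spec].
#' @param params Optional list with elements `theta`, `omega`, `sigma`
#'   overriding the spec's values.
#' @param eta_start Optional list of warm-start eta vectors keyed by subject
#'   id.
#' @return Total -2 log likelihood; per-subject values in attribute
#'   `"by_subject"`, conditional modes in attribute `"eta"` (a matrix), ids
#'   of subjects whose inner optimization failed in attribute `"failed"`.
#' @export
conditional_neg2ll <- function(data, spec, params = NULL, eta_start = NULL) {
  stopifnot(inherits(spec, "pop_model_spec"))
  subs <- if (is.list(data) && !is.data.frame(data) &&
              all(vapply(data, is.list, logical(1)))) data
          else .prep_subjects(data, spec)
  .neg2ll_prepared(subs, spec, params, eta_start)
}

.neg2ll_prepared <- function(subs, spec, params = NULL, eta_start = NULL) {
  if (is.null(params)) {
    params <- list(theta = spec$coeffs$theta, omega = spec$omega,
                   sigma = spec$sigma)
  }
  coeffs <- spec$coeffs
  coeffs$theta <- params$theta
  eta_names <- names(params$omega)
  by_sub <- numeric(length(subs))
  etas <- matrix(0, length(subs), length(eta_names),
                 dimnames = list(names(subs), eta_names))
  failed <- c()
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    typ <- typical_params(sub$covs, coeffs)
    fpred <- .make_fpred(sub, typ, eta_names, .use_ss(sub, spec), spec$tau)
    sig <- .sigma_for_study(params$sigma, sub$study)
    init <- if (!is.null(eta_start[[as.character(sub$id)]]))
      eta_start[[as.character(sub$id)]] else rep(0, length(eta_names))
    val <- laplace_neg2ll(sub$y, fpred, unlist(params$omega[eta_names]),
                          sig, eta_init = init)
    if (isTRUE(attr(val, "failed"))) failed <- c(failed, sub$id)
    by_sub[i] <- as.numeric(val)
    if (!is.null(attr(val, "eta"))) etas[i, ] <- attr(val, "eta")
  }
  total <- sum(by_sub)
  attr(total, "by_subject") <- stats::setNames(by_sub, names(subs))
  attr(total, "eta") <- etas
  attr(total, "failed") <- failed
  total
}

#' Fit a population pharmacokinetic model
#'
#' Minimizes the Laplace-approximate -2 log likelihood over the
#' log-transformed estimated components (theta, omega SDs, sigma SDs) by
#' Nelder-Mead simplex search with per-subject warm-started inner
#' optimizations. Standard errors come from the inverse numerical Hessian
#' at the optimum (delta method back to the natural scale).
#'
#' Fitting a two-compartment model to sparsely sampled data (fewer than six
#' observations per subject) triggers a warning: such designs generally do
#' not support the full profile shape.
#'
#' @param data A `pk_dataset`.
#' @param spec A [pop_model_spec]; its theta/omega/sigma values are the
#'   initial values.
#' @param options List: `maxit` (Nelder-Mead iterations, default 400),
#'   `se` (compute standard errors, default `TRUE`), `trace` (print
#'   progress, default `FALSE`).
#' @return A `fit_result` list: `theta`, `se_theta`, `omega`, `sigma`,
#'   `objective`, `convergence` (`"converged"` or `"iteration-limit"`),
#'   `eta` (per-subject conditional modes), `shrinkage`, `spec`, `trace`
#'   (best objective per accepted improvement).
#' @export
fit_population <- function(data, spec, options = list()) {
  stopifnot(inherits(spec, "pop_model_spec"))
  maxit <- if (is.null(options$maxit)) 400L else options$maxit
  se <- if (is.null(options$se)) TRUE else options$se
  trace <- isTRUE(options$trace)
  subs <- .prep_subjects(data, spec)
  nobs <- vapply(subs, function(s) length(s$y), numeric(1))
  if (spec$structural == "2cpt" && stats::median(nobs) < 6) {
    warning("sparse sampling (median < 6 observations/subject) may not ",
            "support a two-compartment model; consider structural = '1cpt'")
  }
  x0 <- .pack_params(spec)
  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  best <- new.env(parent = emptyenv())
  best$val <- Inf
  best$trace <- numeric(0)
  objfun <- function(x) {
    names(x) <- names(x0)
    pars <- .unpack_params(x, spec)
    val <- .neg2ll_prepared(subs, spec, pars, eta_start = warm$eta)
    etas <- attr(val, "eta")
    warm$eta <- stats::setNames(
      lapply(seq_len(nrow(etas)), function(i) etas[i, ]), rownames(etas))
    v <- as.numeric(val)
    if (is.finite(v) && v < best$val) {
      best$val <- v
      best$trace <- c(best$trace, v)
      if (trace) message(sprintf("neg2ll %.4f", v))
    }
    v
  }
  opt <- stats::optim(x0, objfun, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6))
  convergence <- if (opt$convergence == 0) "converged" else "iteration-limit"
  if (convergence != "converged") {
    warning("fit did not converge within the iteration budget (status ",
            opt$convergence, "); estimates returned with warning status")
  }
  xhat <- opt$par
  names(xhat) <- names(x0)
  pars <- .unpack_params(xhat, spec)
  final <- .neg2ll_prepared(subs, spec, pars, eta_start = warm$eta)
  se_theta <- se_log <- NULL
  if (isTRUE(se)) {
    H <- .fd_hessian(objfun, xhat)
    cov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_log) && all(diag(cov_log) > 0)) {
      se_log <- stats::setNames(sqrt(diag(cov_log)), names(x0))
      th_names <- paste0("theta.", spec$estimate_theta)
      se_theta <- stats::setNames(
        se_log[th_names] * unlist(pars$theta[spec$estimate_theta]),
        spec$estimate_theta)
    } else {
      warning("Hessian not positive definite; standard errors unavailable")
    }
  }
  etas <- attr(final, "eta")
  omega_vec <- unlist(pars$omega)
  shrink <- 1 - apply(etas, 2, stats::sd) / omega_vec[colnames(etas)]
  structure(
    list(theta = pars$theta, se_theta = se_theta, se_log = se_log,
         omega = pars$omega, sigma = pars$sigma,
         objective = as.numeric(final), convergence = convergence,
         eta = etas, shrinkage = shrink, n_subjects = length(subs),
         n_obs = sum(nobs), spec = spec, trace = best$trace),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, %d subjects, %d observations\n",
              x$spec$structural, x$n_subjects, x$n_obs))
  cat(sprintf("  -2LL = %.3f (%s)\n", x$objective, x$convergence))
  est <- unlist(x$theta[x$spec$estimate_theta])
  cat("  theta:\n")
  for (nm in names(est)) {
    se <- if (!is.null(x$se_theta)) sprintf(" (SE %.3g)", x$se_theta[[nm]]) else ""
    cat(sprintf("    %-6s %.4g%s\n", nm, est[[nm]], se))
  }
  cat("  omega (log-SD):", paste(sprintf("%s=%.3f", names(x$omega),
                                         unlist(x$omega)), collapse = ", "), "\n")
  cat("  shrinkage:", paste(sprintf("%s=%.2f", names(x$shrinkage),
                                    x$shrinkage), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical-Bayes individual estimates
#'
#' Re-locates each subject's conditional mode `eta*` at the final population
#' estimates and returns the individual parameters (typical values times
#' `exp(eta*)`) together with the eta modes and the shrinkage statistic
#' `1 - SD(eta*) / omega` per random effect. Subjects without quantifiable
#' observations are excluded (with a message from data preparation).
#'
#' @param data The `pk_dataset` the model was fitted to.
#' @param fit A `fit_result` from [fit_population()].
#' @return A list with `individual` (data frame of per-subject parameters:
#'   id, age, dose level columns absent here - see [derive_posthoc()]),
#'   `eta` (matrix of modes), `shrinkage`.
#' @export
empirical_bayes <- function(data, fit) {
  stopifnot(inherits(fit, "fit_result"))
  spec <- fit$spec
  subs <- .prep_subjects(data, spec)
  pars <- list(theta = fit$theta, omega = fit$omega, sigma = fit$sigma)
  val <- .neg2ll_prepared(subs, spec, pars)
  etas <- attr(val, "eta")
  coeffs <- spec$coeffs
  coeffs$theta <- fit$theta
  ind <- lapply(seq_along(subs), function(i) {
    sub <- subs[[i]]
    typ <- typical_params(sub$covs, coeffs)
    p <- typ
    for (nm in colnames(etas)) {
      if (!is.null(p[[nm]])) p[[nm]] <- p[[nm]] * exp(etas[i, nm])
    }
    data.frame(id = sub$id, age = sub$covs$age, ffm = sub$covs$ffm,
               agp = sub$covs$agp, cl_f = p$cl_f, v2_f = p$v2_f,
               q_f = if (is.null(p$q_f)) NA_real_ else p$q_f,
               v3_f = if (is.null(p$v3_f)) NA_real_ else p$v3_f,
               ka = p$ka, alag = p$alag, f_rel = p$f_rel,
               dose_at_pk = sub$amt_last[length(sub$amt_last)],
               stringsAsFactors = FALSE)
  })
  omega_vec <- unlist(fit$omega)
  list(individual = do.call(rbind, ind), eta = etas,
       shrinkage = 1 - apply(etas, 2, stats::sd) / omega_vec[colnames(etas)])
}
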