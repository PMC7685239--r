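# Per-subject derived exposure metrics from empirical-Bayes parameters,
# geometric summary statistics, classification against the adult reference
# exposure interval, and dose-titration summary tables.

#' Geometric mean and geometric CV\%
#'
#' `geometric mean = exp(mean(log(x)))` and
#' `geometric CV% = sqrt(exp(sd(log(x))^2) - 1) * 100` (sample SD, n-1
#' denominator; CV requires at least two values).
#'
#' @param values Positive numeric vector.
#' @return List with `gm` and `gcv_pct` (`NA` for n = 1).
#' @export
geometric_stats <- function(values) {
  if (!length(values)) stop("'values' must be non-empty")
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("non-positive value at position ", bad[1],
         " (geometric statistics require strictly positive values)")
  }
  lx <- log(values)
  gm <- exp(mean(lx))
  gcv <- if (length(values) >= 2) sqrt(exp(stats::sd(lx)^2) - 1) * 100 else NA_real_
  list(gm = gm, gcv_pct = gcv)
}

#' Adult reference exposure interval
#'
#' The steady-state AUC target and percentile band, from healthy adults
#' receiving 10 mg of the suspension formulation, against which pediatric
#' PED10-equivalent exposures are classified.
#'
#' @param target Target AUC (ng·h/mL), default 889.
#' @param lower,upper Percentile bounds (ng·h/mL), defaults 421 and 1896
#'   (5th-95th percentile).
#' @return A list of class `adult_reference`.
#' @export
adult_reference <- function(target = 889, lower = 421, upper = 1896) {
  if (!(lower < target && target < upper)) stop("must satisfy lower < target < upper")
  structure(list(target = target, lower = lower, upper = upper),
            class = "adult_reference")
}

#' Fraction of exposures inside the adult reference band
#'
#' Closed-interval membership: `lower <= auc <= upper`.
#'
#' @param aucs Positive AUC values (ng·h/mL) at the PED10-equivalent dose.
#' @param ref An [adult_reference].
#' @return Fraction in `[0, 1]`.
#' @export
adult_range_fraction <- function(aucs, ref = adult_reference()) {
  stopifnot(inherits(ref, "adult_reference"))
  if (!length(aucs)) stop("'aucs' must be non-empty")
  if (any(aucs <= 0)) stop("'aucs' must be positive")
  mean(aucs >= ref$lower & aucs <= ref$upper)
}

# round half away from zero (printed tables use half-up at one decimal)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-subject exposure metrics from empirical-Bayes parameters
#'
#' For each subject of an [empirical_bayes()] result, derives the
#' steady-state metrics via [secondary_params()] at the subject's dose at
#' PK sampling: dose-normalized AUC, Cmax and Ctrough, tmax, terminal
#' half-life, CL/F and Vz/F. Under linear kinetics the dose-normalized
#' metrics are invariant to the dose.
#'
#' @param ebe Result of [empirical_bayes()] (or any data frame with columns
#'   `id`, `age`, `cl_f`, `v2_f`, `ka`, `alag`, `f_rel`, `dose_at_pk` and
#'   optionally `q_f`, `v3_f`).
#' @param tau Dosing interval (h), default 24 (once daily).
#' @return Data frame of class `posthoc_rows`: `id`, `age_group`, `dose_mg`,
#'   `auc_per_dose` (ng·h/mL/mg), `cmax_per_dose`, `ctrough_per_dose`
#'   (ng/mL/mg), `tmax` (h), `t_half` (h), `cl_f` (L/h), `vz_f` (L).
#' @export
derive_posthoc <- function(ebe, tau = 24) {
  ind <- if (is.data.frame(ebe)) ebe else ebe$individual
  need <- c("id", "age", "cl_f", "v2_f", "ka", "alag", "f_rel", "dose_at_pk")
  miss <- setdiff(need, names(ind))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(ind$dose_at_pk))) {
    stop("missing dose at PK sampling for subject ",
         ind$id[which(is.na(ind$dose_at_pk))[1]])
  }
  rows <- lapply(seq_len(nrow(ind)), function(i) {
    r <- ind[i, ]
    two <- !is.null(r$q_f) && is.finite(r$q_f) && !is.na(r$q_f)
    p <- structural_params(cl_f = r$cl_f, v2_f = r$v2_f,
                           q_f = if (two) r$q_f else NULL,
                           v3_f = if (two) r$v3_f else NULL,
                           ka = r$ka, alag = r$alag, f_rel = r$f_rel)
    sp <- secondary_params(p, dose_regimen(0, r$dose_at_pk, tau = tau))
    data.frame(id = r$id, age_group = as.character(age_group(r$age)),
               dose_mg = r$dose_at_pk,
               auc_per_dose = sp$auc_inf_per_dose,
               cmax_per_dose = sp$cmax / r$dose_at_pk,
               ctrough_per_dose = sp$ctrough / r$dose_at_pk,
               tmax = sp$tmax, t_half = sp$t_half,
               cl_f = r$cl_f, vz_f = sp$vz_f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posthoc_rows", "data.frame")
  out
}

#' Dosing summary table
#'
#' Counts and percentages per visit, dose level and age group, with
#' percentages of the stratum denominator rounded half-up to one decimal
#' (matching clinical-table convention). Input is either a count table
#' (columns `visit`, `level`, `group`, `n`) with explicit `denominators`,
#' or per-subject assignments (columns `id`, `week`, `level`, `group`) from
#' which counts and denominators are tabulated.
#'
#' @param x Counts or assignments data frame (see above).
#' @param denominators Named vector of stratum sizes (required with counts;
#'   derived from distinct ids with assignments).
#' @return Data frame: `visit`, `level`, `group`, `n`, `pct`.
#' @export
dosing_summary <- function(x, denominators = NULL) {
  if (!nrow(x)) stop("input must be non-empty")
  if (all(c("visit", "level", "group", "n") %in% names(x))) {
    counts <- x
    if (is.null(denominators)) stop("'denominators' required with count input")
  } else if (all(c("id", "week", "level", "group") %in% names(x))) {
    counts <- stats::aggregate(list(n = x$id),
                               by = list(visit = x$week, level = x$level,
                                         group = x$group),
                               FUN = function(v) length(unique(v)))
    if (is.null(denominators)) {
      denominators <- tapply(x$id, x$group, function(v) length(unique(v)))
    }
  } else {
    stop("input must have columns visit/level/group/n or id/week/level/group")
  }
  if (any(!counts$group %in% names(denominators))) {
    stop("denominator missing for some group(s)")
  }
  counts$pct <- round_half_up(100 * counts$n /
                                as.numeric(denominators[counts$group]), 1)
  counts[order(counts$visit, counts$group, counts$level), ]
}

#' Summarize exposure metrics by age group
#'
#' Geometric mean and geometric CV\% per metric per age group plus a pooled
#' `"all"` group; `tmax` is summarized as median (range). Groups without
#' subjects are omitted with a message.
#'
#' @param rows A `posthoc_rows` data frame from [derive_posthoc()].
#' @param metrics Metric columns to summarize.
#' @return Data frame: `group`, `metric`, `n`, `gm`, `gcv_pct`, `median`,
#'   `min`, `max` (median/range filled for `tmax` only).
#' @export
summarize_by_age <- function(rows, metrics = c("auc_per_dose", "cmax_per_dose",
                                               "ctrough_per_dose", "tmax",
                                               "t_half", "cl_f", "vz_f")) {
  if (!nrow(rows)) stop("'rows' must be non-empty")
  groups <- c(split(rows, rows$age_group), list(all = rows))
  groups <- Filter(function(g) nrow(g) > 0, groups)
  out <- list()
  for (g in names(groups)) {
    gr <- groups[[g]]
    for (m in metrics) {
      if (m == "tmax") {
        out[[length(out) + 1L]] <- data.frame(
          group = g, metric = m, n = nrow(gr), gm = NA_real_,
          gcv_pct = NA_real_, median = stats::median(gr[[m]]),
          min = min(gr[[m]]), max = max(gr[[m]]), stringsAsFactors = FALSE)
      } else {
        gs <- geometric_stats(gr[[m]])
        out[[length(out) + 1L]] <- data.frame(
          group = g, metric = m, n = nrow(gr), gm = gs$gm,
          gcv_pct = gs$gcv_pct, median = NA_real_, min = NA_real_,
          max = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
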