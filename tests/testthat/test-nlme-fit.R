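test_that("Laplace objective is exact on linear-normal toy models", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    mu <- runif(1, 1, 10)
    omega <- runif(1, 0.2, 1.5)
    sig <- runif(1, 0.1, 0.8)
    b <- runif(1, 0.5, 2)
    y <- rnorm(n, mu + b * rnorm(1, 0, omega), sig)
    fpred <- function(eta) rep(mu + b * eta[1], n)
    lap <- laplace_neg2ll(y, fpred, omega_sd = omega, sigma = c(0, sig))
    S <- diag(sig^2, n) + omega^2 * b^2
    r <- y - mu
    closed <- n * log(2 * pi) + determinant(S)$modulus[1] +
      drop(t(r) %*% solve(S, r))
    expect_equal(as.numeric(lap), as.numeric(closed), tolerance = 1e-6)
  }
})

test_that("the omega -> 0 limit collapses to extended least squares", {
  set.seed(1)
  y <- rnorm(6, 5, 0.3)
  fpred <- function(eta) rep(5 * exp(eta[1]), 6)
  els <- sum(log(2 * pi * ((0.1 * 5)^2 + 0.2^2)) +
               (y - 5)^2 / ((0.1 * 5)^2 + 0.2^2))
  exact0 <- laplace_neg2ll(y, fpred, omega_sd = 0, sigma = c(0.1, 0.2))
  expect_equal(as.numeric(exact0), els)
  near0 <- laplace_neg2ll(y, fpred, omega_sd = 1e-6, sigma = c(0.1, 0.2))
  expect_equal(as.numeric(near0), els, tolerance = 1e-4)
})

test_that("population objective is exchangeable over subjects", {
  cfg <- trial_config("giraffe")
  cfg$strata[[1]]$n_subjects <- 6
  cfg$strata[[2]]$n_subjects <- 2
  ds <- simulate_trial(cfg, seed = 3)
  spec <- pop_model_spec("2cpt", sigma = data.frame(study = "giraffe",
                                                    prop = 0.15, add = 0.05))
  o1 <- conditional_neg2ll(ds, spec)
  ids <- unique(ds$ID)
  perm <- do.call(rbind, lapply(rev(ids), function(id) ds[ds$ID == id, ]))
  o2 <- conditional_neg2ll(perm, spec)
  expect_equal(as.numeric(o1), as.numeric(o2), tolerance = 1e-10)
  # deterministic
  expect_equal(as.numeric(conditional_neg2ll(ds, spec)), as.numeric(o1))
})

test_that("noise-free rich data identify the fixed effects to < 0.1 %", {
  cfg <- trial_config("giraffe")
  cfg$strata[[1]]$n_subjects <- 6
  cfg$strata[[2]]$n_subjects <- 0
  ds <- simulate_trial(cfg, omega = omega_spec(c(cl_f = 0, v2_f = 0, ka = 0)),
                       sigma = sigma_spec(0, 0), seed = 5, censor = FALSE)
  co <- covariate_coeffs()
  co$theta$cl_f <- 8.81 * 1.25
  co$theta$v2_f <- 162 * 0.8
  co$theta$ka <- 0.742 * 1.2
  spec <- pop_model_spec("2cpt", co,
                         omega = c(cl_f = 0, v2_f = 0, ka = 0),
                         sigma = data.frame(study = "giraffe", prop = 0,
                                            add = 0.01),
                         estimate_omega = character(0),
                         estimate_sigma = character(0))
  fit <- suppressWarnings(
    fit_population(ds, spec, options = list(maxit = 1500, se = FALSE)))
  expect_equal(fit$theta$cl_f, 8.81, tolerance = 1e-3)
  expect_equal(fit$theta$v2_f, 162, tolerance = 1e-3)
  expect_equal(fit$theta$ka, 0.742, tolerance = 1e-3)
})

test_that("optimization never ends above its starting objective", {
  cfg <- trial_config("giraffe")
  cfg$strata[[1]]$n_subjects <- 10
  cfg$strata[[2]]$n_subjects <- 0
  ds <- simulate_trial(cfg, sigma = sigma_spec(0.15, 0.05), seed = 6)
  spec <- pop_model_spec("2cpt", sigma = data.frame(study = "giraffe",
                                                    prop = 0.15, add = 0.05))
  at_truth <- conditional_neg2ll(ds, spec)
  fit <- suppressWarnings(
    fit_population(ds, spec, options = list(maxit = 150, se = FALSE)))
  expect_lte(fit$objective, as.numeric(at_truth) + 1e-8)
  # accepted-improvement trace is monotone decreasing
  expect_true(all(diff(fit$trace) < 0))
})

test_that("empirical-Bayes modes obey the shrinkage limits", {
  set.seed(30)
  p <- final_2cpt_params()
  true_eta <- 0.4
  tt <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 48, 72)
  p_i <- p
  p_i$cl_f <- p$cl_f * exp(true_eta)
  y <- conc_single_dose(tt, 18, p_i) * (1 + rnorm(length(tt), 0, 0.02))
  fpred <- function(eta) conc_single_dose(tt, 18, structural_params(
    cl_f = p$cl_f * exp(eta[1]), v2_f = p$v2_f, q_f = p$q_f, v3_f = p$v3_f,
    ka = p$ka, alag = p$alag))
  # diffuse prior: mode approaches the subject's own deviation
  rich <- laplace_neg2ll(y, fpred, omega_sd = 2, sigma = c(0.02, 0.001))
  expect_equal(attr(rich, "eta")[1], true_eta, tolerance = 0.05)
  # tight prior: complete shrinkage to zero
  tight <- laplace_neg2ll(y, fpred, omega_sd = 1e-4, sigma = c(0.02, 0.001))
  expect_lt(abs(attr(tight, "eta")[1]), 1e-4)
})

test_that("empirical_bayes returns individual parameters and shrinkage", {
  cfg <- trial_config("giraffe")
  cfg$strata[[1]]$n_subjects <- 12
  cfg$strata[[2]]$n_subjects <- 0
  ds <- simulate_trial(cfg, sigma = sigma_spec(0.1, 0.02), seed = 7)
  spec <- pop_model_spec("2cpt", sigma = data.frame(study = "giraffe",
                                                    prop = 0.1, add = 0.02))
  fit <- structure(list(theta = spec$coeffs$theta, omega = as.list(spec$omega),
                        sigma = spec$sigma, spec = spec),
                   class = "fit_result")
  ebe <- empirical_bayes(ds, fit)
  expect_equal(nrow(ebe$individual), 12L)
  expect_true(all(ebe$individual$cl_f > 0))
  expect_true(all(is.finite(ebe$eta)))
  expect_named(ebe$shrinkage, c("cl_f", "v2_f", "ka"))
  # with rich sampling shrinkage should be modest
  expect_true(all(ebe$shrinkage < 0.6))
  # individual parameters equal typical values times exp(eta)
  i1 <- ebe$individual[1, ]
  s1 <- subject(i1$id, age = i1$age, weight = i1$ffm / 0.85, agp = i1$agp,
                ffm = i1$ffm, formulation = "B")
  typ <- typical_params(s1, spec$coeffs)
  expect_equal(i1$cl_f, typ$cl_f * exp(ebe$eta[as.character(i1$id), "cl_f"]),
               tolerance = 1e-10)
})

test_that("subjects without quantifiable observations are excluded", {
  cfg <- trial_config("giraffe")
  cfg$strata[[1]]$n_subjects <- 3
  cfg$strata[[2]]$n_subjects <- 0
  ds <- simulate_trial(cfg, seed = 9)
  # censor every observation of subject 2
  sel <- ds$ID == 2 & ds$EVID == 0
  ds$DV[sel] <- NA
  ds$BLQ[sel] <- 1L
  ds$MDV[sel] <- 1L
  spec <- pop_model_spec("2cpt", sigma = data.frame(study = "giraffe",
                                                    prop = 0.15, add = 0.05))
  expect_message(subs <- pedpk:::.prep_subjects(ds, spec), "excluded 1")
  expect_false("2" %in% names(subs))
})

test_that("two-compartment fits to sparse data raise a warning", {
  cfg <- tiny_trial_config(4)
  ds <- simulate_trial(cfg, seed = 10)
  spec <- pop_model_spec("2cpt", sigma = data.frame(study = "lion",
                                                    prop = 0.2, add = 0.05))
  w <- capture_warnings(fit_population(ds, spec,
                                       options = list(maxit = 2, se = FALSE)))
  expect_match(w, "sparse sampling", all = FALSE)
})
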