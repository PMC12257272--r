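test_that("IV bolus initial concentration and analytic AUC identities hold", {
  set.seed(11)
  for (i in 1:5) {
    d <- random_disp()
    iv <- absorption_params("IV")
    dose <- runif(1, 1, 20)
    expect_equal(conc_profile(d, iv, dose_events(0, dose), 0),
                 dose / d$Vc, tolerance = 1e-9)
    # dense trapezoid converges to dose/Cl (10+ terminal half-lives); the
    # step must resolve the fastest phase of the random parameter set
    hl <- derived_params(d)$terminal_half_life
    fastest <- max(abs(disposition_eigenvalues(d)))
    tt <- seq(0, 12 * hl, by = min(0.05, 0.05 / fastest))
    cc <- conc_profile(d, iv, dose_events(0, dose), tt)
    auc <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
    expect_equal(auc, dose / d$Cl, tolerance = 0.005)
  }
})

test_that("oral profiles start at zero and integrate to F*dose/Cl", {
  d <- disp50()
  a <- abs_tls()
  expect_equal(conc_profile(d, a, dose_events(0, 10), 0), 0)
  hl <- derived_params(d)$terminal_half_life
  tt <- seq(0, 15 * hl + 5 / a$Ka, by = 0.05)
  cc <- conc_profile(d, a, dose_events(0, 10), tt)
  auc <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(auc, a$F * 10 / d$Cl, tolerance = 0.005)
})

test_that("superposition and dose proportionality are exact", {
  d <- disp50()
  a <- abs_tls()
  tt <- seq(0, 48, by = 0.5)
  multi <- conc_profile(d, a, dose_events(c(0, 12, 24), 5), tt)
  single <- function(t0) {
    out <- numeric(length(tt))
    on <- tt >= t0
    out[on] <- conc_profile(d, a, dose_events(0, 5), tt[on] - t0)
    out
  }
  expect_equal(multi, single(0) + single(12) + single(24), tolerance = 1e-10)
  doubled <- conc_profile(d, a, dose_events(c(0, 12, 24), 10), tt)
  expect_equal(doubled, 2 * multi, tolerance = 1e-12)
})

test_that("closed form matches the ODE oracle on random parameter sets", {
  skip_if_not_installed("deSolve")
  set.seed(22)
  tt <- seq(0.25, 72, by = 0.75)
  for (i in 1:10) {
    d <- random_disp()
    iv <- conc_profile(d, absorption_params("IV"), dose_events(0, 10), tt)
    iv_ode <- ode_profile(d, absorption_params("IV"), dose_events(0, 10), tt)
    expect_lt(max(abs(iv - iv_ode) / pmax(iv_ode, 1e-6 * max(iv_ode))), 1e-6)
    a <- absorption_params("FEED_TLS", Ka = exp(runif(1, log(0.05), log(2))),
                           F = runif(1, 0.2, 1))
    or <- conc_profile(d, a, dose_events(c(0, 12), 5), tt)
    or_ode <- ode_profile(d, a, dose_events(c(0, 12), 5), tt)
    expect_lt(max(abs(or - or_ode) / pmax(or_ode, 1e-6 * max(or_ode))), 1e-6)
  }
})

test_that("terminal log-slope matches the smallest eigenvalue", {
  set.seed(33)
  for (i in 1:5) {
    d <- random_disp()
    lam1 <- disposition_eigenvalues(d)[1]
    hl <- log(2) / abs(lam1)
    tt <- seq(20 * hl, 24 * hl, length.out = 50)
    cc <- conc_profile(d, absorption_params("IV"), dose_events(0, 10), tt)
    slope <- coef(lm(log(cc) ~ tt))[2]
    expect_equal(unname(slope), lam1, tolerance = 1e-3)
  }
})

test_that("Ka colliding with an eigenvalue is perturbed, not fatal", {
  d <- disp50()
  lam <- abs(disposition_eigenvalues(d)[2])
  a_hit <- absorption_params("FEED_TLS", Ka = lam, F = 0.5)
  tt <- seq(0, 48, by = 1)
  expect_warning(c_hit <- conc_profile(d, a_hit, dose_events(0, 10), tt),
                 "perturbing")
  a_near <- absorption_params("FEED_TLS", Ka = lam * (1 + 1e-4), F = 0.5)
  c_near <- conc_profile(d, a_near, dose_events(0, 10), tt)
  expect_lt(max(abs(c_hit - c_near) / max(c_near)), 1e-3)
})

test_that("profile input validation catches bad grids and doses", {
  d <- disp50()
  expect_error(conc_profile(d, absorption_params("IV"),
                            dose_events(0, 5), c(2, 1)), "sorted")
  expect_error(dose_events(-1, 5), ">= 0")
  expect_error(dose_events(0, 0), "> 0")
})
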