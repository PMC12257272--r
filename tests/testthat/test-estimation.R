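# The Laplace objective and the fitting machinery, on problems small enough
# to run in seconds; full parameter-recovery checks live in the acceptance
# suite.

# one-subject oral dataset with a single absorption random effect, used for
# the numerical-integration oracle
one_sub_data <- function(conc, times, bw = 50) {
  rbind(data.frame(id = "s1", trial = "T", route = "FEED_TLS", bw = bw,
                   time = 0, evid = 1, amt = 10, conc = NA, lloq = 0.01),
        data.frame(id = "s1", trial = "T", route = "FEED_TLS", bw = bw,
                   time = times, evid = 0, amt = NA, conc = conc,
                   lloq = 0.01))
}

toy_model <- function(omega_F, sd0 = 0.05) {
  pop_model(disp50(), absorption = list(FEED_TLS = abs_tls()),
            omega = c(F_FEED_TLS = omega_F),
            residual = list(FEED_TLS = residual_model(sd0, 0)))
}

test_that("zero-omega OFV equals the pooled fixed-effect -2 log-likelihood", {
  m <- doxy_final_model()
  d <- generate_trials(m, list(iv_design(4)), seed = 21)
  m0 <- pop_model(m$disposition, covariates = m$covariates,
                  omega = numeric(), residual = m$residual)
  ofv <- marginal_ofv(d, m0)
  # direct pooled computation
  obs <- d[d$evid == 0, ]
  ll <- 0
  for (s in unique(obs$id)) {
    sub <- obs[obs$id == s, ]
    disp <- typical_disposition(m0, sub$bw[1])
    pred <- conc_profile(disp, absorption_params("IV"),
                         dose_events(0, d$amt[d$evid == 1 & d$id == s]),
                         sub$time)
    sdv <- sqrt(0.013^2 + (0.139 * pred)^2)
    ll <- ll + sum(dnorm(sub$conc, pred, sdv, log = TRUE))
  }
  expect_equal(ofv, -2 * ll, tolerance = 1e-8)
})

test_that("Laplace OFV matches adaptive numerical integration over the random effect", {
  # single subject, eta on F only: marginal likelihood is a 1-D integral
  times <- c(2, 6, 12, 24)
  truth <- conc_profile(disp50(), abs_tls(), dose_events(0, 10), times)
  set.seed(31)
  y <- truth * exp(0.3) + rnorm(4, 0, 0.05)   # a subject with high F
  d <- one_sub_data(y, times)
  # the Laplace error grows with the random-effect scale: near-linear cases
  # agree to 1e-4, a strongly nonlinear one (omega 0.7) to 1e-3
  for (om in c(0.05, 0.3, 0.7)) {
    mod <- toy_model(om)
    ofv <- marginal_ofv(d, mod)
    lik <- integrate(function(eta) {
      sapply(eta, function(e) {
        pred <- truth * exp(e)
        exp(sum(dnorm(y, pred, 0.05, log = TRUE)) + dnorm(e, 0, om, log = TRUE))
      })
    }, lower = -3, upper = 3, rel.tol = 1e-10)$value
    expect_equal(ofv, -2 * log(lik),
                 tolerance = if (om < 0.3) 1e-4 else 1e-3)
  }
})

test_that("the OFV prefers the generating parameters over perturbed ones", {
  m <- doxy_final_model()
  gen <- pop_model(m$disposition, covariates = m$covariates,
                   omega = c(Cl = m$omega[["Cl"]], Vc = m$omega[["Vc"]]),
                   residual = m$residual)
  pert <- gen
  pert$disposition$Cl <- gen$disposition$Cl * 1.5
  pert$disposition$Vc <- gen$disposition$Vc * 1.5
  wins <- 0
  for (s in 1:5) {
    d <- generate_trials(gen, list(iv_design(12)), seed = 100 + s)
    if (marginal_ofv(d, gen) < marginal_ofv(d, pert)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("a near-noiseless homogeneous dataset is fit almost exactly", {
  gen <- pop_model(disp50(), omega = numeric(),
                   residual = list(IV = residual_model(1e-4, 0)))
  des <- list(iv_design(6, bw_sampler = function(n) rep(50, n), lloq = 1e-6))
  d <- generate_trials(gen, des, seed = 41)
  f <- pkfit(d, stage = "iv_only", random = character(0),
             inits = c(Cl = 0.2, Vc = 0.25),
             control = list(maxit = 150, factr = 1e9))
  for (nm in c("Cl", "Vc", "V2", "Cl2"))
    expect_equal(f$theta[[nm]], disp50()[[nm]], tolerance = 0.01)
})

test_that("AIC identity and method contract of the fit object", {
  m <- doxy_final_model()
  d <- generate_trials(m, list(iv_design(6)), seed = 51)
  f <- pkfit(d, stage = "iv_only", random = "Cl",
             control = list(maxit = 5, factr = 1e13))
  expect_equal(f$aic, f$ofv + 2 * f$n_par, tolerance = 1e-12)
  expect_equal(AIC(f), f$aic, tolerance = 1e-12)
  expect_length(f$ebe, 6)
  co <- coef(f)
  expect_true(all(c("Cl", "Vc", "stdev0_IV", "omega_Cl") %in% names(co)))
  pr <- predict(f)
  expect_equal(nrow(pr), sum(d$evid == 0))
  rs <- residuals(f)
  expect_true(all(is.finite(rs$residual)))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_identical(nrow(sims[[1]]), nrow(d))
})

test_that("shrinkage hits its analytic limits and responds to sparsity", {
  om <- c(Cl = 0.3, Vc = 0.5)
  # EBE spread equal to omega: 0% shrinkage
  ebes <- lapply(seq_len(200), function(i) c(Cl = 0, Vc = 0))
  set.seed(61)
  for (i in seq_along(ebes))
    ebes[[i]] <- c(Cl = rnorm(1, 0, 0.3), Vc = rnorm(1, 0, 0.5))
  sh <- shrinkage(ebes, om)
  expect_lt(abs(sh$eta[["Cl"]]), 15)
  # all EBEs collapsed to zero: 100%
  zero <- lapply(1:5, function(i) c(Cl = 0, Vc = 0))
  expect_equal(unname(shrinkage(zero, om)$eta), c(100, 100))
  # omega = 0 is undefined
  expect_true(is.na(shrinkage(zero, c(Cl = 0, Vc = 0.5))$eta[["Cl"]]))
})

test_that("sparse designs shrink empirical Bayes estimates more than rich ones", {
  m <- doxy_final_model()
  gen <- pop_model(m$disposition, omega = c(Cl = m$omega[["Cl"]]),
                   residual = m$residual)
  rich <- generate_trials(gen, list(iv_design(40)), seed = 71)
  # one early distribution-phase sample per subject: clearance is barely
  # identifiable, so its empirical Bayes estimates must collapse
  sparse <- generate_trials(
    gen, list(trial_design("IVS", 40, "IV", 8, 0, 0.5, 0.001)), seed = 71)
  sh <- function(d) {
    subjects <- doxypk:::.split_subjects(d)
    cache <- new.env(); cache$eta <- vector("list", length(subjects))
    doxypk:::.total_ofv(subjects, c(as.list(unlist(gen$disposition)),
                                    list(stdev0_IV = 0.013, cmult_IV = 0.139)),
                        list(), gen$omega, FALSE, cache = cache)
    shrinkage(cache$eta, gen$omega)$eta[["Cl"]]
  }
  expect_gt(sh(sparse), sh(rich))
})

test_that("unidentifiable designs and bad inputs raise errors", {
  m <- doxy_final_model()
  d <- generate_trials(m, list(iv_design(4, bw_sampler = function(n) rep(50, n))),
                       seed = 81)
  expect_error(pkfit(d, stage = "iv_only", covariates = c(Cl = NA)),
               "constant")
  expect_error(pkfit(d, stage = "oral_given_iv"), "no data left")
  expect_error(pkfit(d, stage = "iv_only", covariates = c(BAD = NA)),
               "disposition")
})
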