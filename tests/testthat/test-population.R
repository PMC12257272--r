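test_that("BSV percent / omega conversion follows the lognormal-CV convention", {
  expect_identical(bsv_percent_to_omega(0), 0)
  # frozen from sqrt(log(1 + cv^2))
  expect_equal(bsv_percent_to_omega(84.8), 0.73607, tolerance = 1e-4)
  expect_equal(bsv_percent_to_omega(34.3), 0.33350, tolerance = 1e-4)
  # round trip to machine precision
  for (cv in c(0.1, 5, 27.1, 84.8, 245.5))
    expect_equal(omega_to_bsv_percent(bsv_percent_to_omega(cv)), cv,
                 tolerance = 1e-12)
  # direct convention
  expect_equal(bsv_percent_to_omega(50, convention = "direct"), 0.5)
  expect_error(bsv_percent_to_omega(-1), ">= 0")
})

test_that("zero omega collapses the population onto the typical animal", {
  m <- doxy_final_model()
  m0 <- pop_model(m$disposition, covariates = m$covariates,
                  absorption = m$absorption, omega = numeric(),
                  residual = m$residual)
  pop <- draw_population(m0, 5, bw = 30, route = "FEED_TLS", seed = 1)
  typ <- typical_disposition(m0, 30)
  for (nm in names(typ)) expect_equal(unique(pop[[nm]]), typ[[nm]])
  expect_equal(unique(pop$F), 0.501)
})

test_that("realised clearance CV matches the model BSV at large n", {
  m <- doxy_final_model()
  pop <- draw_population(m, 10000, bw = 50, route = "FEED_TLS", seed = 4)
  cv <- 100 * sd(pop$Cl) / mean(pop$Cl)
  expect_lt(abs(cv - 27.1), 2)  # within 2 CV points of Table value
  # median close to the typical value (lognormal median = typical)
  expect_equal(median(pop$Cl), 0.259, tolerance = 0.02)
})

test_that("draws are reproducible and covariate-scaled by body weight", {
  m <- doxy_final_model()
  a <- draw_population(m, 50, bw = 10, route = "SOL_DW", seed = 7)
  b <- draw_population(m, 50, bw = 10, route = "SOL_DW", seed = 7)
  expect_identical(a, b)
  # typical Cl at 10 kg is the scaled value
  m0 <- m; m0$omega[] <- 0
  p10 <- draw_population(m0, 1, bw = 10, route = "SOL_DW", seed = 1)
  expect_equal(p10$Cl, 0.259 * (10 / 50)^0.299, tolerance = 1e-12)
  expect_error(draw_population(m, 5, bw = 50, route = "IVX"))
})

test_that("residual error model has the stated variance structure", {
  r <- residual_model(0, 0.139)
  set.seed(11)
  y <- apply_residual_error(rep(1, 20000), r)
  expect_equal(sd(y - 1), 0.139, tolerance = 0.01)
  # pure proportional error leaves zero concentrations untouched
  expect_identical(apply_residual_error(0, r, seed = 1), 0)
  r2 <- residual_model(0.01, 0)
  set.seed(12)
  y2 <- apply_residual_error(rep(0, 20000), r2)
  expect_equal(sd(y2), 0.01, tolerance = 0.001)
  expect_error(residual_model(0, 0), "some error")
})

test_that("bioavailability realisations may exceed 1 unless capped", {
  m <- doxy_final_model()                       # F BSV 84.8%
  pop <- draw_population(m, 2000, bw = 50, route = "FEED_TLS", seed = 3)
  expect_gt(mean(pop$F > 1), 0.05)
  mc <- doxy_final_model(cap_F_at_1 = TRUE)
  popc <- draw_population(mc, 2000, bw = 50, route = "FEED_TLS", seed = 3)
  expect_lte(max(popc$F), 1)
})

test_that("population model round-trips through the YAML configuration", {
  m <- doxy_final_model()
  path <- tempfile(fileext = ".yaml")
  write_pop_model(m, path)
  m2 <- read_pop_model(path)
  expect_equal(unlist(m2$disposition), unlist(m$disposition))
  expect_equal(m2$covariates, m$covariates)
  expect_equal(m2$omega[names(m$omega)], m$omega)
  expect_equal(m2$absorption$SOL_DW$Ka, 0.689)
  expect_equal(m2$residual$FEED_TLS$cmult, 0.228)
})

test_that("the packaged final model carries the published parameters", {
  m <- doxy_final_model()
  expect_equal(m$disposition$Cl, 0.259)
  expect_equal(m$covariates[["Cl2"]], -0.224)
  expect_equal(m$absorption$FEED_TLS$F, 0.501)
  expect_equal(m$absorption$SOL_TUBING$Ka, 0.725)
  expect_equal(omega_to_bsv_percent(m$omega[["F_FEED_TLS"]]), 84.8,
               tolerance = 1e-6)
  expect_equal(m$residual$IV$stdev0, 0.013)
})
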