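# Shared fixtures: published parameter values and small builders.

# Final-model typical disposition at the 50-kg reference.
disp50 <- function() {
  disposition_params(Cl = 0.259, Cl2 = 1.179, Cl3 = 0.072,
                     Vc = 0.192, V2 = 0.595, V3 = 0.536)
}

# Table of secondary-parameter inputs at 10 and 100 kg (scaled columns).
disp10 <- function() {
  disposition_params(Cl = 0.161, Cl2 = 1.692, Cl3 = 0.178,
                     Vc = 0.192, V2 = 0.595, V3 = 0.295)
}
disp100 <- function() {
  disposition_params(Cl = 0.320, Cl2 = 1.010, Cl3 = 0.050,
                     Vc = 0.192, V2 = 0.595, V3 = 0.699)
}

# Published absorption submodels.
abs_tls <- function() absorption_params("FEED_TLS", Ka = 0.072, F = 0.501)
abs_dw  <- function() absorption_params("SOL_DW", Ka = 0.689, F = 0.307)

# Random positive disposition parameter set (log-uniform over wide ranges).
random_disp <- function() {
  disposition_params(Cl = exp(runif(1, log(0.05), log(1))),
                     Cl2 = exp(runif(1, log(0.1), log(3))),
                     Cl3 = exp(runif(1, log(0.01), log(1))),
                     Vc = exp(runif(1, log(0.05), log(1))),
                     V2 = exp(runif(1, log(0.1), log(2))),
                     V3 = exp(runif(1, log(0.1), log(2))))
}

# Published disposition thetas / exponents for freezing staged fits.
iv_theta_published <- function() {
  c(Cl = 0.259, Cl2 = 1.179, Cl3 = 0.072, Vc = 0.192, V2 = 0.595, V3 = 0.536)
}
cov_published <- function() {
  c(Cl = 0.299, Cl2 = -0.224, Cl3 = -0.544, V3 = 0.376)
}

# Reference ODE solution of the compartment system via deSolve (independent
# oracle for the closed-form solver).
ode_profile <- function(disp, absorption, doses, times) {
  k10 <- disp$Cl / disp$Vc; k12 <- disp$Cl2 / disp$Vc; k21 <- disp$Cl2 / disp$V2
  k13 <- disp$Cl3 / disp$Vc; k31 <- disp$Cl3 / disp$V3
  oral <- absorption$route != "IV"
  deriv <- function(t, y, parms) {
    dAd <- if (oral) -absorption$Ka * y["Ad"] else 0
    inp <- if (oral) absorption$Ka * y["Ad"] else 0
    dA1 <- inp - (k10 + k12 + k13) * y["A1"] + k21 * y["A2"] + k31 * y["A3"]
    dA2 <- k12 * y["A1"] - k21 * y["A2"]
    dA3 <- k13 * y["A1"] - k31 * y["A3"]
    list(c(dAd, dA1, dA2, dA3))
  }
  knots <- sort(unique(c(0, times, doses$time)))
  conc <- setNames(numeric(length(knots)), as.character(knots))
  y_cur <- c(Ad = 0, A1 = 0, A2 = 0, A3 = 0)
  t_cur <- 0
  apply_dose <- function(y, amount) {
    if (oral) y["Ad"] <- y["Ad"] + absorption$F * amount
    else y["A1"] <- y["A1"] + amount
    y
  }
  for (i in which(doses$time == 0)) y_cur <- apply_dose(y_cur, doses$amount[i])
  conc[1] <- y_cur["A1"] / disp$Vc
  for (tk in knots[-1]) {
    sol <- deSolve::lsoda(y_cur, c(t_cur, tk), deriv, NULL,
                          rtol = 1e-11, atol = 1e-14)
    y_cur <- sol[nrow(sol), c("Ad", "A1", "A2", "A3")]
    t_cur <- tk
    for (i in which(doses$time == tk)) y_cur <- apply_dose(y_cur, doses$amount[i])
    conc[as.character(tk)] <- y_cur["A1"] / disp$Vc
  }
  unname(conc[as.character(times)])
}

# Tiny IV rich design used by several estimation tests.
iv_design <- function(n, times = c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24),
                      dose = 8, lloq = 0.01, bw_sampler = NULL) {
  trial_design("IVT", n, "IV", dose, 0, times, lloq, bw_sampler = bw_sampler)
}
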