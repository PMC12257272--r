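#' Disposition parameters of the three-compartment model
#'
#' Constructs the six structural disposition parameters of the mammillary
#' three-compartment model: elimination clearance `Cl`, distributional
#' clearances `Cl2`/`Cl3` to the two peripheral compartments, central volume
#' `Vc` and peripheral volumes `V2`/`V3`.  All parameters are per kilogram of
#' body weight (clearances in L/kg/h, volumes in L/kg), the parametrisation
#' used throughout the package.
#'
#' @param Cl elimination (plasma) clearance, L/kg/h.
#' @param Cl2,Cl3 distributional clearances to peripheral compartments 2
#'   (shallow) and 3 (deep), L/kg/h.
#' @param Vc central volume of distribution, L/kg.
#' @param V2,V3 shallow and deep peripheral volumes, L/kg.
#' @return An object of class `"disposition_params"`: a named list of the six
#'   values.
#' @examples
#' disposition_params(Cl = 0.259, Cl2 = 1.179, Cl3 = 0.072,
#'                    Vc = 0.192, V2 = 0.595, V3 = 0.536)
#' @export
disposition_params <- function(Cl, Cl2, Cl3, Vc, V2, V3) {
  p <- list(Cl = Cl, Cl2 = Cl2, Cl3 = Cl3, Vc = Vc, V2 = V2, V3 = V3)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all six disposition parameters must be finite and strictly positive")
  structure(p, class = "disposition_params")
}

#' @export
print.disposition_params <- function(x, ...) {
  cat("3-compartment disposition parameters (per kg):\n")
  print(unlist(x))
  invisible(x)
}

#' Route-specific absorption parameters
#'
#' First-order absorption rate constant and absolute bioavailability for one
#' of the oral administration submodels, or the trivial IV "absorption"
#' (`F = 1`, no `Ka`).  `F` is deliberately not constrained to be at most 1:
#' the population layer multiplies it by a lognormal random effect and the
#' realised values are not truncated.
#'
#' @param route one of `"IV"`, `"FEED_TLS"` (in-feed, field conditions),
#'   `"FEED_OTHERS"` (in-feed, laboratory conditions), `"SOL_DW"` (solution in
#'   drinking water), `"SOL_TUBING"` (solution by stomach tube).
#' @param Ka first-order absorption rate constant, 1/h (omitted for IV).
#' @param F absolute bioavailability fraction (fixed at 1 for IV).
#' @return An object of class `"absorption_params"`.
#' @examples
#' absorption_params("FEED_TLS", Ka = 0.072, F = 0.501)
#' absorption_params("IV")
#' @export
absorption_params <- function(route, Ka = NULL, F = 1) {
  route <- match.arg(route, pk_routes())
  if (route == "IV") {
    Ka <- NA_real_
    F <- 1
  } else {
    if (is.null(Ka) || !is.finite(Ka) || Ka <= 0)
      stop("oral routes require a strictly positive Ka")
  }
  if (!is.finite(F) || F <= 0) stop("F must be strictly positive")
  structure(list(route = route, Ka = Ka, F = F), class = "absorption_params")
}

#' @export
print.absorption_params <- function(x, ...) {
  cat("Absorption submodel:", x$route,
      if (x$route == "IV") "(bolus, F = 1)" else
        sprintf("(Ka = %g 1/h, F = %g)", x$Ka, x$F), "\n")
  invisible(x)
}

#' Recognised administration routes
#'
#' @return Character vector of the five route labels: IV plus the four oral
#'   submodels.
#' @export
pk_routes <- function() {
  c("IV", "FEED_TLS", "FEED_OTHERS", "SOL_DW", "SOL_TUBING")
}

#' Body-weight covariate effect (allometric power model)
#'
#' A power model scales a typical parameter value from the reference body
#' weight (50 kg, close to the population median) to an arbitrary body
#' weight: `theta_pop * (bw / ref_bw)^theta_BW`.
#'
#' @param parameter_name name of the disposition parameter being scaled.
#' @param theta_pop typical value at the reference body weight.
#' @param theta_BW dimensionless power exponent.
#' @param ref_bw reference body weight in kg (default 50).
#' @return An object of class `"covariate_effect"`.
#' @seealso [scale_by_bw()]
#' @export
covariate_effect <- function(parameter_name, theta_pop, theta_BW, ref_bw = 50) {
  if (!is.finite(ref_bw) || ref_bw <= 0) stop("ref_bw must be positive")
  if (!is.finite(theta_pop) || theta_pop <= 0) stop("theta_pop must be positive")
  structure(list(parameter_name = parameter_name, theta_pop = theta_pop,
                 theta_BW = theta_BW, ref_bw = ref_bw),
            class = "covariate_effect")
}

#' Scale a typical parameter value by body weight
#'
#' Evaluates the allometric power model `theta_pop * (bw/ref_bw)^theta_BW`.
#' At `bw = ref_bw` the typical value is returned exactly.
#'
#' @param effect a [covariate_effect()] object.
#' @param bw body weight(s) in kg, strictly positive.
#' @return Scaled parameter value(s), same length as `bw`.
#' @examples
#' eff <- covariate_effect("Cl", theta_pop = 0.259, theta_BW = 0.299)
#' scale_by_bw(eff, 100) # clearance of a typical 100-kg pig
#' @export
scale_by_bw <- function(effect, bw) {
  stopifnot(inherits(effect, "covariate_effect"))
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("bw must be strictly positive")
  effect$theta_pop * (bw / effect$ref_bw)^effect$theta_BW
}

#' Micro rate constants of the three-compartment model
#'
#' @param disp a [disposition_params()] object.
#' @return Named vector `k10, k12, k21, k13, k31` (1/h).
#' @export
micro_constants <- function(disp) {
  stopifnot(inherits(disp, "disposition_params"))
  c(k10 = disp$Cl  / disp$Vc,
    k12 = disp$Cl2 / disp$Vc,
    k21 = disp$Cl2 / disp$V2,
    k13 = disp$Cl3 / disp$Vc,
    k31 = disp$Cl3 / disp$V3)
}

# 3x3 first-order rate matrix of the disposition system (amounts per kg).
# Accepts any list with the six named components (no class check: this sits
# on the estimation hot path).
disposition_matrix <- function(disp) {
  k10 <- disp$Cl / disp$Vc; k12 <- disp$Cl2 / disp$Vc; k21 <- disp$Cl2 / disp$V2
  k13 <- disp$Cl3 / disp$Vc; k31 <- disp$Cl3 / disp$V3
  matrix(c(-(k10 + k12 + k13), k21, k31,
           k12, -k21, 0,
           k13, 0, -k31),
         nrow = 3, byrow = TRUE)
}

#' Disposition eigenvalues
#'
#' The three eigenvalues of the disposition rate matrix.  For a mammillary
#' model with positive micro-constants they are real, negative and distinct;
#' the smallest-magnitude one governs the terminal phase.
#'
#' @param disp a [disposition_params()] object.
#' @return Numeric vector of the three eigenvalues, sorted by increasing
#'   magnitude.
#' @export
disposition_eigenvalues <- function(disp) {
  ev <- eigen(disposition_matrix(disp), only.values = TRUE)$values
  ev <- sort(Re(ev), decreasing = TRUE) # closest to zero first
  ev
}

#' Secondary (derived) pharmacokinetic parameters
#'
#' Computes the terminal half-life (from the smallest-magnitude disposition
#' eigenvalue), steady-state volume `Vss = Vc + V2 + V3`, mean residence time
#' `MRT_iv = Vss / Cl`, mean absorption time `MAT = 1/Ka` (oral routes only)
#' and the steady-state daily AUC `F * daily_dose / Cl`.
#'
#' @param disp a [disposition_params()] object.
#' @param absorption optional [absorption_params()] object; when omitted or IV, MAT
#'   is `NA` and `F = 1` is used for the AUC.
#' @param daily_dose daily dose in mg/kg used for `AUC_ss_24h` (default 20).
#' @return Named list with `terminal_half_life` (h), `Vss` (L/kg), `MRT_iv`
#'   (h), `MAT` (h), `AUC_ss_24h` (ug.h/mL per day).
#' @examples
#' d100 <- disposition_params(0.320, 1.010, 0.050, 0.192, 0.595, 0.699)
#' derived_params(d100)$terminal_half_life # about 11.5 h
#' @export
derived_params <- function(disp, absorption = NULL, daily_dose = 20) {
  stopifnot(inherits(disp, "disposition_params"))
  lambda1 <- disposition_eigenvalues(disp)[1]
  Vss <- disp$Vc + disp$V2 + disp$V3
  F <- 1
  MAT <- NA_real_
  if (!is.null(absorption) && inherits(absorption, "absorption_params") && absorption$route != "IV") {
    F <- absorption$F
    MAT <- 1 / absorption$Ka
  }
  list(terminal_half_life = log(2) / abs(lambda1),
       Vss = Vss,
       MRT_iv = Vss / disp$Cl,
       MAT = MAT,
       AUC_ss_24h = F * daily_dose / disp$Cl)
}

#' Salt-to-base conversion factors for doxycycline
#'
#' Doses in this package are always doxycycline base in mg/kg.  This helper
#' returns the mass fraction of base in the common salt forms (base MW 444.4;
#' hyclate 1025.9 carries two base molecules; monohydrate 462; hydrochloride
#' 480.9 g/mol), so `dose_base = dose_salt * doxy_base_fraction(salt)`.
#'
#' @param salt one of `"base"`, `"hyclate"`, `"monohydrate"`,
#'   `"hydrochloride"`.
#' @return Scalar mass fraction of doxycycline base.
#' @export
doxy_base_fraction <- function(salt = c("base", "hyclate", "monohydrate",
                                        "hydrochloride")) {
  salt <- match.arg(salt)
  mw_base <- 444.4
  switch(salt,
         base = 1,
         hyclate = 2 * mw_base / 1025.9,
         monohydrate = mw_base / 462,
         hydrochloride = mw_base / 480.9)
}
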