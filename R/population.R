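#' Combined additive and proportional residual error model
#'
#' Observed concentration = true + e with
#' `e ~ N(0, stdev0^2 + (cmult * true)^2)`: `stdev0` is the additive standard
#' deviation (ug/mL) and `cmult` the proportional standard deviation (a
#' fraction, readable as a CV).
#'
#' @param stdev0 additive SD, ug/mL, >= 0.
#' @param cmult proportional SD fraction, >= 0.
#' @return List of class `"residual_model"`.
#' @export
residual_model <- function(stdev0, cmult) {
  if (stdev0 < 0 || cmult < 0) stop("residual SDs must be >= 0")
  if (stdev0 == 0 && cmult == 0) stop("residual model must have some error")
  structure(list(stdev0 = stdev0, cmult = cmult), class = "residual_model")
}

#' Convert a between-subject variability CV% to a log-scale SD
#'
#' Between-subject variability is modelled exponentially
#' (`parameter_i = typical * exp(eta_i)`, `eta ~ N(0, omega^2)`) and reported
#' as a coefficient of variation.  The default convention is the lognormal
#' one, `CV% = 100 * sqrt(exp(omega^2) - 1)`, i.e.
#' `omega = sqrt(log(1 + (CV/100)^2))`; the alternative reading
#' `omega = CV/100` is available via `convention = "direct"`.
#'
#' @param bsv_percent CV%, >= 0.
#' @param convention `"lognormal"` (default) or `"direct"`.
#' @return omega, the SD of the log-scale random effect.
#' @seealso [omega_to_bsv_percent()] for the inverse.
#' @examples
#' bsv_percent_to_omega(84.8)  # 0.7361
#' @export
bsv_percent_to_omega <- function(bsv_percent, convention = c("lognormal", "direct")) {
  convention <- match.arg(convention)
  if (any(bsv_percent < 0)) stop("bsv_percent must be >= 0")
  if (convention == "lognormal") sqrt(log1p((bsv_percent / 100)^2))
  else bsv_percent / 100
}

#' Inverse of [bsv_percent_to_omega()]
#'
#' @param omega log-scale SD, >= 0.
#' @inheritParams bsv_percent_to_omega
#' @return BSV as CV%.
#' @export
omega_to_bsv_percent <- function(omega, convention = c("lognormal", "direct")) {
  convention <- match.arg(convention)
  if (any(omega < 0)) stop("omega must be >= 0")
  if (convention == "lognormal") 100 * sqrt(expm1(omega^2))
  else 100 * omega
}

#' Population pharmacokinetic model
#'
#' The generative object of the package: typical disposition parameters at
#' the 50-kg reference body weight, allometric body-weight exponents on a
#' subset of them, route-specific absorption submodels, a diagonal
#' between-subject variability matrix on the log scale, and per-route
#' residual error models.
#'
#' @param disposition a [disposition_params()] object (typical values at
#'   `ref_bw`).
#' @param covariates named numeric vector of power exponents; names must be
#'   disposition parameter names (e.g. `c(Cl = 0.299, V3 = 0.376)`).
#' @param absorption named list of [absorption_params()] objects, one per
#'   oral submodel present.
#' @param omega named numeric vector of log-scale BSV standard deviations;
#'   names among the six disposition parameters and `Ka_<route>`/`F_<route>`.
#'   Missing entries are taken as 0 (no variability).
#' @param residual named list of [residual_model()] objects keyed by route
#'   (must include every route that will be simulated with noise).
#' @param ref_bw reference body weight, kg (default 50).
#' @param cap_F_at_1 if `TRUE`, realised individual bioavailabilities are
#'   truncated at 1; default `FALSE` (no truncation).
#' @return Object of class `"pop_model"`.
#' @seealso [doxy_final_model()] for the published final model,
#'   [draw_population()] to realise individuals.
#' @export
pop_model <- function(disposition, covariates = numeric(), absorption = list(),
                      omega = numeric(), residual = list(), ref_bw = 50,
                      cap_F_at_1 = FALSE) {
  stopifnot(inherits(disposition, "disposition_params"))
  if (length(covariates) &&
      !all(names(covariates) %in% names(disposition)))
    stop("covariate names must be disposition parameter names")
  for (a in absorption) stopifnot(inherits(a, "absorption_params"))
  if (length(omega) && (is.null(names(omega)) || any(omega < 0)))
    stop("omega must be a named non-negative vector")
  structure(list(disposition = disposition, covariates = covariates,
                 absorption = absorption, omega = omega, residual = residual,
                 ref_bw = ref_bw, cap_F_at_1 = cap_F_at_1),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK model (3-compartment, ref BW", x$ref_bw, "kg)\n")
  cat("Typical disposition:\n"); print(unlist(x$disposition))
  if (length(x$covariates)) {
    cat("BW power exponents:\n"); print(x$covariates)
  }
  if (length(x$absorption)) {
    cat("Oral submodels:\n")
    for (a in x$absorption)
      cat(sprintf("  %-12s Ka = %.3f 1/h, F = %.3f\n", a$route, a$Ka, a$F))
  }
  if (length(x$omega)) {
    cat("BSV (CV%, lognormal convention):\n")
    print(round(omega_to_bsv_percent(x$omega), 1))
  }
  invisible(x)
}

#' Typical (covariate-scaled) parameters for a body weight
#'
#' Applies the body-weight power model to each disposition parameter that
#' carries an exponent and returns the typical individual at that weight.
#'
#' @param model a [pop_model()].
#' @param bw body weight, kg.
#' @return A [disposition_params()] object scaled to `bw`.
#' @export
typical_disposition <- function(model, bw) {
  stopifnot(inherits(model, "pop_model"))
  p <- unlist(model$disposition)
  for (nm in names(model$covariates))
    p[nm] <- p[nm] * (bw / model$ref_bw)^model$covariates[nm]
  do.call(disposition_params, as.list(p))
}

#' Draw individual parameter realisations from a population model
#'
#' Random effects are independent normal on the log scale
#' (`parameter_i = typical(bw_i) * exp(eta_i)`), drawn per parameter with the
#' model's diagonal omega.  With all omegas zero every individual equals the
#' covariate-scaled typical animal.  Draws are reproducible given `seed`.
#'
#' @param model a [pop_model()].
#' @param n number of individuals.
#' @param bw a scalar body weight (kg), a vector of length `n`, or a function
#'   `function(n)` sampling weights.
#' @param route route label; for oral routes the corresponding `Ka`/`F`
#'   submodel (and its BSV) is realised as well.
#' @param seed integer seed (required for reproducibility).
#' @return Data frame of class `"pk_population"`: columns `id`, `bw`,
#'   `route`, the six realised disposition parameters, `Ka`, `F`, plus the
#'   drawn `eta.*` columns as an attribute `"eta"`.
#' @examples
#' m <- doxy_final_model()
#' pop <- draw_population(m, 100, bw = 10, route = "FEED_TLS", seed = 1)
#' summary(pop$Cl)
#' @export
draw_population <- function(model, n, bw, route = "IV", seed = NULL) {
  stopifnot(inherits(model, "pop_model"), n >= 1)
  route <- match.arg(route, pk_routes())
  if (route != "IV" && is.null(model$absorption[[route]]))
    stop("route ", route, " not present in the population model")
  if (!is.null(seed)) set.seed(seed)

  bw_i <- if (is.function(bw)) bw(n) else rep_len(bw, n)
  if (any(bw_i <= 0)) stop("body weights must be positive")

  disp_names <- names(model$disposition)
  par_names <- disp_names
  if (route != "IV")
    par_names <- c(par_names, paste0("Ka_", route), paste0("F_", route))

  om <- setNames(numeric(length(par_names)), par_names)
  hit <- intersect(names(model$omega), par_names)
  om[hit] <- model$omega[hit]
  eta <- matrix(rnorm(n * length(par_names)), n) %*% diag(om, length(om))
  colnames(eta) <- par_names

  # covariate-scaled typical values per individual
  typ <- sapply(disp_names, function(nm) {
    v <- rep(model$disposition[[nm]], n)
    if (nm %in% names(model$covariates))
      v <- v * (bw_i / model$ref_bw)^model$covariates[nm]
    v
  })
  if (n == 1) typ <- matrix(typ, nrow = 1, dimnames = list(NULL, disp_names))
  real <- typ * exp(eta[, disp_names, drop = FALSE])

  out <- data.frame(id = seq_len(n), bw = bw_i, route = route, real)
  if (route != "IV") {
    a <- model$absorption[[route]]
    out$Ka <- a$Ka * exp(eta[, paste0("Ka_", route)])
    Fi <- a$F * exp(eta[, paste0("F_", route)])
    if (isTRUE(model$cap_F_at_1)) Fi <- pmin(Fi, 1)
    out$F <- Fi
  } else {
    out$Ka <- NA_real_
    out$F <- 1
  }
  attr(out, "eta") <- eta
  class(out) <- c("pk_population", class(out))
  out
}

#' Add residual error to noise-free concentrations
#'
#' @param true_conc vector of model-predicted concentrations (ug/mL), >= 0.
#' @param residual a [residual_model()].
#' @param seed optional integer seed.
#' @return Observed concentrations; may be negative (LLOQ censoring is the
#'   downstream consumer's job).
#' @export
apply_residual_error <- function(true_conc, residual, seed = NULL) {
  stopifnot(inherits(residual, "residual_model"))
  if (any(true_conc < 0)) stop("true concentrations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sdv <- sqrt(residual$stdev0^2 + (residual$cmult * true_conc)^2)
  true_conc + rnorm(length(true_conc), 0, sdv)
}

#' The published final population model for doxycycline in pigs
#'
#' Loads the packaged fixture holding the final meta-analysis model: typical
#' disposition at 50 kg (Cl 0.259, Cl2 1.179, Cl3 0.072 L/kg/h; Vc 0.192,
#' V2 0.595, V3 0.536 L/kg), body-weight exponents on Cl (0.299),
#' Cl2 (-0.224), Cl3 (-0.544) and V3 (0.376), the four oral submodels
#' (in-feed field: Ka 0.072/h, F 0.501; in-feed laboratory: Ka 0.144/h,
#' F 0.340; drinking water: Ka 0.689/h, F 0.307; stomach tube: Ka 0.725/h,
#' F 0.258), the reported BSV CV percentages, and per-route residual models.
#'
#' @param convention BSV-to-omega convention passed to
#'   [bsv_percent_to_omega()].
#' @param cap_F_at_1 passed through to [pop_model()].
#' @return A [pop_model()].
#' @export
doxy_final_model <- function(convention = c("lognormal", "direct"),
                             cap_F_at_1 = FALSE) {
  convention <- match.arg(convention)
  path <- system.file("extdata", "doxy_final_model.yaml", package = "doxypk",
                      mustWork = TRUE)
  read_pop_model(path, convention = convention, cap_F_at_1 = cap_F_at_1)
}

#' Read a population model from a YAML configuration
#'
#' The file holds the typical disposition parameters, covariate exponents,
#' absorption submodels, between-subject variability (either as `omega`
#' log-scale SDs or as `bsv_percent` CV percentages) and per-route residual
#' models.  See the packaged `doxy_final_model.yaml` for the layout.
#'
#' @param path YAML file path.
#' @inheritParams doxy_final_model
#' @return A [pop_model()].
#' @export
read_pop_model <- function(path, convention = c("lognormal", "direct"),
                           cap_F_at_1 = FALSE) {
  convention <- match.arg(convention)
  cfg <- yaml::read_yaml(path)
  disp <- do.call(disposition_params, cfg$disposition)
  covs <- unlist(cfg$covariates)
  absn <- lapply(names(cfg$absorption), function(r)
    absorption_params(r, Ka = cfg$absorption[[r]]$Ka, F = cfg$absorption[[r]]$F))
  names(absn) <- names(cfg$absorption)
  omega <- if (!is.null(cfg$omega)) unlist(cfg$omega)
           else bsv_percent_to_omega(unlist(cfg$bsv_percent), convention)
  resid <- lapply(cfg$residual, function(r) residual_model(r$stdev0, r$cmult))
  ref_bw <- if (is.null(cfg$ref_bw)) 50 else cfg$ref_bw
  pop_model(disp, covariates = covs, absorption = absn, omega = omega,
            residual = resid, ref_bw = ref_bw, cap_F_at_1 = cap_F_at_1)
}

#' Write a population model to a YAML configuration
#'
#' Omega is written as log-scale SDs so a write/read round trip is exact.
#'
#' @param model a [pop_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pop_model <- function(model, path) {
  stopifnot(inherits(model, "pop_model"))
  cfg <- list(
    disposition = lapply(unclass(model$disposition), identity),
    covariates = as.list(model$covariates),
    absorption = lapply(model$absorption, function(a)
      list(Ka = a$Ka, F = a$F)),
    omega = as.list(model$omega),
    residual = lapply(model$residual, function(r)
      list(stdev0 = r$stdev0, cmult = r$cmult)),
    ref_bw = model$ref_bw)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}
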