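#' @rdname pkfit
#' @section Objective function:
#' The marginal likelihood of each subject's data is approximated by the
#' Laplace method: the joint log-density of observations and random effects
#' is maximised over the subject's random effects (inner optimisation) and
#' corrected by the log-determinant of the curvature at the mode.  The OFV is
#' minus twice the sum of the approximate marginal log-likelihoods.  For a
#' model that is linear in the random effects with Gaussian error the
#' approximation is exact.
#' @name pkfit-objective
NULL

# ---- internal context ------------------------------------------------------

# Split a validated dataset into per-subject design/observation blocks.
.split_subjects <- function(data) {
  data <- validate_pk_dataset(data)
  lapply(split(data, data$id), function(sub) {
    obs <- sub[sub$evid == 0, ]
    dos <- sub[sub$evid == 1, ]
    list(id = sub$id[1], route = sub$route[1], bw = sub$bw[1],
         trial = sub$trial[1],
         times = obs$time, y = obs$conc,
         dose_time = dos$time, dose_amt = dos$amt,
         xcat = if ("health" %in% names(sub)) as.integer(sub$health[1] == "sick") else 0L)
  })
}

# Covariate-scaled disposition list for one subject (no random effects).
.subject_disp <- function(sub, th, covs, eta = list()) {
  disp <- list(Cl = th[["Cl"]], Cl2 = th[["Cl2"]], Cl3 = th[["Cl3"]],
               Vc = th[["Vc"]], V2 = th[["V2"]], V3 = th[["V3"]])
  for (nm in names(covs))
    disp[[nm]] <- disp[[nm]] * (sub$bw / 50)^covs[[nm]]
  for (nm in intersect(names(eta), names(disp)))
    disp[[nm]] <- disp[[nm]] * exp(eta[[nm]])
  disp
}

# Individual absorption parameters (route, Ka, F) for one subject.
.subject_abs <- function(sub, th, eta = list(), cap_F = FALSE) {
  if (sub$route == "IV") return(list(route = "IV", Ka = NA_real_, F = 1))
  ka_nm <- paste0("Ka_", sub$route); f_nm <- paste0("F_", sub$route)
  ka <- th[[ka_nm]]
  Fv <- th[[f_nm]]
  bnm <- paste0("beta_F_", sub$route)
  if (bnm %in% names(th)) Fv <- Fv * exp(th[[bnm]] * sub$xcat)
  if (ka_nm %in% names(eta)) ka <- ka * exp(eta[[ka_nm]])
  if (f_nm %in% names(eta)) Fv <- Fv * exp(eta[[f_nm]])
  if (cap_F) Fv <- min(Fv, 1)
  list(route = sub$route, Ka = ka, F = Fv)
}

# Noise-free prediction for one subject given full parameter set and etas.
.subject_pred <- function(sub, th, covs, eta, ref_bw = 50, cap_F = FALSE) {
  disp <- .subject_disp(sub, th, covs, eta)
  absn <- .subject_abs(sub, th, eta, cap_F)
  sol <- .unit_solution(disp, absn)
  if (is.null(sol)) {
    # essentially never reached for admissible parameters; exact fallback
    return(conc_profile(structure(disp, class = "disposition_params"),
                        structure(absn, class = "absorption_params"),
                        data.frame(time = sub$dose_time, amount = sub$dose_amt),
                        sub$times))
  }
  .profile_eval(sol, sub$dose_time, sub$dose_amt, sub$times)
}

# -2 log joint density of one subject's data and etas (negative joint).
.neg_joint <- function(eta_vec, sub, th, covs, om_i, sd0, cmult, cap_F) {
  eta <- as.list(eta_vec)
  names(eta) <- names(om_i)
  pred <- .subject_pred(sub, th, covs, eta, cap_F = cap_F)
  .neg_joint_ll(sub$y, pred, eta_vec, om_i, sd0, cmult)
}

.neg_joint_ll <- function(y, pred, eta_vec, om_i, sd0, cmult) {
  sdv <- sqrt(sd0^2 + (cmult * pred)^2)
  if (any(!is.finite(sdv)) || any(sdv <= 0)) return(1e10)
  ll <- sum(dnorm(y, pred, sdv, log = TRUE)) +
    sum(dnorm(eta_vec, 0, om_i, log = TRUE))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Laplace-approximate -2 log marginal likelihood for one subject.
# Returns list(ofv, eta) or stops on a non-finite likelihood.  When no
# disposition parameter carries a random effect the eigen-decomposition is
# computed once and reused across the inner iterations.
.subject_ofv <- function(sub, th, covs, omega, cap_F, eta_start = NULL,
                         inner_maxit = 100) {
  rt <- sub$route
  sd0 <- th[[paste0("stdev0_", rt)]]
  cm <- th[[paste0("cmult_", rt)]]
  disp_names <- c("Cl", "Cl2", "Cl3", "Vc", "V2", "V3")
  cand <- c(disp_names,
            if (rt != "IV") c(paste0("Ka_", rt), paste0("F_", rt)))
  om_i <- omega[intersect(names(omega)[omega > 0], cand)]
  d <- length(om_i)

  fast <- !any(names(om_i) %in% disp_names) && rt != "IV"
  if (fast) {
    dsol <- .disp_solution(.subject_disp(sub, th, covs))
    fast <- !is.null(dsol)
  }
  negj <- if (fast) {
    ka_nm <- paste0("Ka_", rt); f_nm <- paste0("F_", rt)
    ka0 <- th[[ka_nm]]
    F0 <- th[[f_nm]]
    bnm <- paste0("beta_F_", rt)
    if (bnm %in% names(th)) F0 <- F0 * exp(th[[bnm]] * sub$xcat)
    function(eta_vec) {
      eta <- setNames(as.list(eta_vec), names(om_i))
      ka <- if (ka_nm %in% names(om_i)) ka0 * exp(eta[[ka_nm]]) else ka0
      Fv <- if (f_nm %in% names(om_i)) F0 * exp(eta[[f_nm]]) else F0
      if (cap_F) Fv <- min(Fv, 1)
      sol <- .oral_weights(dsol, ka, Fv)
      pred <- .profile_eval(sol, sub$dose_time, sub$dose_amt, sub$times)
      .neg_joint_ll(sub$y, pred, eta_vec, om_i, sd0, cm)
    }
  } else {
    function(eta_vec) .neg_joint(eta_vec, sub, th, covs, om_i, sd0, cm, cap_F)
  }

  if (d == 0L) {
    nll <- negj(numeric(0))
    if (nll >= 1e10) stop("non-finite likelihood for subject ", sub$id)
    return(list(ofv = 2 * nll, eta = numeric(0)))
  }
  start <- if (!is.null(eta_start) && length(eta_start) == d) eta_start
           else numeric(d)
  opt <- nlminb(start, negj, control = list(iter.max = inner_maxit))
  H <- optimHess(opt$par, negj,
                 control = list(ndeps = rep(1e-5, d)))
  ld <- determinant(H, logarithm = TRUE)
  if (ld$sign <= 0) {
    # fall back to the prior curvature if the numerical Hessian degenerates
    ldet <- sum(log(1 / om_i^2))
  } else ldet <- as.numeric(ld$modulus)
  ofv <- 2 * opt$objective - d * log(2 * pi) + ldet
  if (!is.finite(ofv) || opt$objective >= 1e10)
    stop("non-finite likelihood for subject ", sub$id)
  list(ofv = ofv, eta = setNames(opt$par, names(om_i)))
}

# Total OFV over subjects with warm-started etas kept in `cache` (an env).
.total_ofv <- function(subjects, th, covs, omega, cap_F, cache = NULL,
                       inner_maxit = 100) {
  tot <- 0
  for (j in seq_along(subjects)) {
    st <- if (!is.null(cache)) cache$eta[[j]] else NULL
    r <- .subject_ofv(subjects[[j]], th, covs, omega, cap_F, eta_start = st,
                      inner_maxit = inner_maxit)
    if (!is.null(cache)) cache$eta[[j]] <- r$eta
    tot <- tot + r$ofv
  }
  tot
}

# ---- exported objective ----------------------------------------------------

#' Approximate marginal -2 log-likelihood of a population model
#'
#' Evaluates the Laplace-type objective function value (OFV) of a population
#' model on a long-format dataset: per subject, the joint density of the
#' observations and the log-scale random effects is maximised over the
#' random effects and the Gaussian curvature correction applied; the OFV is
#' minus twice the summed approximate marginal log-likelihood.  With all
#' omegas zero this reduces to the pooled fixed-effect extended
#' least-squares -2 log-likelihood.
#'
#' @param data validated long-format dataset.
#' @param model a [pop_model()] whose parameters (thetas), omegas and
#'   residual models are to be evaluated; every route in `data` must carry a
#'   residual model.
#' @return The OFV (scalar).
#' @examples
#' m <- doxy_final_model()
#' d <- generate_trials(m, default_trial_designs()[3], seed = 1)
#' marginal_ofv(d, m)
#' @export
marginal_ofv <- function(data, model) {
  stopifnot(inherits(model, "pop_model"))
  subjects <- .split_subjects(data)
  th <- unlist(model$disposition)
  for (r in names(model$absorption)) {
    th[paste0("Ka_", r)] <- model$absorption[[r]]$Ka
    th[paste0("F_", r)] <- model$absorption[[r]]$F
  }
  for (r in names(model$residual)) {
    th[paste0("stdev0_", r)] <- model$residual[[r]]$stdev0
    th[paste0("cmult_", r)] <- model$residual[[r]]$cmult
  }
  for (s in subjects)
    if (!paste0("stdev0_", s$route) %in% names(th))
      stop("no residual model for route ", s$route)
  .total_ofv(subjects, as.list(th), as.list(model$covariates), model$omega,
             isTRUE(model$cap_F_at_1))
}

# ---- the fitting function --------------------------------------------------

#' Fit the population pharmacokinetic model
#'
#' Hierarchical (nonlinear mixed-effects) estimation of the three-compartment
#' population model by minimising the Laplace-type approximate marginal
#' -2 log-likelihood over the free parameters.  Structural parameters,
#' absorption parameters, residual SDs and omegas are estimated on the log
#' scale (bound-constrained); covariate exponents on the natural scale.
#'
#' Three stages replicate the meta-analysis workflow:
#' \describe{
#'   \item{`iv_only`}{fits the six disposition parameters (and optionally
#'     body-weight exponents) to IV data.}
#'   \item{`oral_given_iv`}{freezes disposition and exponents at the values
#'     of a previous IV fit (`ivfit`) and estimates only the `Ka`/`F` of the
#'     oral submodels present in the data, the per-route residual terms and
#'     the requested omegas.}
#'   \item{`joint`}{everything free.}
#' }
#'
#' @param data long-format dataset (see [validate_pk_dataset()]); rows whose
#'   route does not belong to the stage are dropped with a message.
#' @param stage one of `"iv_only"`, `"oral_given_iv"`, `"joint"`.
#' @param random character vector naming the parameters that carry
#'   between-subject variability (disposition names and/or
#'   `Ka_<route>`/`F_<route>`).  Default: `c("Cl", "Vc", "V2")` for IV data
#'   plus `F_<route>` for each oral route present.
#' @param covariates named numeric vector of body-weight power exponents:
#'   `NA` entries are estimated (initialised at 0), non-`NA` entries are
#'   fixed.  `NULL` means no covariate.
#' @param ivfit a previous `"pkfit"` object (stage `iv_only`), or a named
#'   vector of disposition thetas/exponents (`Cl`, ..., `covBW_Cl`, ...);
#'   required for `stage = "oral_given_iv"`, whose disposition parameters are
#'   frozen at these values.
#' @param inits named numeric vector overriding default initial values
#'   (defaults are NCA-derived for clearance and volumes).
#' @param fix named numeric vector of thetas to hold fixed.
#' @param cat_on_F optional name of a 0/1 subject covariate column (e.g.
#'   `"health"`, coded sick = 1) entering bioavailability exponentially:
#'   `F * exp(beta * x)`; `beta` is then estimated.
#' @param control list: `maxit` (outer iterations, default 200), `factr`
#'   (L-BFGS-B relative tolerance factor, default 1e9), `ndeps`
#'   (finite-difference step of the outer gradient, default 1e-3),
#'   `inner_maxit` (default 100), `trace` (default 0).
#' @return Object of class `"pkfit"` with components `theta`, `omega`,
#'   `ofv`, `aic`, `n_par`, `ebe` (empirical Bayes etas), `convergence`,
#'   `stage`, `random`, `covariates`, `data`, and `model` (the fitted
#'   [pop_model()]).  Supported methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `residuals`, `simulate`, `plot`.
#' @seealso [marginal_ofv()], [covariate_search()], [bootstrap_ci()],
#'   [shrinkage()], [vpc_check()]
#' @export
pkfit <- function(data, stage = c("iv_only", "oral_given_iv", "joint"),
                  random = NULL, covariates = NULL, ivfit = NULL,
                  inits = NULL, fix = NULL, cat_on_F = NULL,
                  control = list()) {
  stage <- match.arg(stage)
  ctl <- modifyList(list(maxit = 200, factr = 1e9, ndeps = 1e-3,
                         inner_maxit = 100, trace = 0), control)
  data <- validate_pk_dataset(data)

  if (stage == "iv_only") {
    keep <- data$route == "IV"
  } else if (stage == "oral_given_iv") {
    keep <- data$route != "IV"
  } else keep <- rep(TRUE, nrow(data))
  if (!all(keep)) {
    message("dropping ", sum(!keep), " rows outside stage ", stage)
    data <- data[keep, , drop = FALSE]
  }
  if (!nrow(data)) stop("no data left for stage ", stage)
  subjects <- .split_subjects(data)
  routes <- unique(vapply(subjects, `[[`, "", "route"))
  oral_routes <- setdiff(routes, "IV")

  disp_names <- c("Cl", "Cl2", "Cl3", "Vc", "V2", "V3")

  # ---- initial values (NCA-derived where possible) ----
  th <- c(Cl = 0.25, Cl2 = 1, Cl3 = 0.1, Vc = 0.2, V2 = 0.6, V3 = 0.5)
  if ("IV" %in% routes) {
    nca <- tryCatch(suppressWarnings(nca_table(data[data$route == "IV", ])),
                    error = function(e) NULL)
    if (!is.null(nca) && any(is.finite(nca$Cl_over_F))) {
      cl0 <- median(nca$Cl_over_F, na.rm = TRUE) / 1000
      vss0 <- median(nca$Vss, na.rm = TRUE) / 1000
      if (is.finite(cl0) && cl0 > 0) th["Cl"] <- cl0
      if (is.finite(vss0) && vss0 > 0) {
        th["Vc"] <- 0.2 * vss0; th["V2"] <- 0.45 * vss0; th["V3"] <- 0.35 * vss0
      }
      th["Cl2"] <- 4 * th["Cl"]; th["Cl3"] <- 0.3 * th["Cl"]
    }
  }
  for (r in oral_routes) {
    th[paste0("Ka_", r)] <- if (grepl("^FEED", r)) 0.1 else 0.5
    th[paste0("F_", r)] <- 0.4
  }
  for (r in routes) {
    th[paste0("stdev0_", r)] <- 0.02
    th[paste0("cmult_", r)] <- 0.2
  }

  # covariate exponents
  cov_fixed <- numeric(0); cov_est <- character(0)
  if (!is.null(covariates)) {
    if (is.null(names(covariates)) ||
        !all(names(covariates) %in% disp_names))
      stop("covariates must be named after disposition parameters")
    cov_est <- names(covariates)[is.na(covariates)]
    cov_fixed <- covariates[!is.na(covariates)]
    bws <- vapply(subjects, `[[`, 0, "bw")
    if (length(cov_est) && length(unique(round(bws, 6))) < 2)
      stop("body weight is constant across subjects; exponents are unidentifiable")
  }
  if (length(cov_est)) th[paste0("covBW_", cov_est)] <- 0
  if (length(cov_fixed)) th[paste0("covBW_", names(cov_fixed))] <- cov_fixed

  if (!is.null(cat_on_F)) {
    if (!cat_on_F %in% names(data)) stop("column ", cat_on_F, " not in data")
    for (r in oral_routes) th[paste0("beta_F_", r)] <- 0
  }

  # ---- default random effects ----
  if (is.null(random)) {
    random <- if (length(oral_routes) && stage == "oral_given_iv")
      c("Cl", paste0("F_", oral_routes))
    else c("Cl", "Vc", "V2", if (length(oral_routes)) paste0("F_", oral_routes))
  }
  omega <- setNames(rep(0.3, length(random)), random)

  # ---- freezing / fixing ----
  frozen <- character(0)
  if (stage == "oral_given_iv") {
    if (inherits(ivfit, "pkfit")) base_th <- ivfit$theta
    else if (is.numeric(ivfit) && !is.null(names(ivfit))) base_th <- ivfit
    else stop("stage 'oral_given_iv' requires the IV-stage 'pkfit' (or a ",
              "named vector of its thetas) in ivfit")
    for (nm in intersect(names(base_th),
                         c(disp_names, paste0("covBW_", disp_names))))
      th[nm] <- base_th[nm]
    frozen <- intersect(names(th), c(disp_names, paste0("covBW_", disp_names)))
  }
  if (!is.null(inits)) th[names(inits)] <- inits
  if (!is.null(fix)) {
    th[names(fix)] <- fix
    frozen <- union(frozen, names(fix))
  }

  free_th <- setdiff(names(th), frozen)
  # exponents for fixed covariate values are never free
  free_th <- setdiff(free_th, paste0("covBW_", names(cov_fixed)))

  # transforms: exponents and categorical betas on identity, rest on log
  id_scale <- function(nm) grepl("^covBW_|^beta_F_", nm)
  pack <- function(th, omega) {
    v <- c(
      vapply(free_th, function(nm)
        if (id_scale(nm)) th[[nm]] else log(th[[nm]]), 0),
      log(omega))
    names(v) <- c(free_th,
                  if (length(omega)) paste0("omega_", names(omega)))
    v
  }
  unpack <- function(v) {
    th2 <- th
    for (nm in free_th)
      th2[nm] <- if (id_scale(nm)) v[[nm]] else exp(v[[nm]])
    om2 <- exp(v[grep("^omega_", names(v))])
    names(om2) <- sub("^omega_", "", names(om2))
    list(th = th2, omega = om2)
  }

  cov_names <- union(cov_est, names(cov_fixed))
  covs_all <- if (length(cov_names))
    setNames(as.list(th[paste0("covBW_", cov_names)]), cov_names)
  else list()

  cache <- new.env(parent = emptyenv())
  cache$eta <- vector("list", length(subjects))
  n_eval <- 0L
  objective <- function(v) {
    p <- unpack(v)
    covs <- if (length(covs_all))
      setNames(as.list(p$th[paste0("covBW_", names(covs_all))]),
               names(covs_all))
    else list()
    n_eval <<- n_eval + 1L
    val <- tryCatch(
      .total_ofv(subjects, as.list(p$th), covs, p$omega, FALSE,
                 cache = cache, inner_maxit = ctl$inner_maxit),
      error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    if (ctl$trace > 0 && n_eval %% ctl$trace == 0)
      cat("eval", n_eval, "OFV", round(val, 3), "\n")
    val
  }

  v0 <- pack(th, omega)
  lower <- ifelse(grepl("^covBW_|^beta_F_", names(v0)), -3, v0 - log(1e4))
  upper <- ifelse(grepl("^covBW_|^beta_F_", names(v0)), 3, v0 + log(1e3))
  # L-BFGS-B with coarse finite-difference steps: the inner (Laplace)
  # optimisation leaves numerical noise on the objective, so gradient steps
  # must stay well above it
  opt <- optim(v0, objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = ctl$maxit, factr = ctl$factr,
                              ndeps = rep(ctl$ndeps, length(v0))))
  opt$objective <- opt$value

  p <- unpack(opt$par)
  covs_hat <- if (length(covs_all))
    setNames(vapply(names(covs_all), function(nm)
      p$th[[paste0("covBW_", nm)]], 0), names(covs_all))
  else numeric(0)

  # final pass to refresh EBEs at the optimum
  ofv <- .total_ofv(subjects, as.list(p$th), as.list(covs_hat), p$omega,
                    FALSE, cache = cache, inner_maxit = ctl$inner_maxit)
  ebe <- cache$eta
  names(ebe) <- vapply(subjects, `[[`, "", "id")

  n_par <- length(opt$par)
  absn <- lapply(oral_routes, function(r)
    absorption_params(r, Ka = p$th[[paste0("Ka_", r)]],
                      F = p$th[[paste0("F_", r)]]))
  names(absn) <- oral_routes
  resid <- lapply(routes, function(r)
    residual_model(p$th[[paste0("stdev0_", r)]], p$th[[paste0("cmult_", r)]]))
  names(resid) <- routes
  model <- pop_model(
    do.call(disposition_params, as.list(p$th[disp_names])),
    covariates = covs_hat, absorption = absn,
    omega = p$omega, residual = resid)

  structure(list(theta = p$th, omega = p$omega, covariates = covs_hat,
                 ofv = ofv, aic = ofv + 2 * n_par, n_par = n_par,
                 ebe = ebe, stage = stage, random = random,
                 convergence = opt$convergence == 0,
                 message = if (is.null(opt$message)) "" else opt$message,
                 n_eval = n_eval,
                 data = data, subjects = subjects, model = model),
            class = "pkfit")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK fit (Laplace), stage:", x$stage, "\n")
  cat(sprintf("  %d subjects, OFV = %.3f, AIC = %.3f (%d parameters)\n",
              length(x$subjects), x$ofv, x$aic, x$n_par))
  if (!x$convergence) cat("  WARNING: optimizer did not report convergence:",
                          x$message, "\n")
  cat("Thetas:\n")
  print(signif(x$theta, 4))
  if (length(x$omega)) {
    cat("BSV (CV%):\n")
    print(round(omega_to_bsv_percent(x$omega), 1))
  }
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) {
  c(object$theta, setNames(object$omega, paste0("omega_", names(object$omega))))
}

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$n_par, class = "logLik")
}

#' @export
summary.pkfit <- function(object, ...) {
  sh <- shrinkage(object)
  out <- list(fit = object, shrinkage = sh,
              bsv_percent = omega_to_bsv_percent(object$omega))
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, ...) {
  print(x$fit)
  cat("Eta shrinkage (%):\n"); print(round(x$shrinkage$eta, 1))
  cat(sprintf("Epsilon shrinkage: %.1f%%\n", x$shrinkage$epsilon))
  invisible(x)
}

#' Predictions from a fitted population model
#'
#' @param object a `"pkfit"`.
#' @param newdata optional dataset (defaults to the fitted data).
#' @param type `"individual"` (empirical-Bayes etas, IPRED; only for the
#'   fitted data) or `"population"` (etas zero, PRED).
#' @param ... unused.
#' @return Data frame `id, route, time, observed, predicted`.
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("individual", "population"), ...) {
  type <- match.arg(type)
  subjects <- if (is.null(newdata)) object$subjects
              else .split_subjects(newdata)
  covs <- as.list(object$covariates)
  th <- as.list(object$theta)
  rows <- lapply(seq_along(subjects), function(j) {
    sub <- subjects[[j]]
    eta <- if (type == "individual" && is.null(newdata))
      as.list(object$ebe[[sub$id]]) else list()
    data.frame(id = sub$id, route = sub$route, time = sub$times,
               observed = sub$y,
               predicted = .subject_pred(sub, th, covs, eta))
  })
  do.call(rbind, rows)
}

#' Residuals of a population fit
#'
#' Individual weighted residuals `IWRES = (y - IPRED) / sd(IPRED)` with the
#' fitted combined error model, or population residuals on request.
#'
#' @param object a `"pkfit"`.
#' @param type `"iwres"` (default) or `"pwres"` (population, unweighted by
#'   etas).
#' @param ... unused.
#' @return Data frame `id, route, time, residual`.
#' @export
residuals.pkfit <- function(object, type = c("iwres", "pwres"), ...) {
  type <- match.arg(type)
  pr <- predict(object,
                type = if (type == "iwres") "individual" else "population")
  sd0 <- object$theta[paste0("stdev0_", pr$route)]
  cm <- object$theta[paste0("cmult_", pr$route)]
  sdv <- sqrt(sd0^2 + (cm * pr$predicted)^2)
  data.frame(id = pr$id, route = pr$route, time = pr$time,
             residual = (pr$observed - pr$predicted) / sdv)
}

#' Simulate datasets from a fitted model
#'
#' Re-simulates the fitted subjects' designs (same body weights, doses and
#' sampling times) with new random effects and residual errors.
#'
#' @param object a `"pkfit"`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` datasets.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$model
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    rows <- lapply(object$subjects, function(sub) {
      pop <- draw_population(model, 1, bw = sub$bw, route = sub$route,
                             seed = NULL)
      disp <- do.call(disposition_params,
                      as.list(pop[1, c("Cl", "Cl2", "Cl3", "Vc", "V2", "V3")]))
      absn <- if (sub$route == "IV") absorption_params("IV")
              else absorption_params(sub$route, Ka = pop$Ka[1], F = pop$F[1])
      true <- conc_profile(disp, absn,
                           data.frame(time = sub$dose_time, amount = sub$dose_amt),
                           sub$times)
      obs <- apply_residual_error(true, model$residual[[sub$route]])
      rbind(data.frame(id = sub$id, trial = sub$trial, route = sub$route,
                       bw = sub$bw, time = sub$dose_time, evid = 1,
                       amt = sub$dose_amt, conc = NA_real_, lloq = 0.05),
            data.frame(id = sub$id, trial = sub$trial, route = sub$route,
                       bw = sub$bw, time = sub$times, evid = 0,
                       amt = NA_real_, conc = obs, lloq = 0.05))
    })
    out[[k]] <- do.call(rbind, rows)
  }
  out
}

#' Goodness-of-fit plot for a population fit
#'
#' Observed versus population- and individual-predicted concentrations.
#'
#' @param x a `"pkfit"`.
#' @param log logarithmic axes (`"xy"`, default) or `""`.
#' @param ... passed to [plot()].
#' @export
plot.pkfit <- function(x, log = "xy", ...) {
  ind <- predict(x, type = "individual")
  pop <- predict(x, type = "population")
  keep <- ind$observed > 0 & ind$predicted > 0 & pop$predicted > 0
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(pop$predicted[keep], pop$observed[keep], log = log,
       xlab = "PRED (ug/mL)", ylab = "Observed (ug/mL)", main = "DV vs PRED", ...)
  abline(0, 1, col = 2)
  plot(ind$predicted[keep], ind$observed[keep], log = log,
       xlab = "IPRED (ug/mL)", ylab = "Observed (ug/mL)", main = "DV vs IPRED", ...)
  abline(0, 1, col = 2)
  invisible(x)
}
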