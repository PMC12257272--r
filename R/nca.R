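#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes standard model-free exposure metrics with the linear trapezoidal
#' rule.  The terminal slope `lambda_z` is estimated by log-linear least
#' squares over all contiguous terminal windows of at least three points
#' after Cmax, choosing the window with the best adjusted R-squared.
#' Clearance, `Vss` and `Vz` are only meaningful for IV profiles; for oral
#' profiles `Cl_over_F` is apparent clearance.  For IV profiles whose first
#' sample is after the dose, `C0` is back-extrapolated log-linearly from the
#' first two points so the initial area is included.
#'
#' Concentrations below the limit of quantification should be removed before
#' calling (see [censor_lloq()]); zeros and negative values are dropped with
#' a warning.  When no valid terminal regression exists, the
#' `lambda_z`-dependent fields are returned as `NA` ("not computable").
#'
#' @param time sampling times (h), sorted.
#' @param conc concentrations (ug/mL).
#' @param dose administered dose (mg/kg doxycycline base).
#' @param route route label, `"IV"` or one of the oral submodels; only used
#'   to decide whether clearance/volume fields are absolute or apparent.
#' @return An object of class `"nca_result"`: list with `AUClast`, `AUCinf`,
#'   `AUClast_per_dose`, `lambda_z` (1/h), `n_lambda_z`, `terminal_half_life`
#'   (h), `Cl_over_F` (mL/h/kg), `MRT` (h), `Vss` (mL/kg), `Vz` (mL/kg),
#'   `dose`, `route`.
#' @examples
#' t <- seq(0, 48, by = 0.5)
#' run_nca(t, 10 * exp(-0.1 * t), dose = 10, route = "IV")
#' @export
run_nca <- function(time, conc, dose, route = "IV") {
  if (length(time) != length(conc)) stop("time and conc lengths differ")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  keep <- is.finite(conc) & conc > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive/missing concentration(s) dropped before NCA")
    time <- time[keep]; conc <- conc[keep]
  }
  if (length(conc) < 3) stop("need at least 3 positive concentrations")
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")

  # IV bolus: back-extrapolate C0 from the first two points (log-linear if
  # decreasing, else carry the first concentration back) so the 0-to-tfirst
  # area is not dropped
  if (route == "IV" && time[1] > 0) {
    c0 <- if (conc[1] > conc[2]) {
      exp(log(conc[1]) - time[1] * (log(conc[2]) - log(conc[1])) /
            (time[2] - time[1]))
    } else conc[1]
    time <- c(0, time)
    conc <- c(c0, conc)
  }

  auclast <- .trapz(time, conc)
  aumclast <- .trapz(time, time * conc)

  lz <- .lambda_z(time, conc)
  clast <- conc[length(conc)]
  tlast <- time[length(time)]

  if (is.na(lz$lambda_z)) {
    aucinf <- aumcinf <- thalf <- cl <- mrt <- vss <- vz <- NA_real_
  } else {
    lam <- lz$lambda_z
    aucinf <- auclast + clast / lam
    aumcinf <- aumclast + clast * tlast / lam + clast / lam^2
    thalf <- log(2) / lam
    cl <- dose / aucinf * 1000          # mL/h/kg
    mrt <- aumcinf / aucinf
    vss <- cl * mrt                      # mL/kg (IV interpretation)
    vz <- cl / lam                       # mL/kg
  }
  structure(list(AUClast = auclast, AUCinf = aucinf,
                 AUClast_per_dose = auclast / dose,
                 lambda_z = lz$lambda_z, n_lambda_z = lz$n,
                 terminal_half_life = thalf,
                 Cl_over_F = cl, MRT = mrt, Vss = vss, Vz = vz,
                 dose = dose, route = route),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("NCA (linear trapezoidal), route", x$route, ", dose", x$dose, "mg/kg\n")
  v <- unlist(x[c("AUClast", "AUCinf", "AUClast_per_dose", "lambda_z",
                  "terminal_half_life", "Cl_over_F", "MRT", "Vss", "Vz")])
  print(signif(v, 4))
  invisible(x)
}

# linear trapezoid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# terminal slope: best adjusted R^2 over contiguous windows of >= 3 points
# ending at the last observation, excluding Cmax and earlier points.
.lambda_z <- function(time, conc) {
  n <- length(conc)
  imax <- which.max(conc)
  first <- imax + 1L
  best <- list(lambda_z = NA_real_, n = 0L, adj_r2 = -Inf)
  if (n - first + 1L < 3L) return(best)
  ly <- log(conc)
  for (start in first:(n - 2L)) {
    idx <- start:n
    x <- time[idx]; y <- ly[idx]
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    if (sxx <= 0) next
    slope <- sxy / sxx
    if (!is.finite(slope) || slope >= 0) next
    r2 <- if (syy <= 0) 1 else (sxy^2 / (sxx * syy))
    k <- length(idx)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (adj > best$adj_r2)
      best <- list(lambda_z = -slope, n = k, adj_r2 = adj)
  }
  best
}

#' Absolute oral bioavailability from dose-normalised AUCs
#'
#' `F%` is 100 times the ratio of the dose-normalised oral AUC to the
#' dose-normalised IV AUC.  When no within-trial IV arm exists, supply a
#' reference per-dose IV AUC (for example a cross-trial mean) via `iv`.
#'
#' @param oral an `"nca_result"` from an oral profile, or a per-dose oral AUC
#'   (ug.h/mL per mg/kg).
#' @param iv an `"nca_result"` from the matching IV profile, or a reference
#'   per-dose IV AUC.
#' @return List of class `"bioavailability_result"` with `F_percent`,
#'   `auc_oral_per_dose`, `auc_iv_per_dose`.
#' @examples
#' bioavailability(2.33, 6.27)  # F about 37%
#' @export
bioavailability <- function(oral, iv) {
  auc_or <- if (inherits(oral, "nca_result")) oral$AUClast_per_dose else oral
  auc_iv <- if (inherits(iv, "nca_result")) iv$AUClast_per_dose else iv
  if (!is.finite(auc_iv) || auc_iv <= 0)
    stop("IV reference AUC missing or non-positive")
  if (!is.finite(auc_or) || auc_or <= 0)
    stop("oral AUC missing or non-positive")
  structure(list(F_percent = 100 * auc_or / auc_iv,
                 auc_oral_per_dose = auc_or, auc_iv_per_dose = auc_iv),
            class = "bioavailability_result")
}

#' @export
print.bioavailability_result <- function(x, ...) {
  cat(sprintf("F = %.1f%% (oral %.3g vs IV %.3g ug.h/mL per mg/kg)\n",
              x$F_percent, x$auc_oral_per_dose, x$auc_iv_per_dose))
  invisible(x)
}

#' Per-subject NCA table for a long-format dataset
#'
#' Applies [run_nca()] to every subject profile of a dataset, using the
#' subject's total administered dose.  Subjects whose terminal slope is not
#' computable carry `NA` in the slope-dependent columns.
#'
#' @param data a validated long-format dataset (see [read_pk_dataset()]).
#' @return Data frame with one row per subject and the NCA quantities.
#' @export
nca_table <- function(data) {
  data <- validate_pk_dataset(data)
  ids <- unique(data$id)
  rows <- lapply(ids, function(s) {
    sub <- data[data$id == s, ]
    obs <- sub[sub$evid == 0, ]
    dose <- sum(sub$amt[sub$evid == 1])
    res <- tryCatch(
      run_nca(obs$time, obs$conc, dose = dose, route = sub$route[1]),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(id = s, route = sub$route[1], dose = dose,
                        AUClast = NA, AUCinf = NA, AUClast_per_dose = NA,
                        lambda_z = NA, terminal_half_life = NA,
                        Cl_over_F = NA, MRT = NA, Vss = NA, Vz = NA))
    data.frame(id = s, route = res$route, dose = dose,
               AUClast = res$AUClast, AUCinf = res$AUCinf,
               AUClast_per_dose = res$AUClast_per_dose,
               lambda_z = res$lambda_z,
               terminal_half_life = res$terminal_half_life,
               Cl_over_F = res$Cl_over_F, MRT = res$MRT,
               Vss = res$Vss, Vz = res$Vz)
  })
  do.call(rbind, rows)
}
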