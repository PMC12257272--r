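#' AIC covariate search over body-weight power terms
#'
#' Fits the model with the allometric body-weight power term on every subset
#' of the candidate disposition parameters ("shotgun" search: all `2^k`
#' subsets including the empty one), ranks the subsets by AIC, and flags
#' those improving on the no-covariate base model by at least `threshold`
#' (6.635, the p < 0.01 likelihood-ratio equivalent, by default).  Ties in
#' AIC are broken towards the smaller subset (parsimony).
#'
#' @param data long-format dataset (body weight must vary across subjects).
#' @param params candidate parameters; default all six disposition
#'   parameters (64 subsets).  Reduce for quick screens.
#' @param threshold AIC improvement required to flag a subset.
#' @param subsets optional explicit list of character vectors to evaluate
#'   instead of all subsets of `params`.
#' @param ... further arguments passed to [pkfit()] (e.g. `random`,
#'   `stage`, `control`).
#' @return Object of class `"covsearch"`: data frame with one row per
#'   subset (`subset`, `n_cov`, `aic`, `delta_aic` vs base, `flagged`,
#'   and the fitted exponents), ordered by AIC then subset size; the base
#'   model row has an empty subset.  The full fits are attached as
#'   attribute `"fits"`.
#' @export
covariate_search <- function(data, params = c("Cl", "Cl2", "Cl3", "Vc", "V2", "V3"),
                             threshold = 6.635, subsets = NULL, ...) {
  data <- validate_pk_dataset(data)
  bw_by_id <- tapply(data$bw, data$id, `[`, 1)
  if (length(unique(round(bw_by_id, 6))) < 2)
    stop("body weight is constant across subjects; exponents are unidentifiable")
  if (is.null(subsets)) {
    subsets <- list(character(0))
    for (k in seq_along(params))
      subsets <- c(subsets, combn(params, k, simplify = FALSE))
  } else if (!any(vapply(subsets, length, 0L) == 0)) {
    subsets <- c(list(character(0)), subsets)
  }

  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    covs <- if (length(s)) setNames(rep(NA_real_, length(s)), s) else NULL
    fit <- pkfit(data, covariates = covs, ...)
    fits[[i]] <- fit
    expo <- setNames(rep(NA_real_, length(params)), paste0("covBW_", params))
    if (length(s)) expo[paste0("covBW_", s)] <- fit$covariates[s]
    rows[[i]] <- data.frame(subset = paste(s, collapse = "+"),
                            n_cov = length(s), aic = fit$aic,
                            t(expo))
  }
  res <- do.call(rbind, rows)
  base_aic <- res$aic[res$n_cov == 0]
  res$delta_aic <- res$aic - base_aic
  res$flagged <- res$delta_aic <= -threshold
  o <- order(res$aic, res$n_cov)
  res <- res[o, ]
  attr(res, "fits") <- fits[o]
  attr(res, "threshold") <- threshold
  class(res) <- c("covsearch", "data.frame")
  res
}

#' @export
print.covsearch <- function(x, ...) {
  cat("Covariate search (", sum(x$n_cov > 0), "non-empty subsets; AIC flag",
      "threshold", attr(x, "threshold"), ")\n")
  df <- as.data.frame(x)[, c("subset", "n_cov", "aic", "delta_aic", "flagged")]
  df$subset[df$subset == ""] <- "(base)"
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Bootstrap confidence intervals for a population fit
#'
#' Resamples subjects with replacement (stratified by route, resample size
#' equal to the original subject count per stratum), refits, and reports
#' percentile confidence intervals per parameter.  A covariate exponent is
#' significant when its 95% interval excludes 0.  Aborts when more than 20%
#' of the resample fits fail.
#'
#' @param data long-format dataset.
#' @param n_resamples number of bootstrap resamples (100 in the source
#'   analysis; reduce for quick runs).
#' @param seed integer seed.
#' @param ... arguments passed to [pkfit()] (stage, random, covariates,
#'   control, ...).
#' @return Object of class `"bootstrap_result"`: data frame with one row per
#'   parameter: `mean`, `cv_percent`, `median`, `p2.5`, `p97.5`.  The raw
#'   resample estimates are attached as attribute `"resamples"`.
#' @export
bootstrap_ci <- function(data, n_resamples = 100, seed = 1, ...) {
  data <- validate_pk_dataset(data)
  ids <- unique(data$id)
  if (length(ids) < 10) stop("bootstrap needs at least 10 subjects")
  route_of <- tapply(data$route, data$id, `[`, 1)[ids]
  set.seed(seed)
  draws <- list()
  n_fail <- 0
  for (b in seq_len(n_resamples)) {
    samp <- unlist(lapply(split(ids, route_of), function(g)
      sample(g, length(g), replace = TRUE)), use.names = FALSE)
    pieces <- lapply(seq_along(samp), function(k) {
      d <- data[data$id == samp[k], , drop = FALSE]
      d$id <- paste0("bs", k)
      d
    })
    bd <- do.call(rbind, pieces)
    fit <- tryCatch(suppressMessages(pkfit(bd, ...)), error = function(e) NULL)
    if (is.null(fit)) {
      n_fail <- n_fail + 1
      if (n_fail > 0.2 * n_resamples)
        stop("more than 20% of bootstrap refits failed (", n_fail, " of ",
             b, " attempted)")
      next
    }
    draws[[length(draws) + 1L]] <- coef(fit)
  }
  est <- do.call(rbind, draws)
  res <- data.frame(
    parameter = colnames(est),
    mean = colMeans(est),
    cv_percent = 100 * apply(est, 2, sd) / abs(colMeans(est)),
    median = apply(est, 2, median),
    p2.5 = apply(est, 2, quantile, 0.025),
    p97.5 = apply(est, 2, quantile, 0.975),
    row.names = NULL)
  attr(res, "resamples") <- est
  attr(res, "n_fail") <- n_fail
  class(res) <- c("bootstrap_result", "data.frame")
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap (", nrow(attr(x, "resamples")), "successful resamples,",
      attr(x, "n_fail"), "failures)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare 2- and 3-compartment disposition models by AIC
#'
#' Fits both disposition structures to IV data and reports their AIC; a
#' 2-compartment fit is obtained by pinning the deep compartment to a
#' negligible size (`Cl3`, `V3` fixed small).
#'
#' @param data long-format IV dataset.
#' @param ... passed to [pkfit()].
#' @return Data frame with rows `3-compartment` and `2-compartment` and
#'   their OFV/AIC; the winner has the smaller AIC.
#' @export
compare_compartments <- function(data, ...) {
  f3 <- pkfit(data, ...)
  f2 <- pkfit(data, fix = c(Cl3 = 1e-6, V3 = 1e-4), ...)
  data.frame(model = c("3-compartment", "2-compartment"),
             ofv = c(f3$ofv, f2$ofv),
             n_par = c(f3$n_par, f2$n_par),
             aic = c(f3$aic, f2$aic))
}
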