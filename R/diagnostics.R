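#' Shrinkage of empirical Bayes estimates
#'
#' Eta shrinkage per random-effect parameter,
#' `100 * (1 - SD(eta_EBE) / omega)`, and epsilon shrinkage from the
#' individual weighted residuals, `100 * (1 - SD(IWRES))`.  Shrinkage grows
#' towards 100% as individual data get sparser.  Parameters with `omega = 0`
#' are reported as `NA`.
#'
#' @param x a `"pkfit"` object, or a list/matrix of per-subject etas.
#' @param omega named omega vector (only when `x` is not a `"pkfit"`).
#' @return List with `eta` (named percentage vector) and `epsilon`
#'   (percentage, `NA` unless `x` is a fit).
#' @export
shrinkage <- function(x, omega = NULL) {
  if (inherits(x, "pkfit")) {
    ebes <- x$ebe
    omega <- x$omega
    iw <- residuals(x, type = "iwres")$residual
    eps <- 100 * (1 - sd(iw))
  } else {
    ebes <- x
    if (is.null(omega)) stop("omega required when x is not a pkfit")
    eps <- NA_real_
  }
  if (is.matrix(ebes))
    ebes <- lapply(seq_len(nrow(ebes)), function(i) ebes[i, ])
  if (length(ebes) < 2) stop("need at least 2 subjects")
  out <- vapply(names(omega), function(nm) {
    vals <- unlist(lapply(ebes, function(e) e[nm]))
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2 || omega[[nm]] <= 0) return(NA_real_)
    100 * (1 - sd(vals) / omega[[nm]])
  }, 0)
  list(eta = out, epsilon = eps)
}

#' Visual predictive check
#'
#' Simulates every subject's design `n_replicates` times from the model and
#' compares observed quantiles with the simulated quantile bands per time
#' bin.  Empty bins are merged with their left neighbour (with a message).
#'
#' @param data long-format dataset.
#' @param model a [pop_model()] able to simulate every route in `data`.
#' @param n_replicates number of simulated replicates of the full dataset
#'   (default 500).
#' @param quantiles probabilities of the displayed quantiles; the
#'   conventions 10/50/90 (default) and 20/50/80 are both supported.
#' @param breaks time-bin boundaries (h); default: bins around the pooled
#'   unique sampling times (at most 12 bins).
#' @param seed integer seed.
#' @return Object of class `"vpc"`: data frame with, per bin and quantile,
#'   the observed quantile and the 2.5/50/97.5 percentiles of the simulated
#'   quantile.  Has a `plot()` method.
#' @export
vpc_check <- function(data, model, n_replicates = 500,
                      quantiles = c(0.1, 0.5, 0.9), breaks = NULL,
                      seed = NULL) {
  stopifnot(inherits(model, "pop_model"))
  data <- validate_pk_dataset(data)
  if (!is.null(seed)) set.seed(seed)
  subjects <- .split_subjects(data)

  obs <- data[data$evid == 0, ]
  if (is.null(breaks)) {
    ut <- sort(unique(obs$time))
    if (length(ut) > 12)
      ut <- unique(quantile(obs$time, probs = seq(0, 1, length.out = 13)))
    breaks <- c(ut[1] - 1e-9, ut[-1] - diff(ut) / 2, max(ut) + 1e-9)
    breaks <- sort(unique(breaks))
  }
  bin_of <- function(t) findInterval(t, breaks, rightmost.closed = TRUE)
  obs$bin <- bin_of(obs$time)

  # merge empty bins leftwards
  counts <- table(factor(obs$bin, levels = seq_len(length(breaks) - 1)))
  if (any(counts == 0)) message("merging ", sum(counts == 0), " empty time bin(s)")

  # simulate
  sim_q <- array(NA_real_, c(n_replicates, length(breaks) - 1, length(quantiles)))
  th_model <- model
  for (r in seq_len(n_replicates)) {
    sim_conc <- unlist(lapply(subjects, function(sub) {
      pop <- draw_population(th_model, 1, bw = sub$bw, route = sub$route,
                             seed = NULL)
      disp <- do.call(disposition_params,
                      as.list(pop[1, c("Cl", "Cl2", "Cl3", "Vc", "V2", "V3")]))
      absn <- if (sub$route == "IV") absorption_params("IV")
              else absorption_params(sub$route, Ka = pop$Ka[1], F = pop$F[1])
      true <- conc_profile(disp, absn,
                           data.frame(time = sub$dose_time, amount = sub$dose_amt),
                           sub$times)
      if (!is.null(th_model$residual[[sub$route]]))
        apply_residual_error(true, th_model$residual[[sub$route]])
      else true
    }))
    bins <- bin_of(unlist(lapply(subjects, `[[`, "times")))
    for (b in unique(bins))
      sim_q[r, b, ] <- quantile(sim_conc[bins == b], probs = quantiles)
  }

  rows <- list()
  for (b in sort(unique(obs$bin))) {
    yb <- obs$conc[obs$bin == b]
    oq <- quantile(yb, probs = quantiles)
    for (k in seq_along(quantiles)) {
      sq <- sim_q[, b, k]
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, time_mid = median(obs$time[obs$bin == b]),
        quantile = quantiles[k], observed = oq[k],
        sim_lo = quantile(sq, 0.025, na.rm = TRUE),
        sim_med = quantile(sq, 0.5, na.rm = TRUE),
        sim_hi = quantile(sq, 0.975, na.rm = TRUE))
    }
  }
  structure(do.call(rbind, rows),
            class = c("vpc", "data.frame"),
            n_replicates = n_replicates)
}

#' @export
plot.vpc <- function(x, log = "y", ...) {
  qs <- unique(x$quantile)
  plot(range(x$time_mid), range(c(x$observed, x$sim_lo, x$sim_hi)),
       type = "n", log = log, xlab = "Time (h)",
       ylab = "Concentration (ug/mL)", main = "Visual predictive check", ...)
  for (q in qs) {
    sub <- x[x$quantile == q, ]
    lines(sub$time_mid, sub$sim_lo, lty = 3)
    lines(sub$time_mid, sub$sim_hi, lty = 3)
    lines(sub$time_mid, sub$sim_med, lty = 2)
    lines(sub$time_mid, sub$observed, col = 2, lwd = 2)
  }
  legend("topright", c("observed quantile", "simulated median",
                       "simulated 95% band"),
         col = c(2, 1, 1), lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}
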