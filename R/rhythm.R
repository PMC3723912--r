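#' Detrend a luminescence trace
#'
#' @param times Sampling times (hours), strictly increasing.
#' @param values Luminescence counts.
#' @param method `"linear"` subtracts the ordinary least-squares line
#'   (removing baseline and drift, so the output has ~zero mean);
#'   `"none"` returns the values unchanged.
#' @return Numeric vector of detrended values.
#' @export
detrend <- function(times, values, method = c("linear", "none")) {
  method <- match.arg(method)
  check_trace(times, values)
  if (method == "none") return(values)
  X <- cbind(1, times)
  fit <- stats::lm.fit(X, values)
  fit$residuals
}

check_trace <- function(times, values, min_n = 16L) {
  assert_that(length(times) == length(values), "times and values must have equal length")
  assert_that(length(times) >= min_n,
              paste0("trace must have at least ", min_n, " samples"))
  assert_that(all(is.finite(times)) && all(is.finite(values)),
              "trace contains non-finite values")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  invisible(TRUE)
}

# Design matrix {1, [t,] cos(2*pi*k*t/T), sin(2*pi*k*t/T)}_{k=1..K}.
# The linear trend is fitted jointly with the harmonics (not pre-subtracted):
# detrending a finite window of a pure sinusoid beforehand leaks a spurious
# slope into the residual and biases the period search.
harmonic_design <- function(times, period, n_harmonics, trend = FALSE) {
  w <- 2 * pi * times / period
  cols <- lapply(seq_len(n_harmonics), function(k) cbind(cos(k * w), sin(k * w)))
  if (trend) cbind(1, times - mean(times), do.call(cbind, cols))
  else cbind(1, do.call(cbind, cols))
}

#' Fit a truncated Fourier series at a fixed trial period
#'
#' Ordinary least squares of the values on an intercept plus `n_harmonics`
#' cosine/sine pairs of the trial period; the returned residual sum of
#' squares is the minimum over coefficients for that period.
#'
#' @inheritParams detrend
#' @param period Trial period (hours, > 0).
#' @param n_harmonics Number of harmonics K (>= 1, with 2K+1 <= n samples).
#' @return List with `coefficients` (named: intercept, cos1, sin1, ...),
#'   `rss`, and `fitted`.
#' @export
fit_harmonics <- function(times, values, period, n_harmonics = 3,
                          trend = FALSE) {
  assert_that(period > 0, "`period` must be > 0")
  assert_that(n_harmonics >= 1, "`n_harmonics` must be >= 1")
  assert_that(2 * n_harmonics + 1 + trend <= length(values),
              "too few samples for the requested number of harmonics")
  X <- harmonic_design(times, period, n_harmonics, trend)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("degenerate harmonic fit: design is rank-deficient (period ",
         signif(period, 4), " h too long for the trace span?)", call. = FALSE)
  }
  cf <- qr.coef(qrX, values)
  res <- qr.resid(qrX, values)
  names(cf) <- c("intercept", if (trend) "trend",
                 paste0(rep(c("cos", "sin"), n_harmonics),
                        rep(seq_len(n_harmonics), each = 2)))
  list(coefficients = cf, rss = sum(res^2), fitted = values - res)
}

# rss profile over a period grid for a matrix of traces sharing `times`.
# Y: n x m (one column per trace). Returns m x length(periods) matrix.
grid_rss <- function(times, Y, periods, n_harmonics, trend = FALSE) {
  m <- ncol(Y)
  out <- matrix(NA_real_, m, length(periods))
  for (j in seq_along(periods)) {
    X <- harmonic_design(times, periods[j], n_harmonics, trend)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) next
    R <- qr.resid(qrX, Y)
    out[, j] <- colSums(R^2)
  }
  out
}

# Parabolic refinement of the grid minimum of an rss profile.
refine_parabolic <- function(periods, rss) {
  i <- which.min(rss)
  if (i == 1L || i == length(rss) || anyNA(rss[(i - 1):(i + 1)])) {
    return(periods[i])
  }
  y1 <- rss[i - 1]; y2 <- rss[i]; y3 <- rss[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom <= 0) return(periods[i])
  h <- periods[i + 1] - periods[i]
  periods[i] + h * (y1 - y3) / (2 * denom)
}

# Phase (peak time of the fundamental) and amplitude from coefficients.
fundamental_phase <- function(cf, period) {
  a <- cf[["cos1"]]; b <- cf[["sin1"]]
  amp <- sqrt(a^2 + b^2)
  # a*cos(wt) + b*sin(wt) = amp * cos(w*(t - phi)) with phi = atan2(b, a)/w
  phi <- wrap_period(atan2(b, a) * period / (2 * pi), period)
  list(phase = phi, amplitude = amp)
}

#' Estimate circadian period, phase and amplitude of a trace
#'
#' Harmonic regression with the fundamental period as the free nonlinear
#' parameter: the residual sum of squares of a K-harmonic least-squares fit
#' is minimised over a period grid and refined by local parabolic
#' interpolation. Phase is the peak time of the fitted fundamental component
#' wrapped into `[0, T)`. A trace is flagged arrhythmic when the fundamental
#' amplitude does not exceed `rhythm_gate` times the residual SD.
#'
#' @inheritParams detrend
#' @param window Period search window in hours (default circadian, 16-40 h).
#' @param grid_step Grid spacing in hours (default 0.05 h).
#' @param n_harmonics Number of harmonics (default 3).
#' @param detrend_method `"linear"` fits a linear drift term jointly with
#'   the harmonics (default); `"none"` fits harmonics plus intercept only.
#' @param burn_in Hours discarded from the start of the trace to skip
#'   transients after release into constant light (default 24 h).
#' @param rhythm_gate Amplitude/noise ratio below which the trace is called
#'   arrhythmic (default 2).
#' @return A `rhythm_fit` list: `period`, `phase`, `amplitude`,
#'   `coefficients`, `rss`, `rhythmic`, `n_harmonics`, `n`.
#' @export
estimate_period <- function(times, values, window = c(16, 40), grid_step = 0.05,
                            n_harmonics = 3, detrend_method = "linear",
                            burn_in = 24, rhythm_gate = 2) {
  check_trace(times, values)
  trend <- match.arg(detrend_method, c("linear", "none")) == "linear"
  keep <- times >= (times[1] + burn_in)
  if (sum(keep) < 2 * n_harmonics + 2 + trend) keep <- rep(TRUE, length(times))
  t2 <- times[keep]
  y2 <- values[keep]

  arrhythmic <- function() {
    structure(list(period = NA_real_, phase = NA_real_, amplitude = NA_real_,
                   coefficients = NULL, rss = NA_real_, rhythmic = FALSE,
                   n_harmonics = n_harmonics, n = length(t2)),
              class = "rhythm_fit")
  }
  if (sd(y2) == 0) return(arrhythmic())

  periods <- seq(window[1], window[2], by = grid_step)
  rss <- grid_rss(t2, cbind(y2), periods, n_harmonics, trend)[1, ]
  if (all(is.na(rss))) return(arrhythmic())
  T_star <- refine_parabolic(periods, rss)
  T_star <- min(max(T_star, window[1]), window[2])
  fit <- fit_harmonics(t2, y2, T_star, n_harmonics, trend)
  fp <- fundamental_phase(fit$coefficients, T_star)
  resid_sd <- sqrt(fit$rss / max(1, length(y2) - length(fit$coefficients)))
  rhythmic <- fp$amplitude > rhythm_gate * resid_sd
  structure(list(period = T_star, phase = fp$phase, amplitude = fp$amplitude,
                 coefficients = fit$coefficients, rss = fit$rss,
                 rhythmic = rhythmic, n_harmonics = n_harmonics, n = length(t2)),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (!isTRUE(x$rhythmic) && is.na(x$period)) {
    cat("<rhythm_fit> arrhythmic (no period estimate)\n")
  } else {
    cat(sprintf("<rhythm_fit> period %.2f h, phase %.2f h, amplitude %.1f%s\n",
                x$period, x$phase, x$amplitude,
                if (x$rhythmic) "" else " [below rhythmicity gate]"))
  }
  invisible(x)
}

#' Phase of a fitted rhythm relative to a reference time
#'
#' @param fit A `rhythm_fit` from [estimate_period()].
#' @param reference Reference time in hours (default 0).
#' @return Peak time of the fundamental component relative to `reference`,
#'   wrapped into `[0, T)`.
#' @export
estimate_phase <- function(fit, reference = 0) {
  assert_that(inherits(fit, "rhythm_fit"), "`fit` must be a rhythm_fit")
  if (!isTRUE(fit$rhythmic)) {
    stop("cannot extract a phase from an arrhythmic fit", call. = FALSE)
  }
  wrap_period(fit$phase - reference, fit$period)
}

#' Fit rhythms for every well of a long-format trace table
#'
#' Traces are grouped by `(plate, well)`. Wells sharing an identical time
#' grid are fitted in a single batched grid search (one QR factorisation per
#' trial period serves all wells), which makes plate-scale fitting fast.
#'
#' @param traces Long tibble with columns `time_h`, `lum`, `well`, `plate`
#'   and any metadata (`line`, `treatment`, `dose_uM`, `pulse_start_zt`,
#'   `replicate`).
#' @inheritParams estimate_period
#' @return Tibble with one row per well: metadata plus `period_h`, `phase_h`,
#'   `amplitude`, `rss`, `rhythmic`.
#' @export
fit_rhythms <- function(traces, window = c(16, 40), grid_step = 0.05,
                        n_harmonics = 3, detrend_method = "linear",
                        burn_in = 24, rhythm_gate = 2) {
  req <- c("time_h", "lum", "well", "plate")
  missing_cols <- setdiff(req, names(traces))
  assert_that(length(missing_cols) == 0,
              paste0("traces table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  meta_cols <- intersect(c("well", "plate", "line", "treatment", "dose_uM",
                           "pulse_start_zt", "replicate"), names(traces))
  traces <- dplyr::arrange(traces, .data$plate, .data$well, .data$time_h)
  keyed <- dplyr::group_by(traces, .data$plate, .data$well)
  groups <- dplyr::group_split(keyed)
  meta <- dplyr::summarise(
    keyed, dplyr::across(dplyr::all_of(setdiff(meta_cols, c("well", "plate"))),
                         dplyr::first), .groups = "drop")

  # partition wells by identical time grid for batched fitting
  trend <- match.arg(detrend_method, c("linear", "none")) == "linear"
  grid_key <- vapply(groups, function(g) paste(signif(g$time_h, 10), collapse = ","),
                     character(1))
  periods <- seq(window[1], window[2], by = grid_step)
  res <- vector("list", length(groups))
  for (key in unique(grid_key)) {
    idx <- which(grid_key == key)
    t_all <- groups[[idx[1]]]$time_h
    keep <- t_all >= (t_all[1] + burn_in)
    if (sum(keep) < 2 * n_harmonics + 2 + trend) keep <- rep(TRUE, length(t_all))
    t2 <- t_all[keep]
    Y <- vapply(groups[idx], function(g) g$lum[keep], numeric(length(t2)))
    Y <- matrix(Y, nrow = length(t2))
    RSS <- grid_rss(t2, Y, periods, n_harmonics, trend)
    for (k in seq_along(idx)) {
      yk <- Y[, k]
      if (sd(yk) == 0 || all(is.na(RSS[k, ]))) {
        res[[idx[k]]] <- list(period = NA_real_, phase = NA_real_,
                              amplitude = NA_real_, rss = NA_real_,
                              rhythmic = FALSE)
        next
      }
      T_star <- refine_parabolic(periods, RSS[k, ])
      T_star <- min(max(T_star, window[1]), window[2])
      fit <- fit_harmonics(t2, yk, T_star, n_harmonics, trend)
      fp <- fundamental_phase(fit$coefficients, T_star)
      resid_sd <- sqrt(fit$rss / max(1, length(yk) - length(fit$coefficients)))
      res[[idx[k]]] <- list(period = T_star, phase = fp$phase,
                            amplitude = fp$amplitude, rss = fit$rss,
                            rhythmic = fp$amplitude > rhythm_gate * resid_sd)
    }
  }
  fits <- tibble::tibble(
    plate = vapply(groups, function(g) g$plate[1], character(1)),
    well = vapply(groups, function(g) g$well[1], character(1)),
    period_h = vapply(res, `[[`, numeric(1), "period"),
    phase_h = vapply(res, `[[`, numeric(1), "phase"),
    amplitude = vapply(res, `[[`, numeric(1), "amplitude"),
    rss = vapply(res, `[[`, numeric(1), "rss"),
    rhythmic = vapply(res, `[[`, logical(1), "rhythmic")
  )
  dplyr::left_join(fits, meta, by = c("plate", "well"))
}

#' Compare free-running periods between two replicate groups
#'
#' Welch two-tailed t-test on fitted periods. The difference is reported as
#' `mean(B) - mean(A)` so the comparison is antisymmetric in group order.
#' When both groups have zero variance the difference is still reported but
#' the p-value is undefined (`NA`).
#'
#' @param group_a,group_b Numeric period vectors, lists of `rhythm_fit`
#'   objects, or fit tibbles from [fit_rhythms()] (arrhythmic fits dropped).
#' @return List of class `period_comparison`: `mean_difference`,
#'   `sd_per_group`, `t_statistic`, `p_value`, `n_per_group`.
#' @export
compare_periods <- function(group_a, group_b) {
  pa <- extract_periods(group_a)
  pb <- extract_periods(group_b)
  if (length(pa) < 2 || length(pb) < 2) {
    stop("insufficient replicates: each group needs >= 2 rhythmic fits",
         call. = FALSE)
  }
  diff <- mean(pb) - mean(pa)
  if (sd(pa) == 0 && sd(pb) == 0) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    ht <- t.test(pb, pa, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(list(mean_difference = diff,
                 sd_per_group = c(A = sd(pa), B = sd(pb)),
                 t_statistic = tt$statistic, p_value = tt$p.value,
                 n_per_group = c(A = length(pa), B = length(pb))),
            class = "period_comparison")
}

extract_periods <- function(x) {
  if (is.numeric(x)) return(x[is.finite(x)])
  if (inherits(x, "data.frame")) {
    assert_that("period_h" %in% names(x), "fit table must have a period_h column")
    keep <- if ("rhythmic" %in% names(x)) x$rhythmic else TRUE
    return(x$period_h[keep & is.finite(x$period_h)])
  }
  if (is.list(x)) {
    p <- vapply(x, function(f) {
      if (inherits(f, "rhythm_fit") && isTRUE(f$rhythmic)) f$period else NA_real_
    }, numeric(1))
    return(p[is.finite(p)])
  }
  stop("cannot extract periods from object of class ", class(x)[1], call. = FALSE)
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("<period_comparison> mean difference (B - A): %.3f h, t = %s, p = %s (n = %d/%d)\n",
              x$mean_difference,
              if (is.na(x$t_statistic)) "NA" else sprintf("%.2f", x$t_statistic),
              if (is.na(x$p_value)) "NA (degenerate variance)" else format.pval(x$p_value, digits = 3),
              x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}
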