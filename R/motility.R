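#' Average speed of a track
#'
#' Mean over steps of (step displacement / frame interval), in um/h — the
#' per-cell summary plotted as box-and-whisker distributions in motility
#' assays.
#'
#' @param track A [track()] object.
#' @return Speed in um/h.
#' @export
average_speed <- function(track) {
  stopifnot(inherits(track, "Track"))
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  mean(steps / track$dt_h)
}

#' Hourly running average speed
#'
#' Tiles the track into consecutive windows of `window_h` hours (measured
#' from the first timepoint) and averages the step speeds whose step ends
#' inside each window.
#'
#' @param track A [track()] object spanning at least one window.
#' @param window_h Window length in hours (default 1; must be >= the frame
#'   interval).
#' @return Data frame of class `speed_series` with columns `track_id`,
#'   `t_h` (window centre) and `speed_um_h`.
#' @export
running_average_speed <- function(track, window_h = 1) {
  stopifnot(inherits(track, "Track"))
  if (window_h < track$dt_h)
    stop("running_average_speed: window smaller than the frame interval")
  span <- diff(range(track$times_h))
  if (span < window_h)
    stop("running_average_speed: track shorter than one window")
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2) / track$dt_h
  t_end <- track$times_h[-1] - track$times_h[1]
  win <- ceiling(t_end / window_h - 1e-9)  # window 1 covers (0, window_h]
  agg <- tapply(steps, win, mean)
  out <- data.frame(track_id = track$track_id,
                    t_h = track$times_h[1] +
                      (as.numeric(names(agg)) - 0.5) * window_h,
                    speed_um_h = as.numeric(agg))
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Mean running speed across tracks
#'
#' Hourly running average per track, then the cross-track mean (with s.e.m.)
#' at each window — the form in which washout and inhibition time courses
#' are plotted and fitted.
#'
#' @param tracks List of [track()] objects.
#' @param window_h Window length in hours.
#' @return Data frame with `t_h`, `speed_um_h` (mean), `sem` and `n`.
#' @export
mean_running_speed <- function(tracks, window_h = 1) {
  per <- do.call(rbind, lapply(tracks, running_average_speed, window_h = window_h))
  sp <- split(per$speed_um_h, per$t_h)
  out <- data.frame(t_h = as.numeric(names(sp)),
                    speed_um_h = vapply(sp, mean, numeric(1)),
                    sem = vapply(sp, function(v)
                      stats::sd(v) / sqrt(length(v)), numeric(1)),
                    n = vapply(sp, length, numeric(1)))
  out[order(out$t_h), , drop = FALSE]
}

#' Ensemble mean-squared displacement
#'
#' Time-averaged MSD per track over all ordered same-track pairs at each lag
#' (overlapping windows), then averaged across tracks. Lags run from `dt` up
#' to `max_lag_fraction` of the shortest track; the lag-0 value is 0 by
#' definition and is included for completeness.
#'
#' @param tracks A [track()] object or list of them.
#' @param max_lag_fraction Largest lag as a fraction of the shortest track's
#'   step count (default 0.25, which avoids the noisy high-lag regime).
#' @return Data frame of class `msd_result` with columns `lag_h`, `msd_um2`
#'   and `n_pairs`.
#' @export
msd <- function(tracks, max_lag_fraction = 0.25) {
  if (inherits(tracks, "Track")) tracks <- list(tracks)
  if (!length(tracks)) stop("msd: empty track list")
  n_steps <- vapply(tracks, function(tr) length(tr$times_h) - 1L, integer(1))
  k_max <- max(1L, floor(min(n_steps) * max_lag_fraction))
  dt <- tracks[[1]]$dt_h
  per_track <- vapply(tracks, function(tr) {
    vapply(seq_len(k_max), function(k) {
      dx <- tr$x_um[-seq_len(k)] - tr$x_um[seq_len(length(tr$x_um) - k)]
      dy <- tr$y_um[-seq_len(k)] - tr$y_um[seq_len(length(tr$y_um) - k)]
      mean(dx^2 + dy^2)
    }, numeric(1))
  }, numeric(k_max))
  per_track <- matrix(per_track, nrow = k_max)
  pairs <- vapply(seq_len(k_max), function(k) sum(n_steps + 1L - k), numeric(1))
  out <- data.frame(lag_h = c(0, seq_len(k_max) * dt),
                    msd_um2 = c(0, rowMeans(per_track)),
                    n_pairs = c(sum(n_steps + 1L), pairs))
  class(out) <- c("msd_result", "data.frame")
  out
}

#' Linear regression of MSD on lag time
#'
#' Ordinary least squares of MSD against lag (with intercept, which absorbs
#' static localisation error), excluding the trivial lag-0 point. An R^2 of
#' 1 indicates the linear MSD growth of a total random (diffusive) movement;
#' for a 2D random walk the slope estimates `4 * D`.
#'
#' @param msd_result An [msd()] result with at least 3 non-zero lags.
#' @param through_origin Force a zero intercept (default FALSE).
#' @return List with `slope` (um^2/h), `intercept` (um^2), `r_squared`, and
#'   the underlying `lm` fit.
#' @export
fit_msd_linear <- function(msd_result, through_origin = FALSE) {
  d <- msd_result[msd_result$lag_h > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("fit_msd_linear: need at least 3 non-zero lags")
  fit <- if (through_origin) stats::lm(msd_um2 ~ lag_h - 1, data = d)
         else stats::lm(msd_um2 ~ lag_h, data = d)
  co <- stats::coef(fit)
  list(slope = unname(co[["lag_h"]]),
       intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Classify motion from the MSD scaling exponent
#'
#' Fits `log(MSD) ~ log(lag)` over positive-MSD lags; the slope `alpha`
#' separates diffusive (`alpha ~ 1`, a random walk), superdiffusive
#' (`alpha > 1`, directed motion approaches 2) and subdiffusive movement.
#'
#' @param msd_result An [msd()] result.
#' @param tol Tolerance around 1 for the diffusive call (default 0.1).
#' @return List with `class`, `alpha`, `r_squared` and `degenerate` (TRUE
#'   when fewer than 3 positive-MSD lags exist, e.g. stationary tracks).
#' @export
classify_motion <- function(msd_result, tol = 0.1) {
  d <- msd_result[msd_result$lag_h > 0 & msd_result$msd_um2 > 0, , drop = FALSE]
  if (nrow(d) < 3)
    return(list(class = "subdiffusive", alpha = NA_real_,
                r_squared = NA_real_, degenerate = TRUE))
  fit <- stats::lm(log(msd_um2) ~ log(lag_h), data = d)
  alpha <- unname(stats::coef(fit)[2])
  cls <- if (abs(alpha - 1) <= tol) "diffusive"
         else if (alpha > 1 + tol) "superdiffusive" else "subdiffusive"
  list(class = cls, alpha = alpha, r_squared = summary(fit)$r.squared,
       degenerate = FALSE)
}

#' Fit half-life decay of motility after drug addition
#'
#' Nonlinear least squares of
#' `S(t) = S_inf + (S0 - S_inf) * 2^(-(t - t_drug) / half_life)` on the
#' post-drug portion of a running-speed series. The base-2 form makes the
#' fitted `half_life_h` the literal time for the excess speed to halve.
#'
#' @param series Data frame with columns `t_h` and `speed_um_h` (e.g. from
#'   [mean_running_speed()]).
#' @param t_drug_h Time of drug addition; only `t_h >= t_drug_h` is fitted
#'   (at least 4 windows required).
#' @return Object of class `decay_fit`: list with `S0_um_h`, `S_inf_um_h`,
#'   `half_life_h`, `resid_norm`, `identifiable` and the `nls` fit (NULL for
#'   a flat series, which leaves the half-life unidentifiable).
#' @export
fit_speed_decay <- function(series, t_drug_h = 0) {
  stopifnot(all(c("t_h", "speed_um_h") %in% names(series)))
  d <- series[series$t_h >= t_drug_h, , drop = FALSE]
  if (nrow(d) < 4) stop("fit_speed_decay: need at least 4 post-drug windows")
  s <- d$speed_um_h
  if (stats::sd(s) < 1e-9 * max(mean(s), 1e-12)) {
    return(structure(list(S0_um_h = mean(s), S_inf_um_h = mean(s),
                          half_life_h = NA_real_, resid_norm = 0,
                          identifiable = FALSE, fit = NULL),
                     class = "decay_fit"))
  }
  start <- list(S0 = max(s), S_inf = max(min(s), 0),
                hl = max(diff(range(d$t_h)) / 4, 0.1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      speed_um_h ~ S_inf + (S0 - S_inf) * 2^(-(t_h - t_drug_h) / hl),
      data = d, start = start,
      lower = c(S0 = 0, S_inf = 0, hl = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit_speed_decay: fit did not converge (",
                             conditionMessage(e), "); starts were S0=",
                             signif(start$S0, 3), ", S_inf=",
                             signif(start$S_inf, 3), ", hl=",
                             signif(start$hl, 3)))
  co <- stats::coef(fit)
  structure(list(S0_um_h = unname(co[["S0"]]), S_inf_um_h = unname(co[["S_inf"]]),
                 half_life_h = unname(co[["hl"]]),
                 resid_norm = sqrt(sum(stats::residuals(fit)^2)),
                 identifiable = TRUE, fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$identifiable)
    cat(sprintf("decay_fit: S0 = %.3g, S_inf = %.3g um/h, half-life = %.3g h\n",
                x$S0_um_h, x$S_inf_um_h, x$half_life_h))
  else cat("decay_fit: flat series; half-life unidentifiable\n")
  invisible(x)
}
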