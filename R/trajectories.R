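#' Specification of synthetic 2D cell trajectories
#'
#' Four generative motion models matched to the analytics they exercise:
#'
#' * `random_walk` — i.i.d. isotropic Gaussian steps with per-axis variance
#'   `2 * D * dt`; the null model of purely random (diffusive) migration,
#'   for which the ensemble MSD is linear with slope `4 * D`.
#' * `ballistic` — constant speed along a fixed, per-track random heading;
#'   MSD grows as `v^2 * tau^2`.
#' * `persistent` — constant step length with wrapped-Gaussian heading
#'   increments; `persistence` is the mean cosine of the turning angle.
#' * `decaying_speed` — random heading each step with step length
#'   `S(t) * dt`, where `S(t) = S_inf + (S0 - S_inf) * 2^(-t / half_life_h)`;
#'   emulates motility decay after drug addition, with the half-life as the
#'   literal parameter of the base-2 exponential.
#'
#' @param model One of `"random_walk"`, `"ballistic"`, `"persistent"`,
#'   `"decaying_speed"`.
#' @param n_tracks Number of tracks.
#' @param dt_h Frame interval in hours (default 1/6 h = 10 min).
#' @param duration_h Track duration in hours (default 16).
#' @param D_um2_h Diffusion coefficient for `random_walk` (um^2/h).
#' @param speed_um_h Speed for `ballistic` / `persistent` (um/h).
#' @param persistence Mean cosine of the turning angle, in `[0, 1)`.
#' @param S0_um_h,S_inf_um_h,half_life_h Initial speed, plateau speed and
#'   half-life for `decaying_speed`.
#' @param speed_cv Multiplicative Gaussian coefficient of variation applied to
#'   each `decaying_speed` step length (0 = noiseless).
#' @param seed Integer seed; fixes the tracks exactly.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(model = c("random_walk", "ballistic", "persistent",
                                      "decaying_speed"),
                            n_tracks = 40, dt_h = 1 / 6, duration_h = 16,
                            D_um2_h = NULL, speed_um_h = NULL,
                            persistence = NULL, S0_um_h = NULL,
                            S_inf_um_h = NULL, half_life_h = NULL,
                            speed_cv = 0, seed = 1L) {
  model <- match.arg(model)
  if (dt_h <= 0) stop("trajectory_spec: dt_h must be > 0")
  if (duration_h < 2 * dt_h) stop("trajectory_spec: duration_h must be >= 2 * dt_h")
  need <- function(x, nm, lo = 0) {
    if (is.null(x) || !is.finite(x) || x < lo)
      stop("trajectory_spec: model '", model, "' needs ", nm, " >= ", lo)
    x
  }
  switch(model,
    random_walk = need(D_um2_h, "D_um2_h"),
    ballistic = need(speed_um_h, "speed_um_h"),
    persistent = {
      need(speed_um_h, "speed_um_h")
      if (is.null(persistence) || persistence < 0 || persistence >= 1)
        stop("trajectory_spec: persistence must lie in [0, 1)")
    },
    decaying_speed = {
      need(S0_um_h, "S0_um_h"); need(S_inf_um_h, "S_inf_um_h")
      if (is.null(half_life_h) || half_life_h <= 0)
        stop("trajectory_spec: half_life_h must be > 0")
      if (S0_um_h < S_inf_um_h)
        stop("trajectory_spec: decay requires S0_um_h >= S_inf_um_h")
    })
  structure(as.list(environment())[c("model", "n_tracks", "dt_h", "duration_h",
                                     "D_um2_h", "speed_um_h", "persistence",
                                     "S0_um_h", "S_inf_um_h", "half_life_h",
                                     "speed_cv", "seed")],
            class = "trajectory_spec")
}

#' Simulate trajectories from a trajectory_spec
#'
#' @param spec A [trajectory_spec()].
#' @return List with `tracks` (list of [track()] objects starting at the
#'   origin) and `truth` (the generating parameters, including per-track
#'   headings for the ballistic model).
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n_steps <- round(spec$duration_h / spec$dt_h)
  times <- seq(0, by = spec$dt_h, length.out = n_steps + 1)
  headings <- rep(NA_real_, spec$n_tracks)
  tracks <- with_seed(spec$seed, lapply(seq_len(spec$n_tracks), function(i) {
    dxy <- switch(spec$model,
      random_walk = {
        s <- sqrt(2 * spec$D_um2_h * spec$dt_h)
        cbind(stats::rnorm(n_steps, sd = s), stats::rnorm(n_steps, sd = s))
      },
      ballistic = {
        th <- stats::runif(1, 0, 2 * pi)
        headings[i] <<- th
        step <- spec$speed_um_h * spec$dt_h
        cbind(rep(step * cos(th), n_steps), rep(step * sin(th), n_steps))
      },
      persistent = {
        sigma <- sqrt(-2 * log(max(spec$persistence, 1e-12)))
        th <- cumsum(c(stats::runif(1, 0, 2 * pi),
                       stats::rnorm(n_steps - 1, sd = sigma)))
        step <- spec$speed_um_h * spec$dt_h
        cbind(step * cos(th), step * sin(th))
      },
      decaying_speed = {
        t0 <- times[seq_len(n_steps)]
        sp <- spec$S_inf_um_h +
          (spec$S0_um_h - spec$S_inf_um_h) * 2^(-t0 / spec$half_life_h)
        len <- sp * spec$dt_h
        if (spec$speed_cv > 0)
          len <- pmax(len * (1 + stats::rnorm(n_steps, sd = spec$speed_cv)), 0)
        th <- stats::runif(n_steps, 0, 2 * pi)
        cbind(len * cos(th), len * sin(th))
      })
    track(sprintf("t%03d", i), times,
          cumsum(c(0, dxy[, 1])), cumsum(c(0, dxy[, 2])))
  }))
  list(tracks = tracks,
       truth = list(model = spec$model, spec = spec, headings = headings))
}
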