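#' Osmotic pressure difference of a cell
#'
#' The difference between the osmotic pressures inside and outside the cell,
#' expressed through the isosmotic length \code{li} (the length at which the
#' cell would be isotonic with its surroundings) and the visible length
#' \code{l}: \code{alpha * (li - l) / l}. Positive when the cell is
#' hypertonic (water tends to flow in), negative when hypotonic.
#'
#' @param li isosmotic length (um); vectorized.
#' @param l visible length (um); vectorized.
#' @param params a [mech_params()].
#' @return osmotic pressure difference (bar).
#' @export
osmotic_pressure <- function(li, l, params = mech_params()) {
  if (any(!is.finite(li)) || any(li <= 0))
    stop("osmotic_pressure: isosmotic length must be positive")
  if (any(!is.finite(l)) || any(l <= 0))
    stop("osmotic_pressure: visible length must be positive")
  params$alpha * (li - l) / l
}

#' Turgor pressure of a cell
#'
#' Hydrostatic pressure generated by the elastic stretch of the wall beyond
#' its relaxed length: \code{beta * (l - lr) / lr}. Negative values indicate
#' a compressed wall.
#'
#' @param l visible length (um); vectorized.
#' @param lr relaxed (unstressed wall) length (um); vectorized.
#' @param params a [mech_params()].
#' @return turgor pressure (bar).
#' @export
turgor_pressure <- function(l, lr, params = mech_params()) {
  if (any(!is.finite(l)) || any(l <= 0))
    stop("turgor_pressure: visible length must be positive")
  if (any(!is.finite(lr)) || any(lr <= 0))
    stop("turgor_pressure: relaxed length must be positive")
  params$beta * (l - lr) / lr
}

#' Free specific growth rate of the visible length
#'
#' The relative growth rate (d l / (l dt)) the cell would have if it had no
#' mechanical bonds with neighbours: \code{r * Lw * (P_osm - P_turg)}.
#' Positive exactly when the osmotic pull exceeds the wall stress.
#'
#' @param li,l,lr cell lengths (um); vectorized.
#' @param params a [mech_params()].
#' @return specific growth rate (per hour).
#' @export
free_growth_rate <- function(li, l, lr, params = mech_params()) {
  params$r * params$Lw *
    (osmotic_pressure(li, l, params) - turgor_pressure(l, lr, params))
}

#' Growth rate of the relaxed (wall) length
#'
#' The wall yields irreversibly only above the turgor threshold \code{Pc};
#' its growth rate is proportional to the biomass growth rate \code{dli_dt}
#' and to the cubed excess turgor:
#' \code{eta * dli_dt * (P_turg - Pc)^3} when \code{P_turg > Pc}, else 0.
#' The relaxed length is therefore non-decreasing.
#'
#' @param l,lr cell lengths (um); vectorized.
#' @param dli_dt isosmotic (biomass) growth rate (um/h), must be >= 0.
#' @param params a [mech_params()].
#' @return wall growth rate (um/h), always >= 0.
#' @export
relaxed_length_rate <- function(l, lr, dli_dt, params = mech_params()) {
  if (any(dli_dt < 0))
    stop("relaxed_length_rate: dli_dt must be non-negative")
  excess <- pmax(turgor_pressure(l, lr, params) - params$Pc, 0)
  params$eta * dli_dt * excess^3
}

#' Isosmotic length at a given time
#'
#' Evaluates the piecewise-linear schedule: slope \code{a1} from birth until
#' the isosmotic length reaches \code{li_max}, slope \code{a2} for
#' \code{t_elong} hours after that, constant afterwards. Continuous
#' everywhere.
#'
#' @param t time (h); vectorized. Must be >= the schedule's birth time.
#' @param schedule a [growth_schedule()].
#' @return isosmotic length (um).
#' @export
isosmotic_length <- function(t, schedule) {
  if (any(t < schedule$t0 - 1e-12))
    stop("isosmotic_length: t precedes the cell's birth time t0")
  ts <- schedule$t_switch
  te <- ts + schedule$t_elong
  li_end <- schedule$li_max + schedule$a2 * schedule$t_elong
  ifelse(t < ts, schedule$li0 + schedule$a1 * (t - schedule$t0),
         ifelse(t < te, schedule$li_max + schedule$a2 * (t - ts), li_end))
}

# Schedule slope at time t (um/h). Internal.
schedule_rate <- function(t, schedule) {
  ts <- schedule$t_switch
  te <- ts + schedule$t_elong
  ifelse(t < ts, schedule$a1, ifelse(t < te, schedule$a2, 0))
}

# Core of the linearized-implicit step, shared (in identical form) by the
# isolated-cell integrator and the tissue engine. Advances li explicitly
# along the schedule slope and lr explicitly from the pre-step turgor, then
# returns the free specific growth rate g evaluated at the *updated* li and
# lr (this is what lets the scheme track the quasi-static manifold at steps
# far larger than the relaxation time) together with the local relaxation
# rate Gamma = -l * dg/dl = r*Lw*(alpha*li/l + beta*l/lr). The visible
# length (or, in the tissue, each fragment) is then updated with one Newton
# step of backward Euler, x' = x * (1 + dt*g / (1 + dt*Gamma)):
# unconditionally stable, and it reduces to explicit Euler when
# dt*Gamma << 1. Internal.
step_core <- function(li, l, lr, li_dot, dt, params) {
  rl <- params$r * params$Lw
  pt <- params$beta * (l - lr) / lr
  li2 <- li + dt * li_dot
  lr2 <- lr + dt * params$eta * li_dot * pmax(pt - params$Pc, 0)^3
  g <- rl * (params$alpha * (li2 - l) / l - params$beta * (l - lr2) / lr2)
  gam <- rl * (params$alpha * li2 / l + params$beta * l / lr2)
  list(li = li2, lr = lr2, g = g, gam = gam)
}

# One full step for an isolated cell. Internal.
step_lengths <- function(li, l, lr, li_dot, dt, params) {
  st <- step_core(li, l, lr, li_dot, dt, params)
  list(li = st$li, lr = st$lr,
       l = l * (1 + dt * st$g / (1 + dt * st$gam)))
}

#' Initial mechanical state of a newborn or seed cell
#'
#' A cell of isosmotic length \code{li0} starts isotonic (\code{l = li0},
#' zero osmotic pressure difference) with its wall prestressed exactly to
#' the yield threshold: \code{lr = li0 * beta / (beta + Pc)}, so the initial
#' turgor equals \code{Pc}. This deterministic choice reaches the
#' quasi-equilibrium growth regime after a short recorded transient.
#'
#' @param li0 initial isosmotic length (um).
#' @param params a [mech_params()].
#' @return list with components \code{li}, \code{l}, \code{lr}.
#' @export
initial_cell_state <- function(li0, params = mech_params()) {
  list(li = li0, l = li0, lr = li0 * params$beta / (params$beta + params$Pc))
}

#' Simulate the autonomous growth of an isolated cell
#'
#' Integrates the single-cell model (visible-length dynamics driven by the
#' osmotic/turgor pressure imbalance, irreversible wall growth above the
#' turgor threshold, and the imposed piecewise-linear isosmotic schedule)
#' with a fixed-step linearized-implicit scheme suited to the stiff
#' relaxation of the visible length. Lengths are in um, time in h,
#' pressures in bar.
#'
#' @param params a [mech_params()].
#' @param schedule a [growth_schedule()].
#' @param t_end end of integration, measured from the birth time (h).
#' @param dt integrator step (h), default 0.01.
#' @param record_dt sampling cadence of the returned trajectory (h);
#'   default 1 h. Must be a multiple of \code{dt}.
#' @param init optional initial state list with \code{li}, \code{l},
#'   \code{lr}; defaults to [initial_cell_state()] at \code{schedule$li0}.
#' @return A \code{"cell_trajectory"}: a data.frame with columns
#'   \code{time_h}, \code{li_um}, \code{l_um}, \code{lr_um},
#'   \code{p_osm_bar}, \code{p_turg_bar}, with the parameters and schedule
#'   attached as attributes.
#' @examples
#' sch <- growth_schedule(a1 = 0.69, a2 = 5.04, li0 = 17.05, li_max = 34.1)
#' tr <- simulate_cell(mech_params(), sch, t_end = 24.7)
#' summary(tr)
#' @export
simulate_cell <- function(params, schedule, t_end, dt = 0.01,
                          record_dt = 1, init = NULL) {
  if (t_end <= 0) stop("simulate_cell: t_end must be > 0")
  if (dt <= 0 || dt > t_end) stop("simulate_cell: invalid dt")
  every <- round(record_dt / dt)
  if (abs(every * dt - record_dt) > 1e-9)
    stop("simulate_cell: record_dt must be a multiple of dt")
  if (is.null(init)) init <- initial_cell_state(schedule$li0, params)
  n_steps <- ceiling(t_end / dt - 1e-9)
  n_rec <- floor(n_steps / every) + 1L
  out <- matrix(NA_real_, n_rec, 6L)
  li <- init$li; l <- init$l; lr <- init$lr
  t0 <- schedule$t0
  rec <- 1L
  out[1L, ] <- c(t0, li, l, lr,
                 params$alpha * (li - l) / l,
                 params$beta * (l - lr) / lr)
  for (s in seq_len(n_steps)) {
    t_mid <- t0 + (s - 0.5) * dt   # slope taken at mid-step time
    st <- step_lengths(li, l, lr, schedule_rate(t_mid, schedule), dt, params)
    li <- st$li; l <- st$l; lr <- st$lr
    if (!is.finite(l) || l <= 0)
      stop("simulate_cell: integration failed (non-positive length) at t = ",
           format(t0 + s * dt))
    if (s %% every == 0L) {
      rec <- rec + 1L
      out[rec, ] <- c(t0 + s * dt, li, l, lr,
                      params$alpha * (li - l) / l,
                      params$beta * (l - lr) / lr)
    }
  }
  out <- as.data.frame(out[seq_len(rec), , drop = FALSE])
  names(out) <- c("time_h", "li_um", "l_um", "lr_um", "p_osm_bar",
                  "p_turg_bar")
  structure(out, class = c("cell_trajectory", "data.frame"),
            params = params, schedule = schedule, dt = dt)
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("Isolated-cell trajectory: %d samples, t in [%.3g, %.3g] h\n",
              nrow(x), x$time_h[1], x$time_h[nrow(x)]))
  cat(sprintf("  final l = %.4g um, li = %.4g um, lr = %.4g um\n",
              x$l_um[nrow(x)], x$li_um[nrow(x)], x$lr_um[nrow(x)]))
  cat(sprintf("  final P_osm = %.4g bar, P_turg = %.4g bar\n",
              x$p_osm_bar[nrow(x)], x$p_turg_bar[nrow(x)]))
  invisible(x)
}

#' @export
summary.cell_trajectory <- function(object, transient_frac = 0.5, ...) {
  n <- nrow(object)
  tail_rows <- object[object$time_h >=
                        object$time_h[1] + transient_frac *
                        (object$time_h[n] - object$time_h[1]), ]
  res <- list(
    n = n,
    t_range = range(object$time_h),
    final = object[n, ],
    plateau_p_osm = mean(tail_rows$p_osm_bar),
    plateau_p_turg = mean(tail_rows$p_turg_bar),
    max_abs_dev = max(abs(tail_rows$p_osm_bar - tail_rows$p_turg_bar))
  )
  class(res) <- "summary.cell_trajectory"
  res
}

#' @export
print.summary.cell_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory over t in [%.3g, %.3g] h (%d samples)\n",
              x$t_range[1], x$t_range[2], x$n))
  cat(sprintf("  post-transient mean P_osm  = %.4g bar\n", x$plateau_p_osm))
  cat(sprintf("  post-transient mean P_turg = %.4g bar\n", x$plateau_p_turg))
  cat(sprintf("  max |P_osm - P_turg| after transient = %.3g bar\n",
              x$max_abs_dev))
  invisible(x)
}

#' @export
plot.cell_trajectory <- function(x, which = c("lengths", "pressures"), ...) {
  which <- match.arg(which)
  if (which == "lengths") {
    graphics::matplot(x$time_h, cbind(x$li_um, x$l_um, x$lr_um), type = "l",
                      lty = 1, col = c("black", "forestgreen", "grey50"),
                      xlab = "time (h)", ylab = "length (um)", ...)
    graphics::legend("topleft", c("isosmotic", "visible", "relaxed"),
                     col = c("black", "forestgreen", "grey50"), lty = 1,
                     bty = "n")
  } else {
    graphics::matplot(x$time_h, cbind(x$p_osm_bar, x$p_turg_bar), type = "l",
                      lty = 1, col = c("steelblue", "firebrick"),
                      xlab = "time (h)", ylab = "pressure (bar)", ...)
    graphics::legend("topright", c("osmotic", "turgor"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write a trajectory to a tidy CSV file
#'
#' @param x a \code{"cell_trajectory"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Estimate the wall-growth coefficient eta
#'
#' Scans a grid of eta values in (0, 1), runs the isolated-cell model over
#' one cell cycle for each, and returns the grid point minimizing the
#' time-integrated absolute deviation between turgor and osmotic pressure
#' (trapezoidal rule on a fine sampling grid). The integral (rather than,
#' say, the pointwise maximum) is used as the deviation measure.
#'
#' @param params a [mech_params()]; its \code{eta} entry is ignored.
#' @param schedule a [growth_schedule()]; the cell cycle is taken as the
#'   time from birth to the schedule's switch point.
#' @param grid eta values to scan, all inside (0, 1).
#' @param dt integrator step (h).
#' @param sample_dt sampling cadence for the objective integral (h).
#' @return the selected eta (numeric scalar) with the full objective curve
#'   attached as attribute \code{"objective"} (data.frame eta, deviation).
#' @export
estimate_eta <- function(params, schedule,
                         grid = seq(0.05, 0.95, by = 0.05),
                         dt = 0.01, sample_dt = 0.1) {
  if (length(grid) == 0L) stop("estimate_eta: empty eta grid")
  if (any(grid <= 0 | grid >= 1)) stop("estimate_eta: grid must be in (0,1)")
  cycle <- schedule$t_switch - schedule$t0
  obj <- vapply(grid, function(e) {
    p <- params; p$eta <- e
    tr <- simulate_cell(p, schedule, t_end = cycle, dt = dt,
                        record_dt = sample_dt)
    dev <- abs(tr$p_turg_bar - tr$p_osm_bar)
    tt <- tr$time_h
    sum(diff(tt) * (dev[-1] + dev[-length(dev)]) / 2)
  }, numeric(1))
  structure(grid[which.min(obj)],
            objective = data.frame(eta = grid, deviation = obj))
}
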