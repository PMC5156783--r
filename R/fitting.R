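# Kinematic fitting: interval averaging of cell-length profiles, the
# weighted least-squares cost, the inverse problem recovering the biomass
# schedule from visible-length landmarks, grid + golden-section fitting of
# the growth rates, and sensitivity analysis of the mechanical parameters.

#' Interval edges for axial profile averaging
#'
#' The classic kinematic averaging scheme: fine intervals near the leaf
#' base where cells are small and numerous, coarser intervals distally.
#' By default 0.5 mm intervals up to 4 mm, 1.0 mm up to 10 mm and 2.0 mm
#' beyond.
#'
#' @param max_mm distal end of the scheme (mm); rounded up to a whole
#'   interval.
#' @param widths interval widths (mm) of the three parts.
#' @param breaks boundaries (mm) between the three parts.
#' @return numeric vector of interval edges (mm), starting at 0.
#' @export
interval_scheme <- function(max_mm = 34, widths = c(0.5, 1, 2),
                            breaks = c(4, 10)) {
  stopifnot(length(widths) == 3L, length(breaks) == 2L,
            breaks[1] < breaks[2], max_mm > breaks[2])
  c(seq(0, breaks[1], by = widths[1]),
    seq(breaks[1] + widths[2], breaks[2], by = widths[2]),
    seq(breaks[2] + widths[3], breaks[2] + widths[3] *
          ceiling((max_mm - breaks[2]) / widths[3]), by = widths[3]))
}

#' Interval-averaged cell length profile
#'
#' Averages visible cell lengths over distance intervals from the leaf
#' base. Each cell is assigned to exactly one interval by its midpoint
#' position. Empty intervals are kept with \code{NA} mean and flagged.
#'
#' @param position_mm cell midpoint positions (mm from the base).
#' @param length_um visible cell lengths (um).
#' @param edges interval edges (mm), e.g. from [interval_scheme()].
#' @return A \code{"length_profile"}: data.frame with columns
#'   \code{interval_start_mm}, \code{interval_end_mm},
#'   \code{mean_length_um}, \code{sem_um}, \code{n_cells}.
#' @export
profile_average <- function(position_mm, length_um, edges) {
  if (length(position_mm) == 0L)
    stop("profile_average: no cells to average")
  if (length(position_mm) != length(length_um))
    stop("profile_average: positions and lengths differ in length")
  nb <- length(edges) - 1L
  bin <- findInterval(position_mm, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  bin <- factor(bin[keep], levels = seq_len(nb))
  x <- length_um[keep]
  n <- as.integer(table(bin))
  mu <- as.numeric(tapply(x, bin, mean))
  sdv <- as.numeric(tapply(x, bin, stats::sd))
  out <- data.frame(
    interval_start_mm = edges[-length(edges)],
    interval_end_mm = edges[-1],
    mean_length_um = mu,
    sem_um = ifelse(n > 1L, sdv / sqrt(n), 0),
    n_cells = n
  )
  structure(out, class = c("length_profile", "data.frame"),
            empty_intervals = which(n == 0L))
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("Cell-length profile: %d intervals over [0, %g] mm, %d cells\n",
              nrow(x), x$interval_end_mm[nrow(x)], sum(x$n_cells)))
  ei <- attr(x, "empty_intervals")
  if (length(ei)) cat("  empty intervals:", paste(ei, collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 12), digits = 4)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more intervals\n")
  invisible(x)
}

#' @export
plot.length_profile <- function(x, add = FALSE, col = "black", ...) {
  mid <- (x$interval_start_mm + x$interval_end_mm) / 2
  if (!add)
    graphics::plot(mid, x$mean_length_um, pch = 16, col = col,
                   xlab = "distance from base (mm)",
                   ylab = "mean cell length (um)", ...)
  else graphics::points(mid, x$mean_length_um, pch = 16, col = col)
  ok <- !is.na(x$mean_length_um)
  graphics::arrows(mid[ok], (x$mean_length_um - x$sem_um)[ok],
                   mid[ok], (x$mean_length_um + x$sem_um)[ok],
                   angle = 90, code = 3, length = 0.02, col = col)
  invisible(x)
}

#' Profile of a simulated leaf
#'
#' Convenience wrapper: interval-averages the final snapshot of a
#' [run_simulation()] result.
#'
#' @param sim a \code{"leaf_sim"}.
#' @param edges interval edges (mm); default an [interval_scheme()] covering
#'   the simulated leaf.
#' @return a \code{"length_profile"}.
#' @export
sim_length_profile <- function(sim, edges = NULL) {
  if (is.null(edges))
    edges <- interval_scheme(max_mm = max(12, ceiling(sum(sim$lambda) / 1000)))
  profile_average(sim$cells$position_mm, sim$cells$l, edges)
}

#' Weighted profile mismatch cost
#'
#' Weighted sum of squared differences between two interval-averaged
#' profiles: \code{sum_i k_i (m_i - e_i)^2} with weights proportional to
#' the interval index (\code{k_i = i / sum(i)}), giving greater weight to
#' distal intervals so that the few large cells there are not swamped by
#' the many small basal cells. Intervals empty in either profile are
#' excluded and the weights renormalized.
#'
#' @param model,exp two \code{"length_profile"}s on the same edges.
#' @return the cost (um^2, dimensionless weighting).
#' @export
profile_cost <- function(model, exp) {
  if (nrow(model) != nrow(exp) ||
      max(abs(model$interval_start_mm - exp$interval_start_mm)) > 1e-9 ||
      max(abs(model$interval_end_mm - exp$interval_end_mm)) > 1e-9)
    stop("profile_cost: interval schemes do not match")
  i <- seq_len(nrow(model))
  ok <- !is.na(model$mean_length_um) & !is.na(exp$mean_length_um)
  if (!any(ok)) stop("profile_cost: no jointly non-empty intervals")
  k <- i[ok] / sum(i[ok])
  sum(k * (model$mean_length_um[ok] - exp$mean_length_um[ok])^2)
}

#' Golden-section minimization of a 1-D function
#'
#' Plain golden-ratio section search on a unimodal function.
#'
#' @param f function of one variable.
#' @param lower,upper bracket.
#' @param tol absolute tolerance on the argument.
#' @return list with \code{minimum} (the argument) and \code{objective}.
#' @export
golden_section <- function(f, lower, upper, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  xm <- (a + b) / 2
  list(minimum = xm, objective = f(xm))
}

# Visible length of an isolated cell at time t (h after birth). Internal.
visible_length_at <- function(params, schedule, t, dt = 0.01) {
  tr <- simulate_cell(params, schedule, t_end = t, dt = dt, record_dt = dt)
  tr$l_um[nrow(tr)]
}

#' Recover the biomass growth schedule from visible-length landmarks
#'
#' Solves the inverse problem of the single-cell model: find the
#' piecewise-linear isosmotic schedule such that the cell's *visible*
#' length matches the experimental landmarks — \code{l0} at birth,
#' \code{l_div} at the end of the mean division-zone cycle \code{t_div},
#' and \code{l_elong} at \code{t_div + t_elong}. With the isotonic newborn
#' state the birth constraint pins \code{li0 = l0} directly; \code{a1} is
#' then found by root bracketing on the visible length at \code{t_div}
#' (with \code{li_max = li0 + a1 t_div}, the schedule's switch point), and
#' \code{a2} by root bracketing on the visible length at
#' \code{t_div + t_elong}.
#'
#' @param constants a [kinematic_constants()].
#' @param params a [mech_params()].
#' @param dt integrator step (h).
#' @param a1_bracket,a2_bracket root-search brackets (um/h).
#' @return An \code{"inverse_solution"}: list with the recovered
#'   \code{schedule} (a [growth_schedule()]), the components \code{a1},
#'   \code{a2}, \code{li0}, \code{li_max}, and the replayed visible lengths
#'   \code{l_div_fit}, \code{l_elong_fit}.
#' @examples
#' \donttest{
#' inv <- solve_inverse_problem()
#' coef(inv)
#' }
#' @export
solve_inverse_problem <- function(constants = kinematic_constants(),
                                  params = mech_params(), dt = 0.01,
                                  a1_bracket = c(0.2, 4),
                                  a2_bracket = NULL) {
  li0 <- constants$l0   # isotonic newborn state: l(0) = li(0)
  t_div <- constants$t_div
  sched1 <- function(a1)
    growth_schedule(a1, a2 = 2 * a1 + 1, li0 = li0,
                    li_max = li0 + a1 * t_div, t_elong = constants$t_elong)
  f1 <- function(a1)
    visible_length_at(params, sched1(a1), t_div, dt) - constants$l_div
  r1 <- stats::uniroot(f1, a1_bracket, tol = 1e-7)
  a1 <- r1$root
  li_max <- li0 + a1 * t_div
  if (is.null(a2_bracket)) a2_bracket <- c(a1 * 1.05, 25)
  t_end <- t_div + constants$t_elong
  sched2 <- function(a2)
    growth_schedule(a1, a2, li0 = li0, li_max = li_max,
                    t_elong = constants$t_elong)
  f2 <- function(a2)
    visible_length_at(params, sched2(a2), t_end, dt) - constants$l_elong
  r2 <- stats::uniroot(f2, a2_bracket, tol = 1e-7)
  a2 <- r2$root
  schedule <- sched2(a2)
  structure(list(
    schedule = schedule, a1 = a1, a2 = a2, li0 = li0, li_max = li_max,
    l_div_fit = visible_length_at(params, schedule, t_div, dt),
    l_elong_fit = visible_length_at(params, schedule, t_end, dt),
    constants = constants, params = params, dt = dt
  ), class = "inverse_solution")
}

#' @export
print.inverse_solution <- function(x, ...) {
  cat("Inverse problem solution (isosmotic schedule from visible lengths):\n")
  cat(sprintf("  a1 = %.4f um/h, a2 = %.4f um/h\n", x$a1, x$a2))
  cat(sprintf("  li0 = %.3f um, li_max = %.3f um\n", x$li0, x$li_max))
  cat(sprintf("  replay: l(t_div) = %.3f um (target %.2f), l(t_div+t_elong) = %.2f um (target %.1f)\n",
              x$l_div_fit, x$constants$l_div, x$l_elong_fit,
              x$constants$l_elong))
  invisible(x)
}

#' @export
coef.inverse_solution <- function(object, ...)
  c(a1 = object$a1, a2 = object$a2, li0 = object$li0,
    li_max = object$li_max)

#' Default wheat-leaf growth schedule
#'
#' The schedule used for tissue simulations of the wheat leaf: internal
#' quantities \code{li0} and \code{li_max} come from the inverse problem
#' (visible-length landmarks), while the growth rates default to the
#' reference fitted values a1 = 0.69, a2 = 5.04 um/h.
#'
#' @param a1,a2 slow and fast isosmotic growth rates (um/h).
#' @param constants a [kinematic_constants()].
#' @param params a [mech_params()].
#' @param inverse optionally a precomputed [solve_inverse_problem()] result
#'   (avoids re-solving).
#' @return a [growth_schedule()].
#' @export
wheat_schedule <- function(a1 = 0.69, a2 = 5.04,
                           constants = kinematic_constants(),
                           params = mech_params(), inverse = NULL) {
  if (is.null(inverse))
    inverse <- solve_inverse_problem(constants, params)
  growth_schedule(a1, a2, li0 = inverse$li0, li_max = inverse$li_max,
                  t_elong = constants$t_elong)
}

#' Fit the growth rates to an experimental cell-length profile
#'
#' Minimizes the weighted profile cost of a full tissue simulation against
#' an interval-averaged cell-length profile: grid enumeration of the slow
#' rate \code{a1} with, for each grid point, golden-section adjustment of
#' the fast rate \code{a2}. Simulations during fitting use a fixed seed and
#' a reduced number of files, so the procedure is deterministic.
#'
#' @param exp_profile a \code{"length_profile"} (the fitting target).
#' @param params a [mech_params()].
#' @param constants a [kinematic_constants()] (poses the inverse problem
#'   for the starting point and the internal lengths li0/li_max).
#' @param zonation a [zonation_config()] for the fitting simulations.
#' @param division a [division_rule()].
#' @param n_files files per fitting simulation (default 10).
#' @param seed fixed seed for all fitting simulations.
#' @param dt integrator step (h).
#' @param a1_grid grid of slow rates; default 17 points spanning 60--140\%
#'   of the inverse-problem start.
#' @param a2_bracket golden-section bracket for \code{a2}; default from the
#'   inverse-problem start.
#' @param a2_tol golden-section tolerance (um/h).
#' @param sim_max_time cap (h) on each candidate simulation; candidates
#'   whose leaf cannot reach the stop length in this time score an
#'   infinite cost instead of stalling the search.
#' @param start optionally a precomputed [solve_inverse_problem()].
#' @return A \code{"growth_fit"}: list with \code{a1}, \code{a2},
#'   \code{cost}, the evaluation \code{trace}, the \code{start} point and
#'   the resolved configuration.
#' @export
fit_growth_rates <- function(exp_profile, params = mech_params(),
                             constants = kinematic_constants(),
                             zonation = zonation_config(),
                             division = division_rule(), n_files = 10,
                             seed = 1L, dt = 0.01, a1_grid = NULL,
                             a2_bracket = NULL, a2_tol = 0.02,
                             sim_max_time = 400, start = NULL) {
  if (is.null(start)) start <- solve_inverse_problem(constants, params, dt)
  if (is.null(a1_grid)) a1_grid <- start$a1 * seq(0.6, 1.4, by = 0.05)
  if (is.null(a2_bracket))
    a2_bracket <- c(max(1.05 * max(a1_grid), 0.4 * start$a2), 2.5 * start$a2)
  zon_fit <- zonation
  zon_fit$max_time <- min(zonation$max_time, sim_max_time)
  edges <- c(exp_profile$interval_start_mm[1], exp_profile$interval_end_mm)
  trace <- list()
  evalcost <- function(a1, a2) {
    sch <- growth_schedule(a1, a2, li0 = start$li0, li_max = start$li_max,
                           t_elong = constants$t_elong)
    sim <- tryCatch(
      run_simulation(n_files = n_files, params = params,
                     schedule = sch, zonation = zon_fit,
                     division = division, dt = dt, seed = seed,
                     record = "none"),
      error = function(e) NULL)
    cost <- if (is.null(sim)) Inf else
      profile_cost(profile_average(sim$cells$position_mm,
                                   sim$cells$l, edges), exp_profile)
    if (is.nan(cost)) stop("fit_growth_rates: non-finite cost")
    trace[[length(trace) + 1L]] <<- c(a1 = a1, a2 = a2, cost = cost)
    cost
  }
  best <- NULL
  for (a1 in a1_grid) {
    gs <- golden_section(function(a2) evalcost(a1, a2),
                         a2_bracket[1], a2_bracket[2], tol = a2_tol)
    if (is.null(best) || gs$objective < best$cost)
      best <- list(a1 = a1, a2 = gs$minimum, cost = gs$objective)
  }
  structure(list(
    a1 = best$a1, a2 = best$a2, cost = best$cost,
    trace = as.data.frame(do.call(rbind, trace)),
    start = start, seed = seed, n_files = n_files,
    params = params, constants = constants, zonation = zonation
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth-rate fit: a1 = %.4g, a2 = %.4g um/h (cost %.4g)\n",
    x$a1, x$a2, x$cost))
  cat(sprintf("  start (inverse problem): a1 = %.4g, a2 = %.4g; %d cost evaluations\n",
              x$start$a1, x$start$a2, nrow(x$trace)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...)
  c(a1 = object$a1, a2 = object$a2)

#' Sensitivity of the final visible length to the mechanical parameters
#'
#' Simulates isolated-cell growth over a fixed horizon while varying each
#' mechanical parameter over an equispaced grid spanning +/- \code{rel_range}
#' of its reference value, and reports the least-squares slope of the final
#' visible length with respect to the parameter.
#'
#' @param params reference [mech_params()].
#' @param schedule a [growth_schedule()].
#' @param horizon simulation horizon (h), default 24.
#' @param rel_range relative probe range (default 0.10).
#' @param n_probe probe points per parameter (default 11).
#' @param dt integrator step (h).
#' @param parameters which parameters to probe.
#' @return data.frame with columns \code{parameter}, \code{reference},
#'   \code{sensitivity} (um per parameter unit) and \code{n_ok} (probe
#'   points that integrated successfully).
#' @export
sensitivity_analysis <- function(params = mech_params(), schedule,
                                 horizon = 24, rel_range = 0.10,
                                 n_probe = 11, dt = 0.01,
                                 parameters = c("Lw", "alpha", "beta",
                                                "eta", "Pc")) {
  rows <- lapply(parameters, function(nm) {
    v0 <- params[[nm]]
    vals <- v0 * seq(1 - rel_range, 1 + rel_range, length.out = n_probe)
    lfin <- vapply(vals, function(v) {
      p <- params; p[[nm]] <- v
      tryCatch(visible_length_at(p, schedule, horizon, dt),
               error = function(e) NA_real_)
    }, numeric(1))
    ok <- is.finite(lfin)
    slope <- if (sum(ok) >= 2L)
      unname(stats::coef(stats::lm(lfin[ok] ~ vals[ok]))[2]) else NA_real_
    data.frame(parameter = nm, reference = v0, sensitivity = slope,
               n_ok = sum(ok))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("Sensitivity of final visible length to mechanical parameters\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
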