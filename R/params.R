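#' Mechanical parameters of the cell model
#'
#' Bundles the five mechanical constants of the length-based cell model plus
#' the cell cross-section half-width. Defaults are the values adopted for
#' wheat leaf epidermis: hydraulic conductivity \code{Lw} = 40 (per um per h
#' per bar), osmotic-pressure coefficient \code{alpha} = 10 bar,
#' turgor-pressure coefficient \code{beta} = 100 bar, wall-growth
#' proportionality \code{eta} = 0.15, turgor yield threshold \code{Pc} = 2
#' bar, and cell width/thickness \code{r} = 4 um.
#'
#' Units are fixed throughout the package as um / h / bar. \code{r * Lw}
#' carries units of per-hour per-bar, i.e. it converts a pressure imbalance
#' into a specific (relative) growth rate of the visible length. Note that
#' the per-um reading of \code{Lw} is the one consistent with this; the
#' alternative um-per-hour-per-bar reading found in some descriptions refers
#' to the product \code{r * Lw / r^2} of the volumetric formulation.
#'
#' @param Lw hydraulic conductivity of the cell wall (per um per h per bar).
#' @param alpha coefficient of osmotic pressure (bar); equals c_out * R * T
#'   of the Van't Hoff relation absorbed into one constant.
#' @param beta coefficient of turgor pressure (bar); absorbs the wall
#'   Young's modulus and the wall/lumen cross-section ratio.
#' @param eta dimensionless proportionality between wall (relaxed length)
#'   growth rate and biomass (isosmotic length) growth rate.
#' @param Pc turgor threshold below which the wall does not yield (bar).
#' @param r cell cross-section width and thickness (um).
#' @return An object of class \code{"mech_params"} (a validated named list).
#' @examples
#' p <- mech_params()
#' p$alpha
#' @export
mech_params <- function(Lw = 40, alpha = 10, beta = 100, eta = 0.15,
                        Pc = 2, r = 4) {
  p <- list(Lw = Lw, alpha = alpha, beta = beta, eta = eta, Pc = Pc, r = r)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("mech_params: '", nm, "' must be a single strictly positive number")
  }
  structure(p, class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Mechanical parameters (um / h / bar):\n")
  cat(sprintf("  Lw = %g, alpha = %g, beta = %g, eta = %g, Pc = %g, r = %g\n",
              x$Lw, x$alpha, x$beta, x$eta, x$Pc, x$r))
  invisible(x)
}

#' Piecewise-linear growth schedule for the isosmotic length
#'
#' The isosmotic length (the model's proxy for dry biomass) of a cell grows
#' linearly at a slow rate \code{a1} from its birth value \code{li0} until it
#' reaches the critical value \code{li_max}, then at a fast rate \code{a2}
#' for the elongation duration \code{t_elong}, after which it is constant.
#' By construction the switch happens at \code{t0 + (li_max - li0)/a1}.
#'
#' @param a1 slow (division/transition-zone) isosmotic growth rate (um/h).
#' @param a2 fast (elongation-zone) isosmotic growth rate (um/h); must
#'   exceed \code{a1}.
#' @param li0 initial isosmotic length at birth (um).
#' @param li_max critical isosmotic length triggering division (in the
#'   division zone) or the switch to fast growth (outside it) (um).
#' @param t_elong duration of the fast-growth phase (h).
#' @param t0 birth time (h).
#' @return An object of class \code{"growth_schedule"} with the derived
#'   switch time \code{t_switch} attached.
#' @seealso [isosmotic_length()], [simulate_cell()]
#' @export
growth_schedule <- function(a1, a2, li0, li_max, t_elong = 71.09, t0 = 0) {
  if (!is.numeric(a1) || a1 <= 0) stop("growth_schedule: a1 must be > 0")
  if (!is.numeric(a2) || a2 <= a1) stop("growth_schedule: need a2 > a1")
  if (!is.numeric(li0) || li0 <= 0 || li0 >= li_max)
    stop("growth_schedule: need 0 < li0 < li_max")
  if (t_elong <= 0) stop("growth_schedule: t_elong must be > 0")
  structure(list(a1 = a1, a2 = a2, li0 = li0, li_max = li_max,
                 t_elong = t_elong, t0 = t0,
                 t_switch = t0 + (li_max - li0) / a1),
            class = "growth_schedule")
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat(sprintf(
    "Growth schedule: a1 = %.4g, a2 = %.4g um/h; li0 = %.4g, li_max = %.4g um\n",
    x$a1, x$a2, x$li0, x$li_max))
  cat(sprintf("  birth t0 = %.4g h, switch at %.4g h, elongation %.4g h\n",
              x$t0, x$t_switch, x$t_elong))
  invisible(x)
}

#' Longitudinal zonation of the leaf growth zone
#'
#' The growth zone is modelled as stationary with respect to the leaf base:
#' a division zone (DZ) of length \code{L_DZ}, a transition region where
#' cells still grow slowly but no longer divide, and an elongation zone, the
#' whole growth zone spanning \code{L_GZ}. A cell whose midpoint passes
#' \code{L_GZ} stops growing (matures). The simulation stops once the leaf
#' reaches \code{stop_length} or the clock reaches \code{max_time}.
#'
#' @param L_DZ division-zone length (mm).
#' @param L_GZ growth-zone length (mm).
#' @param stop_length target leaf length at which a simulation stops (mm);
#'   default the growth zone plus a 40\% mature-tissue margin.
#' @param max_time maximum simulated time (h).
#' @return An object of class \code{"zonation_config"}.
#' @export
zonation_config <- function(L_DZ = 3.3, L_GZ = 23.8,
                            stop_length = 1.4 * L_GZ, max_time = 2000) {
  if (!(L_DZ > 0 && L_GZ > L_DZ))
    stop("zonation_config: need 0 < L_DZ < L_GZ")
  if (stop_length <= L_DZ) stop("zonation_config: stop_length too small")
  if (max_time <= 0) stop("zonation_config: max_time must be > 0")
  structure(list(L_DZ = L_DZ, L_GZ = L_GZ, stop_length = stop_length,
                 max_time = max_time),
            class = "zonation_config")
}

#' Stochastic division rule
#'
#' At division the mother's lengths are split between the daughters in the
#' proportion d / (1 - d), where the division factor d is drawn from a
#' normal distribution truncated to \code{bounds}.
#'
#' @param mu_d mean of the division factor (default 0.5).
#' @param sigma_d standard deviation (default 0.1).
#' @param bounds length-2 truncation interval, default (0.1, 0.9).
#' @return An object of class \code{"division_rule"}.
#' @export
division_rule <- function(mu_d = 0.5, sigma_d = 0.1, bounds = c(0.1, 0.9)) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2] ||
      bounds[1] <= 0 || bounds[2] >= 1)
    stop("division_rule: bounds must be inside (0, 1) and increasing")
  if (sigma_d <= 0) stop("division_rule: sigma_d must be > 0")
  if (mu_d <= bounds[1] || mu_d >= bounds[2])
    stop("division_rule: mu_d must lie inside bounds")
  structure(list(mu_d = mu_d, sigma_d = sigma_d, bounds = bounds),
            class = "division_rule")
}

#' Draw division factors
#'
#' Rejection sampling from N(mu_d, sigma_d) until the draw falls inside the
#' truncation bounds (equivalent to inverse-CDF truncated-normal sampling).
#'
#' @param n number of draws.
#' @param rule a [division_rule()].
#' @return numeric vector of division factors, all inside \code{rule$bounds}.
#' @export
rdivision_factor <- function(n, rule = division_rule()) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      d <- stats::rnorm(1L, rule$mu_d, rule$sigma_d)
      if (d > rule$bounds[1] && d < rule$bounds[2]) break
    }
    out[i] <- d
  }
  out
}

#' Reference kinematic constants for the wheat leaf
#'
#' Experimental summary values for the wheat leaf growth zone used to pose
#' the inverse problem: zone lengths (mm), the mean division-zone cell cycle
#' t_div and elongation period t_elong (h), and the mean visible cell
#' lengths at birth (l0), at the end of the division period (l_div) and at
#' the end of elongation (l_elong) (um).
#'
#' @param L_GZ,L_DZ,L_EZ growth/division/elongation zone lengths (mm).
#' @param t_div mean cell cycle duration in the division zone (h).
#' @param t_elong mean elongation period (h).
#' @param l0,l_div,l_elong mean visible cell lengths (um).
#' @return An object of class \code{"table_constants"} (named list).
#' @export
kinematic_constants <- function(L_GZ = 23.8, L_DZ = 3.3, L_EZ = 20.5,
                                t_div = 24.7, t_elong = 71.09,
                                l0 = 14.74, l_div = 29.48, l_elong = 197.2) {
  stopifnot(L_DZ > 0, L_GZ > L_DZ, t_div > 0, t_elong > 0,
            0 < l0, l0 < l_div, l_div < l_elong)
  structure(list(L_GZ = L_GZ, L_DZ = L_DZ, L_EZ = L_EZ, t_div = t_div,
                 t_elong = t_elong, l0 = l0, l_div = l_div,
                 l_elong = l_elong),
            class = "table_constants")
}
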