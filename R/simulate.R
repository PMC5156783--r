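#' Simulate the growth of the leaf epidermis
#'
#' Runs the full symplastic tissue simulation: builds (or takes) an initial
#' tissue of \code{n_files} cell files spanning the division zone, then
#' advances the coupled fragment system until the leaf reaches the
#' configured stop length. All randomness (initial desynchronization and
#' division factors) flows from \code{seed}; reruns with the same seed are
#' bit-identical.
#'
#' @param n_files number of cell files.
#' @param params a [mech_params()].
#' @param schedule template [growth_schedule()] shared by all cells.
#' @param zonation a [zonation_config()]; its \code{stop_length} (mm) is the
#'   stop rule. Use \code{stop_length = Inf} with a finite \code{max_time}
#'   for a duration-limited run.
#' @param division a [division_rule()].
#' @param dt integrator step (h).
#' @param seed integer seed.
#' @param record \code{"none"} (counts, lifespans, final snapshot and the
#'   running turgor maximum only), \code{"pressures"} (additionally per-cell
#'   osmotic/turgor series at whole hours of each cell's life, up to
#'   \code{horizon} hours), or \code{"full"} (additionally visible and
#'   isosmotic length series).
#' @param horizon recorded hours per cell (default 75).
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference
#'   implementation; identical semantics, for small problems and testing).
#' @param tissue optional pre-built \code{"leaf_tissue"} starting state
#'   (then \code{n_files} etc. are taken from it).
#' @param verbose print one progress line per 10 simulated hours (leaf
#'   length, cell count, running turgor maximum).
#' @return A \code{"leaf_sim"} object: final \code{cells} snapshot (with
#'   positions, pressures and zones), the per-cell \code{log} (birth/end
#'   times, lifespans, parentage), the final fragment partition, cadence
#'   recordings if requested, the running maximum turgor, and the resolved
#'   configuration.
#' @examples
#' sch <- growth_schedule(a1 = 0.69, a2 = 5.04, li0 = 14.74,
#'                        li_max = 14.74 + 0.69 * 24.7)
#' zo <- zonation_config(L_DZ = 0.2, L_GZ = 1, stop_length = 1.2)
#' sim <- run_simulation(n_files = 3, schedule = sch, zonation = zo,
#'                       seed = 1, record = "none")
#' sim
#' @export
run_simulation <- function(n_files = 100, params = mech_params(), schedule,
                           zonation = zonation_config(),
                           division = division_rule(), dt = 0.01, seed = 1L,
                           record = c("pressures", "none", "full"),
                           horizon = 75L, engine = c("cpp", "r"),
                           tissue = NULL, verbose = FALSE) {
  record <- match.arg(record)
  engine <- match.arg(engine)
  rec_lev <- match(record, c("none", "pressures", "full")) - 1L
  set.seed(seed)
  if (is.null(tissue))
    tissue <- build_initial_tissue(n_files, params, schedule, zonation,
                                   division)
  else
    n_files <- tissue$n_files
  cfg <- list(dt = dt, L_DZ_um = zonation$L_DZ * 1000,
              L_GZ_um = zonation$L_GZ * 1000,
              stop_um = zonation$stop_length * 1000,
              max_time = zonation$max_time, record = rec_lev,
              horizon = as.integer(horizon), divide = TRUE,
              verbose = verbose)
  res <- if (engine == "cpp") .engine_run(tissue, cfg)
         else r_engine_run(tissue, cfg)
  if (res$stopped_by == "time" && is.finite(cfg$stop_um))
    stop("run_simulation: leaf did not reach the stop length within ",
         "max_time = ", zonation$max_time, " h (reached ",
         format(sum(res$lambda) / 1000), " mm)")
  cells <- res$cells
  cells$position_mm <- cells$position_um / 1000
  cells$p_osm <- osmotic_pressure(cells$li, cells$l, params)
  cells$p_turg <- turgor_pressure(cells$l, cells$lr, params)
  log <- res$log
  log$lifespan <- log$t_end - log$t0
  structure(list(
    cells = cells, log = log, lambda = res$lambda,
    membership = res$membership, clock = res$clock,
    n_created = res$n_created, max_turgor = res$max_turgor,
    pressures = res$pressures, l_rec = res$l_rec, li_rec = res$li_rec,
    horizon = as.integer(horizon), stopped_by = res$stopped_by,
    config = list(n_files = n_files, params = params, schedule = schedule,
                  zonation = zonation, division = division, dt = dt,
                  seed = seed, record = record, engine = engine)
  ), class = "leaf_sim")
}

# Pure-R engine: same semantics as the compiled path, built from
# step_tissue(); no cadence recording. Internal (reachable via
# run_simulation(engine = "r")).
r_engine_run <- function(tissue, cfg) {
  stop_um <- cfg$stop_um
  stopped <- "time"
  while (tissue$clock < cfg$max_time - 1e-9) {
    if (tissue_leaf_length(tissue) >= stop_um) { stopped <- "length"; break }
    tissue <- step_tissue(tissue, cfg$dt, divide = cfg$divide)
    if (tissue_leaf_length(tissue) >= stop_um) { stopped <- "length"; break }
  }
  cl <- tissue$cells
  pos <- cell_positions(tissue)
  log <- tissue$log
  log$t_end[is.na(log$t_end)] <- tissue$clock
  # report cells in file-major order with positions, like the engine
  list(cells = data.frame(cl[c("id", "file", "li", "l", "lr", "li0", "t0",
                               "t_switch", "zone")],
                          position_um = pos, stringsAsFactors = FALSE),
       log = log, lambda = tissue$lambda, membership = tissue$membership,
       clock = tissue$clock, n_created = tissue$n_created,
       max_turgor = tissue$max_turgor, pressures = NULL, l_rec = NULL,
       li_rec = NULL, stopped_by = stopped)
}

#' @export
print.leaf_sim <- function(x, ...) {
  cat(sprintf(
    "Leaf simulation: %d files, leaf length %.3g mm at t = %.4g h\n",
    x$config$n_files, sum(x$lambda) / 1000, x$clock))
  cat(sprintf(
    "  %d cells alive, %d created in total, max turgor %.3g bar\n",
    nrow(x$cells), x$n_created, x$max_turgor))
  cat(sprintf("  max lifespan %.3g h; stopped by %s\n",
              max(x$log$lifespan), x$stopped_by))
  invisible(x)
}

#' @export
summary.leaf_sim <- function(object, ...) {
  z <- table(factor(object$cells$zone, levels = ZONES))
  res <- list(
    n_files = object$config$n_files,
    leaf_mm = sum(object$lambda) / 1000,
    clock = object$clock,
    n_alive = nrow(object$cells),
    n_created = object$n_created,
    n_divisions = sum(object$log$divided),
    max_turgor = object$max_turgor,
    max_lifespan = max(object$log$lifespan),
    mean_cycle = if (any(object$log$divided))
      mean(object$log$lifespan[object$log$divided]) else NA_real_,
    zones = z
  )
  class(res) <- "summary.leaf_sim"
  res
}

#' @export
print.summary.leaf_sim <- function(x, ...) {
  cat(sprintf("Leaf of %.3g mm after %.4g h (%d files)\n",
              x$leaf_mm, x$clock, x$n_files))
  cat(sprintf("  cells: %d alive / %d created; %d divisions\n",
              x$n_alive, x$n_created, x$n_divisions))
  cat(sprintf("  mean completed cell cycle %.3g h; max lifespan %.3g h\n",
              x$mean_cycle, x$max_lifespan))
  cat(sprintf("  max turgor %.3g bar\n", x$max_turgor))
  print(x$zones)
  invisible(x)
}

#' @export
plot.leaf_sim <- function(x, what = c("lengths", "pressures"), ...) {
  what <- match.arg(what)
  cl <- x$cells
  if (what == "lengths") {
    graphics::plot(cl$position_mm, cl$l, pch = 16, cex = 0.3,
                   xlab = "distance from base (mm)",
                   ylab = "visible cell length (um)", ...)
  } else {
    graphics::plot(cl$position_mm, cl$p_osm, pch = 16, cex = 0.3,
                   col = "steelblue", xlab = "distance from base (mm)",
                   ylab = "pressure (bar)", ...)
    graphics::points(cl$position_mm, cl$p_turg, pch = 16, cex = 0.3,
                     col = "firebrick")
    graphics::legend("topright", c("osmotic", "turgor"),
                     col = c("steelblue", "firebrick"), pch = 16, bty = "n")
  }
  invisible(x)
}

#' Write state snapshots of a simulation
#'
#' Writes the final cells table and the fragment partition as CSV files.
#'
#' @param sim a \code{"leaf_sim"}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_snapshot <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  frag <- data.frame(k = seq_along(sim$lambda), lambda_um = sim$lambda)
  memb <- as.data.frame(sim$membership)
  names(memb) <- paste0("cell_file", seq_len(ncol(memb)))
  utils::write.csv(cbind(frag, memb), file.path(dir, "fragments.csv"),
                   row.names = FALSE)
  invisible(dir)
}
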