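# File formats: cell-length profile CSV, run configuration YAML, synthetic
# profile generation. All user-facing distances are in mm, lengths in um,
# pressures in bar, times in h.

PROFILE_COLUMNS <- c("interval_start_mm", "interval_end_mm",
                     "mean_length_um", "sem_um", "n_cells")

#' Read a cell-length profile from CSV
#'
#' Expects columns \code{interval_start_mm}, \code{interval_end_mm},
#' \code{mean_length_um}, \code{sem_um}, \code{n_cells}. Intervals must be
#' contiguous with strictly increasing edges; offending rows are reported
#' by number.
#'
#' @param path CSV file path.
#' @return a \code{"length_profile"}.
#' @export
read_length_profile <- function(path) {
  if (!file.exists(path)) stop("read_length_profile: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PROFILE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("read_length_profile: missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[PROFILE_COLUMNS]
  bad <- which(df$interval_end_mm <= df$interval_start_mm)
  if (length(bad))
    stop("read_length_profile: interval edges not increasing in row(s) ",
         paste(bad, collapse = ", "))
  if (nrow(df) > 1L) {
    gap <- which(abs(df$interval_start_mm[-1] -
                       df$interval_end_mm[-nrow(df)]) > 1e-9)
    if (length(gap))
      stop("read_length_profile: intervals not contiguous after row(s) ",
           paste(gap, collapse = ", "))
  }
  bad <- which(!is.na(df$mean_length_um) & df$mean_length_um <= 0)
  if (length(bad))
    stop("read_length_profile: non-positive mean length in row(s) ",
         paste(bad, collapse = ", "))
  structure(df, class = c("length_profile", "data.frame"),
            empty_intervals = which(df$n_cells == 0L))
}

#' Write a cell-length profile to CSV
#'
#' @param profile a \code{"length_profile"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_length_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[PROFILE_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Bundles all ingredients of a reproducible simulation run. Serializes
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param params a [mech_params()].
#' @param schedule a [growth_schedule()].
#' @param zonation a [zonation_config()].
#' @param division a [division_rule()].
#' @param n_files number of cell files.
#' @param dt integrator step (h).
#' @param seed integer seed.
#' @param record recording level (\code{"none"}, \code{"pressures"},
#'   \code{"full"}).
#' @return a \code{"run_config"} list.
#' @export
run_config <- function(params = mech_params(), schedule,
                       zonation = zonation_config(),
                       division = division_rule(), n_files = 100L,
                       dt = 0.01, seed = 1L, record = "pressures") {
  stopifnot(inherits(params, "mech_params"),
            inherits(schedule, "growth_schedule"),
            inherits(zonation, "zonation_config"),
            inherits(division, "division_rule"),
            n_files >= 1, dt > 0,
            record %in% c("none", "pressures", "full"))
  structure(list(params = params, schedule = schedule, zonation = zonation,
                 division = division, n_files = as.integer(n_files),
                 dt = dt, seed = as.integer(seed), record = record),
            class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  sch <- config$schedule
  obj <- list(
    mechanics = unclass(config$params)[c("Lw", "alpha", "beta", "eta",
                                         "Pc", "r")],
    schedule = list(a1 = sch$a1, a2 = sch$a2, li0 = sch$li0,
                    li_max = sch$li_max, t_elong = sch$t_elong),
    zonation = unclass(config$zonation),
    division = list(mu_d = config$division$mu_d,
                    sigma_d = config$division$sigma_d,
                    bounds = config$division$bounds),
    run = list(n_files = config$n_files, dt = config$dt,
               seed = config$seed, record = config$record)
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Missing sections fall back to package defaults; a missing schedule
#' section is filled by solving the inverse problem for the packaged
#' kinematic constants (with the reference fitted rates).
#'
#' @param path YAML file path.
#' @return a \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  obj <- yaml::read_yaml(path)
  params <- if (is.null(obj$mechanics)) mech_params()
            else do.call(mech_params, obj$mechanics)
  schedule <- if (is.null(obj$schedule)) wheat_schedule(params = params)
              else do.call(growth_schedule, obj$schedule)
  zonation <- if (is.null(obj$zonation)) zonation_config()
              else do.call(zonation_config, obj$zonation)
  division <- if (is.null(obj$division)) division_rule()
              else do.call(division_rule, obj$division)
  run <- obj$run
  run_config(params = params, schedule = schedule, zonation = zonation,
             division = division,
             n_files = if (is.null(run$n_files)) 100L else run$n_files,
             dt = if (is.null(run$dt)) 0.01 else run$dt,
             seed = if (is.null(run$seed)) 1L else run$seed,
             record = if (is.null(run$record)) "pressures" else run$record)
}

#' Run a simulation from a configuration
#'
#' @param config a [run_config()].
#' @param ... overrides passed on to [run_simulation()] (e.g. \code{seed},
#'   \code{verbose}).
#' @return a \code{"leaf_sim"}.
#' @export
run_from_config <- function(config, ...) {
  args <- list(n_files = config$n_files, params = config$params,
               schedule = config$schedule, zonation = config$zonation,
               division = config$division, dt = config$dt,
               seed = config$seed, record = config$record)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_simulation, args)
}

#' Generate a synthetic experimental cell-length profile
#'
#' Stand-in for a digitized experimental profile: runs the tissue
#' simulator with the given growth rates, interval-averages the final
#' snapshot over the standard scheme, and adds Gaussian noise to the
#' interval means. Deterministic for a given seed.
#'
#' @param a1,a2 isosmotic growth rates (um/h).
#' @param config a [run_config()] providing everything else (its
#'   schedule's li0/li_max/t_elong are kept, the rates are replaced).
#' @param noise_sd standard deviation of the additive noise on the
#'   interval means (um); 0 gives exactly the simulator's averages.
#' @param seed integer seed (simulation and noise).
#' @param edges interval edges (mm); default the standard scheme.
#' @param path optional CSV path; if given the profile is also written.
#' @return a \code{"length_profile"} (invisibly the path if written).
#' @export
generate_synthetic_profile <- function(a1, a2, config, noise_sd = 0,
                                       seed = 1L, edges = NULL,
                                       path = NULL) {
  sch0 <- config$schedule
  sch <- growth_schedule(a1, a2, li0 = sch0$li0, li_max = sch0$li_max,
                         t_elong = sch0$t_elong)
  sim <- run_from_config(config, schedule = sch, seed = seed,
                         record = "none")
  if (is.null(edges))
    edges <- interval_scheme(max_mm = max(12,
                                          ceiling(sum(sim$lambda) / 1000)))
  prof <- profile_average(sim$cells$position_mm, sim$cells$l, edges)
  if (noise_sd > 0) {
    ok <- !is.na(prof$mean_length_um)
    prof$mean_length_um[ok] <- prof$mean_length_um[ok] +
      stats::rnorm(sum(ok), 0, noise_sd)
  }
  if (!is.null(path)) {
    write_length_profile(prof, path)
    return(invisible(prof))
  }
  prof
}
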