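# Post-simulation analytics: per-cell pressure-profile vectors and their
# k-means clustering, axial pressure profiles, and growth curves aligned to
# cell birth.

#' Pressure-profile vector of one cell
#'
#' Fixed-length descriptor of a cell's pressure history: entries 1..75 hold
#' the osmotic pressure at hours 1..75 of the cell's life, entries 76..150
#' the turgor pressure at the same hours; entries after the cell's death
#' (division or simulation end) are zero. Cells living longer than the
#' horizon are truncated with a warning.
#'
#' @param p_osm,p_turg per-hour pressure series of one cell (bar), sampled
#'   at whole hours of its life (hour 1, 2, ...).
#' @param times optional sampling ages (h); if given, they must be
#'   1, 2, ... at unit spacing, else an error is raised.
#' @param horizon hours per pressure block (default 75; vector length is
#'   twice this).
#' @return numeric vector of length \code{2 * horizon}.
#' @export
pressure_profile_vector <- function(p_osm, p_turg, times = NULL,
                                    horizon = 75L) {
  if (length(p_osm) != length(p_turg))
    stop("pressure_profile_vector: series lengths differ")
  if (!is.null(times)) {
    if (length(times) != length(p_osm) ||
        any(abs(times - seq_along(times)) > 1e-6))
      stop("pressure_profile_vector: cadence mismatch, need samples at ",
           "whole hours 1, 2, ... of the cell's life")
  }
  n <- length(p_osm)
  if (n > horizon) {
    warning("pressure_profile_vector: cell lived ", n,
            " h, truncating to the ", horizon, " h horizon")
    p_osm <- p_osm[seq_len(horizon)]
    p_turg <- p_turg[seq_len(horizon)]
    n <- horizon
  }
  v <- numeric(2L * horizon)
  v[seq_len(n)] <- p_osm
  v[horizon + seq_len(n)] <- p_turg
  v
}

#' Pressure-profile matrix of a simulation
#'
#' One row per cell ever created, as recorded by
#' \code{run_simulation(record = "pressures")}: columns \code{p1..p150}
#' (osmotic then turgor blocks), zero after each cell's death.
#'
#' @param sim a \code{"leaf_sim"} run with recording on.
#' @return numeric matrix with attribute \code{lifespan_h} (per row) and
#'   column names \code{p1..p150}.
#' @export
pressure_profile_matrix <- function(sim) {
  if (is.null(sim$pressures))
    stop("pressure_profile_matrix: simulation was run with record = \"none\"")
  m <- sim$pressures
  colnames(m) <- paste0("p", seq_len(ncol(m)))
  if (any(sim$log$lifespan > sim$horizon))
    warning("pressure_profile_matrix: ",
            sum(sim$log$lifespan > sim$horizon),
            " cells outlived the ", sim$horizon, " h recording horizon")
  attr(m, "lifespan_h") <- sim$log$lifespan
  attr(m, "cell_id") <- sim$log$id
  m
}

#' Cluster cells by their pressure profiles
#'
#' k-means clustering (Euclidean distance, seeded k-means++-style restarts
#' via \code{nstart}) of the fixed-length pressure-profile vectors.
#' Clusters are relabelled in order of increasing mean lifespan of their
#' member cells, so low cluster numbers are short-lived cells and high
#' numbers long-lived ones.
#'
#' @param vectors matrix with one profile vector per row (e.g. from
#'   [pressure_profile_matrix()]).
#' @param k number of clusters (default 10).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart random restarts (default 10).
#' @param lifespan_h per-row lifespans; defaults to the matrix attribute,
#'   else inferred as the number of non-zero entries in the osmotic block.
#' @param algorithm k-means variant; MacQueen by default, which is robust
#'   for the many near-duplicate zero-padded rows these matrices contain
#'   (Hartigan-Wong emits spurious Quick-TRANSfer warnings there).
#' @return A \code{"pressure_clusters"}: list with \code{cluster} (per-row
#'   labels 1..k), \code{centers} (reordered), \code{size},
#'   \code{mean_lifespan_h} per cluster, and the within-cluster sum of
#'   squares.
#' @export
cluster_pressure_profiles <- function(vectors, k = 10L, seed = 1L,
                                      nstart = 10L, lifespan_h = NULL,
                                      algorithm = "MacQueen") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < k)
    stop("cluster_pressure_profiles: fewer vectors (", nrow(vectors),
         ") than clusters (", k, ")")
  if (is.null(lifespan_h)) lifespan_h <- attr(vectors, "lifespan_h")
  if (is.null(lifespan_h)) {
    half <- ncol(vectors) %/% 2L
    lifespan_h <- rowSums(vectors[, seq_len(half), drop = FALSE] != 0)
  }
  set.seed(seed)
  km <- stats::kmeans(vectors, centers = k, nstart = nstart,
                      iter.max = 200L, algorithm = algorithm)
  mls <- as.numeric(tapply(lifespan_h, factor(km$cluster, seq_len(k)),
                           mean))
  ord <- order(mls)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(
    cluster = relabel[km$cluster],
    centers = km$centers[ord, , drop = FALSE],
    size = as.integer(km$size[ord]),
    mean_lifespan_h = mls[ord],
    tot_withinss = km$tot.withinss,
    k = k, seed = seed
  ), class = "pressure_clusters")
}

#' @export
print.pressure_clusters <- function(x, ...) {
  cat(sprintf("k-means pressure-profile clusters (k = %d)\n", x$k))
  print(data.frame(cluster = seq_len(x$k), size = x$size,
                   mean_lifespan_h = round(x$mean_lifespan_h, 1)),
        row.names = FALSE)
  invisible(x)
}

#' Axial profile of osmotic and turgor pressure
#'
#' Per-interval mean and standard deviation of both pressures in a tissue
#' snapshot, as a function of distance from the leaf base.
#'
#' @param cells snapshot data.frame with columns \code{position_mm},
#'   \code{p_osm}, \code{p_turg} (e.g. \code{sim$cells}), or a
#'   \code{"leaf_sim"}.
#' @param edges interval edges (mm); default [interval_scheme()] covering
#'   the snapshot.
#' @return An \code{"axial_pressure_profile"}: data.frame with interval
#'   edges and \code{mean_p_osm}, \code{sd_p_osm}, \code{mean_p_turg},
#'   \code{sd_p_turg}, \code{n_cells}.
#' @export
axial_pressure_profile <- function(cells, edges = NULL) {
  if (inherits(cells, "leaf_sim")) cells <- cells$cells
  if (nrow(cells) == 0L) stop("axial_pressure_profile: empty snapshot")
  if (is.null(edges))
    edges <- interval_scheme(max_mm = max(12,
                                          ceiling(max(cells$position_mm))))
  nb <- length(edges) - 1L
  bin <- findInterval(cells$position_mm, edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  f <- factor(bin[keep], levels = seq_len(nb))
  agg <- function(x, fun) as.numeric(tapply(x[keep], f, fun))
  n <- as.integer(table(f))
  out <- data.frame(
    interval_start_mm = edges[-length(edges)],
    interval_end_mm = edges[-1],
    mean_p_osm = agg(cells$p_osm, mean),
    sd_p_osm = ifelse(n > 1, agg(cells$p_osm, stats::sd), 0),
    mean_p_turg = agg(cells$p_turg, mean),
    sd_p_turg = ifelse(n > 1, agg(cells$p_turg, stats::sd), 0),
    n_cells = n
  )
  structure(out, class = c("axial_pressure_profile", "data.frame"))
}

#' @export
plot.axial_pressure_profile <- function(x, ...) {
  mid <- (x$interval_start_mm + x$interval_end_mm) / 2
  rng <- range(c(x$mean_p_osm - x$sd_p_osm, x$mean_p_osm + x$sd_p_osm,
                 x$mean_p_turg - x$sd_p_turg, x$mean_p_turg + x$sd_p_turg),
               na.rm = TRUE)
  graphics::plot(mid, x$mean_p_osm, type = "b", col = "steelblue",
                 ylim = rng, xlab = "distance from base (mm)",
                 ylab = "pressure (bar)", pch = 16, ...)
  graphics::lines(mid, x$mean_p_turg, type = "b", col = "firebrick",
                  pch = 16)
  ok <- x$n_cells > 0
  graphics::arrows(mid[ok], (x$mean_p_osm - x$sd_p_osm)[ok], mid[ok],
                   (x$mean_p_osm + x$sd_p_osm)[ok], angle = 90, code = 3,
                   length = 0.02, col = "steelblue")
  graphics::arrows(mid[ok], (x$mean_p_turg - x$sd_p_turg)[ok], mid[ok],
                   (x$mean_p_turg + x$sd_p_turg)[ok], angle = 90, code = 3,
                   length = 0.02, col = "firebrick")
  graphics::legend("topright", c("osmotic", "turgor"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Growth curves aligned to cell birth
#'
#' Per-cell time series of visible and isosmotic length at whole hours of
#' each cell's life, plus the age-wise mean over all cells alive at each
#' age. Requires \code{run_simulation(record = "full")}.
#'
#' @param sim a \code{"leaf_sim"} with length recording.
#' @param ids cell ids to extract (default all).
#' @return A \code{"growth_curves"}: list with \code{age_h}, matrices
#'   \code{l} and \code{li} (one row per cell, NA after death) and
#'   data.frame \code{mean_curve} (age, mean visible, mean isosmotic,
#'   number of cells alive).
#' @export
growth_curves <- function(sim, ids = NULL) {
  if (is.null(sim$l_rec))
    stop("growth_curves: simulation was not run with record = \"full\"")
  l <- sim$l_rec; li <- sim$li_rec
  life <- sim$log$lifespan
  sel <- if (is.null(ids)) seq_len(nrow(l)) else match(ids, sim$log$id)
  ages <- seq_len(ncol(l))
  alive <- outer(floor(life[sel]), ages, ">=")
  lm <- l[sel, , drop = FALSE]; lim <- li[sel, , drop = FALSE]
  lm[!alive] <- NA; lim[!alive] <- NA
  n_alive <- colSums(alive)
  structure(list(
    age_h = ages,
    l = lm, li = lim,
    cell_id = sim$log$id[sel],
    mean_curve = data.frame(
      age_h = ages,
      mean_l_um = colMeans(lm, na.rm = TRUE),
      mean_li_um = colMeans(lim, na.rm = TRUE),
      n_cells = n_alive)
  ), class = "growth_curves")
}

#' @export
plot.growth_curves <- function(x, n_show = 50, ...) {
  sel <- seq_len(min(n_show, nrow(x$l)))
  graphics::matplot(x$age_h, t(x$l[sel, , drop = FALSE]), type = "l",
                    lty = 1, col = grDevices::grey(0.7, 0.4),
                    xlab = "cell age (h)", ylab = "visible length (um)",
                    ...)
  graphics::lines(x$mean_curve$age_h, x$mean_curve$mean_l_um, lwd = 2)
  invisible(x)
}

#' Write pressure-profile vectors to CSV
#'
#' One row per cell: \code{cell_id}, \code{lifespan_h}, then
#' \code{p1..p150}.
#'
#' @param m matrix from [pressure_profile_matrix()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pressure_vectors <- function(m, path) {
  df <- data.frame(cell_id = attr(m, "cell_id"),
                   lifespan_h = attr(m, "lifespan_h"))
  df <- cbind(df, as.data.frame(unclass(m[, , drop = FALSE])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
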