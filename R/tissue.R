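# Tissue representation: N cell files glued into a "brickwork" through a
# shared partition of the leaf axis into transverse fragments. The fragment
# table is the single source of truth for visible lengths: every cell's l is
# the sum of its member fragments, and every file spans the same total
# length (the sum of all fragments) by construction.

ZONES <- c("DZ", "TZ", "EZ", "MATURE")

# Build the fragment partition from per-file cell boundary positions.
# Returns list(lambda, membership) where membership[k, n] is the row index
# (into the file-major cells table) of the cell of file n containing
# fragment k. Internal.
build_fragments <- function(lengths_by_file) {
  n_files <- length(lengths_by_file)
  cums <- lapply(lengths_by_file, cumsum)
  total <- vapply(cums, function(x) x[length(x)], numeric(1))
  if (max(total) - min(total) > 1e-6 * max(total))
    stop("build_fragments: files span different total lengths")
  bounds <- sort(unique(unlist(cums)))
  # merge boundaries that coincide up to rounding (files sharing a wall)
  keep <- c(diff(bounds) > 1e-9, TRUE)
  bounds <- bounds[keep]
  lambda <- diff(c(0, bounds))
  mids <- bounds - lambda / 2
  membership <- matrix(0L, length(lambda), n_files)
  offset <- 0L
  for (n in seq_len(n_files)) {
    idx <- pmin(findInterval(mids, cums[[n]]) + 1L,
                length(lengths_by_file[[n]]))
    membership[, n] <- offset + idx
    offset <- offset + length(lengths_by_file[[n]])
  }
  list(lambda = lambda, membership = membership)
}

#' Construct a tissue from explicit per-file cell lengths
#'
#' Low-level constructor used for small hand-built tissues: takes one vector
#' of visible cell lengths per file (all files must span the same total
#' length), derives the transverse fragment partition as the union of all
#' cell boundaries, and resets each visible length to the sum of its member
#' fragments so that the partition identity holds by construction.
#'
#' @param lengths_by_file list of numeric vectors, one per file, base to
#'   tip, of visible cell lengths (um).
#' @param params a [mech_params()].
#' @param schedule template [growth_schedule()] carrying a1, a2, li_max and
#'   t_elong for all cells.
#' @param zonation a [zonation_config()].
#' @param division a [division_rule()].
#' @param li optional per-file list of isosmotic lengths; default isotonic
#'   (equal to the visible lengths).
#' @param lr optional per-file list of relaxed lengths; default prestressed
#'   to the turgor threshold, \code{l * beta / (beta + Pc)}.
#' @param clock simulation time assigned to the state (h).
#' @return A \code{"leaf_tissue"} object.
#' @export
leaf_tissue_from_lengths <- function(lengths_by_file, params = mech_params(),
                                     schedule, zonation = zonation_config(),
                                     division = division_rule(),
                                     li = NULL, lr = NULL, clock = 0) {
  n_files <- length(lengths_by_file)
  if (n_files < 1L) stop("leaf_tissue_from_lengths: need at least one file")
  if (any(unlist(lengths_by_file) <= 0))
    stop("leaf_tissue_from_lengths: cell lengths must be positive")
  if (is.null(li)) li <- lengths_by_file
  if (is.null(lr))
    lr <- lapply(lengths_by_file,
                 function(l) l * params$beta / (params$beta + params$Pc))
  frag <- build_fragments(lengths_by_file)
  n_cells <- vapply(lengths_by_file, length, integer(1))
  cells <- data.frame(
    id = seq_len(sum(n_cells)),
    file = rep(seq_len(n_files), n_cells),
    li = unlist(li),
    l = unlist(lengths_by_file),
    lr = unlist(lr),
    li0 = unlist(li),
    t0 = clock,
    t_switch = NA_real_,
    zone = "DZ",
    stringsAsFactors = FALSE
  )
  # make the partition identity exact: l := sum of member fragments
  cells$l <- reconstitute_lengths(frag$lambda, frag$membership, nrow(cells))
  tis <- structure(list(
    cells = cells, lambda = frag$lambda, membership = frag$membership,
    clock = clock, params = params, schedule = schedule,
    zonation = zonation, division = division, n_files = n_files,
    n_created = nrow(cells), next_id = nrow(cells) + 1L,
    max_turgor = max(turgor_pressure(cells$l, cells$lr, params)),
    log = data.frame(id = cells$id, file = cells$file, t0 = cells$t0,
                     li0 = cells$li0, t_end = NA_real_, divided = FALSE,
                     parent = NA_integer_)
  ), class = "leaf_tissue")
  update_zones(tis)
}

# Visible lengths as sums of member fragments (the partition identity).
# Internal.
reconstitute_lengths <- function(lambda, membership, n_cells) {
  l <- numeric(n_cells)
  for (n in seq_len(ncol(membership))) {
    s <- rowsum(lambda, membership[, n])
    l[as.integer(rownames(s))] <- s[, 1]
  }
  l
}

#' Build the initial tissue state
#'
#' Seeds every file with enough division-zone cells of mean isosmotic size
#' to fill the division zone. Initial isosmotic lengths are drawn uniformly
#' between the schedule's \code{li0} and \code{li_max} so that divisions
#' desynchronize; visible lengths are the drawn isosmotic lengths rescaled
#' (per file) so that every file spans exactly the division zone; relaxed
#' lengths are prestressed to the turgor threshold.
#'
#' Uses the current R random number generator state: call \code{set.seed()}
#' first (or use [run_simulation()], which does) for reproducibility.
#'
#' @param n_files number of cell files (>= 1).
#' @param params a [mech_params()].
#' @param schedule template [growth_schedule()].
#' @param zonation a [zonation_config()].
#' @param division a [division_rule()].
#' @return A \code{"leaf_tissue"} object.
#' @export
build_initial_tissue <- function(n_files, params = mech_params(), schedule,
                                 zonation = zonation_config(),
                                 division = division_rule()) {
  if (n_files < 1L) stop("build_initial_tissue: n_files must be >= 1")
  L_DZ_um <- zonation$L_DZ * 1000
  mean_li <- (schedule$li0 + schedule$li_max) / 2
  n0 <- max(1L, as.integer(ceiling(L_DZ_um / mean_li)))
  lengths <- li <- vector("list", n_files)
  for (n in seq_len(n_files)) {
    li_n <- stats::runif(n0, schedule$li0, schedule$li_max)
    li[[n]] <- li_n
    lengths[[n]] <- li_n * (L_DZ_um / sum(li_n))
  }
  leaf_tissue_from_lengths(lengths, params, schedule, zonation, division,
                           li = li)
}

#' @export
print.leaf_tissue <- function(x, ...) {
  cat(sprintf(
    "Leaf tissue: %d files, %d cells, %d fragments, leaf length %.3g mm\n",
    x$n_files, nrow(x$cells), length(x$lambda), sum(x$lambda) / 1000))
  cat(sprintf("  clock %.4g h, %d cells created so far\n",
              x$clock, x$n_created))
  print(table(factor(x$cells$zone, levels = ZONES)))
  invisible(x)
}

# Midpoint positions (um from the leaf base) of all cells, file-major.
# Internal.
cell_positions <- function(tissue) {
  pos <- numeric(nrow(tissue$cells))
  for (n in seq_len(tissue$n_files)) {
    idx <- which(tissue$cells$file == n)
    l <- tissue$cells$l[idx]
    pos[idx] <- cumsum(l) - l / 2
  }
  pos
}

#' Zone label for a cell position and state
#'
#' Static zonation rule: division zone (DZ) while the cell midpoint is
#' within \code{L_DZ} of the base; transition zone (TZ) beyond it while the
#' isosmotic length is still below \code{li_max}; elongation zone (EZ) from
#' the moment the isosmotic length reaches \code{li_max} outside the DZ;
#' MATURE once elongation has ended (or the midpoint has left the growth
#' zone). Within a simulation the zone sequence of a cell is monotone
#' DZ - TZ - EZ - MATURE.
#'
#' @param position_mm cell midpoint distance from the leaf base (mm);
#'   vectorized.
#' @param li isosmotic length (um); vectorized.
#' @param li_max critical isosmotic length (um).
#' @param zonation a [zonation_config()].
#' @param elongation_done logical; whether the cell's fast-growth period has
#'   already elapsed (vectorized).
#' @return character vector of zone labels.
#' @export
assign_zone <- function(position_mm, li, li_max,
                        zonation = zonation_config(),
                        elongation_done = FALSE) {
  if (any(position_mm < 0)) stop("assign_zone: negative position")
  ifelse(position_mm >= zonation$L_GZ | elongation_done, "MATURE",
         ifelse(position_mm < zonation$L_DZ, "DZ",
                ifelse(li < li_max, "TZ", "EZ")))
}

# Monotone zone-state update after a step; stamps t_switch on TZ->EZ.
# Internal.
update_zones <- function(tissue) {
  cl <- tissue$cells
  pos_mm <- cell_positions(tissue) / 1000
  zo <- tissue$zonation
  sch <- tissue$schedule
  # DZ -> TZ
  adv <- cl$zone == "DZ" & pos_mm >= zo$L_DZ
  cl$zone[adv] <- "TZ"
  # TZ -> EZ when biomass reaches the critical size
  sw <- cl$zone == "TZ" & cl$li >= sch$li_max - 1e-9
  cl$zone[sw] <- "EZ"
  cl$t_switch[sw] <- tissue$clock
  # EZ -> MATURE after t_elong, or on leaving the growth zone
  done <- cl$zone == "EZ" &
    (tissue$clock - cl$t_switch >= sch$t_elong - 1e-9 | pos_mm >= zo$L_GZ)
  cl$zone[done] <- "MATURE"
  # any slow cell pushed out of the growth zone stops growing too
  out <- cl$zone %in% c("TZ") & pos_mm >= zo$L_GZ
  cl$zone[out] <- "MATURE"
  tissue$cells <- cl
  tissue
}

#' Instantaneous fragment growth rates
#'
#' The growth rate of each transverse fragment is its length times the mean,
#' over the N files, of the free specific growth rates of the cells that
#' contain it: \code{dlambda_k/dt = (lambda_k / N) * sum_n g_mn}.
#'
#' @param tissue a \code{"leaf_tissue"}.
#' @return numeric vector of fragment growth rates (um/h), base to tip.
#' @export
fragment_growth_rates <- function(tissue) {
  cl <- tissue$cells
  g <- free_growth_rate(cl$li, cl$l, cl$lr, tissue$params)
  gm <- matrix(g[tissue$membership], nrow(tissue$membership),
               tissue$n_files)
  tissue$lambda * rowMeans(gm)
}

# Schedule slope of every cell given its zone. Internal.
cell_li_rates <- function(tissue) {
  sch <- tissue$schedule
  ifelse(tissue$cells$zone %in% c("DZ", "TZ"), sch$a1,
         ifelse(tissue$cells$zone == "EZ", sch$a2, 0))
}

#' Advance the tissue by one time step
#'
#' Reference (pure R) implementation of the coupled update, mirroring the
#' compiled engine exactly: all rates are evaluated from a frozen copy of
#' the state (a Jacobi sweep, so file order cannot bias the result); every
#' fragment is advanced with the linearized-implicit update
#' \code{lambda * (1 + dt*gbar / (1 + dt*Gammabar))} where \code{gbar} and
#' \code{Gammabar} average the member cells' free growth and relaxation
#' rates; visible lengths are then reconstituted as member-fragment sums;
#' isosmotic and relaxed lengths advance cell-autonomously; finally zones
#' are refreshed and due divisions executed.
#'
#' @param tissue a \code{"leaf_tissue"}.
#' @param dt time step (h).
#' @param divide if \code{FALSE}, skip the division sweep (used by tests).
#' @return the advanced \code{"leaf_tissue"}.
#' @export
step_tissue <- function(tissue, dt, divide = TRUE) {
  if (dt <= 0) stop("step_tissue: dt must be positive")
  cl <- tissue$cells
  st <- step_core(cl$li, cl$l, cl$lr, cell_li_rates(tissue), dt,
                  tissue$params)
  memb <- tissue$membership
  gbar <- rowMeans(matrix(st$g[memb], nrow(memb), tissue$n_files))
  gambar <- rowMeans(matrix(st$gam[memb], nrow(memb), tissue$n_files))
  lambda2 <- tissue$lambda * (1 + dt * gbar / (1 + dt * gambar))
  if (any(lambda2 <= 0))
    stop("step_tissue: fragment length became non-positive at t = ",
         format(tissue$clock + dt), "; reduce dt")
  tissue$lambda <- lambda2
  cl$li <- st$li
  cl$lr <- st$lr
  cl$l <- reconstitute_lengths(lambda2, memb, nrow(cl))
  tissue$cells <- cl
  tissue$clock <- tissue$clock + dt
  tissue$max_turgor <- max(tissue$max_turgor,
                           turgor_pressure(cl$l, cl$lr, tissue$params))
  tissue <- update_zones(tissue)
  if (divide) {
    repeat {
      due <- which(tissue$cells$zone == "DZ" &
                     tissue$cells$li >= tissue$schedule$li_max - 1e-9)
      if (length(due) == 0L) break
      tissue <- divide_cell(tissue, row = due[1])
    }
  }
  tissue
}

#' Divide a cell
#'
#' Splits a division-zone cell into two daughters in the proportion
#' \code{d / (1 - d)}: isosmotic, visible and relaxed lengths are divided
#' exactly (sums conserved), the daughters' recorded initial isosmotic
#' lengths are \code{d * li_max} and \code{(1 - d) * li_max}, their birth
#' time is the current clock, and the new transverse wall is inserted into
#' the fragment partition leaf-wide (the single affected fragment is split;
#' all other files' membership is inherited).
#'
#' @param tissue a \code{"leaf_tissue"}.
#' @param row row index of the mother in \code{tissue$cells}; alternatively
#'   give \code{file_n} and \code{cell_m}.
#' @param file_n,cell_m file index and (base-to-tip) cell index within the
#'   file, used when \code{row} is missing.
#' @param d division factor; drawn from the tissue's [division_rule()] when
#'   \code{NULL}.
#' @return the updated \code{"leaf_tissue"}.
#' @export
divide_cell <- function(tissue, row = NULL, file_n = NULL, cell_m = NULL,
                        d = NULL) {
  cl <- tissue$cells
  if (is.null(row)) {
    rows_n <- which(cl$file == file_n)
    if (cell_m < 1L || cell_m > length(rows_n))
      stop("divide_cell: no such cell")
    row <- rows_n[cell_m]
  }
  if (cl$zone[row] != "DZ")
    stop("divide_cell: division requested outside the division zone")
  if (is.null(d)) d <- rdivision_factor(1L, tissue$division)
  mother_id_row <- row
  file_n <- cl$file[row]
  memb <- tissue$membership
  lambda <- tissue$lambda
  frag_rows <- which(memb[, file_n] == row)
  frag_rows <- frag_rows[order(frag_rows)]   # spatial order
  lam_m <- lambda[frag_rows]
  target <- d * cl$l[row]
  cum <- cumsum(lam_m)
  j_loc <- which(cum >= target - 1e-12)[1]
  if (is.na(j_loc)) j_loc <- length(lam_m)
  cum_before <- if (j_loc > 1L) cum[j_loc - 1L] else 0
  lamA <- target - cum_before
  j <- frag_rows[j_loc]
  split_needed <- lamA > 1e-12 && lamA < lambda[j] - 1e-12
  if (split_needed) {
    lamB <- lambda[j] - lamA
    lambda[j] <- lamA
    lambda <- append(lambda, lamB, after = j)
    memb <- rbind(memb[seq_len(j), , drop = FALSE],
                  memb[j, , drop = FALSE],
                  if (j < nrow(memb)) memb[-seq_len(j), , drop = FALSE])
    below <- c(frag_rows[seq_len(j_loc)])
    above <- c(j + 1L, frag_rows[frag_rows > j] + 1L)
  } else {
    # boundary coincides with an existing fragment edge
    if (lamA <= 1e-12) {
      below <- frag_rows[frag_rows < j]
      above <- frag_rows[frag_rows >= j]
    } else {
      below <- frag_rows[frag_rows <= j]
      above <- frag_rows[frag_rows > j]
    }
    if (length(below) == 0L || length(above) == 0L)
      stop("divide_cell: degenerate split (cell has a single fragment ",
           "and d puts the wall on its edge)")
  }
  id1 <- tissue$next_id
  id2 <- id1 + 1L
  mother_id <- cl$id[row]
  sch <- tissue$schedule
  d1 <- d2 <- cl[row, ]
  d1$id <- id1; d2$id <- id2
  d1$li <- d * cl$li[row];  d2$li <- cl$li[row] - d1$li
  d1$lr <- d * cl$lr[row];  d2$lr <- cl$lr[row] - d1$lr
  d1$li0 <- d * sch$li_max; d2$li0 <- (1 - d) * sch$li_max
  d1$t0 <- d2$t0 <- tissue$clock
  d1$t_switch <- d2$t_switch <- NA_real_
  d1$zone <- d2$zone <- "DZ"
  # insert daughters in place of the mother (row order stays file-major,
  # base to tip); membership rows referencing cells after `row` shift by 1
  memb[memb > row] <- memb[memb > row] + 1L
  memb[below, file_n] <- row
  memb[above, file_n] <- row + 1L
  cl <- rbind(cl[seq_len(row - 1L), , drop = FALSE], d1, d2,
              if (row < nrow(cl)) cl[-seq_len(row), , drop = FALSE])
  cl$l[row] <- sum(lambda[below])
  cl$l[row + 1L] <- sum(lambda[above])
  rownames(cl) <- NULL
  tissue$cells <- cl
  tissue$lambda <- lambda
  tissue$membership <- memb
  tissue$next_id <- id2 + 1L
  tissue$n_created <- tissue$n_created + 2L
  # close the mother's log entry, open the daughters'
  mrow <- which(tissue$log$id == mother_id)
  tissue$log$t_end[mrow] <- tissue$clock
  tissue$log$divided[mrow] <- TRUE
  tissue$log <- rbind(tissue$log, data.frame(
    id = c(id1, id2), file = file_n, t0 = tissue$clock,
    li0 = c(d1$li0, d2$li0), t_end = NA_real_, divided = FALSE,
    parent = mother_id))
  tissue
}

#' Total leaf length spanned by the fragment partition
#'
#' @param tissue a \code{"leaf_tissue"}.
#' @return leaf length (um); every file spans this same length.
#' @export
tissue_leaf_length <- function(tissue) sum(tissue$lambda)

#' Consistency check of the fragment partition
#'
#' Asserts that every visible cell length equals the sum of its member
#' fragments and that every file spans the same total length. Used after
#' every step and division in tests.
#'
#' @param tissue a \code{"leaf_tissue"}.
#' @param tol relative tolerance.
#' @return \code{TRUE} invisibly; otherwise an error describing the breach.
#' @export
check_partition <- function(tissue, tol = 1e-9) {
  cl <- tissue$cells
  lsum <- reconstitute_lengths(tissue$lambda, tissue$membership, nrow(cl))
  if (max(abs(lsum - cl$l) / pmax(cl$l, 1)) > tol)
    stop("check_partition: visible lengths do not match fragment sums")
  for (n in seq_len(tissue$n_files)) {
    fl <- sum(cl$l[cl$file == n])
    if (abs(fl - sum(tissue$lambda)) > tol * sum(tissue$lambda))
      stop("check_partition: file ", n, " does not span the leaf length")
    m <- tissue$membership[, n]
    if (any(diff(m) < 0))
      stop("check_partition: membership not monotone along the axis")
  }
  invisible(TRUE)
}
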