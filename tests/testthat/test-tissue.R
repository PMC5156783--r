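# Fragment partition, coupled stepping, zonation and division.

p <- mech_params()

test_that("fragment partition handles degenerate, aligned and interleaved files", {
  sch <- test_schedule()
  # one file, one cell: a single fragment equal to the cell
  t1 <- leaf_tissue_from_lengths(list(30), schedule = sch)
  expect_length(t1$lambda, 1L)
  expect_equal(t1$lambda, 30)
  # two identical files: fragments == cells per file
  t2 <- leaf_tissue_from_lengths(list(c(10, 20), c(10, 20)), schedule = sch)
  expect_length(t2$lambda, 2L)
  # interleaved boundaries (2 vs 3 cells) -> 4 fragments, each mapped to
  # exactly one cell per file (hand enumeration of the boundary union)
  t3 <- leaf_tissue_from_lengths(list(c(10, 20), c(8, 12, 10)),
                                 schedule = sch)
  expect_equal(t3$lambda, c(8, 2, 10, 10))
  expect_equal(t3$membership[, 1], c(1L, 1L, 2L, 2L))
  expect_equal(t3$membership[, 2], c(3L, 4L, 4L, 5L))
  expect_silent(check_partition(t3))
  expect_error(leaf_tissue_from_lengths(list(c(10, 20), c(10, 25)),
                                        schedule = sch), "total length")
})

test_that("fragment growth rates implement the file-averaged coupling", {
  sch <- test_schedule()
  # all cells at water-potential equilibrium: all fragment rates zero
  th <- homogeneous_tissue(2, 2, li = 20)
  th$cells$lr <- th$cells$l  # P_turg = 0 = P_osm
  expect_equal(fragment_growth_rates(th), rep(0, length(th$lambda)))
  # one shared fragment, two cells with known free rates g_A, g_B
  tt <- leaf_tissue_from_lengths(list(20, 20), schedule = sch,
                                 li = list(30, 20))
  tt$cells$lr <- c(20, 20)   # g_A = r*Lw*5, g_B = 0
  g <- free_growth_rate(tt$cells$li, tt$cells$l, tt$cells$lr, p)
  expect_equal(fragment_growth_rates(tt), 20 * (g[1] + g[2]) / 2)
})

test_that("a homogeneous tissue reproduces the isolated cell exactly", {
  sch <- growth_schedule(a1 = 0.69, a2 = 5.04, li0 = 20, li_max = 40.315,
                         t_elong = 71.09)
  th <- homogeneous_tissue(3, 3, li = 20, schedule = sch)
  for (i in 1:150) th <- step_tissue(th, 0.01, divide = FALSE)
  tr <- simulate_cell(p, sch, t_end = 1.5, dt = 0.01, record_dt = 1.5)
  expect_equal(th$cells$l, rep(tr$l_um[nrow(tr)], 9), tolerance = 1e-12)
  expect_equal(th$cells$lr, rep(tr$lr_um[nrow(tr)], 9), tolerance = 1e-12)
  expect_silent(check_partition(th))
})

test_that("every file spans the same leaf length after arbitrary stepping", {
  set.seed(3)
  sch <- test_schedule()
  tis <- build_initial_tissue(4, p, sch, small_zonation(), division_rule())
  for (i in 1:300) tis <- step_tissue(tis, 0.01)
  check_partition(tis)
  totals <- tapply(tis$cells$l, tis$cells$file, sum)
  expect_lt(diff(range(totals)) / mean(totals), 1e-12)
  expect_equal(sum(tis$lambda), unname(totals[1]), tolerance = 1e-12)
})

test_that("symplastic coupling drags fast cells below and slow cells above their free rates", {
  sch <- test_schedule()
  # two files, one hypertonic (fast) and one equilibrated (slow)
  tt <- leaf_tissue_from_lengths(list(20, 20), schedule = sch,
                                 li = list(26, 20))
  g_free <- free_growth_rate(tt$cells$li, tt$cells$l, tt$cells$lr, p)
  l0 <- tt$cells$l
  tt2 <- step_tissue(tt, 1e-5, divide = FALSE)
  realized <- (tt2$cells$l - l0) / (l0 * 1e-5)
  expect_lt(realized[1], g_free[1])  # fast cell held back
  expect_gt(realized[2], g_free[2])  # slow cell stretched
})

test_that("division conserves lengths, samples inside bounds, splits leaf-wide", {
  set.seed(11)
  sch <- test_schedule()
  tt <- leaf_tissue_from_lengths(list(c(10, 20), c(8, 12, 10)),
                                 schedule = sch)
  sums0 <- c(sum(tt$cells$li), sum(tt$cells$l), sum(tt$cells$lr))
  K0 <- length(tt$lambda)
  td <- divide_cell(tt, row = 1, d = 0.5)
  expect_equal(td$cells$li[1], td$cells$li[2])
  expect_equal(td$cells$l[1], td$cells$l[2], tolerance = 1e-12)
  expect_equal(c(sum(td$cells$li), sum(td$cells$l), sum(td$cells$lr)),
               sums0, tolerance = 1e-12)
  expect_equal(sum(td$lambda), sum(tt$lambda))
  expect_gte(length(td$lambda), K0)
  check_partition(td)
  # partition equals a brute-force rebuild from the per-file lengths
  rebuilt <- leaf_tissue_from_lengths(
    split(td$cells$l, td$cells$file), schedule = sch)
  expect_equal(sort(td$lambda), sort(rebuilt$lambda), tolerance = 1e-9)
  # division factors always inside the truncation bounds
  d <- rdivision_factor(2000, division_rule())
  expect_true(all(d > 0.1 & d < 0.9))
  expect_gt(mean(d), 0.45); expect_lt(mean(d), 0.55)
  # outside the division zone -> error
  tz <- td; tz$cells$zone[1] <- "TZ"
  expect_error(divide_cell(tz, row = 1), "outside the division zone")
})

test_that("zone assignment follows position and biomass thresholds", {
  zo <- zonation_config()  # DZ 3.3 mm, GZ 23.8 mm
  expect_equal(assign_zone(1.0, 20, 40, zo), "DZ")
  expect_equal(assign_zone(5.0, 20, 40, zo), "TZ")
  expect_equal(assign_zone(5.0, 41, 40, zo), "EZ")
  expect_equal(assign_zone(25, 41, 40, zo), "MATURE")
  expect_equal(assign_zone(5, 41, 40, zo, elongation_done = TRUE),
               "MATURE")
  expect_error(assign_zone(-1, 20, 40, zo), "negative")
})

test_that("compiled engine and R reference produce identical runs", {
  sch <- test_schedule()
  zo <- small_zonation()
  simc <- run_simulation(n_files = 3, schedule = sch, zonation = zo,
                         seed = 7, record = "none", engine = "cpp")
  simr <- run_simulation(n_files = 3, schedule = sch, zonation = zo,
                         seed = 7, record = "none", engine = "r")
  expect_identical(simc$cells$id, simr$cells$id)
  expect_identical(simc$cells$zone, simr$cells$zone)
  expect_equal(simc$cells$l, simr$cells$l, tolerance = 1e-12)
  expect_equal(simc$cells$li, simr$cells$li, tolerance = 1e-12)
  expect_equal(simc$lambda, simr$lambda, tolerance = 1e-12)
  expect_identical(simc$membership, simr$membership)
  expect_equal(simc$clock, simr$clock)
  expect_equal(simc$n_created, simr$n_created)
  expect_equal(simc$max_turgor, simr$max_turgor, tolerance = 1e-12)
})

test_that("runs are reproducible and bookkeeping is monotone", {
  sch <- test_schedule()
  zo <- small_zonation()
  s1 <- run_simulation(n_files = 3, schedule = sch, zonation = zo,
                       seed = 5, record = "none")
  s2 <- run_simulation(n_files = 3, schedule = sch, zonation = zo,
                       seed = 5, record = "none")
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$lambda, s2$lambda)
  # different seed, different realization
  s3 <- run_simulation(n_files = 3, schedule = sch, zonation = zo,
                       seed = 6, record = "none")
  expect_false(identical(s1$cells$l, s3$cells$l))
  # counts can only grow: created >= initial cells; fragments >= initial
  n_init <- sum(!duplicated(s1$log$id[is.na(s1$log$parent)]))
  expect_gte(s1$n_created, n_init)
  expect_gte(length(s1$lambda), n_init - 2 * 3)
  # timeout when the stop length is unreachable in max_time
  expect_error(
    run_simulation(n_files = 2, schedule = sch,
                   zonation = zonation_config(L_DZ = 0.15, L_GZ = 0.6,
                                              stop_length = 50,
                                              max_time = 2),
                   seed = 1, record = "none"),
    "max_time")
})

test_that("division-zone cycle times match the division mechanics and the reference cycle", {
  sim <- scaled_full_sim()
  done <- sim$log[sim$log$divided, ]
  expect_gt(nrow(done), 500)
  # over the whole run (initial desynchronized cohort included) the mean
  # completed cycle sits at the experimental reference of 24.7 h
  expect_lt(abs(mean(done$lifespan) - 24.7) / 24.7, 0.10)
  # steady-state cohort (born after the initial burst, with time to
  # complete any admissible cycle before the run ends): the mean tracks
  # the mechanistic expectation E[1-d] * li_max / a1, slightly shortened
  # because slow-cycling cells advect out of the division zone
  sch <- sim$config$schedule
  ss <- done[done$t0 > 5 & done$t0 < sim$clock - 55, ]
  expect_gt(nrow(ss), 300)
  expected <- 0.5 * sch$li_max / sch$a1
  expect_lt(abs(mean(ss$lifespan) - expected) / expected, 0.07)
  expect_lte(mean(ss$lifespan), expected + 0.5)
})
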