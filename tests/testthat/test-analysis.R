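# Pressure-profile vectors, clustering, axial profiles, growth curves.

test_that("pressure-profile vectors are zero-padded and truncated correctly", {
  v <- pressure_profile_vector(rep(3.6, 10), rep(3.5, 10))
  expect_length(v, 150L)
  expect_equal(v[1:10], rep(3.6, 10))
  expect_equal(v[11:75], rep(0, 65))
  expect_equal(v[76:85], rep(3.5, 10))
  expect_equal(v[86:150], rep(0, 65))
  expect_warning(pressure_profile_vector(rep(1, 80), rep(1, 80)),
                 "truncat")
  expect_error(pressure_profile_vector(1:5, 1:4), "lengths differ")
  expect_error(pressure_profile_vector(1:3, 1:3, times = c(1, 2.5, 3)),
               "cadence")
})

test_that("recorded vectors have no signal beyond each cell's lifespan", {
  sim <- scaled_full_sim()
  # some cells outlive the 75 h horizon in this run; that is reported
  expect_warning(m <- pressure_profile_matrix(sim), "outlived")
  life <- attr(m, "lifespan_h")
  # exhaustive scan: entries after floor(lifespan) (both blocks) are zero,
  # entries within the lifespan carry signal
  n <- pmin(75L, floor(life))
  ages <- matrix(rep(1:75, each = nrow(m)), nrow(m), 75)
  dead <- ages > n
  expect_true(all(m[, 1:75][dead] == 0))
  expect_true(all(m[, 76:150][dead] == 0))
  has_signal <- rowSums(m[, 1:75] != 0) > 0
  expect_true(all(has_signal[n >= 1L]))
})

test_that("k-means recovers separable groups and is invariant to row order", {
  set.seed(42)
  templates <- diag(10)[rep(1:10, each = 10), ] * 8
  m <- templates + matrix(rnorm(1000, sd = 0.01), 100, 10)
  truth <- rep(1:10, each = 10)
  cl <- cluster_pressure_profiles(m, k = 10, seed = 1,
                                  lifespan_h = truth)  # lifespans = group
  # perfect recovery: partition identical to the template groups
  expect_equal(length(unique(cl$cluster)), 10L)
  expect_true(all(tapply(cl$cluster, truth,
                         function(x) length(unique(x))) == 1L))
  expect_equal(sum(cl$size), 100L)
  expect_true(all(cl$size > 0))
  # ordered by mean lifespan
  expect_true(!is.unsorted(cl$mean_lifespan_h))
  # permuting the rows yields the same partition
  perm <- sample(100)
  cl2 <- cluster_pressure_profiles(m[perm, ], k = 10, seed = 1,
                                   lifespan_h = truth[perm])
  expect_identical(cl$cluster[perm], cl2$cluster)
  expect_error(cluster_pressure_profiles(m[1:5, ], k = 10), "fewer")
})

test_that("full-run clusters are non-empty, partition all cells, and order by lifespan", {
  sim <- scaled_full_sim()
  m <- suppressWarnings(pressure_profile_matrix(sim))
  cl <- cluster_pressure_profiles(m, k = 10, seed = 3)
  expect_equal(sum(cl$size), nrow(m))
  expect_true(all(cl$size > 0))
  expect_true(!is.unsorted(cl$mean_lifespan_h))
  # short / medium / long lifespan structure across ordered clusters
  expect_lt(mean(cl$mean_lifespan_h[1:3]), mean(cl$mean_lifespan_h[8:10]))
})

test_that("axial profile of a homogeneous equilibrated tissue is flat", {
  sch <- growth_schedule(a1 = 0.69, a2 = 5.04, li0 = 20, li_max = 40.315,
                         t_elong = 71.09)
  th <- homogeneous_tissue(3, 40, li = 20, schedule = sch)
  cl <- th$cells
  cl$position_mm <- symplast:::cell_positions(th) / 1000
  cl$p_osm <- osmotic_pressure(cl$li, cl$l, default_params)
  cl$p_turg <- turgor_pressure(cl$l, cl$lr, default_params)
  prof <- axial_pressure_profile(cl, edges = seq(0, 0.8, by = 0.2))
  ok <- prof$n_cells > 0
  expect_lt(diff(range(prof$mean_p_osm[ok])), 1e-12)
  expect_true(all(prof$sd_p_osm[ok] >= 0))
  expect_true(all(prof$sd_p_turg[ok] >= 0))
})

test_that("single-cell intervals report zero dispersion", {
  cells <- data.frame(position_mm = c(0.1, 0.5, 0.6),
                      p_osm = c(3, 4, 5), p_turg = c(2, 3, 4))
  prof <- axial_pressure_profile(cells, edges = c(0, 0.25, 0.75))
  expect_equal(prof$sd_p_osm[1], 0)
  expect_gt(prof$sd_p_osm[2], 0)
  expect_error(axial_pressure_profile(cells[0, ]), "empty")
})

test_that("growth curves match the isolated-cell trajectory for a lone cell", {
  sch <- growth_schedule(a1 = 1.0354, a2 = 3.2264, li0 = 14.74,
                         li_max = 40.315, t_elong = 71.09)
  tis <- leaf_tissue_from_lengths(
    list(14.74), default_params, sch,
    zonation = zonation_config(L_DZ = 1e5, L_GZ = 2e5, stop_length = 3e5,
                               max_time = 10),
    li = list(14.74))
  sim <- run_simulation(schedule = sch,
                        zonation = zonation_config(L_DZ = 1e5, L_GZ = 2e5,
                                                   stop_length = Inf,
                                                   max_time = 10),
                        seed = 1, record = "full", tissue = tis)
  gc <- growth_curves(sim)
  tr <- simulate_cell(default_params, sch, t_end = 10, record_dt = 1)
  expect_equal(as.numeric(gc$l[1, 1:10]), tr$l_um[2:11], tolerance = 1e-9)
  expect_equal(as.numeric(gc$li[1, 1:10]), tr$li_um[2:11],
               tolerance = 1e-9)
})

test_that("tissue growth curves: piecewise-linear biomass, smooth monotone mean visible curve", {
  sch <- wheat_schedule(inverse = wheat_inverse())
  sim <- run_simulation(n_files = 4, schedule = sch,
                        zonation = zonation_config(stop_length = 12),
                        seed = 9, record = "full")
  gc <- growth_curves(sim)
  # biomass curves: hourly increments take only the schedule slopes
  inc <- t(apply(gc$li, 1, diff))
  inc <- inc[is.finite(inc)]
  ok <- abs(inc - sch$a1) < 0.02 | abs(inc - sch$a2) < 0.02 | abs(inc) < 0.02
  expect_gt(mean(ok), 0.99)
  # age-wise mean visible curve is monotone and well fit by a cubic
  mc <- gc$mean_curve[gc$mean_curve$n_cells >= 30, ]
  expect_true(all(diff(mc$mean_l_um) > -1e-6))
  fitc <- lm(mean_l_um ~ poly(age_h, 3), data = mc)
  expect_gt(summary(fitc)$r.squared, 0.97)
})
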