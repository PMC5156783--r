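# Single-cell biomechanics: pressures, growth laws, the isosmotic schedule
# and the isolated-cell integrator.

p <- mech_params()

test_that("pressure formulas reproduce hand-computed cases and signs", {
  cases <- list(
    # li, l, expected osmotic
    c(20, 20, 0), c(30, 20, 5), c(20, 25, -2))
  for (cs in cases)
    expect_equal(osmotic_pressure(cs[1], cs[2], p), cs[3])
  cases <- list(
    # l, lr, expected turgor
    c(20, 20, 0), c(20.4, 20, 2), c(19, 20, -5))
  for (cs in cases)
    expect_equal(turgor_pressure(cs[1], cs[2], p), cs[3])
  expect_error(osmotic_pressure(-1, 20, p), "positive")
  expect_error(osmotic_pressure(20, 0, p), "positive")
  expect_error(turgor_pressure(20, -3, p), "positive")
})

test_that("free growth rate composes the two pressures with r*Lw", {
  # P_osm = 5, P_turg = 0 -> 4 * 40 * 5 = 800 per hour
  expect_equal(free_growth_rate(30, 20, 20, p), 800)
  # water-potential equilibrium
  expect_equal(free_growth_rate(20, 20, 20 * 100 / 100, p), 0)
  # sign consistency on random states
  set.seed(1)
  for (i in 1:50) {
    li <- runif(1, 10, 50); l <- runif(1, 10, 50); lr <- runif(1, 10, 50)
    g <- free_growth_rate(li, l, lr, p)
    dp <- osmotic_pressure(li, l, p) - turgor_pressure(l, lr, p)
    expect_identical(g > 0, dp > 0)
  }
})

test_that("wall growth is thresholded, cubic, and freezes below Pc", {
  # exactly at threshold: no yield
  lr <- 20; l <- lr * (1 + p$Pc / p$beta)
  expect_equal(relaxed_length_rate(l, lr, 1, p), 0)
  # one bar above threshold, dli_dt = 0.69: eta * 0.69 * 1^3
  l1 <- lr * (1 + (p$Pc + 1) / p$beta)
  expect_equal(relaxed_length_rate(l1, lr, 0.69, p), 0.15 * 0.69,
               tolerance = 1e-12)
  # below threshold: zero for any biomass rate
  l0 <- lr * (1 + (p$Pc - 0.5) / p$beta)
  expect_equal(relaxed_length_rate(l0, lr, 100, p), 0)
  expect_error(relaxed_length_rate(l1, lr, -1, p), "non-negative")
})

test_that("isosmotic schedule is piecewise linear and continuous", {
  sch <- growth_schedule(a1 = 0.69, a2 = 5.04, li0 = 17.05,
                         li_max = 34.1, t_elong = 71.09)
  expect_equal(isosmotic_length(sch$t0, sch), 17.05)
  expect_equal(isosmotic_length(sch$t0 + 10, sch), 23.95)
  ts <- sch$t_switch; te <- ts + sch$t_elong
  eps <- 1e-9
  expect_equal(isosmotic_length(ts - eps, sch),
               isosmotic_length(ts + eps, sch), tolerance = 1e-6)
  expect_equal(isosmotic_length(te - eps, sch),
               isosmotic_length(te + eps, sch), tolerance = 1e-6)
  # constant after elongation
  expect_equal(isosmotic_length(te + 5, sch), isosmotic_length(te, sch))
  expect_error(isosmotic_length(sch$t0 - 1, sch), "birth")
  expect_error(growth_schedule(a1 = 1, a2 = 0.5, li0 = 10, li_max = 20),
               "a2 > a1")
})

test_that("a cell with no biomass growth is a fixed point", {
  sch <- growth_schedule(a1 = 1e-12, a2 = 1, li0 = 20, li_max = 1e6)
  tr <- simulate_cell(p, sch, t_end = 5,
                      init = list(li = 20, l = 20, lr = 20))
  expect_equal(tr$l_um, rep(20, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$lr_um, rep(20, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$p_osm_bar, rep(0, nrow(tr)), tolerance = 1e-9)
})

test_that("isolated cell reaches quasi-equilibrium; wall length is monotone", {
  sch <- test_schedule(a1 = 1.0354, a2 = 3.2264)
  tr <- simulate_cell(p, sch, t_end = 24.7, record_dt = 0.1)
  late <- tr[tr$time_h > 5, ]
  expect_lt(max(abs(late$p_osm_bar - late$p_turg_bar)), 0.1)
  # relaxed length never decreases (irreversible wall growth)
  expect_true(all(diff(tr$lr_um) >= -1e-12))
  # the free specific rate at quasi-equilibrium tracks biomass growth
  n <- nrow(tr)
  spec_rate <- diff(log(tr$l_um[(n - 20):n])) / 0.1
  expect_equal(mean(spec_rate), sch$a1 / mean(tr$li_um[(n - 20):n]),
               tolerance = 0.15)
})

test_that("halving the integrator step changes the final length by < 0.1%", {
  sch <- test_schedule(a1 = 1.0354, a2 = 3.2264)
  l1 <- simulate_cell(p, sch, 24.7, dt = 0.01, record_dt = 24.7 / 2)
  l2 <- simulate_cell(p, sch, 24.7, dt = 0.005, record_dt = 24.7 / 2)
  expect_lt(abs(l2$l_um[nrow(l2)] - l1$l_um[nrow(l1)]) / l1$l_um[nrow(l1)],
            1e-3)
})

test_that("with frozen wall and constant biomass, l converges to the quadratic root", {
  # Pturg stays below Pc along the way, so lr is frozen and the fixed
  # point solves alpha*(li-l)/l = beta*(l-lr)/lr in closed form.
  li <- 30; lr <- 25
  a <- p$beta; b <- (p$alpha - p$beta) * lr; cc <- -p$alpha * lr * li
  lstar <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expect_lt(turgor_pressure(lstar, lr, p), p$Pc)  # frozen-wall regime holds
  sch <- growth_schedule(a1 = 1e-12, a2 = 1, li0 = li, li_max = 1e6)
  tr <- simulate_cell(p, sch, t_end = 1,
                      init = list(li = li, l = 20, lr = lr))
  expect_equal(tr$l_um[nrow(tr)], lstar, tolerance = 1e-6)
})

test_that("at large hydraulic conductivity the visible length tracks the quasi-static root", {
  # with eta ~ 0 the wall never yields appreciably, so at every t the
  # closed-form root for li(t) and fixed lr is the quasi-static oracle
  pfast <- mech_params(Lw = 4000, eta = 1e-9)
  lr <- 19.6
  sch <- growth_schedule(a1 = 0.69, a2 = 5.04, li0 = 20, li_max = 1e6)
  tr <- simulate_cell(pfast, sch, t_end = 10, record_dt = 1,
                      init = list(li = 20, l = 20, lr = lr))
  a <- pfast$beta
  for (i in 3:nrow(tr)) {
    li_t <- tr$li_um[i]
    b <- (pfast$alpha - pfast$beta) * lr; cc <- -pfast$alpha * lr * li_t
    lstar <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    expect_equal(tr$l_um[i], lstar, tolerance = 1e-3)
  }
})

test_that("eta selection returns the grid argmin of the pressure deviation", {
  sch <- test_schedule(a1 = 1.0354, a2 = 3.2264)
  grid <- c(0.1, 0.15, 0.5, 0.9)
  e <- estimate_eta(p, sch, grid = grid, sample_dt = 0.5)
  obj <- attr(e, "objective")
  expect_equal(nrow(obj), length(grid))
  expect_true(all(obj$deviation[obj$eta == as.numeric(e)] <=
                    obj$deviation + 1e-15))
  # independent recomputation of the objective at each grid point
  brute <- vapply(grid, function(eta) {
    pe <- p; pe$eta <- eta
    tr <- simulate_cell(pe, sch, t_end = sch$t_switch, record_dt = 0.5)
    dev <- abs(tr$p_turg_bar - tr$p_osm_bar)
    sum(diff(tr$time_h) * (dev[-1] + dev[-length(dev)]) / 2)
  }, numeric(1))
  expect_equal(obj$deviation, brute, tolerance = 1e-12)
  expect_equal(as.numeric(e), grid[which.min(brute)])
  expect_error(estimate_eta(p, sch, grid = numeric(0)), "empty")
  expect_error(estimate_eta(p, sch, grid = c(0.5, 1.2)), "in \\(0,1\\)")
})
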