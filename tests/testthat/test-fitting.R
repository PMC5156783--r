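# Interval averaging, the weighted cost, the golden-section optimizer, the
# inverse problem and the sensitivity analysis.

test_that("interval averaging uses the midpoint rule and flags empty intervals", {
  # two cells in one interval -> mean 15
  prof <- profile_average(c(0.2, 0.3), c(10, 20), edges = c(0, 0.5, 1))
  expect_equal(prof$mean_length_um[1], 15)
  expect_equal(prof$n_cells, c(2L, 0L))
  expect_true(is.na(prof$mean_length_um[2]))
  expect_equal(attr(prof, "empty_intervals"), 2L)
  # a cell spanning an interval boundary belongs to exactly one interval
  # (its midpoint interval): midpoint 0.49 -> first interval even though
  # the cell [0.39, 0.59] crosses 0.5
  prof2 <- profile_average(0.49, 200, edges = c(0, 0.5, 1))
  expect_equal(prof2$n_cells, c(1L, 0L))
  expect_error(profile_average(numeric(0), numeric(0), c(0, 1)),
               "no cells")
})

test_that("profile cost is zero iff profiles match and weights grow distally", {
  mk <- function(means) {
    structure(data.frame(interval_start_mm = 0:2, interval_end_mm = 1:3,
                         mean_length_um = means, sem_um = 0,
                         n_cells = 5L),
              class = c("length_profile", "data.frame"))
  }
  base <- mk(c(10, 20, 30))
  expect_equal(profile_cost(base, base), 0)
  # same deviation costs more in the last interval than in the first
  expect_gt(profile_cost(mk(c(10, 20, 33)), base),
            profile_cost(mk(c(13, 20, 30)), base))
  # hand arithmetic: k = (1,2,3)/6, deviations (1, 0, 2)
  expect_equal(profile_cost(mk(c(11, 20, 32)), base), 13 / 6)
  # mismatched schemes error
  bad <- mk(c(10, 20, 30)); bad$interval_end_mm <- bad$interval_end_mm + 0.1
  expect_error(profile_cost(bad, base), "schemes")
})

test_that("golden-section search minimizes a quadratic", {
  gs <- golden_section(function(x) (x - 3)^2, 0, 10, tol = 1e-8)
  expect_equal(gs$minimum, 3, tolerance = 1e-6)
  expect_equal(gs$objective, 0, tolerance = 1e-12)
})

test_that("the inverse problem reproduces the visible-length landmarks", {
  inv <- wheat_inverse()
  cons <- kinematic_constants()
  expect_equal(inv$li0, cons$l0)
  # defining property: replay hits the division-zone landmark
  expect_lt(abs(inv$l_div_fit - cons$l_div), 0.1)
  # and the end-of-elongation landmark
  expect_lt(abs(inv$l_elong_fit - cons$l_elong), 0.5)
  # li_max is the schedule value at the switch
  expect_equal(inv$li_max, inv$li0 + inv$a1 * cons$t_div)
  expect_named(coef(inv), c("a1", "a2", "li0", "li_max"))
})

test_that("in the rigid-osmotic limit the slow rate approaches the kinematic estimate", {
  # alpha -> infinity makes the visible length track the isosmotic length,
  # so a1 -> (l_div - l0) / t_div = 0.5967 um/h analytically
  inv <- solve_inverse_problem(params = mech_params(alpha = 1e5),
                               a1_bracket = c(0.3, 2))
  expect_equal(inv$a1, (29.48 - 14.74) / 24.7, tolerance = 0.02)
})

test_that("sensitivities carry the expected signs with eta dominant", {
  inv <- wheat_inverse()
  tab <- sensitivity_analysis(mech_params(), inv$schedule, horizon = 24,
                              n_probe = 7)
  s <- stats::setNames(tab$sensitivity, tab$parameter)
  expect_true(all(tab$n_ok == 7))
  expect_gt(s["Lw"], 0)
  expect_gt(s["alpha"], 0)
  expect_gt(s["eta"], 0)
  expect_lt(s["beta"], 0)
  expect_lt(s["Pc"], 0)
  expect_true(all(abs(s["eta"]) > abs(s[c("Lw", "alpha", "beta", "Pc")])))
  # the strongest runners-up keep their relative order
  expect_gt(abs(s["Pc"]), abs(s["alpha"]))
})
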