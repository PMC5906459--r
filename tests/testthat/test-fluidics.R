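test_that("tube volume matches geometry and a numerical-integration oracle", {
  expect_equal(round(tube_volume(tube_spec())), 11)
  expect_equal(tube_volume(tube_spec(22, 250)), 10.799, tolerance = 1e-4)
  expect_equal(tube_volume(tube_spec(0, 250)), 0)
  expect_equal(tube_volume(tube_spec(10, 500)), 19.63, tolerance = 1e-3)

  # oracle: integrate the (constant) cross-section along the length
  for (tb in list(tube_spec(), tube_spec(10, 500), tube_spec(3.7, 127))) {
    area_ul_per_cm <- function(x) {
      rep(pi * (tb$inner_diameter_um / 2 * 1e-4)^2 * 1e3, length(x))
    }
    oracle <- stats::integrate(area_ul_per_cm, 0, tb$length_cm,
                               rel.tol = 1e-12)$value
    expect_equal(tube_volume(tb), oracle, tolerance = 1e-9)
  }
})

test_that("breakthrough is 0.5 at one tube volume and saturates to 1", {
  tb <- tube_spec(); fl <- flow_spec()
  t_one <- tube_volume(tb) / fl$flowrate_ul_s
  expect_equal(breakthrough(tb, fl, t_one), 0.5)
  expect_equal(breakthrough(tb, fl, 1e7), 1, tolerance = 1e-9)
  expect_equal(breakthrough(tb, fl, 0), 0)
  expect_error(breakthrough(tb, flow_spec(flowrate_ul_s = 0), 1), "flowrate")
})

test_that("breakthrough is non-decreasing and bounded in [0,1] across random specs", {
  set.seed(7)
  for (rep in 1:25) {
    tb <- tube_spec(runif(1, 5, 50), runif(1, 100, 800))
    fl <- flow_spec(runif(1, 0.5, 5), 10^runif(1, -10, -9))
    times <- sort(runif(60, 0, 6 * tube_volume(tb) / fl$flowrate_ul_s))
    c_t <- breakthrough(tb, fl, times)
    expect_true(all(c_t >= 0 & c_t <= 1))
    expect_true(all(diff(c_t) >= -1e-12))
  }
})

test_that("switch completeness needs about 4.5 tube volumes at defaults, under 5", {
  tb <- tube_spec(); fl <- flow_spec()
  n999 <- volumes_to_completeness(tb, fl, 0.999)
  expect_lt(n999, 5)
  expect_gt(n999, 4)
  expect_equal(n999, 4.486, tolerance = 1e-3)
  expect_equal(volumes_to_completeness(tb, fl, 0.5 + 1e-9), 1, tolerance = 1e-3)
  expect_lt(volumes_to_completeness(tb, fl, 0.99), n999)
  expect_error(volumes_to_completeness(tb, fl, 0.4), "threshold")
  expect_error(volumes_to_completeness(tb, fl, 1), "threshold")
})

test_that("completeness threshold of 0.5 needs exactly one tube volume for any spec", {
  set.seed(11)
  for (rep in 1:10) {
    tb <- tube_spec(runif(1, 5, 50), runif(1, 100, 800))
    fl <- flow_spec(runif(1, 0.5, 5))
    expect_equal(volumes_to_completeness(tb, fl, 0.5 + 1e-12), 1,
                 tolerance = 1e-4)
  }
})

test_that("plug-flow limit: without shear dispersion and tiny diffusivity the switch is a step", {
  tb <- tube_spec()
  fl <- flow_spec(diffusivity_m2_s = 1e-14)
  t_one <- tube_volume(tb) / fl$flowrate_ul_s
  expect_lt(breakthrough(tb, fl, 0.99 * t_one, dispersion = FALSE), 1e-6)
  expect_gt(breakthrough(tb, fl, 1.01 * t_one, dispersion = FALSE), 1 - 1e-6)
  # with dispersion enabled the front is spread over a finite width
  expect_gt(breakthrough(tb, flow_spec(), 0.9 * t_one), 0.05)
})

test_that("dispersion regime diagnostic flags the marginal default operating point", {
  reg <- dispersion_regime(tube_spec(), flow_spec())
  expect_true(reg$marginal)
  expect_warning(breakthrough(tube_spec(), flow_spec(), 10, warn_regime = TRUE),
                 "marginal")
  # slow flow in a hair-thin tube is deep in the Taylor regime
  reg2 <- dispersion_regime(tube_spec(100, 20), flow_spec(0.001))
  expect_false(reg2$marginal)
})

test_that("wash steps reduce carryover geometrically", {
  m <- carryover_model()
  expect_equal(carryover_after_washes(m, 0), 0.32)
  expect_equal(carryover_after_washes(m, 1), 0.032)
  expect_lt(carryover_after_washes(m, 2), 0.02)
  expect_equal(carryover_after_washes(carryover_model(f = 0), 0:5),
               rep(0, 6))
  pcts <- carryover_after_washes(m, 0:4)
  expect_true(all(diff(pcts) < 0))
  expect_error(carryover_after_washes(m, -1))
})

test_that("backpressure balance classifies bubble vs droplet risk", {
  balanced_h <- 200 / (1000 * 9.80665) * 100  # cm giving exactly 200 Pa
  expect_equal(as.character(backpressure_state(
    backpressure_config(reservoir_height_cm = balanced_h))), "balanced")
  expect_equal(as.character(backpressure_state(
    backpressure_config(reservoir_height_cm = 0))), "bubble_risk")
  expect_equal(as.character(backpressure_state(
    backpressure_config(reservoir_height_cm = 50))), "droplet_risk")
})

test_that("breakthrough curves export as CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_breakthrough_csv(tube_spec(), flow_spec(), c(0, 5, 10, 27), path)
  df <- read.csv(path)
  expect_equal(names(df), c("time_s", "fraction"))
  expect_equal(df$fraction,
               breakthrough(tube_spec(), flow_spec(), c(0, 5, 10, 27)))
})
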