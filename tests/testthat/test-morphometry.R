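test_that("the single-pit rim edge matches the closed form sigma*sqrt(3+sqrt(6))", {
  fit <- make_fit()  # A_para = 0, sigma_pit = 500
  rim <- locate_rim_edge(fit, "nasal")
  expect_equal(rim$d, 500 * sqrt(3 + sqrt(6)), tolerance = 1e-6)
  # brute-force verification on a 0.01 µm grid
  grid <- seq(0.01, 3000, by = 0.01)
  brute <- grid[which.max(dog_eval(fit, "nasal", grid, order = 3))]
  expect_lt(abs(rim$d - brute), 1)
})

test_that("rim refinement agrees with a brute-force argmax on random fits", {
  set.seed(77)
  for (rep in seq_len(10)) {
    fit <- make_fit(baseline = runif(1, 100, 300), nasal = random_side(),
                    temporal = random_side())
    for (side in c("nasal", "temporal")) {
      rim <- locate_rim_edge(fit, side)
      grid <- seq(0.01, fit$d_max[[side]], by = 0.01)
      brute <- grid[which.max(dog_eval(fit, side, grid, order = 3))]
      expect_lt(abs(rim$d - brute), 1)
    }
  }
})

test_that("symmetric fits give equal rim distances and slopes on both sides", {
  fit <- make_fit(baseline = 200,
                  nasal = list(a_pit = 90, sigma_pit = 400,
                               a_para = 30, sigma_para = 1400))
  rn <- locate_rim_edge(fit, "nasal")
  rt <- locate_rim_edge(fit, "temporal")
  expect_equal(rn$d, rt$d, tolerance = 1e-8)
  expect_equal(steepest_slope(fit, "nasal")$gradient,
               steepest_slope(fit, "temporal")$gradient, tolerance = 1e-10)
})

test_that("the single-pit steepest slope matches A/(sigma*sqrt(e)) at d = sigma", {
  fit <- make_fit()
  sl <- steepest_slope(fit, "nasal", rim_d = 500 * sqrt(3 + sqrt(6)))
  expect_equal(sl$gradient, 100 / (500 * sqrt(exp(1))), tolerance = 1e-8)
  expect_equal(sl$d, 500, tolerance = 1e-3)
  expect_equal(sl$degrees, atan(sl$gradient) * 180 / pi)
})

test_that("steepest slope matches a brute-force grid maximum on random fits", {
  set.seed(42)
  for (rep in seq_len(10)) {
    fit <- make_fit(baseline = runif(1, 100, 300), nasal = random_side())
    rim <- locate_rim_edge(fit, "nasal")
    sl <- steepest_slope(fit, "nasal", rim$d)
    grid <- seq(1e-3, rim$d, length.out = 200000)
    brute <- max(abs(dog_eval(fit, "nasal", grid, order = 1)))
    expect_lt(abs(sl$gradient - brute) / brute, 1e-4)
  }
})

test_that("analytic pit area agrees with a trapezoid oracle within 0.1%", {
  set.seed(9)
  for (rep in seq_len(10)) {
    fit <- make_fit(baseline = runif(1, 150, 250), nasal = random_side(),
                    temporal = random_side())
    m <- compute_metrics(fit)
    rim_n <- locate_rim_edge(fit, "nasal")
    rim_t <- locate_rim_edge(fit, "temporal")
    x <- seq(-rim_t$d, rim_n$d, by = 0.1)
    contour <- ifelse(
      x >= 0, dog_eval(fit, "nasal", pmax(x, 0)),
      dog_eval(fit, "temporal", pmax(-x, 0)))
    chord <- rim_t$h + (rim_n$h - rim_t$h) * (x + rim_t$d) / (rim_n$d + rim_t$d)
    trap_fun <- chord - contour
    trap <- sum((trap_fun[-1] + trap_fun[-length(x)]) / 2 * diff(x))
    expect_lt(abs(m$area - trap) / abs(trap), 1e-3)
  }
})

test_that("metric definitions combine the rim landmarks as documented", {
  # symmetric single pit: width = 2 * 2.3344 * sigma, cft = B - A_pit
  fit <- make_fit(baseline = 200)
  m <- compute_metrics(fit)
  expect_equal(m$width, 2 * sqrt(3 + sqrt(6)) * 500, tolerance = 1e-4)
  expect_equal(m$cft, 100, tolerance = 1e-9)
  expect_equal(m$depth, (m$rim_h_nasal + m$rim_h_temporal) / 2 - m$cft)
  expect_equal(m$width, m$rim_d_nasal + m$rim_d_temporal)
  expect_gt(m$depth, 0)
  expect_gt(m$area, 0)
  # pRT at 1000 µm equals the fitted contour there
  expect_equal(m$prt_nasal, dog_eval(fit, "nasal", 1000), tolerance = 1e-12)
})

test_that("pRT is flagged missing when the profile stops short of 1000 µm", {
  fit <- make_fit()
  short_profile <- ilm_profile(seq(-800, 800, by = 20),
                               rep(100, 81), units = "um")
  m <- compute_metrics(fit, short_profile)
  expect_true(all(m$prt_missing))
  expect_true(is.na(m$prt_nasal) && is.na(m$prt_temporal))
  expect_false(is.na(m$width))
})

test_that("parafovea classification follows the amplitude sign with a dead zone", {
  side <- function(a) list(a_pit = 100, sigma_pit = 500,
                           a_para = a, sigma_para = 1500)
  expect_equal(classify_parafovea(make_fit(nasal = side(-50)), "nasal"),
               "inverted")
  expect_equal(classify_parafovea(make_fit(nasal = side(50)), "nasal"),
               "noninverted")
  expect_equal(classify_parafovea(make_fit(nasal = side(0.5)), "nasal"),
               "indeterminate")
})

test_that("scaling fitted heights scales thickness metrics and leaves distances fixed", {
  fit <- make_fit(baseline = 200,
                  nasal = list(a_pit = 90, sigma_pit = 400,
                               a_para = 30, sigma_para = 1400),
                  temporal = list(a_pit = 70, sigma_pit = 350,
                                  a_para = -20, sigma_para = 1200))
  m1 <- compute_metrics(fit)
  c_scale <- 2.5
  fit2 <- fit
  fit2$baseline <- fit$baseline * c_scale
  for (s in c("nasal", "temporal")) {
    fit2[[s]]$a_pit <- fit[[s]]$a_pit * c_scale
    fit2[[s]]$a_para <- fit[[s]]$a_para * c_scale
  }
  m2 <- compute_metrics(fit2)
  expect_equal(m2$width, m1$width, tolerance = 1e-6)
  expect_equal(m2$rim_d_nasal, m1$rim_d_nasal, tolerance = 1e-6)
  expect_equal(m2$cft, m1$cft * c_scale, tolerance = 1e-6)
  expect_equal(m2$depth, m1$depth * c_scale, tolerance = 1e-6)
  expect_equal(m2$area, m1$area * c_scale, tolerance = 1e-6)
  expect_equal(m2$slope_nasal, m1$slope_nasal * c_scale, tolerance = 1e-6)
})

test_that("mirroring swaps nasal and temporal metrics without changing totals", {
  nasal <- list(a_pit = 90, sigma_pit = 400, a_para = 30, sigma_para = 1400)
  temporal <- list(a_pit = 70, sigma_pit = 350, a_para = -20, sigma_para = 1200)
  m <- compute_metrics(make_fit(baseline = 200, nasal = nasal,
                                temporal = temporal))
  mm <- compute_metrics(make_fit(baseline = 200, nasal = temporal,
                                 temporal = nasal))
  expect_equal(m$width, mm$width, tolerance = 1e-9)
  expect_equal(m$area, mm$area, tolerance = 1e-9)
  expect_equal(m$depth, mm$depth, tolerance = 1e-9)
  expect_equal(m$slope_nasal, mm$slope_temporal, tolerance = 1e-9)
  expect_equal(m$rim_d_nasal, mm$rim_d_temporal, tolerance = 1e-9)
  expect_equal(m$prt_nasal, mm$prt_temporal, tolerance = 1e-12)
})
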