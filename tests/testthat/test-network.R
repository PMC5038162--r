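test_that("wall stiffness follows the exponential-plus-offset law", {
  p0 <- tube_law_params(k1 = 0, k3 = 8e5)
  expect_equal(wall_stiffness(c(0.1, 1, 2), p0), rep(8e5, 3))

  p <- tube_law_params()
  # strictly decreasing in radius for k1 > 0, k2 < 0
  r <- seq(0.05, 1.5, by = 0.05)
  expect_true(all(diff(wall_stiffness(r, p)) < 0))
  expect_gt(wall_stiffness(0.2, p), wall_stiffness(0.4, p))

  # doubling k3 (arterial stiffening scenario) adds exactly k3 at fixed r0
  p2 <- tube_law_params(k3 = 2 * p$k3)
  expect_equal(wall_stiffness(0.7, p2) - wall_stiffness(0.7, p), p$k3)
  expect_error(wall_stiffness(-1, p), "positive")
})

test_that("tube law and its inverse are consistent", {
  p <- tube_law_params(P0_mmHg = 10)
  r0 <- 0.6
  A0 <- pi * r0^2
  expect_equal(pressure_from_area(A0, r0, p), p$P0)
  f <- (4 / 3) * wall_stiffness(r0, p)
  expect_equal(pressure_from_area(4 * A0, r0, p), p$P0 + f / 2)
  expect_equal(area_from_pressure(p$P0, r0, p), A0)
  expect_equal(area_from_pressure(p$P0 + f / 2, r0, p), 4 * A0)

  # round trip on random states
  set.seed(42)
  A <- A0 * exp(stats::runif(100, -0.5, 1.5))
  back <- area_from_pressure(pressure_from_area(A, r0, p), r0, p)
  expect_lt(max(abs(back - A) / A), 1e-12)

  # monotone: increasing pressure -> increasing area
  Ps <- p$P0 + seq(0, 0.9, by = 0.05) * f
  expect_true(all(diff(area_from_pressure(Ps, r0, p)) > 0))

  # asymptote rejected with a message naming the limit
  expect_error(area_from_pressure(p$P0 + f, r0, p), "asymptote")
})

test_that("wave speed matches the analytic pressure-area derivative", {
  p <- tube_law_params()
  r0 <- 0.5
  A0 <- pi * r0^2
  expect_equal(wave_speed(A0, r0, p),
               sqrt(2 * wall_stiffness(r0, p) / (3 * p$rho * 1)))
  # central finite-difference oracle for c^2 = (A/rho) dP/dA
  for (A in c(0.6, 1, 1.7) * A0) {
    h <- 1e-6 * A
    dPdA <- (pressure_from_area(A + h, r0, p) -
               pressure_from_area(A - h, r0, p)) / (2 * h)
    expect_equal(wave_speed(A, r0, p), sqrt(A / p$rho * dPdA),
                 tolerance = 1e-6)
  }
  # stiffening raises the wave speed at fixed area
  p2 <- tube_law_params(k3 = 2 * p$k3)
  expect_gt(wave_speed(A0, r0, p2), wave_speed(A0, r0, p))
})

test_that("segment taper is monotone between the end radii", {
  seg <- list(length_cm = 10, r_top_cm = 0.8, r_bottom_cm = 0.5)
  x <- seq(0, 10, length.out = 50)
  r <- taper_radius(seg, x)
  expect_equal(r[1], 0.8)
  expect_equal(r[50], 0.5)
  expect_true(all(diff(r) < 0))
  expect_error(taper_radius(seg, 11), "outside")
})

test_that("network validation enforces the topology invariants", {
  seg <- tibble::tibble(
    id = 1:3, name = c("p", "a", "b"), length_cm = 5,
    r_top_cm = c(0.5, 0.3, 0.3), r_bottom_cm = c(0.5, 0.3, 0.3),
    daughter_1 = c(2L, NA, NA), daughter_2 = c(3L, NA, NA),
    bed_root_radius_cm = c(NA, 0.3, 0.3))
  expect_s3_class(arterial_network(seg), "arterial_network")

  bad <- seg; bad$daughter_1[2] <- 1L      # cycle / double parent
  expect_error(arterial_network(bad))
  bad <- seg; bad$bed_root_radius_cm[1] <- 0.2  # bed on a non-terminal
  expect_error(arterial_network(bad), "terminal")
  bad <- seg; bad$r_bottom_cm[1] <- 0.6    # inverted taper
  expect_error(arterial_network(bad), "taper")
  bad <- seg[1:2, ]                        # daughter 3 missing
  expect_error(arterial_network(bad), "unknown")
})

test_that("the default network has 24 connected segments and 12 beds", {
  net <- default_network()
  expect_equal(nrow(net$segments), 24L)
  expect_length(terminal_ids(net), 12L)
  expect_equal(net$segments$name[net$segments$id == net$root_id],
               "ascending_aorta")
  # one series (single-daughter) junction in the abdominal aorta
  n_d <- rowSums(!is.na(net$segments[, c("daughter_1", "daughter_2")]))
  expect_equal(sort(unique(n_d)), c(0, 1, 2))
  expect_equal(sum(n_d == 1), 1L)
})

test_that("network files round-trip through CSV and JSON", {
  net <- make_test_network("symmetric_bifurcation")
  for (ext in c("csv", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_network(net, f)
    back <- read_network(f)
    expect_equal(back$segments$r_top_cm, net$segments$r_top_cm)
    expect_equal(back$segments$daughter_2, net$segments$daughter_2)
    unlink(f)
  }
})
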