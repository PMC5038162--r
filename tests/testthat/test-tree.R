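test_that("daughter scaling factors satisfy the radius-exponent identity", {
  ab <- alpha_beta(3, 1)
  expect_equal(unname(ab["alpha"]), 2^(-1 / 3))
  expect_equal(unname(ab["beta"]), 2^(-1 / 3))

  for (xi in c(2.33, 2.4, 2.76, 3)) {
    for (g in c(1, 1.5, 1 / 0.41, 4)) {
      ab <- alpha_beta(xi, g)
      expect_lt(abs(ab[["alpha"]]^xi + ab[["beta"]]^xi - 1), 1e-12)
      expect_true(ab[["beta"]] <= ab[["alpha"]])
      expect_true(ab[["alpha"]] < 1 && ab[["beta"]] > 0)
      # area ratio from the returned pair equals the closed form
      eta <- ab[["alpha"]]^2 + ab[["beta"]]^2
      expect_lt(abs(eta - lvsa:::area_ratio(xi, g)), 1e-10)
    }
  }
  # the asymmetry-ratio convention (< 1) is normalised by reciprocal
  expect_equal(alpha_beta(2.76, 0.41), alpha_beta(2.76, 1 / 0.41))
})

test_that("tree generation terminates at r_min with the expected census", {
  # alpha = 0.8, beta = 0.6 arises exactly from xi = 2, gamma = (4/3)^2
  suppressWarnings(p <- tree_params(xi = 2, gamma = 16 / 9, r_min = 0.01))
  ab <- alpha_beta(2, 16 / 9)
  expect_equal(unname(ab), c(0.8, 0.6), tolerance = 1e-12)
  bed <- build_tree(0.02, p)
  # enumeration oracle: radii (um) 200; 160,120; 128,96,96,72; 102.4,76.8;
  # 81.92,61.44 -> 11 vessels, 6 leaves
  expect_equal(bed$vessel_count, 11L)
  expect_equal(bed$leaf_count, 6L)
  expect_setequal(round(1e4 * bed$vessels$radius, 2),
                  c(200, 160, 120, 128, 96, 96, 72, 102.4, 76.8, 81.92, 61.44))
  expect_true(all(bed$vessels$length == p$lr_ratio * bed$vessels$radius))

  # root below r_min: a single leaf vessel
  single <- build_tree(0.005, p)
  expect_equal(single$vessel_count, 1L)
  expect_true(single$vessels$is_leaf)

  # memoised count agrees with the materialised records
  expect_equal(count_tree_vessels(0.02, p), nrow(bed$vessels))
})

test_that("memoised counts equal brute-force recounts and shrink under rarefaction", {
  p76 <- tree_params(xi = 2.76, r_min = 0.02)
  for (r in c(0.05, 0.11, 0.2)) {
    bed <- build_tree(r, p76)
    expect_equal(count_tree_vessels(r, p76), nrow(bed$vessels))
  }
  # vessel counts are non-increasing as xi falls (alpha/beta shrink)
  counts <- vapply(c(3, 2.76, 2.5, 2.4, 2.33),
                   function(x) count_tree_vessels(0.2, tree_params(xi = x, r_min = 0.02)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  net <- make_test_network("symmetric_bifurcation")
  expect_equal(count_network_vessels(net, p76),
               2 * count_tree_vessels(0.35, p76))
  one <- arterial_network(tibble::tibble(
    id = 1L, name = "v", length_cm = 5, r_top_cm = 0.3, r_bottom_cm = 0.3,
    daughter_1 = NA_integer_, daughter_2 = NA_integer_,
    bed_root_radius_cm = 0.01))
  expect_equal(count_network_vessels(one, p76), 1)
})

test_that("root impedance has the Poiseuille DC limit and a real impulse response", {
  law <- tube_law_params()
  mu <- law$rho * law$nu
  # single vessel (root below r_min)
  p <- tree_params(r_min = 0.05)
  zs <- root_impedance(0.03, p, law, n_freq = 512)
  L <- p$lr_ratio * 0.03
  expect_equal(zs$R_dc, 8 * mu * L / (pi * 0.03^4))
  expect_equal(Re(zs$Z[1]), zs$R_dc)

  # symmetric two-leaf tree: R_parent + R_leaf/2 (gamma = 1 -> equal daughters)
  p2 <- tree_params(xi = 2.76, gamma = 1, r_min = 0.05)
  ab <- alpha_beta(2.76, 1)
  r0 <- 0.06
  z2 <- root_impedance(r0, p2, law, n_freq = 512)
  rl <- ab[["alpha"]] * r0
  expect_lt(rl, p2$r_min)
  R_par <- 8 * mu * (p2$lr_ratio * r0) / (pi * r0^4)
  R_leaf <- 8 * mu * (p2$lr_ratio * rl) / (pi * rl^4)
  expect_equal(z2$R_dc, R_par + R_leaf / 2, tolerance = 1e-12)

  # DC oracle: independent series/parallel recursion over explicit records
  p3 <- tree_params(r_min = 0.04)
  bed <- build_tree(0.15, p3)
  resist <- function(id) {
    v <- bed$vessels[bed$vessels$id == id, ]
    own <- 8 * mu * v$length / (pi * v$radius^4)
    kids <- bed$vessels$id[bed$vessels$parent == id]
    if (length(kids) == 0) return(own)
    own + 1 / sum(1 / vapply(kids, resist, numeric(1)))
  }
  z3 <- root_impedance(0.15, p3, law, n_freq = 512)
  expect_lt(abs(z3$R_dc - resist(1)) / resist(1), 1e-8)

  # Hermitian symmetry was used: impulse response is real and the convolution
  # of a constant flow reproduces the DC resistance
  expect_true(is.numeric(z3$z_time))
  expect_lt(abs(sum(z3$z_time) * z3$dt - z3$R_dc) / z3$R_dc, 1e-8)
})

test_that("terminating radius and rarefaction move the DC resistance as expected", {
  law <- tube_law_params()
  # for xi < 3 each added generation contributes more resistance than it
  # removes by parallelism (2^(3/xi - 1) > 1), so deeper trees (smaller
  # r_min) are more resistive and truncating earlier lowers Z(0)
  z_lo <- root_impedance(0.2, tree_params(r_min = 0.02), law, n_freq = 256)
  z_hi <- root_impedance(0.2, tree_params(r_min = 0.05), law, n_freq = 256)
  expect_lt(z_hi$R_dc, z_lo$R_dc)
  # rarefaction (xi 2.76 -> 2.4) raises the resistance at fixed gamma
  z_rare <- root_impedance(0.2, tree_params(xi = 2.4, r_min = 0.02), law,
                           n_freq = 256)
  expect_gt(z_rare$R_dc, z_lo$R_dc)
  expect_lt(count_tree_vessels(0.2, tree_params(xi = 2.4, r_min = 0.02)),
            count_tree_vessels(0.2, tree_params(xi = 2.76, r_min = 0.02)))
})

test_that("tree parameter validation and serialisation work", {
  expect_warning(tree_params(xi = 2.0), "physiological")
  expect_error(tree_params(xi = -1), "positive")
  expect_equal(tree_params(gamma = 0.41)$gamma, 1 / 0.41)

  suppressWarnings(bed <- build_tree(0.02, tree_params(xi = 2, gamma = 16 / 9)))
  f <- tempfile(fileext = ".json")
  write_bed(bed, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(nrow(back$vessels), bed$vessel_count)
  unlink(f)

  zs <- root_impedance(0.03, tree_params(r_min = 0.05), n_freq = 256)
  f2 <- tempfile(fileext = ".csv")
  write_impedance(zs, f2)
  tab <- utils::read.csv(f2)
  expect_equal(nrow(tab), 129)  # N/2 + 1 frequencies
  expect_equal(tab$Re_Z[1], zs$R_dc)
  unlink(f2)
})
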