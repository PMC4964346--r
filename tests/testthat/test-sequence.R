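# Effective b-matrix computation, prospective adjustment, polarity reversal
# and gradient calibration.

test_that("numeric b integration matches the Stejskal-Tanner closed form", {
  sq <- sequence_timing(g_amplitude = 0.5, direction = c(1, 0, 0))
  bc <- compute_b_components(sq)
  gam <- sq$gyromagnetic_ratio
  bst <- gam^2 * 0.5^2 * (2e-3)^2 * (5.5e-3 - 2e-3 / 3) / 1e6
  expect_lt(abs(bc$b_diffusion - bst) / bst, 1e-9)
  expect_equal(bc$b_imaging, 0)
  expect_equal(bc$b_cross, 0)

  # zero gradients: all components vanish
  b0 <- compute_b_components(sequence_timing(g_amplitude = 0))
  expect_equal(b0$b_effective, 0)

  # amplitude helper inverts the closed form
  g <- stejskal_tanner_amplitude(sq, 1000)
  sq$g_amplitude <- g
  expect_equal(compute_b_components(sq)$b_diffusion, 1000, tolerance = 1e-9)
})

test_that("cross-terms respect geometry, sign reversal and bilinearity", {
  base <- calibrate_crusher(sequence_timing(g_amplitude = 0.5,
                                            direction = c(0, 0, 1)), 61)
  # direction perpendicular to the crusher axis: no cross-term
  perp <- base; perp$direction <- c(1, 0, 0)
  expect_equal(compute_b_components(perp)$b_cross, 0)

  bz <- compute_b_components(base)
  expect_gt(abs(bz$b_cross), 1)
  # reversing the diffusion direction flips the cross-term exactly
  neg <- base; neg$direction <- -base$direction
  bn <- compute_b_components(neg)
  expect_equal(bn$b_cross, -bz$b_cross, tolerance = 1e-12)
  expect_equal(bn$b_diffusion, bz$b_diffusion, tolerance = 1e-12)

  # bilinearity: doubling the crusher doubles b_cross, quadruples b_imaging
  dbl <- base; dbl$crusher_amplitude <- 2 * base$crusher_amplitude
  bd <- compute_b_components(dbl)
  expect_equal(bd$b_cross / bz$b_cross, 2, tolerance = 1e-9)
  expect_equal(bd$b_imaging / bz$b_imaging, 4, tolerance = 1e-9)

  # decomposition additivity
  expect_lt(abs(bz$b_effective - (bz$b_diffusion + bz$b_imaging + bz$b_cross)),
            1e-9 * bz$b_effective)
})

test_that("overlapping gradient lobes are rejected", {
  sq <- sequence_timing(g_amplitude = 0.5, crusher_amplitude = 0.5,
                        crusher_duration = 2, crusher_gap = 0.2)
  expect_error(compute_b_components(sq), "overlap")
})

test_that("prospective adjustment reaches the nominal b in every direction", {
  seq_t <- calibrate_crusher(sequence_timing(), 61)
  s0 <- seq_t; s0$g_amplitude <- 0
  expect_equal(compute_b_components(s0)$b_imaging, 61, tolerance = 1e-9)

  sch <- scheme61()
  adj <- prospective_adjust(sch, seq_t)
  expect_true(all(adj$table$b_effective >= 999))
  expect_true(all(adj$table$b_effective <= 1001))
  expect_true(all(abs(adj$table$b_effective - 1000) < 0.001 * 1000))
  expect_true(all(adj$table$iterations <= 3))

  # direction perpendicular to the crusher: additive split 939 + 61
  perp_i <- which.min(abs(sch$directions[, 3]))
  expect_lt(abs(sch$directions[perp_i, 3]), 0.2)
  perp_dirs <- matrix(c(1, 0, 0), 1)
  adj2 <- prospective_adjust(gradient_scheme(directions = perp_dirs), seq_t)
  expect_equal(adj2$table$b_diffusion, 939, tolerance = 1e-3)
  expect_equal(adj2$table$b_effective, 1000, tolerance = 1)

  # fixed point: no crushers means the Stejskal-Tanner amplitude is kept
  noc <- sequence_timing()
  adj3 <- prospective_adjust(gradient_scheme(directions = perp_dirs), noc)
  expect_equal(adj3$table$g_adjusted, adj3$table$g_unadjusted,
               tolerance = 1e-12)

  # unreachable target
  expect_error(
    prospective_adjust(gradient_scheme(directions = perp_dirs, b_nominal = 50),
                       seq_t), "unreachable")
})

test_that("adjustment round-trips for random crusher configurations", {
  set.seed(42)
  for (i in 1:100) {
    u <- unitv(rnorm(3))
    cd <- runif(1, 0.4, 1.5)
    gp <- runif(1, 0.05, 1.7 - cd)
    bi <- runif(1, 5, 100)
    sq <- calibrate_crusher(sequence_timing(crusher_duration = cd,
                                            crusher_gap = gp), bi)
    sq$direction <- u
    adj <- prospective_adjust(gradient_scheme(directions = matrix(u, 1)), sq)
    sq$g_amplitude <- adj$table$g_adjusted
    expect_equal(compute_b_components(sq)$b_effective, 1000, tolerance = 1)
  }
})

test_that("reversed-polarity combination cancels cross-terms exactly", {
  sch <- scheme61()
  b <- 1000; cc <- 200; D <- 1.1e-3  # mm^2/s
  nd <- nrow(sch$directions)
  mk <- function(sgn) {
    s <- exp(-(b + sgn * cc) * D)
    stack <- list(data = array(rep(c(rep(exp(0), sch$n_b0), rep(s, nd)),
                                   each = 8), c(2, 2, 2, sch$n_b0 + nd)),
                  scheme = if (sgn > 0) sch else
                    gradient_scheme(sch$n_b0, -sch$directions, sch$b_nominal),
                  voxel_size = 0.1)
    class(stack) <- "dwi_stack"
    stack
  }
  plus <- mk(1); minus <- mk(-1)
  comb <- combine_reversed_polarity(plus, minus)
  expect_equal(max(abs(comb$data[, , , sch$n_b0 + 1] - exp(-b * D))), 0,
               tolerance = 1e-12 * exp(-b * D))

  # cross-free inputs pass through unchanged
  p0 <- mk(1); p0$data <- abs(p0$data)
  m0 <- mk(-1); m0$data <- p0$data
  same <- combine_reversed_polarity(p0, m0)
  expect_equal(same$data, p0$data)

  # a zero voxel in one input stays zero and is counted
  z <- mk(1); z$data[1, 1, 1, 9] <- 0
  cz <- combine_reversed_polarity(z, minus)
  expect_equal(cz$data[1, 1, 1, 9], 0)
  expect_gte(attr(cz, "n_zero"), 1)

  # mismatched schemes are rejected
  expect_error(combine_reversed_polarity(plus, plus), "sign")
})

test_that("gradient calibration factors follow the square-root law", {
  expect_equal(unname(gradient_calibration_factors(c(1, 1, 1), 1)$scale),
               c(1, 1, 1))
  f <- gradient_calibration_factors(c(1, 0.81, 1), 1)
  expect_equal(unname(f$scale[2]), 1 / 0.9, tolerance = 1e-12)
  expect_error(gradient_calibration_factors(c(1, -1, 1), 1), "positive")

  # simulation round trip: measure per-axis ADC under a hidden scale,
  # apply the correction, re-measure
  hidden <- c(1, 0.9, 0.95)
  D <- 1.4e-3
  measure <- function(applied) {
    vapply(1:3, function(ax) {
      u <- c(0, 0, 0); u[ax] <- 1
      g <- hidden[ax] * applied[ax]
      -log(exp(-1000 * g^2 * D)) / 1000   # fitted with nominal b = 1000
    }, numeric(1))
  }
  f2 <- gradient_calibration_factors(measure(c(1, 1, 1)), D)
  remeasured <- measure(f2$scale)
  f3 <- gradient_calibration_factors(remeasured, D)
  expect_equal(unname(f3$scale), c(1, 1, 1), tolerance = 1e-6)
})

test_that("reference diffusivity table interpolates monotonically", {
  d20 <- reference_diffusivity(20)
  d25 <- reference_diffusivity(25)
  expect_gt(d25, d20)
  expect_equal(reference_diffusivity(22.5),
               mean(c(reference_diffusivity(22), reference_diffusivity(23))),
               tolerance = 0.01)
})
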