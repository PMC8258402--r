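test_that("vessel length sums consecutive Euclidean steps", {
  expect_equal(vessel_length(centerline(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(vessel_length(centerline(rbind(c(0, 0), c(1, 0), c(2, 0)))), 2)
  semi <- generate_curve(curve_spec("circular_arc", 2, arc_angle = pi,
                                    sample_count = 2000))$centerline
  expect_equal(vessel_length(semi), pi, tolerance = 1e-3)
})

test_that("distance metric matches closed forms", {
  straight <- centerline(cbind(seq(0, 10, length.out = 50), 0))
  expect_equal(distance_metric(straight), 1)
  semi <- generate_curve(curve_spec("circular_arc", 2, arc_angle = pi,
                                    sample_count = 1000))$centerline
  expect_equal(distance_metric(semi), pi / 2, tolerance = 1e-4)
  sine <- centerline(sine_unit_samples(1000))
  expect_equal(distance_metric(sine), 1.216007, tolerance = 1e-3)
  loop <- centerline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_error(distance_metric(loop), "coincident")
})

test_that("tangent angles match the analytic derivative of sin", {
  sine <- centerline(sine_unit_samples(2000))
  ang <- tangent_angles(sine, window = 3, frame = "image")
  oracle <- atan(cos(sine_unit_samples(2000)[, 1])) * 180 / pi
  interior <- 10:1990
  expect_lt(max(abs(ang[interior] - oracle[interior])), 1)
})

test_that("straight lines give zero angles in any orientation", {
  for (a in c(0, 0.7, 2.1)) {
    pts <- rotate_points(cbind(seq(0, 10, length.out = 80), 0), a, c(3, -2))
    ang <- tangent_angles(centerline(pts), frame = "chord")
    expect_lt(max(abs(ang)), 1e-8)
  }
})

test_that("sd_theta matches a numeric oracle on dense sine samples", {
  expect_equal(sd_theta(rep(42, 10)), 0)
  sine <- centerline(sine_unit_samples(5000))
  # oracle: SD of arctan(cos x) over the same arc-length-uniform sampling
  oracle <- sd(atan(cos(sine_unit_samples(5000)[, 1])) * 180 / pi)
  expect_equal(sd_theta(tangent_angles(sine, frame = "image")), oracle,
               tolerance = 0.02)
  expect_error(sd_theta(5), ">= 2")
})

test_that("critical points count slope sign changes", {
  straight <- centerline(cbind(seq(0, 10, length.out = 50), 0))
  expect_identical(critical_points(straight)$n, 0L)
  semi <- generate_curve(curve_spec("circular_arc", 2, arc_angle = pi,
                                    sample_count = 500))$centerline
  expect_identical(critical_points(semi)$n, 1L)
  sine <- centerline(sine_unit_samples(500))
  cp <- critical_points(sine)
  expect_identical(cp$n, 2L)
  # locations near the quarter- and three-quarter-period apices
  x_at <- sine_unit_samples(500)[cp$index, 1]
  expect_equal(x_at, c(pi / 2, 3 * pi / 2), tolerance = 0.1)
})

test_that("zero-slope plateaus collapse to a single candidate", {
  # flat-top pulse: rise, plateau, fall -> one critical point, not two
  x <- seq(0, 10, length.out = 101)
  y <- pmin(1, pmin(x, 10 - x))
  cp <- critical_points(centerline(cbind(x, y)), window = 1, min_run = 1)
  expect_identical(cp$n, 1L)
})

test_that("inflection segments split where curvature changes sign", {
  straight <- centerline(cbind(seq(0, 10, length.out = 50), 0))
  expect_length(inflection_segments(straight), 1)
  semi <- generate_curve(curve_spec("circular_arc", 2, arc_angle = pi,
                                    sample_count = 500))$centerline
  expect_length(inflection_segments(semi), 1)
  sine <- centerline(sine_unit_samples(800))
  segs <- inflection_segments(sine)
  expect_length(segs, 2)
  # split near x = pi, and the segments cover the curve end to end
  cut <- as.matrix(segs[[1]])[nrow(segs[[1]]), ]
  expect_equal(unname(cut[1]), pi, tolerance = 0.1)
  expect_equal(as.matrix(segs[[1]])[1, ], as.matrix(sine)[1, ])
  expect_equal(as.matrix(segs[[2]])[nrow(segs[[2]]), ],
               as.matrix(sine)[nrow(sine), ])
})

test_that("curvature magnitude is the segment-mean arc/chord ratio", {
  straight <- centerline(cbind(seq(0, 10, length.out = 50), 0))
  expect_equal(curve_magnitude(straight), 1)
  semi <- generate_curve(curve_spec("circular_arc", 2, arc_angle = pi,
                                    sample_count = 800))$centerline
  expect_equal(curve_magnitude(semi), pi / 2, tolerance = 1e-3)
  # sine: mean of the two half-period ratios = (pi/2-ish each) from
  # quadrature: each half has arc 3.820198 and chord pi
  sine <- centerline(sine_unit_samples(800))
  oracle <- sine_arc_quadrature(pi, 1, 2 * pi) / pi
  expect_equal(curve_magnitude(sine), oracle, tolerance = 0.01)
})

test_that("vti is zero iff no critical points and matches the factor oracle", {
  straight <- centerline(cbind(seq(0, 10, length.out = 50), 0))
  expect_identical(vti(straight), 0)
  # monotone-slope arc: no sign change in the image frame, so VTI = 0
  # there; the chord-aligned frame sees the apex
  quarter <- generate_curve(curve_spec("circular_arc", 10, arc_angle = 0.8,
                                       sample_count = 300))$centerline
  tilted <- centerline(rotate_points(as.matrix(quarter), 0.5))
  expect_identical(critical_points(tilted, frame = "image")$n, 0L)
  expect_identical(vti(tilted, frame = "image"), 0)
  expect_identical(tortuosity_metrics(quarter, frame = "chord")$n_critical, 1L)
  # independent oracle: all five factors evaluated on a 10x denser
  # analytic sample of sin(x)
  sine <- centerline(sine_unit_samples(400))
  dense <- sine_unit_samples(4000)
  ang <- atan(cos(dense[, 1])) * 180 / pi
  arc <- sine_arc_quadrature(2 * pi, 1, 2 * pi)
  vti_oracle <- 0.1 * sd(ang) * 2 * (sine_arc_quadrature(pi, 1, 2 * pi) / pi) *
    (arc / (2 * pi))
  expect_equal(vti(sine), vti_oracle, tolerance = 0.02)
})

test_that("dm and vti are rigid-motion invariant and scale correctly", {
  gc <- generate_curve(curve_spec("sinusoid", 20, amplitude = 2,
                                  wavelength = 10, sample_count = 300))
  m0 <- tortuosity_metrics(gc$centerline)
  for (a in c(0.4, 1.3, 2.8)) {
    pts <- rotate_points(as.matrix(gc$centerline), a, c(7, -4))
    m <- tortuosity_metrics(centerline(pts))
    expect_equal(m$dm, m0$dm, tolerance = 1e-6)
    expect_equal(m$vti, m0$vti, tolerance = 1e-6)
  }
  ms <- tortuosity_metrics(centerline(as.matrix(gc$centerline) * 2.5))
  expect_equal(ms$vl_mm, 2.5 * m0$vl_mm, tolerance = 1e-9)
  expect_equal(ms$dm, m0$dm, tolerance = 1e-9)
  expect_equal(ms$vti, m0$vti, tolerance = 1e-9)
})

test_that("dm and vti increase strictly with sinusoid amplitude", {
  amps <- c(0.5, 1, 1.5, 2, 2.5)
  m <- lapply(amps, function(a)
    tortuosity_metrics(generate_curve(curve_spec("sinusoid", 20,
      amplitude = a, wavelength = 10, sample_count = 300))$centerline))
  dms <- vapply(m, `[[`, numeric(1), "dm")
  vtis <- vapply(m, `[[`, numeric(1), "vti")
  expect_true(all(diff(dms) > 0))
  expect_true(all(diff(vtis) > 0))
})

test_that("subject summaries aggregate per-vessel metrics", {
  mk <- function(dm) data.frame(vl_mm = 10 * dm, chord_mm = 10, dm = dm,
                                sd_theta_deg = 5, n_critical = 1L,
                                magnitude = dm, vti = dm)
  metrics <- do.call(rbind, lapply(c(1.0, 1.2, 1.4), mk))
  s <- summarize_subject(metrics)
  expect_identical(s$lsa_count, 3L)
  expect_equal(s$dm_median, 1.2)
  expect_equal(s$dm_mean, 1.2)
  expect_equal(s$dm_sd, sd(c(1, 1.2, 1.4)))
  # single vessel: median = mean, SD reported as 0
  s1 <- summarize_subject(mk(1.3))
  expect_identical(s1$lsa_count, 1L)
  expect_equal(s1$dm_median, s1$dm_mean)
  expect_identical(s1$dm_sd, 0)
  expect_error(summarize_subject(mk(1)[0, ]), "non-empty")
})
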