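test_that("Menger curvature is exact on circles and zero on lines", {
  circ <- circle_cl(10)
  pc <- pointwise_curvature(circ)
  expect_equal(pc$max, 0.1, tolerance = 1e-12)
  expect_true(all(abs(pc$profile - 0.1) < 1e-12))

  line <- straight_cl(30)
  pl <- pointwise_curvature(line)
  expect_equal(pl$max, 0)
  expect_true(all(pl$profile == 0))
})

test_that("helix curvature at 1 mm sampling is within 1% of r/(r^2+c^2)", {
  hel <- helix_cl(10, 5)
  pc <- pointwise_curvature(hel)
  kappa <- 10 / (10^2 + 5^2)
  expect_lt(max(abs(pc$profile - kappa)) / kappa, 0.01)
})

test_that("module curvature equals brute-force circumradius on every triple", {
  set.seed(31)
  pts <- cbind(cumsum(runif(20, 0.5, 1.5)), rnorm(20), rnorm(20))
  cl <- centerline(pts)
  pc <- pointwise_curvature(cl)
  brute <- vapply(2:19, function(i) {
    a <- sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
    b <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
    c_ <- sqrt(sum((pts[i + 1, ] - pts[i - 1, ])^2))
    s <- (a + b + c_) / 2
    A2 <- max(s * (s - a) * (s - b) * (s - c_), 0)
    if (A2 == 0) 0 else 4 * sqrt(A2) / (a * b * c_)
  }, numeric(1))
  expect_equal(pc$profile, brute, tolerance = 1e-9)
})

test_that("branching angle reads perpendicular, parallel and oblique take-offs", {
  a <- generate_aorta_centerline(200, 10, 0, 201)
  perp <- generate_renal_branch(a, "right", 90, 40, 3, 0, seed = 1)
  expect_lt(abs(branching_angle(a, perp) - 90), 1)
  obl <- generate_renal_branch(a, "left", 60, 40, 3, 0, seed = 1)
  expect_lt(abs(branching_angle(a, obl) - 60), 1)
  # near-parallel synthetic: angle tends to the 0-degree limit
  par_ <- generate_renal_branch(a, "left", 12, 40, 3, 0, seed = 1)
  expect_lt(branching_angle(a, par_), 15)
  expect_lt(abs(branching_angle(a, perp, fit_window_mm = 5) - 90), 1)
})

test_that("end-stent angle is zero for straight arteries and recovers a built kink", {
  br <- straight_cl(40)
  dep <- deploy_geometric(br, sg_lookup(1, "RRA", "nominal"), 4, 8)  # s_end 19
  expect_lt(end_stent_angle(br, dep), 1e-9)

  # synthetic kink of 20 degrees placed exactly at the stent end
  ang <- 20 * pi / 180
  s_end <- dep$s_end
  z <- seq(0, 40, by = 1)
  pts <- t(vapply(z, function(s) {
    if (s <= s_end) c(0, 0, s)
    else c((s - s_end) * sin(ang), 0, s_end + (s - s_end) * cos(ang))
  }, numeric(3)))
  kinked <- centerline(pts)
  expect_lt(abs(end_stent_angle(kinked, dep) - 20), 1)

  # unavailable when the stent reaches the distal end
  short <- straight_cl(21)
  dep2 <- deploy_geometric(short, sg_lookup(1, "RRA", "nominal"), 4, 8)
  expect_true(is.na(end_stent_angle(short, dep2)))
})

test_that("breathing deltas are absolute and reject mismatched configurations", {
  a <- generate_aorta_centerline(200, 10, 0, 201)
  br <- generate_renal_branch(a, "left", 80, 40, 3, 0.02, seed = 2)
  m1 <- morpho_metrics(a, br, label = "cfg")
  expect_s3_class(m1, "morpho_metrics")
  d0 <- breathing_deltas(m1, m1)
  expect_equal(d0$d_branching_angle_deg, 0)
  expect_equal(d0$d_max_curvature, 0)

  m2 <- m1; m2$branching_angle <- m1$branching_angle - 9
  class(m2) <- "morpho_metrics"
  expect_equal(breathing_deltas(m1, m2)$d_branching_angle_deg, 9)

  m3 <- m1; m3$label <- "other"
  class(m3) <- "morpho_metrics"
  expect_error(breathing_deltas(m1, m3), "invalid pairing")
})

test_that("all metrics are invariant under rigid motion", {
  a <- generate_aorta_centerline(200, 10, 2, 201, seed = 3)
  br <- generate_renal_branch(a, "right", 75, 45, 3, 0.03, seed = 4)
  dep <- deploy_geometric(br, sg_lookup(1, "RRA", "nominal"), 3.95, 8)
  R <- rotation_matrix(c(1, 0.2, -0.7), 1.1)
  mv <- function(cl) centerline(rigid_move(cl, c(1, 0.2, -0.7), 1.1,
                                           c(10, -4, 7)),
                                radius = attr(cl, "radius"))
  a2 <- mv(a); br2 <- mv(br)
  expect_equal(branching_angle(a2, br2), branching_angle(a, br),
               tolerance = 1e-9)
  rs <- resample_centerline(br, 1); rs2 <- resample_centerline(br2, 1)
  expect_equal(pointwise_curvature(rs2)$max, pointwise_curvature(rs)$max,
               tolerance = 1e-9)
  expect_equal(end_stent_angle(rs2, dep), end_stent_angle(rs, dep),
               tolerance = 1e-9)
})

test_that("curvature scales as 1/s under uniform scaling; angles do not change", {
  a <- generate_aorta_centerline(200, 10, 2, 201, seed = 5)
  br <- generate_renal_branch(a, "left", 85, 45, 3, 0.03, seed = 6)
  s <- 2.5
  a2 <- centerline(unclass(as.matrix(a)) * s, radius = attr(a, "radius") * s)
  br2 <- centerline(unclass(as.matrix(br)) * s,
                    radius = attr(br, "radius") * s)
  expect_equal(branching_angle(a2, br2), branching_angle(a, br),
               tolerance = 1e-9)
  k1 <- pointwise_curvature(resample_centerline(br, 1))$max
  k2 <- pointwise_curvature(resample_centerline(br2, s))$max
  expect_equal(k2, k1 / s, tolerance = 1e-9)
})
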