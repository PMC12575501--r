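test_that("build_rod discretises at 1 mm with correct stiffness bookkeeping", {
  br <- straight_cl(40)
  rod <- build_rod(br)
  expect_equal(nrow(rod$rest), 41L)
  expect_equal(rod$h, 1)
  expect_equal(length(unique(rod$kb)), 1L)
  expect_equal(rod$kb[1], artery_bending_rigidity())

  dep <- deploy_geometric(br, sg_lookup(1, "RRA", "nominal"), 4, 8)
  rod2 <- build_rod(br, deployed_sg = dep)
  s_int <- 1:39
  expect_equal(sort(rod2$stented_nodes),
               which(s_int <= dep$s_end + 1e-9) + 1L)
  ratio <- max(rod2$kb) / min(rod2$kb)
  expect_gt(ratio, 100)    # stiff Co-Cr + graft vs soft wall
  expect_error(build_rod(centerline(cbind(0, 0, 0:5))), "10 mm")
})

test_that("the analytic energy gradient matches finite differences", {
  p <- test_patient(2)
  rod <- build_rod(p$renal_left)
  n <- nrow(rod$rest)
  set.seed(5)
  x <- rod$rest + matrix(rnorm(3 * n, 0, 0.3), ncol = 3)
  g <- renalrod:::.rod_energy_grad(rod, x)
  idx <- cbind(sample(n, 25, replace = TRUE), sample(3, 25, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    xp <- x; xm <- x
    xp[idx[k, 1], idx[k, 2]] <- xp[idx[k, 1], idx[k, 2]] + 1e-6
    xm[idx[k, 1], idx[k, 2]] <- xm[idx[k, 1], idx[k, 2]] - 1e-6
    fd <- (rod_energy(rod, xp) - rod_energy(rod, xm)) / 2e-6
    expect_equal(g[idx[k, 1], idx[k, 2]], fd,
                 tolerance = 1e-5)
  }
})

test_that("zero breathing displacement returns the rest shape at zero energy", {
  p <- test_patient(4)
  rod <- build_rod(p$renal_right)
  sol <- solve_equilibrium(rod, c(0, 0, 0))
  expect_identical(sol$coords, rod$rest)
  expect_equal(sol$energy, 0)
  expect_true(sol$converged)
})

test_that("small transverse tip displacement reproduces the clamped-pinned beam profile", {
  L <- 19
  rod <- build_rod(straight_cl(L))
  delta <- 0.01
  sol <- solve_equilibrium(rod, c(delta, 0, 0))
  expect_true(sol$converged)
  z <- rod$rest[, 3]
  beam <- delta * (3 * L * z^2 - z^3) / (2 * L^3)   # w(0)=w'(0)=0, w(L)=d, M(L)=0
  expect_lt(max(abs(sol$coords[, 1] - beam)) / delta, 0.02)
})

test_that("equilibrium energy beats every configuration on a brute-force grid", {
  # 5-node rod: two free interior nodes = 6 coordinates
  br <- centerline(cbind(c(0, 0.1, 0.3, 0.2, 0), c(0, 0.2, 0.5, 0.9, 1.1),
                         c(0, 3, 6, 9, 12)))
  rod <- build_rod(br, h = 3)
  expect_equal(nrow(rod$rest), 5L)
  bv <- c(0.6, -0.4, 0.5)
  sol <- solve_equilibrium(rod, bv)
  expect_true(sol$converged)
  free <- 3:4
  base <- sol$coords
  grid <- seq(-0.1, 0.1, by = 0.05)
  combos <- as.matrix(expand.grid(grid, grid, grid, grid, grid, grid))
  energies <- apply(combos, 1, function(d) {
    x <- base
    x[free, ] <- x[free, ] + matrix(d, 2, 3)
    rod_energy(rod, x)
  })
  expect_lte(sol$energy, min(energies) + 1e-10)
})

test_that("solutions are objective: rotating geometry and BC rotates the solution", {
  p <- test_patient(6)
  br <- p$renal_left
  rod <- build_rod(br)
  bv <- p$breathing$left
  sol <- solve_equilibrium(rod, bv)

  R <- rotation_matrix(c(0.3, -1, 0.5), 0.7)
  br_rot <- centerline(unclass(as.matrix(br)) %*% t(R),
                       radius = attr(br, "radius"))
  rod_rot <- build_rod(br_rot)
  sol_rot <- solve_equilibrium(rod_rot, as.numeric(R %*% bv))
  expect_lt(max(abs(sol_rot$coords - sol$coords %*% t(R))), 1e-6)
})

test_that("solver is deterministic", {
  p <- test_patient(8)
  rod <- build_rod(p$renal_right)
  s1 <- solve_equilibrium(rod, p$breathing$right)
  s2 <- solve_equilibrium(rod, p$breathing$right)
  expect_identical(s1$coords, s2$coords)
})

test_that("deployment straightening preserves arc length and continuity", {
  p <- test_patient(9)
  br <- p$renal_left
  dep <- deploy_geometric(br, sg_lookup(1, "LRA", "nominal"), 3.95, 8)
  st <- stented_rest_shape(br, dep)
  expect_equal(arc_length(st), arc_length(resample_centerline(br, 1)),
               tolerance = 1e-9)
  # stented span is straight: curvature ~ 0 inside [0, s_end]
  pc <- pointwise_curvature(st)
  inside <- pc$arc < dep$s_end - 1
  expect_lt(max(pc$profile[inside]), 1e-8)
  # and the take-off direction is approximately preserved (the straightened
  # window loses the arc's half-window curvature offset, ~4 deg at 5 mm)
  expect_lt(abs(branching_angle(p$aorta, st, fit_window_mm = 5) -
                  branching_angle(p$aorta, br, fit_window_mm = 5)), 6)
})

test_that("breathing simulation isolates the stent effect with identical BCs", {
  p <- test_patient(5)
  zero_bc <- generate_breathing_bc(0, 0, 0, 0, seed = 1)
  sim0 <- simulate_breathing(p, bc = zero_bc)
  for (side in c("left", "right")) {
    expect_equal(unclass(sim0[[side]]$expiration),
                 unclass(sim0[[side]]$inspiration), ignore_attr = TRUE)
  }
  sim1 <- simulate_breathing(p)
  sim2 <- simulate_breathing(p)
  expect_identical(unclass(sim1$left$expiration),
                   unclass(sim2$left$expiration))
  # a nominal stent reduces the breathing branching-angle delta
  dep <- deploy_geometric(p$renal_right, sg_lookup(1, "RRA", "nominal"),
                          3.95, 8)
  sim_sg <- simulate_breathing(p, deployed = list(right = dep))
  d_pre <- breathing_deltas(
    morpho_metrics(p$aorta, sim1$right$inspiration, label = "x"),
    morpho_metrics(p$aorta, sim1$right$expiration, label = "x"))
  d_sg <- breathing_deltas(
    morpho_metrics(p$aorta, sim_sg$right$inspiration, dep, label = "x"),
    morpho_metrics(p$aorta, sim_sg$right$expiration, dep, label = "x"))
  expect_lt(d_sg$d_branching_angle_deg, d_pre$d_branching_angle_deg)
})
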