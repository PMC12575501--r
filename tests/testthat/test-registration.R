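test_that("Kabsch alignment recovers known rigid transforms", {
  set.seed(11)
  src <- matrix(rnorm(60), ncol = 3)
  idt <- kabsch_align(src, src)
  expect_equal(idt$R, diag(3), tolerance = 1e-10)
  expect_equal(idt$t, c(0, 0, 0), tolerance = 1e-10)

  R <- rotation_matrix(c(2, -1, 0.5), 0.9)
  tr <- c(4, -7, 2)
  tgt <- sweep(src %*% t(R), 2, tr, "+")
  est <- kabsch_align(src, tgt)
  expect_lt(max(abs(est$R - R)), 1e-9)
  expect_lt(max(abs(est$t - tr)), 1e-9)
  expect_lt(max(abs(apply_transform(est, src) - tgt)), 1e-9)
})

test_that("Kabsch never returns an improper rotation", {
  set.seed(12)
  # near-reflective: a flat cloud mapped through a reflection + noise
  src <- cbind(rnorm(30), rnorm(30), rnorm(30) * 1e-3)
  tgt <- src %*% diag(c(1, 1, -1)) + matrix(rnorm(90, 0, 1e-4), ncol = 3)
  est <- kabsch_align(src, tgt)
  expect_equal(det(est$R), 1, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(est$R) - diag(3))), 1e-10)
  # degenerate (collinear) input is refused
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_align(line, line + 1), "rank deficiency")
})

test_that("ICP solves pure translation via the centroid step", {
  p <- test_patient(14)
  src <- unclass(as.matrix(resample_centerline(p$renal_left, 1)))
  tgt <- sweep(src, 2, c(5, -3, 2), "+")
  out <- icp(src, tgt)
  expect_lt(out$rms_history[length(out$rms_history)], 1e-6)
  expect_lt(max(abs(out$transform$t - c(5, -3, 2))), 1e-6)
})

test_that("ICP recovers a known rotation with final RMS below 1e-6 mm", {
  # a curve with genuine 3-D character: a planar circular arc rotated in its
  # own plane is close to a self-symmetry and registration of it is ill-posed
  a <- generate_aorta_centerline(200, 10, 0, 201)
  br <- generate_renal_branch(a, "left", 85, 50, 3,
                              list(kappa = 0.03, wobble_amp_mm = 1,
                                   wobble_period_mm = 14), seed = 5)
  src <- unclass(as.matrix(resample_centerline(br, 1)))
  R <- rotation_matrix(c(0, 0, 1), 10 * pi / 180)
  tgt <- src %*% t(R)
  out <- icp(src, tgt)
  expect_lt(out$rms_history[length(out$rms_history)], 1e-6)
  expect_true(all(diff(out$rms_history) <= 1e-12))
})

test_that("ICP RMS history is non-increasing on noisy inputs", {
  set.seed(17)
  p <- test_patient(16)
  src <- unclass(as.matrix(resample_centerline(p$renal_left, 1)))
  tgt <- rigid_move(src, c(1, 1, 0), 0.3, c(8, 0, -5)) +
    matrix(rnorm(length(src), 0, 0.4), ncol = 3)
  out <- icp(src, tgt)
  expect_true(all(diff(out$rms_history) <= 1e-12))
})

test_that("centerline distances use corresponding points and exact statistics", {
  a <- straight_cl(50)
  expect_equal(centerline_distance(a, a)$max_mm, 0)

  b <- centerline(sweep(unclass(as.matrix(a)), 2, c(2, 0, 0), "+"))
  prof <- centerline_distance(a, b)
  expect_equal(prof$mean_mm, 2, tolerance = 1e-12)
  expect_equal(prof$max_mm, 2, tolerance = 1e-12)

  # statistics equal brute-force recomputation from the per-point list
  p <- test_patient(18)
  c1 <- p$renal_left
  c2 <- centerline(unclass(as.matrix(c1)) +
                     matrix(sin(seq_len(length(c1))), ncol = 3))
  pr <- centerline_distance(c1, c2, n_corresponding = 57)
  expect_equal(length(pr$distances_mm), 57L)
  expect_identical(pr$mean_mm, mean(pr$distances_mm))
  expect_identical(pr$max_mm, max(pr$distances_mm))
  expect_identical(pr$sd_mm, stats::sd(pr$distances_mm))
})

test_that("opposite orientations are detected and auto-reversed", {
  a <- test_patient(19)$renal_right
  rev_pts <- unclass(as.matrix(a))[nrow(a):1, ]
  expect_message(prof <- centerline_distance(a, centerline(rev_pts)),
                 "reversing")
  expect_lt(prof$max_mm, 1e-9)
})

test_that("placement score counts strictly-below-threshold points", {
  uniform <- rep(1.59, 100)
  expect_equal(placement_accuracy_score(uniform, 3)$accuracy_score_pct, 100)
  expect_equal(placement_accuracy_score(rep(3.5, 40), 3)$accuracy_score_pct, 0)
  expect_equal(placement_accuracy_score(c(rep(1, 40), rep(4, 60)),
                                        3)$accuracy_score_pct, 40)
  # ties at exactly the threshold count as failures
  expect_equal(placement_accuracy_score(c(3, 3, 1, 1), 3)$accuracy_score_pct,
               50)
})

test_that("score is bounded and 100 exactly when the maximum is below threshold", {
  set.seed(23)
  for (i in 1:25) {
    d <- runif(50, 0, 6)
    sc <- placement_accuracy_score(d, 3)
    expect_gte(sc$accuracy_score_pct, 0)
    expect_lte(sc$accuracy_score_pct, 100)
    expect_equal(sc$accuracy_score_pct == 100, max(d) < 3)
  }
})

test_that("the twelve reported protrusion lengths average 3.95 mm and all pass", {
  tab <- published_protrusions()
  expect_equal(nrow(tab), 12L)
  chk <- check_protrusions(tab$protrusion_mm)
  expect_equal(round(chk$mean_mm, 2), 3.95)
  expect_true(chk$all_pass)
  expect_lte(max(tab$protrusion_mm), 4.3)
  expect_false(check_protrusions(5.0)$all_pass)
})
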