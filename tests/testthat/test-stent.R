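test_that("the stent-graft catalog holds the twelve study devices", {
  cat_ <- sg_catalog()
  expect_equal(nrow(cat_), 12L)
  expect_setequal(unique(cat_$length_mm), c(18, 22, 23, 27, 28))
  expect_setequal(unique(cat_$diameter_mm), c(5, 6, 7))
  n1 <- sg_lookup(1, "RRA", "nominal")
  expect_equal(c(n1$length_mm, n1$diameter_mm), c(23, 7))
  l2 <- sg_lookup(2, "LRA", "longer")
  expect_equal(c(l2$length_mm, l2$diameter_mm), c(28, 5))
  s1 <- sg_lookup(1, "LRA", "shorter")
  expect_equal(c(s1$length_mm, s1$diameter_mm), c(18, 5))
  # every (patient, artery) has the three size classes
  expect_true(all(table(cat_$patient, cat_$artery) == 3L))
  expect_error(sg_lookup(3, "RRA", "nominal"), "no catalog entry")
})

test_that("strut contribution matches numeric integration over the section", {
  cs <- strut_cross_section()
  # I = w h^3 / 12 about the centroidal axis, by midpoint quadrature
  h <- cs$height_mm
  y <- seq(-h / 2 + h / 2e5, h / 2 - h / 2e5, length.out = 1e5)
  I_num <- sum(y^2) * (h / 1e5) * cs$width_mm
  expect_equal(cs$I_mm4, I_num, tolerance = 1e-6)
  expect_equal(cs$I_mm4, 0.115 * 0.145^3 / 12)
})

test_that("graft tube rigidity matches a numeric annulus integral", {
  mat <- material_properties()
  spec <- sg_lookup(1, "RRA", "nominal")          # 7 mm tube
  r <- spec$diameter_mm / 2
  t <- mat$graft_thickness_mm
  thin_wall <- mat$graft_E1_mpa * pi * r^3 * t
  I_annulus <- pi / 4 * ((r + t / 2)^4 - (r - t / 2)^4)
  expect_equal(thin_wall, mat$graft_E1_mpa * I_annulus,
               tolerance = 2 * (t / r)^2)
})

test_that("the degenerate composite returns the bare artery rigidity", {
  mat <- material_properties()
  mat$graft_thickness_mm <- 0
  spec <- sg_lookup(1, "RRA", "nominal")
  out <- effective_bending_rigidity(mat, strut_cross_section(), spec,
                                    struts_per_ring = 0,
                                    artery_rigidity = 123.4)
  expect_equal(out, 123.4)
})

test_that("composite rigidity is strictly stiffer and monotone in its parts", {
  spec <- sg_lookup(1, "RRA", "nominal")
  base <- effective_bending_rigidity(spec = spec, artery_rigidity = 85)
  expect_gt(base, 85)
  more_struts <- effective_bending_rigidity(spec = spec, struts_per_ring = 8,
                                            artery_rigidity = 85)
  expect_gt(more_struts, base)
  fat <- effective_bending_rigidity(cross_section =
                                      strut_cross_section(0.2, 0.2),
                                    spec = spec, artery_rigidity = 85)
  expect_gt(fat, base)
  thick <- material_properties()
  thick$graft_thickness_mm <- 0.4
  expect_gt(effective_bending_rigidity(thick, spec = spec,
                                       artery_rigidity = 85), base)
  expect_error(effective_bending_rigidity(spec = spec, artery_rigidity = -1),
               "invalid config")
})

test_that("three-point bending force matches a discretised beam solve", {
  # independent oracle: simply-supported Euler-Bernoulli beam, midspan point
  # load, 100 Hermite beam elements (w, w\' dofs per node)
  EI <- 500; L <- 38; delta <- 2
  ne <- 100L
  h <- L / ne
  ke <- EI / h^3 * matrix(c(12, 6 * h, -12, 6 * h,
                            6 * h, 4 * h^2, -6 * h, 2 * h^2,
                            -12, -6 * h, 12, -6 * h,
                            6 * h, 2 * h^2, -6 * h, 4 * h^2), 4, 4,
                          byrow = TRUE)
  ndof <- 2L * (ne + 1L)
  K <- matrix(0, ndof, ndof)
  for (e in seq_len(ne)) {
    idx <- (2L * (e - 1L) + 1L):(2L * (e - 1L) + 4L)
    K[idx, idx] <- K[idx, idx] + ke
  }
  f <- rep(0, ndof)
  f[2L * (ne / 2L) + 1L] <- 1                       # unit load at midspan
  fixed <- c(1L, ndof - 1L)                         # w = 0 at both ends
  free <- setdiff(seq_len(ndof), fixed)
  w <- rep(0, ndof)
  w[free] <- solve(K[free, free], f[free])
  F_num <- delta / w[2L * (ne / 2L) + 1L]
  expect_equal(three_point_bending_force(EI, L, delta), F_num,
               tolerance = 5e-3)
})

test_that("three-point bending is linear and bounded by the plastic limit", {
  expect_equal(three_point_bending_force(1000, 38, 0), 0)
  f1 <- three_point_bending_force(1000, 38, 1.5)
  expect_equal(three_point_bending_force(2000, 38, 1.5), 2 * f1)
  expect_error(three_point_bending_force(1000, 38, 3.5), "plastic")
})

test_that("geometric deployment implements the ostium-anchored contract", {
  br <- straight_cl(40)
  dep <- deploy_geometric(br, sg_lookup(1, "RRA", "nominal"), 4.0, 8)
  expect_equal(dep$protrusion_length_mm, 4.0)
  expect_equal(dep$s_start, -4.0)
  expect_equal(dep$s_end, 19.0)
  expect_equal(dep$s_end - dep$s_start, 23)
  expect_equal(dep$flare_diameter_mm, 8)
  # conservation: in-artery + protrusion = device length, across the catalog
  cat_ <- sg_catalog()
  for (i in seq_len(nrow(cat_))) {
    d <- deploy_geometric(straight_cl(40),
                          cat_[i, , drop = FALSE], 3.9, 8)
    expect_equal((d$s_end - 0) + d$protrusion_length_mm,
                 cat_$length_mm[i])
  }
})

test_that("deployment fails when the stent outruns the branch", {
  br <- straight_cl(20)
  expect_error(deploy_geometric(br, sg_lookup(2, "LRA", "longer"), 4.0, 8),
               "infeasible")
})
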