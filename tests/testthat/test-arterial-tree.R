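test_that("packaged nominal tree loads to 55 validated vessels", {
  tree <- nominal_tree()
  expect_s3_class(tree, "arterial_tree")
  expect_equal(nrow(tree$vessels), 55)
  expect_equal(sum(tree$vessels$terminal), 28)
  expect_silent(validate_tree(tree))
  ## tapering invariant and positive geometry everywhere
  expect_true(all(tree$vessels$length_cm > 0))
  expect_true(all(tree$vessels$r_in_cm >= tree$vessels$r_out_cm))
  expect_true(all(tree$vessels$r_out_cm > 0))
})

test_that("toy single-vessel file loads and topology errors are caught", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = "one", nominal_height_cm = 176, p_ref_mmHg = 97, root = 1,
    vessels = list(list(id = 1, name = "v", length_cm = 10, r_in_cm = 0.5,
                        r_out_cm = 0.4, daughters = list(),
                        windkessel = list(R1 = 100, R2 = 1000, C = 1e-3,
                                          p_out_mmHg = 5))),
    named_sites = list()), f, auto_unbox = TRUE)
  tr <- load_tree(f)
  expect_equal(nrow(tr$vessels), 1)
  expect_true(tr$vessels$terminal)

  ## one daughter -> validation error naming the vessel
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = "bad", root = 1,
    vessels = list(
      list(id = 1, name = "v", length_cm = 10, r_in_cm = 0.5, r_out_cm = 0.4,
           daughters = list(2)),
      list(id = 2, name = "w", length_cm = 5, r_in_cm = 0.3, r_out_cm = 0.3,
           daughters = list(),
           windkessel = list(R1 = 1, R2 = 1, C = 1, p_out_mmHg = 5))),
    named_sites = list()), f2, auto_unbox = TRUE)
  expect_error(load_tree(f2), "daughter")

  expect_error(load_tree(tempfile()), "not found")
})

test_that("height scaling is linear in lengths only and bounded", {
  tree <- nominal_tree()
  same <- scale_tree_to_height(tree, tree$nominal_height_cm)
  expect_equal(same$vessels$length_cm, tree$vessels$length_cm)

  tall <- scale_tree_to_height(tree, 2 * tree$nominal_height_cm,
                               bounds = c(100, 400))
  expect_equal(tall$vessels$length_cm, 2 * tree$vessels$length_cm)
  expect_equal(tall$vessels$r_in_cm, tree$vessels$r_in_cm)

  ## the cohort-mean height rescales any path by the same factor
  short <- scale_tree_to_height(tree, 168.6)
  d_nom <- site_distance(tree, "aortic_arch", "femoral")
  d_scl <- site_distance(short, "aortic_arch", "femoral")
  expect_equal(d_scl / d_nom, 168.6 / tree$nominal_height_cm,
               tolerance = 1e-12)

  expect_error(scale_tree_to_height(tree, 90), "range")
  expect_error(scale_tree_to_height(tree, 300), "range")
})

test_that("wall stiffness follows the exponential-plus-offset law", {
  w <- wall_model(k1 = 2.28e7, k3 = 14.51e5)
  ## k1 = 0: the exponential term vanishes
  expect_equal(wall_stiffness(1.3, wall_model(k1 = 0, k3 = 2e6)),
               (4 / 3) * 2e6)
  ## large vessels are governed by k3 alone
  expect_lt(abs(wall_stiffness(10, w) - (4 / 3) * w$k3) /
              ((4 / 3) * w$k3), 0.001)
  ## frozen scalar evaluation at the cohort-mean coefficients, r0 = 0.1 cm
  expect_equal(wall_stiffness(0.1, w), 5.129205e6, tolerance = 1e-6)
  expect_error(wall_stiffness(0, w), "positive")
})

test_that("wall stiffness is monotone in r0, k1 and k3", {
  set.seed(7)
  for (i in 1:25) {
    k1 <- runif(1, 1e5, 9e7); k3 <- runif(1, 1e5, 5e6)
    r <- sort(runif(2, 0.05, 0.5)) # range where the exponential term is
                                   # numerically non-negligible
    w <- wall_model(k1, k3)
    expect_gt(wall_stiffness(r[1], w), wall_stiffness(r[2], w))
    expect_gt(wall_stiffness(r[1], wall_model(k1 * 1.3, k3)),
              wall_stiffness(r[1], w))
    expect_gt(wall_stiffness(r[1], wall_model(k1, k3 * 1.3)),
              wall_stiffness(r[1], w))
  }
})

test_that("tube law anchors at the reference pressure and inverts exactly", {
  F <- wall_stiffness(0.5, wall_model(2e7, 1.5e6))
  A0 <- pi * 0.5^2
  expect_equal(tube_law(A0, A0, F), 97)
  ## asymptote p -> p_ref + F as A -> infinity
  expect_equal(tube_law(1e9 * A0, A0, F), 97 + F / 1333.22,
               tolerance = 1e-4)
  ## round trip at 120 mmHg
  A <- inverse_tube_law(120, A0, F)
  expect_equal(tube_law(A, A0, F), 120, tolerance = 1e-10)
  ## pressures at or above the p_ref + F asymptote are unreachable
  expect_error(inverse_tube_law(97 + F / 1333.22 + 1, A0, F), "reachable")
})

test_that("linearised wave speed is finite and positive across the tree", {
  tree <- nominal_tree()
  w <- wall_model(2.28e7, 14.51e5)
  r <- c(tree$vessels$r_in_cm, tree$vessels$r_out_cm)
  c0 <- wave_speed_c0(r, w)
  expect_true(all(is.finite(c0) & c0 > 0))
  ## r0 interpolation hits the endpoints exactly
  i <- 9
  L <- tree$vessels$length_cm[i]
  expect_equal(pulsewave:::vessel_r0(tree, tree$vessels$id[i], c(0, L)),
               c(tree$vessels$r_in_cm[i], tree$vessels$r_out_cm[i]))
})

test_that("site distances require a common root-to-leaf path", {
  tree <- nominal_tree()
  expect_gt(site_distance(tree, "aortic_arch", "femoral"), 40)
  expect_error(site_distance(tree, "radial_distal", "femoral"),
               "common root-to-leaf")
  expect_error(site_distance(tree, "femoral", "femoral"), "zero distance")
})
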