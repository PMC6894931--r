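test_that("rigid registration recovers constructed transforms", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ft <- fitRigidTransform(P, P)
  expect_equal(rotation(ft), diag(3), tolerance = 1e-12)
  expect_equal(translation(ft), c(0, 0, 0), tolerance = 1e-12)

  Rz90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  Q <- t(Rz90 %*% t(P)) + rep(c(10, 20, 30), each = nrow(P))
  ft <- fitRigidTransform(P, Q)
  expect_lt(ft@rms, 1e-9)
  expect_equal(rotation(ft), Rz90, tolerance = 1e-9)
  expect_equal(translation(ft), c(10, 20, 30), tolerance = 1e-9)
  expect_equal(toScope(ft, c(0, 0, 0)), c(10, 20, 30), tolerance = 1e-9)
})

test_that("registration is exact on noiseless random rigid motions", {
  set.seed(101)
  for (i in 1:20) {
    P <- matrix(rnorm(30, sd = 500), 10, 3)
    R <- randomRotation()
    tv <- rnorm(3, sd = 1000)
    Q <- t(R %*% t(P)) + rep(tv, each = 10)
    ft <- fitRigidTransform(P, Q)
    expect_lt(ft@rms, 1e-9)
    expect_equal(det(rotation(ft)), 1, tolerance = 1e-9)
    expect_equal(max(abs(toScope(ft, P) - Q)), 0, tolerance = 1e-8)
  }
})

test_that("reflections are never returned as rotations", {
  set.seed(5)
  P <- matrix(rnorm(15), 5, 3)
  Q <- P %*% diag(c(1, 1, -1))      # mirrored correspondence
  ft <- fitRigidTransform(P, Q)
  expect_equal(det(rotation(ft)), 1, tolerance = 1e-9)
})

test_that("registration residual is invariant under global rigid motion", {
  set.seed(7)
  P <- matrix(rnorm(24), 8, 3)
  Q <- P + matrix(rnorm(24, sd = 0.1), 8, 3)   # noisy correspondence
  base <- fitRigidTransform(P, Q)@rms
  R <- randomRotation(); tv <- c(3, -5, 11)
  moveP <- t(R %*% t(P)) + rep(tv, each = 8)
  moveQ <- t(R %*% t(Q)) + rep(tv, each = 8)
  expect_equal(fitRigidTransform(moveP, moveQ)@rms, base, tolerance = 1e-9)
})

test_that("degenerate geometry is rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fitRigidTransform(line, line), "degenerate")
  expect_error(fitRigidTransform(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("scope/manipulator mapping inverts exactly", {
  set.seed(9)
  P <- matrix(rnorm(30), 10, 3)
  R <- randomRotation()
  Q <- t(R %*% t(P)) + rep(c(1, 2, 3), each = 10)
  ft <- fitRigidTransform(P, Q)
  p <- c(14.2, -3.1, 7.7)
  expect_equal(toManip(ft, toScope(ft, p)), p, tolerance = 1e-9)
  ident <- new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0))
  expect_equal(toScope(ident, c(1, 2, 3)), c(1, 2, 3))
  shift <- new("RigidTransform", rotation = diag(3), translation = c(5, 0, 0))
  expect_equal(toScope(shift, c(0, 0, 0)), c(5, 0, 0))
})

test_that("target planning spaces pipettes by azimuth with collision check", {
  poses <- pipettePoses(1:8, azimuth_deg = seq(0, 315, by = 45))
  tg <- planTargets(poses, roi_center = c(0, 0, 0), spread_radius = 50)
  expect_identical(nrow(tg), 8L)
  expect_true(all(tg$z_um == 200))
  chord <- 2 * 50 * sin(pi / 8)
  expect_equal(attr(tg, "min_pair_distance"), chord, tolerance = 1e-9)
  expect_false(attr(tg, "collision"))

  tight <- planTargets(poses, c(0, 0, 0), spread_radius = 10, clearance = 20)
  expect_true(attr(tight, "collision"))
  expect_lt(attr(tight, "min_pair_distance"), 20)

  single <- planTargets(pipettePoses(1, 0), c(0, 0, 0), spread_radius = 50)
  expect_equal(c(single$x_um, single$y_um, single$z_um), c(50, 0, 200))

  # permutation stability: shuffled pose order gives identical assignment
  shuf <- poses[c(5, 2, 8, 1, 3, 7, 4, 6), ]
  tg2 <- planTargets(shuf, c(0, 0, 0), spread_radius = 50)
  expect_equal(tg2, tg, ignore_attr = TRUE)
})

test_that("approach paths end with an axis-parallel segment", {
  poses <- pipettePoses(1, azimuth_deg = 0, approach_deg = 27,
                        tip = matrix(c(500, 0, 400), 1))
  path <- approachPath(poses[1, ], target = c(0, 0, 0), standoff = 100)
  expect_identical(path$segment[nrow(path)], "axial")
  last <- as.numeric(path[nrow(path), 1:3]) - as.numeric(path[nrow(path) - 1L, 1:3])
  horiz <- sqrt(sum(last[1:2]^2))
  expect_equal(-last[3] / horiz, tan(27 * pi / 180), tolerance = 1e-9)
  # 100 um horizontal travel along the axis drops ~50.95 um
  expect_equal(100 * tan(27 * pi / 180), 50.95254, tolerance = 1e-4)
  expect_error(approachPath(poses[1, ], target = c(0, 0, 600)),
               "path-infeasible")
})

test_that("reachability reflects wall clearance at the approach angle", {
  pose <- pipettePoses(1, azimuth_deg = 0, approach_deg = 27)
  well <- list(inner_radius = 13000, wall_height = 2000)
  ok <- reachability(pose[1, ], well, target = c(8500, 0, 0))
  expect_true(ok$reachable)
  expect_equal(ok$standoff_required, 2000 / tan(27 * pi / 180),
               tolerance = 1e-9)
  expect_equal(ok$standoff_available, 4500, tolerance = 1e-9)

  near <- reachability(pose[1, ], well, target = c(10000, 0, 0))
  expect_false(near$reachable)
  expect_identical(near$limit, "wall_clearance")

  flat <- reachability(pose[1, ], list(inner_radius = 13000, wall_height = 0),
                       target = c(10000, 0, 0))
  expect_true(flat$reachable)
})
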