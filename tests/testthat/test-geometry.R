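# Heart localization, frame construction, Euler angles and electrode
# transforms.

test_that("heart_position solves axis-aligned and constructed intersections", {
  # coordinate planes through the origin
  expect_equal(heart_position(plane3d(c(1, 0, 0), c(0, 0, 0)),
                              plane3d(c(0, 1, 0), c(0, 0, 0)),
                              plane3d(c(0, 0, 1), c(0, 0, 0))),
               c(0, 0, 0))
  # orthonormal planes all through a common point intersect there
  expect_equal(heart_position(plane3d(c(1, 0, 0), c(10, -20, 5)),
                              plane3d(c(0, 1, 0), c(10, -20, 5)),
                              plane3d(c(0, 0, 1), c(10, -20, 5))),
               c(10, -20, 5))
})

test_that("heart_position satisfies all three plane equations on random triples", {
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    tri <- random_plane_triple()
    pos <- heart_position(tri$planes[[1]], tri$planes[[2]], tri$planes[[3]])
    res <- vapply(tri$planes, function(p) abs(sum(p$normal * (pos - p$point))),
                  numeric(1))
    worst <- max(worst, res)
    expect_equal(pos, tri$point, tolerance = 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("near-coplanar plane normals are rejected", {
  expect_error(heart_position(plane3d(c(1, 0, 0), c(0, 0, 0)),
                              plane3d(c(1, 1e-12, 0), c(5, 0, 0)),
                              plane3d(c(0, 0, 1), c(0, 0, 0))),
               class = "ecgvae_degenerate_geometry")
  expect_error(heart_frame(plane3d(c(0, 0, 1), c(0, 0, 0)),
                           plane3d(c(0, 0, 1), c(1, 1, 1))),
               class = "ecgvae_degenerate_geometry")
})

test_that("heart_frame matches direct evaluation and is right-handed", {
  # nSAX = z, n4CH = y: eX = normalize(z x y) = -x, eZ = y
  fr <- heart_frame(plane3d(c(0, 0, 1), c(0, 0, 0)),
                    plane3d(c(0, 1, 0), c(0, 0, 0)))
  expect_equal(fr$eX, c(-1, 0, 0))
  expect_equal(fr$eZ, c(0, 1, 0))
  expect_equal(abs(sum(fr$eY * c(0, 0, 1))), 1)  # eY along +-z
  expect_equal(det(cbind(fr$eX, fr$eY, fr$eZ)), 1, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:100) {
    n1 <- random_unit(); n2 <- random_unit()
    if (sqrt(sum((n1 - n2)^2)) < 1e-3) next
    fr <- heart_frame(plane3d(n1, c(0, 0, 0)), plane3d(n2, c(0, 0, 0)))
    # independent evaluation of the construction
    L <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
           n1[1] * n2[2] - n1[2] * n2[1])
    eX <- L / sqrt(sum(L^2))
    eZ <- n2 - sum(n2 * eX) * eX; eZ <- eZ / sqrt(sum(eZ^2))
    expect_equal(fr$eX, eX, tolerance = 1e-12)
    expect_equal(fr$eZ, eZ, tolerance = 1e-12)
    R <- cbind(fr$eX, fr$eY, fr$eZ)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    # when n4CH is unit, the projection term vanishes: eZ = n4CH
    expect_equal(fr$eZ, n2, tolerance = 1e-9)
    expect_lt(abs(sum(fr$eX * fr$eZ)), 1e-12)
  }
})

test_that("euler_angles evaluates the three projection formulas", {
  expect_equal(euler_angles(list(eX = c(1, 0, 0), eY = c(0, 1, 0), eZ = c(0, 0, 1))),
               c(alpha = 0, beta = 0, gamma = -90))
  # frame rotated 90 degrees about z
  expect_equal(euler_angles(list(eX = c(0, 1, 0), eY = c(-1, 0, 0), eZ = c(0, 0, 1))),
               c(alpha = 90, beta = 0, gamma = -90))
  set.seed(13)
  for (i in 1:100) {
    fr <- random_frame()
    ang <- euler_angles(fr)
    # independent evaluation
    r2d <- 180 / pi
    expect_equal(as.numeric(ang["alpha"]), acos(min(1, max(-1, fr$eX[1]))) * r2d)
    expect_equal(as.numeric(ang["beta"]), -acos(min(1, max(-1, fr$eZ[3]))) * r2d)
    expect_equal(as.numeric(ang["gamma"]), -acos(min(1, max(-1, fr$eX[3]))) * r2d)
  }
})

test_that("euler_angles on heart_frame output is deterministic", {
  sax <- plane3d(c(0.3, -0.2, 0.9), c(12, 3, -8))
  ch4 <- plane3d(c(-0.1, 0.95, 0.2), c(12, 3, -8))
  a1 <- euler_angles(heart_frame(sax, ch4))
  a2 <- euler_angles(heart_frame(sax, ch4))
  expect_identical(a1, a2)
})

test_that("to_heart_frame maps the heart to the origin and is rigid", {
  set.seed(21)
  lay <- template_layout()
  for (i in 1:20) {
    fr <- random_frame()
    pose <- heart_pose(stats::rnorm(3, sd = 30), fr)
    hl <- to_heart_frame(lay, pose)
    expect_identical(hl$frame, "heart")
    # heart position itself maps to the origin
    m <- lay$coords; m["RA", ] <- pose$position
    hl2 <- to_heart_frame(electrode_layout(m, "anatomical"), pose)
    expect_equal(as.numeric(hl2$coords["RA", ]), c(0, 0, 0))
    # rigid: pairwise distances preserved
    expect_equal(as.numeric(dist(hl$coords)), as.numeric(dist(lay$coords)),
                 tolerance = 1e-9)
    # round trip
    back <- to_anatomical_frame(hl, pose)
    expect_equal(back$coords, lay$coords, tolerance = 1e-9)
  }
  # identity pose leaves coordinates unchanged
  idpose <- heart_pose(c(0, 0, 0), list(eX = c(1, 0, 0), eY = c(0, 1, 0),
                                        eZ = c(0, 0, 1)))
  expect_equal(to_heart_frame(lay, idpose)$coords, lay$coords)
  expect_error(to_heart_frame(to_heart_frame(lay, idpose), idpose),
               class = "ecgvae_frame_mismatch")
})

test_that("layout flattening uses the canonical electrode order", {
  lay <- template_layout()
  v <- flatten_layout(lay)
  expect_length(v, 30)
  expect_equal(v[1:3], as.numeric(lay$coords["RA", ]))
  expect_equal(v[28:30], as.numeric(lay$coords["V6", ]))
})

test_that("plane and electrode CSV round trips preserve values", {
  dir <- withr::local_tempdir()
  subs <- sample_population(3, seed = 5)
  planes <- lapply(subs, function(s) planes_from_pose(s$pose))
  names(planes) <- vapply(subs, function(s) s$subject_id, character(1))
  f <- file.path(dir, "planes.csv")
  write_planes_csv(planes, f)
  rt <- read_planes_csv(f)
  expect_equal(rt[["S0001"]]$SAX$normal, planes[["S0001"]]$SAX$normal,
               tolerance = 1e-12)
  # pose recovered from the synthetic planes equals the generating pose
  p <- pose_from_planes(rt[["S0002"]]$SAX, rt[["S0002"]][["2CH"]],
                        rt[["S0002"]][["4CH"]])
  expect_equal(p$position, subs[[2]]$pose$position, tolerance = 1e-6)
  expect_equal(p$eX, subs[[2]]$pose$eX, tolerance = 1e-9)

  lays <- lapply(subs, function(s) s$layout)
  names(lays) <- names(planes)
  f2 <- file.path(dir, "el.csv")
  write_electrodes_csv(lays, f2)
  rt2 <- read_electrodes_csv(f2)
  expect_equal(rt2[["S0003"]]$coords, lays[["S0003"]]$coords, tolerance = 1e-9)
})
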