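test_that("dihedral follows the IUPAC convention and detects degeneracy", {
  # cis (syn-periplanar) arrangement
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0)), 0)
  # trans (anti-periplanar)
  expect_equal(abs(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))), 180)
  # quarter turn has magnitude 90 and flips sign under mirror images
  expect_equal(abs(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 0, 1))), 90)
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 0, 1)),
               -dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 0, -1)))
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               class = "lnahelix_geometry_error")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "lnahelix_geometry_error")
})

test_that("dihedral is invariant under rigid motions", {
  withr::with_seed(21, {
    for (i in 1:10) {
      pts <- matrix(rnorm(12, sd = 3), 4, 3)
      ref <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      mo <- rigid_case(i)
      moved <- lnahelix:::apply_rigid(pts, mo)
      expect_equal(dihedral(moved[1, ], moved[2, ], moved[3, ], moved[4, ]), ref,
                   tolerance = 1e-9)
    }
  })
})

test_that("pseudorotation round-trips across the full cycle including nu2 < 0", {
  # both sign branches of nu2 at the canonical puckers
  for (case in list(c(18, 40), c(162, 35), c(162, 38), c(-60, 30), c(250, 45))) {
    ring <- lnahelix:::solve_rings(case[1], case[2])
    m <- lnahelix:::measure_rings(ring)
    expect_equal(m$P, case[1], tolerance = 1e-6)
    expect_equal(m$tau_m, case[2], tolerance = 1e-6)
  }
  # dense grid over (-90, 270] at three amplitudes
  grid <- expand.grid(P = seq(-85, 270, by = 5), tau = c(20, 40, 60))
  rings <- lnahelix:::solve_rings(grid$P, grid$tau)
  m <- lnahelix:::measure_rings(rings)
  expect_lt(max(abs(m$P - grid$P)), 1e-6)
  expect_lt(max(abs(m$tau_m - grid$tau)), 1e-6)
})

test_that("planar rings have undefined pucker", {
  s <- fx_duplex_b()
  idx <- which(s$chain == "W" & s$residue == 3 & s$atom %in% lnahelix:::RING_ATOMS)
  flat <- s
  flat$z[idx] <- 0
  # flatten in the ring plane: project onto the ring's own best plane instead
  xyz <- as.matrix(flat[idx, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  proj <- sweep(sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2]), 2, ctr, "+")
  flat$x[idx] <- proj[, 1]; flat$y[idx] <- proj[, 2]; flat$z[idx] <- proj[, 3]
  expect_error(pseudorotation(flat, "W", 3), "planar", class = "lnahelix_pucker_error")
})

test_that("set_sugar_pucker hits its target exactly and preserves chi", {
  s <- fx_duplex_b()
  chi0 <- glycosidic_chi(s, "W", 5)
  s2 <- set_sugar_pucker(s, "W", 5, 18, 40)
  m <- pseudorotation(s2, "W", 5)
  expect_equal(m$P, 18, tolerance = 1e-4)
  expect_equal(m$tau_m, 40, tolerance = 1e-4)
  expect_equal(glycosidic_chi(s2, "W", 5), chi0, tolerance = 1e-6)

  # south target exercises the nu2 < 0 branch
  s3 <- set_sugar_pucker(s, "W", 5, 162, 35)
  m3 <- pseudorotation(s3, "W", 5)
  expect_equal(m3$P, 162, tolerance = 1e-4)
  expect_equal(m3$tau_m, 35, tolerance = 1e-4)

  # the phosphate is re-attached rigidly: its coordinates in the sugar-local
  # frame are unchanged by the rebuild
  local_p <- function(x) {
    xyz <- lnahelix:::residue_atoms(x, "W", 5, c("C1'", "O4'", "C2'", "P"))
    fr <- lnahelix:::sugar_frame(xyz["C1'", ], xyz["O4'", ], xyz["C2'", ])
    as.vector(t(fr$R) %*% (xyz["P", ] - as.vector(fr$o)))
  }
  expect_equal(local_p(s3), local_p(s), tolerance = 1e-9)
})

test_that("LNA residues reject south puckers", {
  sh <- build_duplex(get_target("c-MYC_DS19-Hetero"), helix_spec("B"))
  lna_res <- unique(sh$residue[sh$chain == "C" & sh$chemistry == "LNA"])[1]
  expect_error(set_sugar_pucker(sh, "C", lna_res, 180, 38),
               "locked", class = "lnahelix_locked_error")
  # north targets are fine
  s2 <- set_sugar_pucker(sh, "C", lna_res, 17, 48)
  expect_equal(pseudorotation(s2, "C", lna_res)$P, 17, tolerance = 1e-4)
})

test_that("built sugars are D-configured on every strand", {
  tx <- fx_triplex()
  for (ch in c("W", "C", "T")) {
    for (r in lnahelix:::chain_residues(tx, ch)) {
      expect_gt(lnahelix:::sugar_chirality(tx, ch, r), 0)
    }
  }
})
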