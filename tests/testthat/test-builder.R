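test_that("duplex builder produces the expected residues, chains and chemistry", {
  s <- fx_duplex_b()
  expect_equal(sort(structure_chains(s)), c("C", "W"))
  expect_equal(length(unique(paste(s$chain, s$residue))), 38)
  expect_equal(lnahelix:::chain_sequence(s, "W"), "GGGGAAAAGAAAAAAGATC")
  # 1-bp duplex: 2 residues, no steps
  tiny <- build_duplex(duplex_target("g"), helix_spec("B"))
  expect_equal(length(unique(paste(tiny$chain, tiny$residue))), 2)
  expect_error(step_parameters(tiny), class = "lnahelix_value_error")
})

test_that("non-complementary strands are rejected with the first mismatch position", {
  expect_error(build_duplex(duplex_target("ggaa", "ttct")),
               class = "lnahelix_duplex_error")
})

test_that("hetero-duplex pyrimidine strand gets locked north LNA sugars", {
  sh <- build_duplex(get_target("c-MYC_DS19-Hetero"), helix_spec("B"))
  lna <- unique(sh$residue[sh$chain == "C" & sh$chemistry == "LNA"])
  expect_equal(length(lna), 9)
  for (r in lna) {
    expect_equal(pseudorotation(sh, "C", r)$P, 17, tolerance = 1e-3)
  }
  dna <- setdiff(unique(sh$residue[sh$chain == "C"]), lna)
  expect_equal(pseudorotation(sh, "C", dna[1])$P, 162, tolerance = 1e-3)
})

test_that("builder and step analysis agree on twist and rise for any spec", {
  dx <- get_target("c-MYC_DS19")
  for (tw in c(30, 32.7, 36)) {
    spec <- helix_spec("B", twist = tw, rise = 3.2)
    m <- step_means(step_parameters(build_duplex(dx, spec)))
    expect_equal(m$twist, tw, tolerance = 0.1)
    expect_equal(m$rise, 3.2, tolerance = 0.01)
  }
  # A form: negative x-displacement recovered
  mA <- step_means(step_parameters(build_duplex(dx, helix_spec("A"))))
  expect_equal(mA$twist, 32.7, tolerance = 0.1)
  expect_equal(mA$rise, 2.81, tolerance = 0.01)
  expect_equal(mA$x_disp, -4.4, tolerance = 0.05)
  expect_lt(mA$x_disp, 0)
})

test_that("triplex builder satisfies the Hoogsteen distance postcondition", {
  tx <- fx_triplex()
  expect_equal(sort(structure_chains(tx)), c("C", "T", "W"))
  expect_equal(vapply(c("W", "C", "T"),
                      function(ch) length(lnahelix:::chain_residues(tx, ch)),
                      integer(1)),
               c(W = 19L, C = 19L, T = 15L))
  reg <- pair_registry(tx)
  hg <- reg[reg$kind == "HG", ]
  expect_equal(nrow(hg), 15)
  d <- vapply(seq_len(nrow(hg)), function(i) pair_distance(tx, hg[i, ]), numeric(1))
  expect_true(all(d < 3.5))
  expect_equal(d, rep(2.9, 15), tolerance = 1e-6)
  # TFO cytosines protonated
  expect_true(all(tx$protonated[tx$chain == "T" & tx$base == "C"]))
  expect_false(any(tx$protonated[tx$chain != "T"]))
})

test_that("FXN triplex carries only T.A and C+.G triads", {
  tx <- build_triplex(get_target("FXN_DS19"), get_oligo("ON4-3'LNA-reduced"),
                      helix_spec("B"))
  reg <- pair_registry(tx)
  hg <- reg[reg$kind == "HG", ]
  expect_equal(nrow(hg), 15)
  expect_true(all(hg$triad %in% c("T.A", "C+.G")))
  expect_equal(hg$triad == "C+.G", hg$base2 == "C")
})

test_that("triplex builder rejects impossible targets", {
  no_tract <- duplex_target("gatcgatcgatc")
  expect_error(build_triplex(no_tract, get_oligo("ON1")), "no TFO binding site",
               class = "lnahelix_build_error")
  expect_error(build_triplex(get_target("c-MYC_DS19"), "ggaaa"),
               class = "lnahelix_parse_error")
})

test_that("analysis results are invariant under rigid motions of the structure", {
  s <- fx_duplex_b()
  m0 <- step_means(step_parameters(s))
  g0 <- groove_widths(s)
  p0 <- pseudorotation(s, "W", 7)
  chi0 <- glycosidic_chi(s, "W", 7)
  for (i in 1:3) {
    mo <- rigid_case(100 + i)
    s2 <- transform_structure(s, mo$R, mo$t)
    m2 <- step_means(step_parameters(s2))
    expect_equal(m2$twist, m0$twist, tolerance = 1e-6)
    expect_equal(m2$rise, m0$rise, tolerance = 1e-6)
    expect_equal(m2$x_disp, m0$x_disp, tolerance = 1e-6)
    expect_equal(groove_widths(s2)$minor, g0$minor, tolerance = 1e-6)
    expect_equal(pseudorotation(s2, "W", 7)$P, p0$P, tolerance = 1e-6)
    expect_equal(glycosidic_chi(s2, "W", 7), chi0, tolerance = 1e-6)
  }
})

test_that("PDB round trip preserves the atom table to 1e-3 A", {
  s <- fx_triplex()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  back <- read_pdb(path)
  expect_equal(back$atom, s$atom)
  expect_equal(back$chain, s$chain)
  expect_equal(back$residue, s$residue)
  expect_equal(back$base, s$base)
  expect_equal(back$chemistry, s$chemistry)
  expect_equal(back$protonated, s$protonated)
  expect_equal(coords_matrix_of(back), coords_matrix_of(s), tolerance = 2e-3)
})

test_that("multi-model PDB files round trip trajectories", {
  tx <- build_duplex(duplex_target("ggaaagg"), helix_spec("B"))
  gen <- generate_trajectory(tx, traj_spec(n_frames = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(gen$trajectory, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MODEL")), 5)
  back <- read_pdb(path)
  expect_s3_class(back, "dna_trajectory")
  expect_equal(n_frames(back), 5)
  expect_equal(back$frame_interval, 40)
  expect_equal(back$coords, gen$trajectory$coords, tolerance = 2e-3)
})

test_that("malformed and truncated PDB files error instead of partial reads", {
  s <- build_duplex(duplex_target("gga"), helix_spec("B"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  lines <- readLines(path)
  # truncated: drop END
  writeLines(head(lines, -1), path)
  expect_error(read_pdb(path), "truncated", class = "lnahelix_pdb_error")
  # malformed ATOM line
  lines2 <- lines
  lines2[3] <- substr(lines2[3], 1, 40)
  writeLines(lines2, path)
  expect_error(read_pdb(path), "line 3", class = "lnahelix_pdb_error")
  # unclosed MODEL
  tr <- generate_trajectory(s, traj_spec(n_frames = 2, seed = 1))$trajectory
  write_pdb(tr, path)
  lines3 <- readLines(path)
  lines3 <- lines3[-max(which(startsWith(lines3, "ENDMDL")))]
  writeLines(lines3, path)
  expect_error(read_pdb(path), class = "lnahelix_pdb_error")
})

test_that("an independent PDB reader agrees with ours", {
  skip_if_not_installed("bio3d")
  s <- fx_duplex_b()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(nrow(ref$atom), nrow(s))
  expect_equal(ref$atom$elety, s$atom)
  expect_equal(unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)),
               coords_matrix_of(s), tolerance = 2e-3)
})
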