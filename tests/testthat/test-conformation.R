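test_that("chi classification reproduces the bin definitions exactly", {
  expect_equal(as.character(classify_chi(200)), "low_anti")
  expect_equal(as.character(classify_chi(60)), "syn")
  expect_equal(as.character(classify_chi(280)), "high_anti")
  expect_equal(as.character(classify_chi(100)), "other")
  # boundaries: syn and anti are open intervals; 220/270 belong to mid anti
  expect_equal(as.character(classify_chi(c(30, 90, 170, 320, 220, 270, 219.99, 270.01))),
               c("other", "other", "other", "other", "mid_anti", "mid_anti",
                 "low_anti", "high_anti"))
})

test_that("pucker classification uses north (-90, 90] / south (90, 270]", {
  expect_equal(as.character(classify_pucker(17)), "north")
  expect_equal(as.character(classify_pucker(162)), "south")
  expect_equal(as.character(classify_pucker(90)), "north")
  expect_equal(as.character(classify_pucker(90.0001)), "south")
  expect_equal(as.character(classify_pucker(270)), "south")
  expect_error(classify_pucker(271))
})

test_that("every (chi, P) combination maps to exactly one label per family", {
  chi <- seq(0, 359.5, by = 0.5)
  labs <- classify_chi(chi)
  expect_false(anyNA(labs))
  P <- seq(-89.5, 270, by = 0.5)
  plabs <- classify_pucker(P)
  expect_false(anyNA(plabs))
})

test_that("glycosidic chi dispatches by base type and reports missing atoms", {
  s <- fx_duplex_b()
  # purine residue uses N9; its chi sits in the anti band on the built model
  for (r in c(3, 8, 14)) {
    expect_true(classify_chi(glycosidic_chi(s, "W", r)) %in%
                  c("low_anti", "mid_anti", "high_anti"))
  }
  # pyrimidine residue (no N9) uses the N1-C2 path
  expect_false("N9" %in% s$atom[s$chain == "C" & s$residue == 5])
  expect_equal(glycosidic_chi(s, "C", 5), 262, tolerance = 1e-6)
  # missing O4'
  broken <- s[!(s$chain == "W" & s$residue == 4 & s$atom == "O4'"), ]
  expect_error(glycosidic_chi(broken, "W", 4), "O4'",
               class = "lnahelix_missing_atom_error")
})

test_that("profiles of a pure-LNA strand are 100% north", {
  all_lna <- build_single_strand("CTTTTCTTTTTTCT", helix_spec("A"))
  gen <- generate_trajectory(all_lna, traj_spec(n_frames = 60, seed = 5))
  prof <- conformation_profile(gen$trajectory)
  expect_true(all(prof$fractions$north == 1))
  expect_true(all(prof$fractions$south == 0))
})

test_that("single-frame profiles are point masses and fractions sum to one", {
  s <- fx_duplex_b()
  prof <- conformation_profile(s)
  expect_equal(prof$n_frames, 1)
  counts <- prof$p_hist %>% dplyr::count(chain, residue, wt = count)
  expect_true(all(counts$n == 1))
  f <- prof$fractions
  expect_equal(f$syn + f$low_anti + f$mid_anti + f$high_anti + f$other,
               rep(1, nrow(f)))
  expect_equal(f$north + f$south, rep(1, nrow(f)))
})

test_that("end exclusion drops the terminal residues of every strand", {
  s <- fx_duplex_b()
  prof <- conformation_profile(s, exclude_ends = 2)
  expect_equal(sort(unique(prof$fractions$residue[prof$fractions$chain == "W"])), 3:17)
  prof0 <- conformation_profile(s, exclude_ends = 0)
  expect_equal(nrow(prof0$fractions), 38)
  expect_error(conformation_profile(s, exclude_ends = 10),
               class = "lnahelix_value_error")
})

test_that("the generator's north fraction is recovered from the trajectory", {
  # all-DNA strand, independent frames so the binomial error model applies
  strand <- build_single_strand(get_oligo("ON1"), helix_spec("B"))
  gen <- generate_trajectory(strand, traj_spec(n_frames = 2000, seed = 303,
                                               flip_rate = 1))
  prof <- conformation_profile(gen$trajectory)
  # strand-wide mean: 3 SDs of the pooled binomial
  n_pool <- 2000 * nrow(prof$fractions)
  expect_lt(abs(mean(prof$fractions$north) - 0.30), 3 * sqrt(0.30 * 0.70 / n_pool))
  # per residue: 4 SDs keeps the familywise false-alarm rate below 0.1%
  sd1 <- sqrt(0.30 * 0.70 / 2000)
  for (i in seq_len(nrow(prof$fractions))) {
    expect_lt(abs(prof$fractions$north[i] - 0.30), 4 * sd1)
  }
  # and the labels agree with the generator's realized states exactly
  gt <- gen$ground_truth$pucker
  rec <- prof$records
  merged <- dplyr::inner_join(rec, gt, by = c("chain", "residue", "frame"))
  expect_equal(as.character(merged$pucker_label), merged$state)
})
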