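test_that("pair registry enumerates WC and HG pairs with correct counts", {
  tx <- fx_triplex()
  reg <- pair_registry(tx)
  expect_equal(sum(reg$kind == "WC"), 19)
  expect_equal(sum(reg$kind == "HG"), 15)
  # WC pairs link W and C; HG pairs link W and T
  wc <- reg[reg$kind == "WC", ]
  expect_true(all(sort(c(wc$chain1, wc$chain2)) %in% c("C", "W")))
  hg <- reg[reg$kind == "HG", ]
  expect_true(all(hg$chain1 == "W" & hg$chain2 == "T"))
  expect_true(all(hg$atom1 == "N7" & hg$atom2 == "N3"))
  expect_true(all(wc$atom1 == "N1" & wc$atom2 == "N3"))
  # duplex only: no HG pairs
  reg_d <- pair_registry(fx_duplex_b())
  expect_equal(sum(reg_d$kind == "HG"), 0)
})

test_that("FXN registry assigns alternating triad types per sequence", {
  tx <- build_triplex(get_target("FXN_DS19"), get_oligo("ON4-5'LNA-reduced"),
                      helix_spec("B"))
  hg <- pair_registry(tx)
  hg <- hg[hg$kind == "HG", ]
  # TFO cttcttCtTcTtCtT reads C,T,T,C,T,T,... along the site
  expect_equal(hg$triad, rep(c("C+.G", "T.A", "T.A"), 5))
})

test_that("pair distances behave geometrically", {
  tx <- fx_triplex()
  reg <- pair_registry(tx)
  hg1 <- reg[reg$kind == "HG", ][1, ]
  d0 <- pair_distance(tx, hg1)
  expect_lt(d0, 3.5)
  mo <- rigid_case(7)
  expect_equal(pair_distance(transform_structure(tx, mo$R, mo$t), hg1), d0,
               tolerance = 1e-9)
  # pair referencing an absent chain
  dup <- fx_duplex_b()
  expect_error(pair_distance(dup, hg1), class = "lnahelix_lookup_error")
})

test_that("persistence of built models is all-true at the default cutoff", {
  combos <- list(
    c("c-MYC_DS19", "ON2-5'DNA"),
    c("c-MYC_DS19", "ON2"),
    c("c-MYC_DS19", "ON2-3'LNA-reduced"),
    c("FXN_DS19", "ON4-3'LNA-reduced"),
    c("c-MYC_DS45", "ON2-3'-penultimate-TINA"),
    c("c-MYC_DS19-Hetero", "ON2-5'DNA")
  )
  for (cb in combos) {
    tx <- build_triplex(get_target(cb[1]), get_oligo(cb[2]), helix_spec("B"))
    pm <- persistence_matrix(tx)
    expect_true(all(pm$paired), info = paste(cb, collapse = " + "))
  }
})

test_that("raising the cutoff never decreases any paired fraction", {
  run <- fx_recovery_run()
  pm35 <- persistence_matrix(run$gen$trajectory, cutoff = 3.5)
  pm45 <- persistence_matrix(run$gen$trajectory, cutoff = 4.5)
  expect_true(all(rowMeans(pm45$paired) >= rowMeans(pm35$paired)))
  expect_error(persistence_matrix(run$gen$trajectory, cutoff = -1),
               class = "lnahelix_value_error")
})

test_that("stationary open probability is recovered from a long trajectory", {
  run <- fx_recovery_run()
  pm <- persistence_matrix(run$gen$trajectory)
  hg <- pm$pairs$kind == "HG"
  frac <- rowMeans(pm$paired[hg, ])
  nf <- ncol(pm$paired)
  for (k in seq_along(frac)) {
    p_closed <- 1 - run$p_open[k]
    sd3 <- 3 * sqrt(max(p_closed * (1 - p_closed), 1e-12) / nf)
    expect_lt(abs(frac[k] - p_closed), sd3 + 1e-9)
  }
})

test_that("emitted persistence equals generator ground truth exactly", {
  run <- fx_recovery_run()
  pm <- persistence_matrix(run$gen$trajectory)
  hg <- which(pm$pairs$kind == "HG")
  gt <- run$gen$ground_truth$pairs
  gt_open <- matrix(gt$open, nrow = length(hg))
  expect_identical(unname(pm$paired[hg, ]), !gt_open)
  expect_true(all(pm$paired[-hg, ]))
})

test_that("lost pairs are detected from the final window only", {
  tx <- fx_triplex()
  reg <- pair_registry(tx)
  n_hg <- sum(reg$kind == "HG")
  # force the 3 terminal 3'-end HG pairs permanently open
  p_open <- rep(0, n_hg)
  p_open[(n_hg - 2):n_hg] <- 1
  gen <- generate_trajectory(tx, traj_spec(n_frames = 60, seed = 17, p_open = p_open))
  pm <- persistence_matrix(gen$trajectory)
  lost <- lost_pairs(pm)
  expect_equal(attr(lost, "n_lost"), 3)
  expect_true(all(lost$end == "3prime"))
  expect_equal(sort(lost$res2), (n_hg - 2):n_hg)

  # all-true persistence: nothing lost
  pm_all <- persistence_matrix(tx)
  expect_error(lost_pairs(pm_all), class = "lnahelix_value_error") # 1 frame
  gen2 <- generate_trajectory(tx, traj_spec(n_frames = 30, seed = 2))
  expect_equal(attr(lost_pairs(persistence_matrix(gen2$trajectory)), "n_lost"), 0)

  # open only in the first half, closed later: not lost
  fake <- pm
  fake$paired[,] <- TRUE
  k <- which(reg$kind == "HG")[5]
  fake$paired[k, 1:30] <- FALSE
  expect_equal(attr(lost_pairs(fake), "n_lost"), 0)

  # lowering the threshold can only add losses
  l_low <- lost_pairs(pm, open_threshold = 0.2)
  l_high <- lost_pairs(pm, open_threshold = 0.8)
  expect_true(all(l_high$pair_id %in% l_low$pair_id))
})

test_that("persistence exports are well-formed", {
  run <- fx_recovery_run()
  pm <- persistence_matrix(run$gen$trajectory)
  long <- tibble::as_tibble(pm)
  expect_equal(nrow(long), nrow(pm$paired) * ncol(pm$paired))
  expect_equal(unique(diff(sort(unique(long$time_ps)))), 40)
  mosaic <- utils::capture.output(persistence_mosaic(pm, width = 40))
  expect_equal(length(mosaic), nrow(pm$paired))
})
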