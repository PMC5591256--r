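# Seeded synthetic trajectory generator. Emulates the statistical structure
# of MD snapshot series: locked-north LNA sugars, two-state south-preferring
# DNA sugar repuckering, Gaussian positional noise, and two-state Hoogsteen
# base-pair opening with an end-/chemistry-biased opening profile. The
# generator records its realized states as ground truth so every analysis
# stage can be validated by parameter recovery.

#' Specification of a synthetic trajectory
#'
#' Sugar puckering and base-pair opening are independent two-state Markov
#' chains whose stationary probabilities are the contract; transition
#' intensity `flip_rate` (per frame) only sets how fast states mix.
#' In the north state P is drawn from Normal(17, 5) truncated to the north
#' range, in the south state from Normal(162, 8) truncated to the south
#' range. Open Hoogsteen pairs displace the whole TFO nucleotide rigidly by
#' `opening_displacement` along the groove-exit direction. After adding
#' isotropic Gaussian noise, noise draws that would contradict the realized
#' states are rejected and redrawn: the nitrogen noise of any monitored pair
#' whose formed/open state would flip at the 3.5 A cutoff, and the ring-atom
#' noise of any residue whose measured north/south class would flip. The
#' emitted persistence matrix and measured pucker classes therefore equal
#' the ground truth exactly.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Frame spacing in ps (default 40, the usual MD
#'   snapshot interval).
#' @param seed Integer seed; the entire trajectory is a deterministic
#'   function of it.
#' @param noise_sigma Isotropic positional noise, A per coordinate
#'   (default 0.15).
#' @param f_north_dna Stationary north fraction of DNA sugars (default 0.30;
#'   DNA prefers south). LNA is fixed at 1.
#' @param flip_rate Markov transition intensity per frame (default 0.1).
#' @param p_open Stationary open probability of Hoogsteen pairs: a scalar,
#'   or a vector with one entry per HG pair (default 0).
#' @param opening_displacement Rigid displacement of an open TFO nucleotide,
#'   A (default 3).
#' @param tau_north,tau_south Puckering amplitudes used in each state
#'   (degrees); LNA uses `tau_lna` in the north state.
#' @return A `traj_spec` list.
#' @export
traj_spec <- function(n_frames, frame_interval = 40, seed = 1,
                      noise_sigma = 0.15, f_north_dna = 0.30,
                      flip_rate = 0.1, p_open = 0,
                      opening_displacement = 3,
                      tau_north = 40, tau_south = 38, tau_lna = 48) {
  spec <- list(n_frames = as.integer(n_frames), frame_interval = frame_interval,
               seed = as.integer(seed), noise_sigma = noise_sigma,
               f_north_dna = f_north_dna, f_north_lna = 1,
               flip_rate = flip_rate, p_open = p_open,
               opening_displacement = opening_displacement,
               tau_north = tau_north, tau_south = tau_south, tau_lna = tau_lna)
  validate_traj_spec(spec)
  class(spec) <- "traj_spec"
  spec
}

validate_traj_spec <- function(spec) {
  if (spec$n_frames < 1) abort("n_frames must be >= 1", class = "lnahelix_spec_error")
  if (spec$frame_interval <= 0) abort("frame_interval must be positive", class = "lnahelix_spec_error")
  if (spec$f_north_dna < 0 || spec$f_north_dna > 1) {
    abort("f_north_dna must be in [0, 1]", class = "lnahelix_spec_error")
  }
  if (spec$f_north_lna != 1) abort("LNA north fraction must be 1 (locked)", class = "lnahelix_spec_error")
  if (any(spec$p_open < 0) || any(spec$p_open > 1)) {
    abort("p_open must be in [0, 1]", class = "lnahelix_spec_error")
  }
  if (spec$flip_rate < 0 || spec$flip_rate > 1) {
    abort("flip_rate must be in [0, 1]", class = "lnahelix_spec_error")
  }
  if (spec$noise_sigma < 0) abort("noise_sigma must be >= 0", class = "lnahelix_spec_error")
  invisible(spec)
}

# simulate a two-state Markov chain with stationary probability p (of state
# TRUE) and intensity kappa: P(F->T) = kappa p, P(T->F) = kappa (1 - p).
# Vectorized over chains: p length-m, returns m x n matrix.
markov_chain <- function(p, n, kappa) {
  m <- length(p)
  out <- matrix(FALSE, m, n)
  state <- runif(m) < p
  out[, 1] <- state
  if (n > 1) {
    a <- kappa * p          # off -> on
    b <- kappa * (1 - p)    # on -> off
    for (f in 2:n) {
      u <- runif(m)
      state <- ifelse(state, u >= b, u < a)
      out[, f] <- state
    }
  }
  out
}

# truncated normal draw via inverse CDF (vectorized, deterministic given RNG)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic trajectory with ground truth
#'
#' Starting from a built structure, advances per-residue sugar pucker chains
#' (rebuilding each ring at the drawn phase) and per-Hoogsteen-pair opening
#' chains, adds Gaussian noise, and emits the frames together with the
#' realized states. Two calls with the same spec produce identical
#' coordinates.
#'
#' @param base A `dna_structure` (duplex, triplex or single strand).
#' @param spec A [traj_spec()].
#' @return A list with `trajectory` (a `dna_trajectory`), `ground_truth`
#'   (list of tibbles `pucker` and `pairs`), and `pairs` (the registry used
#'   for opening, or NULL).
#' @export
generate_trajectory <- function(base, spec) {
  stopifnot(is_dna_structure(base))
  validate_traj_spec(spec)
  withr::with_seed(spec$seed, generate_trajectory_impl(base, spec))
}

generate_trajectory_impl <- function(base, spec) {
  topo <- base
  nf <- spec$n_frames
  xyz0 <- coords_matrix(topo)
  n_atoms <- nrow(xyz0)

  # --- residue bookkeeping for pucker dynamics -------------------------------
  res <- topo[!duplicated(paste(topo$chain, topo$residue)),
              c("chain", "residue", "base", "chemistry")]
  res <- res[!is.na(res$base), ]
  nr <- nrow(res)
  res_rows <- lapply(seq_len(nr), function(i) {
    which(topo$chain == res$chain[i] & topo$residue == res$residue[i])
  })
  # static attachment geometry per residue (base atoms never move except
  # noise/displacement, applied later)
  att <- lapply(seq_len(nr), function(i) {
    idx <- res_rows[[i]]
    atoms <- topo$atom[idx]
    b <- res$base[i]
    need <- c("C1'", "O4'", "C2'", glycosidic_n(b), chi_c_atom(b))
    pos <- match(need, atoms)
    xyz <- xyz0[idx[pos], , drop = FALSE]
    rownames(xyz) <- need
    chi <- dihedral(xyz["O4'", ], xyz["C1'", ], xyz[glycosidic_n(b), ],
                    xyz[chi_c_atom(b), ], range = "positive")
    ring_pos <- match(RING_ATOMS, atoms)
    exo_pos <- which(!atoms %in% c(RING_ATOMS, rownames(base_template(b))))
    old_frame <- sugar_frame(xyz["C1'", ], xyz["O4'", ], xyz["C2'", ])
    exo_local <- if (length(exo_pos)) {
      t(t(old_frame$R) %*% (t(xyz0[idx[exo_pos], , drop = FALSE]) - as.vector(old_frame$o)))
    } else NULL
    list(idx = idx, chi = chi, c1 = xyz["C1'", ], nat = xyz[glycosidic_n(b), ],
         cx = xyz[chi_c_atom(b), ], ring_pos = ring_pos, exo_pos = exo_pos,
         exo_local = exo_local)
  })
  is_lna <- res$chemistry == "LNA"
  f_north <- ifelse(is_lna, 1, spec$f_north_dna)

  # --- pair bookkeeping for opening dynamics ---------------------------------
  pairs <- NULL; hg <- NULL; open_dirs <- NULL; hg_res_rows <- NULL
  if (all(c("W", "C") %in% structure_chains(topo))) {
    pairs <- pair_registry(topo)
  }
  if (!is.null(pairs) && any(pairs$kind == "HG")) {
    hg <- pairs[pairs$kind == "HG", ]
    p_open <- rep(spec$p_open, length.out = nrow(hg))
    ii <- pair_atom_indices(topo, hg)
    open_dirs <- vunit(as_row3(xyz0[ii[, 2], , drop = FALSE] - xyz0[ii[, 1], , drop = FALSE]))
    hg_res_rows <- lapply(seq_len(nrow(hg)), function(k) {
      which(topo$chain == hg$chain2[k] & topo$residue == hg$res2[k])
    })
  } else {
    p_open <- numeric(0)
  }
  pair_idx <- if (!is.null(pairs)) pair_atom_indices(topo, pairs) else NULL

  # --- realized state series -------------------------------------------------
  north_states <- markov_chain(f_north, nf, spec$flip_rate)   # TRUE = north
  open_states <- if (!is.null(hg)) markov_chain(p_open, nf, spec$flip_rate) else NULL

  P_draw <- matrix(NA_real_, nr, nf)
  tau_draw <- matrix(NA_real_, nr, nf)
  for (i in seq_len(nr)) {
    north <- north_states[i, ]
    tau_n <- if (is_lna[i]) spec$tau_lna else spec$tau_north
    Pn <- rtruncnorm(nf, 17, 5, -90, 90)
    Ps <- rtruncnorm(nf, 162, 8, 90 + 1e-9, 270)
    P_draw[i, ] <- ifelse(north, Pn, Ps)
    tau_draw[i, ] <- ifelse(north, tau_n, spec$tau_south)
  }

  # --- frames ----------------------------------------------------------------
  coords <- array(NA_real_, c(n_atoms, 3, nf))
  cutoff <- DEFAULT_HBOND_CUTOFF
  for (f in seq_len(nf)) {
    xyz <- xyz0
    # rebuild rings at the drawn pucker (solved jointly for all residues)
    rings <- solve_rings(P_draw[, f], tau_draw[, f], tol = 1e-5)
    for (i in seq_len(nr)) {
      a <- att[[i]]
      placed <- place_ring(rings[i, , ], a$c1, a$nat, a$cx, a$chi)
      xyz[a$idx[a$ring_pos], ] <- placed
      if (length(a$exo_pos)) {
        nf_frame <- sugar_frame(placed["C1'", ], placed["O4'", ], placed["C2'", ])
        xyz[a$idx[a$exo_pos], ] <- t(nf_frame$R %*% t(a$exo_local) + as.vector(nf_frame$o))
      }
    }
    # displace open TFO nucleotides
    if (!is.null(hg)) {
      for (k in which(open_states[, f])) {
        rows <- hg_res_rows[[k]]
        xyz[rows, ] <- xyz[rows, ] + matrix(spec$opening_displacement * open_dirs[k, ],
                                            length(rows), 3, byrow = TRUE)
      }
    }
    # noise, with redraw so the emitted frame agrees with ground truth: a
    # residue's measured pucker class must match its realized state, and a
    # monitored pair's distance must sit on the correct side of the cutoff
    noise <- matrix(rnorm(n_atoms * 3, sd = spec$noise_sigma), n_atoms, 3)
    if (spec$noise_sigma > 0) {
      ring_rows <- vapply(seq_len(nr), function(i) att[[i]]$idx[att[[i]]$ring_pos],
                          integer(5))
      want_north <- north_states[, f]
      for (iter in 1:500) {
        rn <- array(NA_real_, c(nr, 5, 3))
        for (a in 1:5) rn[, a, ] <- xyz[ring_rows[a, ], ] + noise[ring_rows[a, ], ]
        lab_north <- measure_rings(rn)$P <= 90
        bad <- which(lab_north != want_north)
        if (!length(bad)) break
        for (i in bad) {
          noise[ring_rows[, i], ] <- rnorm(15, sd = spec$noise_sigma)
        }
      }
    }
    if (!is.null(pairs) && spec$noise_sigma > 0) {
      want_open <- rep(FALSE, nrow(pairs))
      if (!is.null(hg)) want_open[pairs$kind == "HG"] <- open_states[, f]
      for (k in seq_len(nrow(pairs))) {
        i1 <- pair_idx[k, 1]; i2 <- pair_idx[k, 2]
        for (try in 1:200) {
          d <- sqrt(sum((xyz[i1, ] + noise[i1, ] - xyz[i2, ] - noise[i2, ])^2))
          state_ok <- if (want_open[k]) d >= cutoff else d < cutoff
          if (state_ok) break
          noise[i1, ] <- rnorm(3, sd = spec$noise_sigma)
          noise[i2, ] <- rnorm(3, sd = spec$noise_sigma)
        }
      }
    }
    coords[, , f] <- xyz + noise
  }

  gt_pucker <- tibble(
    chain = rep(res$chain, nf), residue = rep(res$residue, nf),
    frame = rep(seq_len(nf), each = nr),
    state = ifelse(as.vector(north_states), "north", "south"),
    P = as.vector(P_draw)
  )
  gt_pairs <- if (!is.null(hg)) {
    tibble(
      pair_id = rep(hg$pair_id, nf),
      frame = rep(seq_len(nf), each = nrow(hg)),
      open = as.vector(open_states)
    )
  } else tibble(pair_id = character(), frame = integer(), open = logical())

  list(
    trajectory = dna_trajectory(topo, coords, frame_interval = spec$frame_interval),
    ground_truth = list(pucker = gt_pucker, pairs = gt_pairs),
    pairs = pairs
  )
}

#' Ready-made study scenarios
#'
#' Named presets bundling a target duplex, an optional TFO, a fiber form and
#' a trajectory spec that reproduce the qualitative signatures studied on
#' these systems:
#'
#' * `"3prime-reduced"`: triplex with a TFO whose 3' segment is DNA-only
#'   (reduced LNA); opening probability is raised on that segment, so lost
#'   pairs localize to the 3' end.
#' * `"5prime-reduced"`: the mirror construct (DNA-only 5' segment).
#' * `"lna-tfo"`: stable triplex with the alternating LNA/DNA TFO; TFO
#'   sugars are 100% north while duplex DNA mixes north/south.
#' * `"hetero-duplex"`: the LNA-substituted duplex built from an axially
#'   displaced low-inclination A-like spec (the LirA-leaning start).
#' * `"duplex-only"`: the unmodified duplex, no third strand.
#'
#' @param name Preset name.
#' @param n_frames Frames to simulate (default 400).
#' @param seed Integer seed.
#' @return A list with `name`, `duplex`, `tfo` (or NULL), `spec`
#'   ([helix_spec()]), `traj_spec`, and the built `structure`.
#' @export
preset_scenario <- function(name, n_frames = 400, seed = 1) {
  presets <- c("3prime-reduced", "5prime-reduced", "lna-tfo",
               "hetero-duplex", "duplex-only")
  if (!name %in% presets) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(presets, collapse = ", ")),
          class = "lnahelix_lookup_error")
  }
  base_open <- 0.02
  raised_open <- 0.9
  if (name == "3prime-reduced") {
    duplex <- get_target("c-MYC_DS19")
    tfo <- get_oligo("ON2-3'LNA-reduced")
    hspec <- helix_spec("B")
    structure <- build_triplex(duplex, tfo, hspec)
    p_open <- end_bias_profile(tfo, base = base_open, raised = raised_open, end = "3prime")
    ts <- traj_spec(n_frames, seed = seed, p_open = p_open)
  } else if (name == "5prime-reduced") {
    duplex <- get_target("c-MYC_DS19")
    tfo <- get_oligo("ON2-5'LNA-reduced")
    hspec <- helix_spec("B")
    structure <- build_triplex(duplex, tfo, hspec)
    p_open <- end_bias_profile(tfo, base = base_open, raised = raised_open, end = "5prime")
    ts <- traj_spec(n_frames, seed = seed, p_open = p_open)
  } else if (name == "lna-tfo") {
    duplex <- get_target("c-MYC_DS19")
    tfo <- get_oligo("ON2")
    hspec <- helix_spec("B")
    structure <- build_triplex(duplex, tfo, hspec)
    ts <- traj_spec(n_frames, seed = seed, p_open = base_open)
  } else if (name == "hetero-duplex") {
    duplex <- get_target("c-MYC_DS19-Hetero")
    tfo <- NULL
    hspec <- helix_spec("A", twist = 30, rise = 3.0, x_disp = -4.3, inclination = 0)
    structure <- build_duplex(duplex, hspec)
    ts <- traj_spec(n_frames, seed = seed)
  } else {
    duplex <- get_target("c-MYC_DS19")
    tfo <- NULL
    hspec <- helix_spec("B")
    structure <- build_duplex(duplex, hspec)
    ts <- traj_spec(n_frames, seed = seed)
  }
  list(name = name, duplex = duplex, tfo = tfo, spec = hspec,
       traj_spec = ts, structure = structure)
}

#' Opening-probability profile with end bias
#'
#' Assigns a raised stationary open probability to the Hoogsteen pairs whose
#' TFO nucleotide lies in the terminal DNA-only run at the chosen end
#' (opening happens preferentially where LNA is absent), and the base
#' probability elsewhere.
#'
#' @param tfo An `oligo`.
#' @param base Baseline open probability.
#' @param raised Open probability on the DNA-only terminal run.
#' @param end `"3prime"` or `"5prime"`.
#' @return Numeric vector, one entry per TFO nucleotide.
#' @export
end_bias_profile <- function(tfo, base = 0.02, raised = 0.9,
                             end = c("3prime", "5prime")) {
  end <- match.arg(end)
  nt <- tfo[!is.na(tfo$base), ]
  m <- nrow(nt)
  p <- rep(base, m)
  chem <- nt$chemistry
  if (end == "3prime") {
    run <- rev(cumprod(rev(chem == "DNA")) == 1)
  } else {
    run <- cumprod(chem == "DNA") == 1
  }
  p[run] <- raised
  p
}
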