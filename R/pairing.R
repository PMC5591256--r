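# Base-pair bookkeeping and hydrogen-bond persistence. Watson-Crick pairs
# are monitored through the purine N1 - pyrimidine N3 distance, Hoogsteen
# pairs through purine N7 - TFO pyrimidine N3; a heavy-atom distance below
# 3.5 Angstroms counts as a formed hydrogen bond.

DEFAULT_HBOND_CUTOFF <- 3.5

#' Enumerate the base pairs of a duplex or triplex structure
#'
#' One Watson-Crick pair per duplex position (chains W and C, antiparallel
#' registry) and, when a third chain T is present, one Hoogsteen pair per
#' TFO position aligned to the binding site (taken from the structure's
#' site attribute, or located by sequence via
#' [find_tfo_binding_site()]).
#'
#' @param structure A `dna_structure` with chains W and C (T optional).
#' @return A tibble with one row per pair: `pair_id`, `kind` (WC/HG),
#'   `chain1`, `res1`, `atom1` (donor-side purine nitrogen), `chain2`,
#'   `res2`, `atom2`, `triad` (T.A / C+.G for HG pairs), `base1`, `base2`.
#' @export
pair_registry <- function(structure) {
  stopifnot(is_dna_structure(structure))
  chains <- structure_chains(structure)
  if (!all(c("W", "C") %in% chains)) {
    abort("pair registry needs duplex chains W and C", class = "lnahelix_value_error")
  }
  seqW <- strsplit(chain_sequence(structure, "W"), "")[[1]]
  seqC <- strsplit(chain_sequence(structure, "C"), "")[[1]]
  n <- length(seqW)
  if (length(seqC) != n) abort("duplex chains differ in length", class = "lnahelix_value_error")
  partner <- n + 1 - seq_len(n)
  bad <- which(WC_PARTNER[seqW] != seqC[partner])
  if (length(bad)) {
    abort(sprintf("unpairable residue: W/%d (%s) does not complement C/%d (%s)",
                  bad[1], seqW[bad[1]], partner[bad[1]], seqC[partner[bad[1]]]),
          class = "lnahelix_value_error")
  }
  purine_on_W <- is_purine(seqW)
  wc <- tibble(
    kind = "WC",
    chain1 = ifelse(purine_on_W, "W", "C"),
    res1 = ifelse(purine_on_W, seq_len(n), partner),
    atom1 = "N1",
    chain2 = ifelse(purine_on_W, "C", "W"),
    res2 = ifelse(purine_on_W, partner, seq_len(n)),
    atom2 = "N3",
    triad = NA_character_,
    base1 = ifelse(purine_on_W, seqW, seqC[partner]),
    base2 = ifelse(purine_on_W, seqC[partner], seqW)
  )
  out <- wc
  if ("T" %in% chains) {
    seqT <- strsplit(chain_sequence(structure, "T"), "")[[1]]
    site <- structure_site(structure)
    if (is.null(site)) {
      dx <- duplex_target(paste0(tolower(seqW), collapse = ""))
      site <- find_tfo_binding_site(dx, paste0(tolower(seqT), collapse = ""))
      if (is.null(site)) {
        abort("cannot align TFO chain to the purine strand", class = "lnahelix_value_error")
      }
    }
    m <- length(seqT)
    hg <- tibble(
      kind = "HG",
      chain1 = "W", res1 = site[1] + seq_len(m) - 1L, atom1 = "N7",
      chain2 = "T", res2 = seq_len(m), atom2 = "N3",
      triad = ifelse(seqT == "T", "T.A", "C+.G"),
      base1 = seqW[site[1] + seq_len(m) - 1L],
      base2 = seqT
    )
    if (any(!is_purine(hg$base1))) {
      bad <- which(!is_purine(hg$base1))[1]
      abort(sprintf("unpairable residue: Hoogsteen partner W/%d is not a purine", hg$res1[bad]),
            class = "lnahelix_value_error")
    }
    out <- bind_rows(wc, hg)
  }
  out$pair_id <- paste0(out$kind, "_", out$chain1, out$res1, ":", out$chain2, out$res2)
  out[, c("pair_id", "kind", "chain1", "res1", "atom1",
          "chain2", "res2", "atom2", "triad", "base1", "base2")]
}

#' Hydrogen-bond proxy distance of one pair in one frame
#'
#' Euclidean distance between the pair's two ring nitrogens (heavy atoms
#' only; no hydrogen or angle criterion).
#'
#' @param frame A `dna_structure`.
#' @param pair One row of a [pair_registry()] tibble.
#' @return Distance in Angstroms.
#' @export
pair_distance <- function(frame, pair) {
  a <- residue_atoms(frame, pair$chain1, pair$res1, pair$atom1)
  b <- residue_atoms(frame, pair$chain2, pair$res2, pair$atom2)
  sqrt(sum((a - b)^2))
}

pair_atom_indices <- function(topology, pairs) {
  key <- paste(topology$chain, topology$residue, topology$atom)
  i1 <- match(paste(pairs$chain1, pairs$res1, pairs$atom1), key)
  i2 <- match(paste(pairs$chain2, pairs$res2, pairs$atom2), key)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- which(is.na(i1) | is.na(i2))[1]
    abort(sprintf("pair %s references atoms absent from the structure", pairs$pair_id[bad]),
          class = "lnahelix_missing_atom_error")
  }
  cbind(i1, i2)
}

# distances for all pairs over all frames: pairs x frames matrix
pair_distance_matrix <- function(trajectory, pairs) {
  traj <- as_trajectory(trajectory)
  ii <- pair_atom_indices(traj$topology, pairs)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nrow(pairs), nf)
  for (f in seq_len(nf)) {
    d <- traj$coords[ii[, 1], , f] - traj$coords[ii[, 2], , f]
    out[, f] <- sqrt(rowSums(as_row3(d)^2))
  }
  rownames(out) <- pairs$pair_id
  out
}

#' Pair persistence over a trajectory
#'
#' Monitors every registered pair's nitrogen-nitrogen distance per frame and
#' marks the pair formed when the distance is below `cutoff`.
#'
#' @param trajectory A `dna_trajectory` (or single structure).
#' @param pairs A [pair_registry()] tibble; default: registry of the
#'   trajectory's topology.
#' @param cutoff Distance criterion in Angstroms (default 3.5).
#' @return A `pair_persistence`: list with `pairs`, logical `paired`
#'   (pairs x frames), numeric `distance` (same shape), `cutoff` and
#'   `frame_interval`.
#' @export
persistence_matrix <- function(trajectory, pairs = NULL, cutoff = DEFAULT_HBOND_CUTOFF) {
  if (cutoff <= 0) abort("cutoff must be positive", class = "lnahelix_value_error")
  traj <- as_trajectory(trajectory)
  if (is.null(pairs)) pairs <- pair_registry(traj$topology)
  d <- pair_distance_matrix(traj, pairs)
  structure(
    list(pairs = pairs, paired = d < cutoff, distance = d,
         cutoff = cutoff, frame_interval = traj$frame_interval),
    class = "pair_persistence"
  )
}

#' @export
print.pair_persistence <- function(x, ...) {
  cat(sprintf("<pair_persistence> %d pairs x %d frames, cutoff %.2f A\n",
              nrow(x$paired), ncol(x$paired), x$cutoff))
  cat(sprintf("  overall paired fraction: %.3f\n", mean(x$paired)))
  invisible(x)
}

#' Paired fraction per pair
#' @param persistence A `pair_persistence`.
#' @return Tibble with `pair_id`, `kind`, `paired_fraction`.
#' @export
paired_fractions <- function(persistence) {
  tibble(
    pair_id = persistence$pairs$pair_id,
    kind = persistence$pairs$kind,
    paired_fraction = rowMeans(persistence$paired)
  )
}

#' Pairs lost by the end of a trajectory
#'
#' A pair counts as lost when its unpaired fraction over the final
#' `window_fraction` of frames exceeds `open_threshold`. Positions are
#' annotated with their proximity to the 5' and 3' ends of the second
#' (typically TFO) residue's chain.
#'
#' @param persistence A `pair_persistence`.
#' @param window_fraction Fraction of trailing frames examined (default 1/3).
#' @param open_threshold Unpaired-fraction threshold (default 0.5).
#' @return A tibble of lost pairs: `pair_id`, `kind`, `res2`, `unpaired_final`,
#'   `dist_to_5p`, `dist_to_3p`, `end` (`"5prime"`/`"3prime"`), plus the
#'   count as attribute `"n_lost"`.
#' @export
lost_pairs <- function(persistence, window_fraction = 1/3, open_threshold = 0.5) {
  nf <- ncol(persistence$paired)
  if (nf < 3) abort("lost_pairs needs at least 3 frames", class = "lnahelix_value_error")
  w <- floor(nf * window_fraction)
  if (w < 1) abort("final window is shorter than one frame", class = "lnahelix_value_error")
  win <- (nf - w + 1):nf
  unpaired <- rowMeans(!persistence$paired[, win, drop = FALSE])
  pairs <- persistence$pairs
  lost <- which(unpaired > open_threshold)
  out <- pairs[lost, c("pair_id", "kind", "chain2", "res2")]
  out$unpaired_final <- unpaired[lost]
  # end proximity within the partner chain
  out$dist_to_5p <- NA_integer_
  out$dist_to_3p <- NA_integer_
  for (ch in unique(out$chain2)) {
    r <- range(pairs$res2[pairs$chain2 == ch])
    i <- out$chain2 == ch
    out$dist_to_5p[i] <- out$res2[i] - r[1]
    out$dist_to_3p[i] <- r[2] - out$res2[i]
  }
  out$end <- ifelse(out$dist_to_3p <= out$dist_to_5p, "3prime", "5prime")
  attr(out, "n_lost") <- nrow(out)
  out
}

#' Text mosaic of a persistence matrix
#'
#' Renders the pair x time matrix as text, one row per pair ('#' paired,
#' '.' open), mirroring hydrogen-bond-versus-time persistence plots where
#' blank stretches mark lost hydrogen bonds.
#'
#' @param persistence A `pair_persistence`.
#' @param width Number of character columns (frames are block-averaged).
#' @return Character vector of lines, invisibly; also printed.
#' @export
persistence_mosaic <- function(persistence, width = 80) {
  m <- persistence$paired
  nf <- ncol(m)
  cols <- min(width, nf)
  breaks <- floor(seq(0, nf, length.out = cols + 1))
  lines <- vapply(seq_len(nrow(m)), function(i) {
    cells <- vapply(seq_len(cols), function(j) {
      seg <- m[i, (breaks[j] + 1):breaks[j + 1]]
      if (mean(seg) >= 0.5) "#" else "."
    }, character(1))
    sprintf("%-18s %s", persistence$pairs$pair_id[i], paste0(cells, collapse = ""))
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}
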