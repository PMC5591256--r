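# Per-residue conformational observables: glycosidic torsion chi, sugar
# pseudorotation, and their classification into the standard bins.
#
# chi is reported in [0, 360) so the bins anti (170, 320) -- split into low
# anti below 220, mid anti in [220, 270], high anti above 270 -- and syn
# (30, 90) read off directly. P is reported in (-90, 270] so north
# (-90 < P <= 90) and south (90 < P <= 270) partition the pseudorotation
# cycle.

#' Glycosidic torsion of a residue
#'
#' The torsion O4'-C1'-N1-C2 for pyrimidines or O4'-C1'-N9-C4 for purines,
#' in degrees mapped to \[0, 360). The atom quadruple is chosen by base
#' type: residues with an N9 atom use the purine path, others the
#' pyrimidine path.
#'
#' @param structure A `dna_structure`.
#' @param chain Chain id.
#' @param residue Residue index.
#' @return chi in degrees, \[0, 360).
#' @export
glycosidic_chi <- function(structure, chain, residue) {
  sel <- structure$chain == chain & structure$residue == residue
  if (!any(sel)) abort(sprintf("no residue %s/%s", chain, residue), class = "lnahelix_lookup_error")
  atoms <- structure$atom[sel]
  quad <- if ("N9" %in% atoms) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  xyz <- residue_atoms(structure, chain, residue, quad)
  dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ], range = "positive")
}

#' Classify a glycosidic torsion
#'
#' Bins: syn (30, 90); anti (170, 320), subdivided into low anti below 220,
#' mid anti in \[220, 270\] and high anti above 270; everything else is
#' `other`.
#'
#' @param chi Torsion(s) in degrees, \[0, 360). Vectorized.
#' @return Factor with levels syn, low_anti, mid_anti, high_anti, other.
#' @examples
#' classify_chi(c(200, 60, 280, 100))
#' @export
classify_chi <- function(chi) {
  if (any(chi < 0 | chi >= 360)) abort("chi must be in [0, 360)")
  lab <- ifelse(chi > 30 & chi < 90, "syn",
         ifelse(chi > 170 & chi < 320,
                ifelse(chi < 220, "low_anti",
                ifelse(chi > 270, "high_anti", "mid_anti")),
                "other"))
  factor(lab, levels = CHI_LEVELS)
}

CHI_LEVELS <- c("syn", "low_anti", "mid_anti", "high_anti", "other")
PUCKER_LEVELS <- c("north", "south")

#' Classify a pseudorotation phase
#'
#' north: -90 < P <= 90; south: 90 < P <= 270 (boundary 90 is north).
#'
#' @param P Phase(s) in degrees, (-90, 270]. Vectorized.
#' @return Factor with levels north, south.
#' @examples
#' classify_pucker(c(17, 162, 90))
#' @export
classify_pucker <- function(P) {
  if (any(P <= -90 | P > 270)) abort("P must be in (-90, 270]")
  factor(ifelse(P <= 90, "north", "south"), levels = PUCKER_LEVELS)
}

# indices (into the structure tibble) of one atom per residue; NA when absent
atom_index_by_residue <- function(structure, residues, atom) {
  key <- paste(structure$chain, structure$residue, structure$atom)
  match(paste(residues$chain, residues$residue, atom), key)
}

# residues retained by the end-exclusion rule, per chain
included_residues <- function(structure, chains = NULL, exclude_ends = 2) {
  res <- structure[!duplicated(paste(structure$chain, structure$residue)),
                   c("chain", "residue", "base", "chemistry")]
  if (!is.null(chains)) res <- res[res$chain %in% chains, ]
  keep <- unlist(lapply(split(seq_len(nrow(res)), res$chain), function(ix) {
    r <- res$residue[ix]
    lo <- min(r) + exclude_ends
    hi <- max(r) - exclude_ends
    ix[r >= lo & r <= hi]
  }))
  out <- res[sort(keep), ]
  if (!nrow(out)) abort("empty selection after end exclusion", class = "lnahelix_value_error")
  out
}

#' Per-residue conformational profile over a trajectory
#'
#' For every included residue and frame, computes the glycosidic torsion chi
#' and pseudorotation phase P, classifies them, and summarizes class
#' fractions and binned histograms per residue. Following the convention
#' used for trajectory analyses of duplexes and triplexes, the terminal
#' `exclude_ends` nucleotides at each end of each strand are omitted (set
#' `exclude_ends = 0` to keep them).
#'
#' @param trajectory A `dna_trajectory` (or a single `dna_structure`).
#' @param chains Chain ids to include (default: all).
#' @param exclude_ends Number of residues dropped from each end of each
#'   chain (default 2).
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return A `conformation_profile`: list with tibbles `fractions` (one row
#'   per residue, chi-class and pucker-class fractions), `records` (one row
#'   per residue x frame with chi, P, tau_m and labels), `chi_hist` and
#'   `p_hist` (long-format histograms).
#' @export
conformation_profile <- function(trajectory, chains = NULL, exclude_ends = 2,
                                 bin_width = 5) {
  traj <- as_trajectory(trajectory)
  topo <- traj$topology
  res <- included_residues(topo, chains, exclude_ends)
  nf <- n_frames(traj)
  nr <- nrow(res)

  # atom row indices per residue for the chi quadruple and the ring
  has_n9 <- !is.na(atom_index_by_residue(topo, res, "N9"))
  chi_atoms <- cbind(
    atom_index_by_residue(topo, res, "O4'"),
    atom_index_by_residue(topo, res, "C1'"),
    ifelse(has_n9, atom_index_by_residue(topo, res, "N9"),
                   atom_index_by_residue(topo, res, "N1")),
    ifelse(has_n9, atom_index_by_residue(topo, res, "C4"),
                   atom_index_by_residue(topo, res, "C2"))
  )
  ring_idx <- sapply(RING_ATOMS, function(a) atom_index_by_residue(topo, res, a))
  if (anyNA(chi_atoms) || anyNA(ring_idx)) {
    miss <- which(is.na(chi_atoms) | rowSums(is.na(ring_idx)) > 0)[1]
    abort(sprintf("residue %s/%d is missing atoms required for conformation analysis",
                  res$chain[miss], res$residue[miss]),
          class = "lnahelix_missing_atom_error")
  }

  grab <- function(idx_mat_col, f) traj$coords[idx_mat_col, , f]
  recs <- vector("list", nf)
  for (f in seq_len(nf)) {
    chi <- dihedral(grab(chi_atoms[, 1], f), grab(chi_atoms[, 2], f),
                    grab(chi_atoms[, 3], f), grab(chi_atoms[, 4], f),
                    range = "positive")
    rings <- array(NA_real_, c(nr, 5, 3))
    for (a in 1:5) rings[, a, ] <- traj$coords[ring_idx[, a], , f]
    m <- measure_rings(rings)
    recs[[f]] <- tibble(
      chain = res$chain, residue = res$residue, frame = f,
      chi = chi, P = m$P, tau_m = m$tau_m
    )
  }
  records <- bind_rows(recs)
  records$chi_label <- classify_chi(records$chi)
  records$pucker_label <- classify_pucker(records$P)

  frac_chi <- records %>%
    group_by(.data$chain, .data$residue) %>%
    summarise(total = n(),
              syn = mean(.data$chi_label == "syn"),
              low_anti = mean(.data$chi_label == "low_anti"),
              mid_anti = mean(.data$chi_label == "mid_anti"),
              high_anti = mean(.data$chi_label == "high_anti"),
              other = mean(.data$chi_label == "other"),
              north = mean(.data$pucker_label == "north"),
              south = mean(.data$pucker_label == "south"),
              .groups = "drop")
  fractions <- dplyr::left_join(res, frac_chi, by = c("chain", "residue"))

  hist_of <- function(values, lo, hi) {
    brk <- seq(lo, hi, by = bin_width)
    records %>%
      mutate(bin = cut({{ values }}, breaks = brk, include.lowest = TRUE,
                       labels = utils::head(brk, -1) + bin_width / 2)) %>%
      group_by(.data$chain, .data$residue, .data$bin) %>%
      summarise(count = n(), .groups = "drop") %>%
      mutate(bin_mid = as.numeric(as.character(.data$bin)),
             fraction = .data$count / nf) %>%
      select(-"bin")
  }
  chi_hist <- hist_of(.data$chi, 0, 360)
  p_hist <- hist_of(.data$P, -90, 270)

  structure(
    list(fractions = fractions, records = records,
         chi_hist = chi_hist, p_hist = p_hist,
         n_frames = nf, bin_width = bin_width, exclude_ends = exclude_ends),
    class = "conformation_profile"
  )
}

#' @export
print.conformation_profile <- function(x, ...) {
  cat(sprintf("<conformation_profile> %d residues x %d frames (ends excluded: %d)\n",
              nrow(x$fractions), x$n_frames, x$exclude_ends))
  print(x$fractions, n = 6)
  invisible(x)
}
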