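# The structure container: a tibble of atoms (one row per atom) with chain,
# residue, base, chemistry and Cartesian coordinates in Angstroms. Chain ids
# follow the builder convention: W = strand carrying the polypurine tract,
# C = its Watson-Crick complement, T = the Hoogsteen third strand.

new_dna_structure <- function(atoms, site = NULL) {
  stopifnot(all(c("chain", "residue", "base", "chemistry", "protonated",
                  "atom", "x", "y", "z") %in% names(atoms)))
  tibble::new_tibble(atoms, class = "dna_structure", site = site)
}

#' Test for the structure class
#' @param x An object.
#' @return `TRUE` for a `dna_structure`.
#' @export
is_dna_structure <- function(x) inherits(x, "dna_structure")

#' @exportS3Method pillar::tbl_sum
tbl_sum.dna_structure <- function(x, ...) {
  ch <- split(x$residue, x$chain)
  desc <- paste(vapply(names(ch), function(k) {
    sprintf("%s: %d res", k, length(unique(ch[[k]])))
  }, character(1)), collapse = ", ")
  c("DNA structure" = sprintf("%d atoms (%s)", nrow(x), desc))
}

structure_site <- function(structure) attr(structure, "site", exact = TRUE)

#' Chains of a structure
#' @param structure A `dna_structure`.
#' @return Character vector of chain ids, in order of appearance.
#' @export
structure_chains <- function(structure) unique(structure$chain)

# residues of one chain, in order
chain_residues <- function(structure, chain) {
  sort(unique(structure$residue[structure$chain == chain]))
}

# base sequence of a chain, 5' to 3'
chain_sequence <- function(structure, chain) {
  sub <- structure[structure$chain == chain, ]
  sub <- sub[!duplicated(sub$residue), ]
  sub <- sub[order(sub$residue), ]
  paste0(sub$base, collapse = "")
}

# named coordinate matrix for selected atoms of one residue; errors when an
# atom is missing.
residue_atoms <- function(structure, chain, residue, atom_names) {
  sel <- structure$chain == chain & structure$residue == residue
  if (!any(sel)) {
    abort(sprintf("no residue %s/%s", chain, residue), class = "lnahelix_lookup_error")
  }
  sub <- structure[sel, ]
  i <- match(atom_names, sub$atom)
  if (anyNA(i)) {
    abort(sprintf("residue %s/%s is missing atom %s", chain, residue,
                  atom_names[which(is.na(i))[1]]),
          class = "lnahelix_missing_atom_error")
  }
  m <- as.matrix(sub[i, c("x", "y", "z")])
  rownames(m) <- atom_names
  m
}

coords_matrix <- function(structure) as.matrix(structure[, c("x", "y", "z")])

set_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' Apply a rigid motion to a structure
#'
#' Rotates and translates all atoms. Every analysis in this package is
#' invariant under such motions.
#'
#' @param structure A `dna_structure`.
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  set_coords(structure, apply_rigid(coords_matrix(structure), list(R = R, t = t)))
}

# ---- trajectory -------------------------------------------------------------

#' Construct a trajectory
#'
#' A trajectory is an ordered series of conformations (frames) of one
#' topology, with a fixed inter-frame interval in picoseconds.
#'
#' @param topology A `dna_structure` providing atom identities (its
#'   coordinates are frame 1 unless `coords` says otherwise).
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param frame_interval Time between frames, ps.
#' @return A `dna_trajectory`.
#' @export
dna_trajectory <- function(topology, coords, frame_interval = 40) {
  stopifnot(is_dna_structure(topology),
            length(dim(coords)) == 3,
            dim(coords)[1] == nrow(topology),
            dim(coords)[2] == 3,
            frame_interval > 0)
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "dna_trajectory")
}

#' @export
print.dna_trajectory <- function(x, ...) {
  cat(sprintf("<dna_trajectory> %d frames x %d atoms, %g ps/frame\n",
              n_frames(x), nrow(x$topology), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `dna_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) {
  stopifnot(inherits(trajectory, "dna_trajectory"))
  dim(trajectory$coords)[3]
}

#' Extract one frame of a trajectory as a structure
#' @param trajectory A `dna_trajectory`.
#' @param frame Frame index (1-based).
#' @return A `dna_structure`.
#' @export
trajectory_frame <- function(trajectory, frame) {
  stopifnot(inherits(trajectory, "dna_trajectory"),
            frame >= 1, frame <= n_frames(trajectory))
  set_coords(trajectory$topology, trajectory$coords[, , frame])
}

# promote a single structure to a 1-frame trajectory
as_trajectory <- function(x, frame_interval = 40) {
  if (inherits(x, "dna_trajectory")) return(x)
  stopifnot(is_dna_structure(x))
  dna_trajectory(x, array(coords_matrix(x), c(nrow(x), 3, 1)), frame_interval)
}

#' @method as_tibble dna_trajectory
#' @export
as_tibble.dna_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  base <- x$topology[, c("chain", "residue", "base", "chemistry", "atom")]
  purrr::map_dfr(seq_len(nf), function(f) {
    out <- base
    out$frame <- f
    out$time_ps <- (f - 1) * x$frame_interval
    out$x <- x$coords[, 1, f]
    out$y <- x$coords[, 2, f]
    out$z <- x$coords[, 3, f]
    out
  })
}
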