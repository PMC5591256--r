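# PDB v3.3 input/output. Single-model files hold a structure; multi-model
# files (MODEL/ENDMDL) hold a trajectory. Chemistry is encoded in the
# residue name: DA/DC/DG/DT for DNA, LA/LC/LG/LT for LNA. Protonation of
# third-strand cytosines is a chemical flag, not an atom, and is restored on
# read for chain T.

resname_for <- function(base, chemistry) {
  paste0(ifelse(chemistry == "LNA", "L", "D"), base)
}

base_from_resname <- function(resname) {
  b <- substr(resname, 2, 2)
  chem <- ifelse(substr(resname, 1, 1) == "L", "LNA", "DNA")
  list(base = b, chemistry = chem)
}

element_of <- function(atom) substr(gsub("[^A-Z]", "", toupper(atom)), 1, 1)

format_atom_lines <- function(structure) {
  n <- nrow(structure)
  serial <- seq_len(n)
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, structure$atom,
          resname_for(structure$base, structure$chemistry),
          structure$chain, structure$residue,
          structure$x, structure$y, structure$z, 1, 0,
          element_of(structure$atom))
}

#' Write a structure or trajectory to a PDB file
#'
#' Structures are written as a single model; trajectories as MODEL/ENDMDL
#' blocks, one per frame. A REMARK line records the frame interval so that
#' [read_pdb()] round-trips it.
#'
#' @param x A `dna_structure` or `dna_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (is_dna_structure(x)) {
    writeLines(format_atom_lines(x), con)
    writeLines("END", con)
  } else if (inherits(x, "dna_trajectory")) {
    writeLines(sprintf("REMARK 250 FRAME INTERVAL %g PS", x$frame_interval), con)
    for (f in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL %8d", f), con)
      writeLines(format_atom_lines(trajectory_frame(x, f)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    abort("x must be a dna_structure or dna_trajectory")
  }
  invisible(path)
}

parse_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    abort(sprintf("malformed ATOM record at line %d (too short)", lineno),
          class = "lnahelix_pdb_error")
  }
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38), substr(line, 39, 46),
                                       substr(line, 47, 54))))
  resseq <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (anyNA(xyz) || is.na(resseq)) {
    abort(sprintf("malformed ATOM record at line %d (unparseable fields)", lineno),
          class = "lnahelix_pdb_error")
  }
  list(
    atom = trimws(substr(line, 13, 16)),
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    residue = resseq,
    x = xyz[1], y = xyz[2], z = xyz[3]
  )
}

#' Read a structure or trajectory from a PDB file
#'
#' Single-model files yield a `dna_structure`; files with MODEL/ENDMDL
#' blocks yield a `dna_trajectory`. Truncated files (an unclosed MODEL or a
#' missing END) and malformed ATOM records raise errors rather than reading
#' partially.
#'
#' @param path PDB path.
#' @param frame_interval Frame interval in ps used when the file does not
#'   record one.
#' @return A `dna_structure` or `dna_trajectory`.
#' @export
read_pdb <- function(path, frame_interval = 40) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file", path), class = "lnahelix_pdb_error")
  }
  lines <- readLines(path)
  if (!length(lines)) abort("empty PDB file", class = "lnahelix_pdb_error")
  rec <- substr(lines, 1, 6)
  fi <- frame_interval
  rem <- grep("^REMARK 250 FRAME INTERVAL", lines, value = TRUE)
  if (length(rem)) {
    fi <- as.numeric(sub("^REMARK 250 FRAME INTERVAL +([0-9.eE+-]+) PS.*$", "\\1", rem[1]))
  }
  has_models <- any(rec == "MODEL ")
  if (!any(trimws(lines) == "END")) {
    abort("truncated PDB: no END record", class = "lnahelix_pdb_error")
  }
  atom_tbl <- function(idx) {
    parsed <- lapply(idx, function(i) parse_atom_line(lines[i], i))
    bc <- base_from_resname(vapply(parsed, `[[`, character(1), "resname"))
    chain <- vapply(parsed, `[[`, character(1), "chain")
    base <- bc$base
    tibble(
      chain = chain,
      residue = vapply(parsed, `[[`, integer(1), "residue"),
      base = base,
      chemistry = bc$chemistry,
      protonated = chain == "T" & base == "C",
      atom = vapply(parsed, `[[`, character(1), "atom"),
      x = vapply(parsed, `[[`, numeric(1), "x"),
      y = vapply(parsed, `[[`, numeric(1), "y"),
      z = vapply(parsed, `[[`, numeric(1), "z")
    )
  }
  if (!has_models) {
    idx <- which(rec == "ATOM  ")
    if (!length(idx)) abort("no ATOM records", class = "lnahelix_pdb_error")
    return(new_dna_structure(atom_tbl(idx)))
  }
  starts <- which(rec == "MODEL ")
  ends <- which(rec == "ENDMDL")
  if (length(ends) < length(starts)) {
    abort(sprintf("truncated PDB: MODEL at line %d has no ENDMDL", starts[length(starts)]),
          class = "lnahelix_pdb_error")
  }
  frames <- vector("list", length(starts))
  for (f in seq_along(starts)) {
    span <- (starts[f] + 1):(ends[f] - 1)
    frames[[f]] <- atom_tbl(span[rec[span] == "ATOM  "])
  }
  n_atoms <- vapply(frames, nrow, integer(1))
  if (length(unique(n_atoms)) != 1) {
    abort("inconsistent atom counts across MODEL blocks", class = "lnahelix_pdb_error")
  }
  topo <- new_dna_structure(frames[[1]])
  coords <- array(NA_real_, c(n_atoms[1], 3, length(frames)))
  for (f in seq_along(frames)) {
    coords[, , f] <- as.matrix(frames[[f]][, c("x", "y", "z")])
  }
  dna_trajectory(topo, coords, frame_interval = fi)
}
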