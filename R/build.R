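# Fiber-model builder: idealized duplexes and parallel pyrimidine-motif
# triplexes generated from fixed per-step helical parameters, with
# per-residue sugar pucker control.

#' Helical parameter specification for fiber building
#'
#' Canonical fiber values: B-DNA twist 36.0 deg, rise 3.38 A, zero
#' x-displacement, C2'-endo sugars (P = 162, tau_m = 38); A-DNA twist
#' 32.7 deg, rise 2.81 A, x-displacement -4.4 A, C3'-endo sugars (P = 18,
#' tau_m = 40). LNA residues are always built north (P = 17, tau_m = 48)
#' regardless of form. The default inclination is zero for both forms, so
#' the builder's twist is recovered exactly by the step analysis; the
#' A-form default therefore corresponds to an axially displaced,
#' low-inclination A-like fiber.
#'
#' @param form `"B"` or `"A"`; sets defaults for the remaining parameters.
#' @param twist Helical twist per step, degrees (0 < twist < 60).
#' @param rise Rise per step, Angstroms (> 0).
#' @param x_disp Displacement of the base-pair origin from the helix axis
#'   along the pair x axis, Angstroms (negative = A-like).
#' @param inclination Tilt of the base-pair long axis relative to the plane
#'   normal to the helix axis, degrees.
#' @param pucker_P,pucker_tau Sugar pucker applied to DNA residues.
#' @param chi Glycosidic torsion applied to all residues, degrees.
#' @return A `helix_spec` list.
#' @export
helix_spec <- function(form = c("B", "A"), twist = NULL, rise = NULL,
                       x_disp = NULL, inclination = 0,
                       pucker_P = NULL, pucker_tau = NULL, chi = NULL) {
  form <- match.arg(form)
  def <- if (form == "B") {
    list(twist = 36.0, rise = 3.38, x_disp = 0.0, pucker_P = 162, pucker_tau = 38, chi = 262)
  } else {
    list(twist = 32.7, rise = 2.81, x_disp = -4.4, pucker_P = 18, pucker_tau = 40, chi = 200)
  }
  spec <- list(
    form = form,
    twist = twist %||% def$twist,
    rise = rise %||% def$rise,
    x_disp = x_disp %||% def$x_disp,
    inclination = inclination,
    pucker_P = pucker_P %||% def$pucker_P,
    pucker_tau = pucker_tau %||% def$pucker_tau,
    chi = chi %||% def$chi
  )
  if (spec$twist <= 0 || spec$twist >= 60) abort("twist must be in (0, 60) degrees")
  if (spec$rise <= 0) abort("rise must be positive")
  class(spec) <- "helix_spec"
  spec
}

LNA_PUCKER <- c(P = 17, tau_m = 48)

# Local coordinates (standard base frame) of one residue: base template plus
# sugar ring at the requested pucker/chi plus the phosphate. Cached, since a
# build uses only a handful of distinct combinations.
residue_local_coords <- local({
  cache <- new.env(parent = emptyenv())
  function(base, chi, P, tau) {
    key <- sprintf("%s|%.6f|%.6f|%.6f", base, chi, P, tau)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tmpl <- base_template(base)
    ring <- solve_rings(P, tau)[1, , ]
    placed <- place_ring(ring, tmpl["C1'", ], tmpl[glycosidic_n(base), ],
                         tmpl[chi_c_atom(base), ], chi)
    sugar <- placed[c("O4'", "C2'", "C3'", "C4'"), ]
    out <- rbind(tmpl, sugar, P = PHOSPHATE_LOCAL)
    cache[[key]] <- out
    out
  }
})

# pair frame k (0-based step index) of a fiber
fiber_frame <- function(k, spec) {
  Rk <- rot_z(k * spec$twist * pi / 180)
  if (spec$inclination != 0) Rk <- Rk %*% rot_x(spec$inclination * pi / 180)
  o <- as.vector(rot_z(k * spec$twist * pi / 180) %*% c(spec$x_disp, 0, 0)) +
    c(0, 0, k * spec$rise)
  list(R = Rk, o = o)
}

residue_rows <- function(local, chain, residue, base, chemistry, protonated, R, o) {
  xyz <- t(R %*% t(local)) + matrix(o, nrow(local), 3, byrow = TRUE)
  tibble(
    chain = chain, residue = as.integer(residue), base = base,
    chemistry = chemistry, protonated = protonated,
    atom = rownames(local), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

pucker_for <- function(chemistry, spec) {
  if (chemistry == "LNA") c(LNA_PUCKER[["P"]], LNA_PUCKER[["tau_m"]])
  else c(spec$pucker_P, spec$pucker_tau)
}

#' Build an idealized duplex fiber model
#'
#' Generates a two-chain fiber in which successive base-pair frames are
#' related by exactly `spec$twist` about and `spec$rise` along the global
#' helix axis. LNA residues are built with the locked north pucker; DNA
#' residues take the form's canonical pucker. Chain `W` is the purine-tract
#' strand, chain `C` the complementary strand; residues are numbered 1-based
#' from each chain's 5' end.
#'
#' @param duplex A `duplex_target` (or a notation string for an all-DNA
#'   homo-duplex).
#' @param spec A [helix_spec()].
#' @return A `dna_structure`.
#' @examples
#' s <- build_duplex(get_target("c-MYC_DS19"), helix_spec("B"))
#' @export
build_duplex <- function(duplex, spec = helix_spec("B")) {
  if (is.character(duplex)) duplex <- duplex_target(duplex)
  stopifnot(inherits(duplex, "duplex_target"), inherits(spec, "helix_spec"))
  pur <- duplex$purine[!is.na(duplex$purine$base), ]
  pyr <- duplex$pyrimidine[!is.na(duplex$pyrimidine$base), ]
  n <- nrow(pur)
  rows <- vector("list", 2 * n)
  for (k in seq_len(n)) {
    fr <- fiber_frame(k - 1, spec)
    # strand W residue k pairs strand C residue n + 1 - k
    bW <- pur$base[k]; chemW <- pur$chemistry[k]
    pkW <- pucker_for(chemW, spec)
    rows[[k]] <- residue_rows(
      residue_local_coords(bW, spec$chi, pkW[1], pkW[2]),
      "W", k, bW, chemW, FALSE, fr$R, fr$o
    )
    jC <- n + 1 - k
    bC <- pyr$base[jC]; chemC <- pyr$chemistry[jC]
    pkC <- pucker_for(chemC, spec)
    rows[[n + k]] <- residue_rows(
      residue_local_coords(bC, spec$chi, pkC[1], pkC[2]),
      "C", jC, bC, chemC, FALSE, fr$R %*% PAIR_FLIP, fr$o
    )
  }
  atoms <- bind_rows(rows)
  atoms <- atoms[order(match(atoms$chain, c("W", "C")), atoms$residue), ]
  new_dna_structure(atoms, site = duplex$site)
}

#' Build an idealized parallel triplex fiber model
#'
#' Places the TFO in the major groove, parallel to the purine strand (TFO
#' residue 1 pairs the 5'-most purine of the binding site), using idealized
#' T.A and C+.G Hoogsteen triad templates with an N7-N3 distance of 2.9 A.
#' TFO cytosines are flagged protonated. TINA monomers carry no atoms and
#' are skipped.
#'
#' @param duplex A `duplex_target`.
#' @param tfo An `oligo` or notation string (pyrimidine-motif TFO).
#' @param spec A [helix_spec()].
#' @return A `dna_structure` with chains `W`, `C` and `T`.
#' @export
build_triplex <- function(duplex, tfo, spec = helix_spec("B")) {
  if (is.character(duplex)) duplex <- duplex_target(duplex)
  tf <- if (inherits(tfo, "oligo")) tfo else parse_mixmer(tfo)
  site <- find_tfo_binding_site(duplex, tf)
  if (is.null(site)) {
    abort("no TFO binding site on this duplex", class = "lnahelix_build_error")
  }
  m <- nt_length(tf)
  if (m > nt_length(duplex$purine) - site[1] + 1) {
    abort("TFO is longer than the available binding site", class = "lnahelix_build_error")
  }
  base <- build_duplex(duplex, spec)
  tf_nt <- tf[!is.na(tf$base), ]
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    k <- site[1] + j - 1          # purine-strand residue index
    fr <- fiber_frame(k - 1, spec)
    b <- tf_nt$base[j]; chem <- tf_nt$chemistry[j]
    pk <- pucker_for(chem, spec)
    local <- residue_local_coords(b, spec$chi, pk[1], pk[2])
    pl <- HG_PLACEMENT[[b]]
    if (is.null(pl)) {
      abort(sprintf("TFO base '%s' has no Hoogsteen triad template", b),
            class = "lnahelix_build_error")
    }
    local_hg <- t(rot_z(pl$theta) %*% t(local)) + matrix(pl$t, nrow(local), 3, byrow = TRUE)
    rows[[j]] <- residue_rows(local_hg, "T", j, b, chem,
                              protonated = (b == "C"), fr$R, fr$o)
  }
  out <- bind_rows(list(base, bind_rows(rows)))
  new_dna_structure(out, site = site)
}

#' Build a single-strand fiber model
#'
#' Lays one oligonucleotide along an idealized helical path (useful as a
#' starting conformation for single-strand trajectory emulation). The chain
#' id is `W`.
#'
#' @param oligo An `oligo` or notation string.
#' @param spec A [helix_spec()].
#' @return A `dna_structure` with a single chain.
#' @export
build_single_strand <- function(oligo, spec = helix_spec("B")) {
  o <- if (inherits(oligo, "oligo")) oligo else parse_mixmer(oligo)
  nt <- o[!is.na(o$base), ]
  rows <- vector("list", nrow(nt))
  for (k in seq_len(nrow(nt))) {
    fr <- fiber_frame(k - 1, spec)
    chem <- nt$chemistry[k]
    pk <- pucker_for(chem, spec)
    rows[[k]] <- residue_rows(
      residue_local_coords(nt$base[k], spec$chi, pk[1], pk[2]),
      "W", k, nt$base[k], chem, FALSE, fr$R, fr$o
    )
  }
  new_dna_structure(bind_rows(rows))
}
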