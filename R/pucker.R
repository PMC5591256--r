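# Furanose ring pseudorotation: measurement (Altona-Sundaralingam phase and
# amplitude from the five endocyclic torsions) and construction (rebuilding
# a ring so the measured phase/amplitude hit a requested target exactly).

RING_ATOMS <- c("O4'", "C1'", "C2'", "C3'", "C4'")

# bond lengths used by the ring constructor (Angstroms)
RING_BONDS <- c(`O4'-C1'` = 1.414, `C1'-C2'` = 1.526, `C2'-C3'` = 1.525,
                `C3'-C4'` = 1.526, `C4'-O4'` = 1.446)

# angles used when chaining atoms (degrees)
RING_ANGLES <- c(`O4'-C1'-C2'` = 106.6, `C1'-C2'-C3'` = 101.5, `C2'-C3'-C4'` = 102.6)

SIN36_72 <- sin(36 * pi / 180) + sin(72 * pi / 180)

# Altona-Sundaralingam phase/amplitude from five torsions (degrees).
# Vectorized: nu* may be vectors. tan P = ((nu4+nu1)-(nu3+nu0)) /
# (2 nu2 (sin36 + sin72)); nu2 < 0 shifts P by 180 (handled by atan2);
# tau_m = nu2 / cos P, switched to the sine form near cos P = 0 where the
# cosine form is ill-conditioned. P is mapped into (-90, 270].
pseudorotation_from_torsions <- function(nu0, nu1, nu2, nu3, nu4) {
  amp_proxy <- pmax(abs(nu0), abs(nu1), abs(nu2), abs(nu3), abs(nu4))
  if (any(amp_proxy < 1e-6)) {
    abort("undefined pucker: ring is planar", class = "lnahelix_pucker_error")
  }
  num <- (nu4 + nu1) - (nu3 + nu0)
  den <- 2 * nu2 * SIN36_72
  P <- atan2(num, den) * 180 / pi
  P <- ifelse(P <= -90, P + 360, P)
  Pr <- P * pi / 180
  tau <- ifelse(abs(cos(Pr)) >= abs(sin(Pr)),
                nu2 / cos(Pr),
                num / (2 * SIN36_72 * sin(Pr)))
  list(P = P, tau_m = tau)
}

# lean torsion kernel (no degeneracy checks) for the ring solver hot path
dihedral_fast <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

# measure the five ring torsions for rings given as an n x 5 x 3 array
# (atom order O4', C1', C2', C3', C4')
ring_torsions <- function(rings) {
  if (length(dim(rings)) == 2) rings <- array(rings, c(1, dim(rings)))
  g <- function(i) as_row3(rings[, i, , drop = FALSE][, 1, ])
  O4 <- g(1); C1 <- g(2); C2 <- g(3); C3 <- g(4); C4 <- g(5)
  list(
    nu0 = dihedral_fast(C4, O4, C1, C2),
    nu1 = dihedral_fast(O4, C1, C2, C3),
    nu2 = dihedral_fast(C1, C2, C3, C4),
    nu3 = dihedral_fast(C2, C3, C4, O4),
    nu4 = dihedral_fast(C3, C4, O4, C1)
  )
}

# Build rings by chaining atoms with torsion targets nu_j = tau cos(P +
# 144 (j - 2)) for nu1 and nu2; the remaining torsions follow from closure.
# Vectorized over length-n P/tau. Returns n x 5 x 3 array.
chain_rings <- function(P, tau) {
  n <- length(P)
  nu <- function(j) tau * cos((P + 144 * (j - 2)) * pi / 180)
  O4 <- matrix(0, n, 3)
  C1 <- matrix(rep(c(RING_BONDS[["O4'-C1'"]], 0, 0), each = n), n, 3)
  th <- RING_ANGLES[["O4'-C1'-C2'"]] * pi / 180
  C2 <- C1 + RING_BONDS[["C1'-C2'"]] * matrix(rep(c(-cos(th), sin(th), 0), each = n), n, 3)
  C3 <- place_atoms(O4, C1, C2, RING_BONDS[["C2'-C3'"]], RING_ANGLES[["C1'-C2'-C3'"]], nu(1))
  C4 <- place_atoms(C1, C2, C3, RING_BONDS[["C3'-C4'"]], RING_ANGLES[["C2'-C3'-C4'"]], nu(2))
  out <- array(NA_real_, c(n, 5, 3), dimnames = list(NULL, RING_ATOMS, c("x", "y", "z")))
  out[, 1, ] <- O4; out[, 2, ] <- C1; out[, 3, ] <- C2; out[, 4, ] <- C3; out[, 5, ] <- C4
  out
}

measure_rings <- function(rings) {
  nu <- ring_torsions(rings)
  pseudorotation_from_torsions(nu$nu0, nu$nu1, nu$nu2, nu$nu3, nu$nu4)
}

# Solve for rings whose measured (P, tau_m) equal the targets, by fixed-point
# iteration on the chain parameters. Converges to ~1e-10 degrees in a few
# dozen iterations over the whole pseudorotation cycle.
solve_rings <- function(P, tau, tol = 1e-9, maxit = 120) {
  stopifnot(length(P) == length(tau))
  p <- P; t_ <- tau
  rings <- chain_rings(p, t_)
  for (i in seq_len(maxit)) {
    m <- measure_rings(rings)
    dP <- ((P - m$P + 180) %% 360) - 180
    dT <- tau - m$tau_m
    if (max(abs(dP)) < tol && max(abs(dT)) < tol) return(rings)
    p <- p + dP
    t_ <- t_ + dT
    rings <- chain_rings(p, t_)
  }
  warn(sprintf("ring pucker solve did not reach %.1e (residual %.2e deg)",
               tol, max(abs(dP), abs(dT))))
  rings
}

# direction of the glycosidic bond (C1' -> N) in ring-local coordinates:
# intersection of the cones at fixed O4'-C1'-N and C2'-C1'-N angles.
# `branch` picks the ring face carrying the base (chirality).
glyco_direction <- function(ring, ang_o4 = 108.2, ang_c2 = 113.7, branch = 1) {
  c1 <- ring["C1'", ]
  v1 <- ring["O4'", ] - c1; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- ring["C2'", ] - c1; v2 <- v2 / sqrt(sum(v2^2))
  c12 <- sum(v1 * v2)
  b1 <- cos(ang_o4 * pi / 180); b2 <- cos(ang_c2 * pi / 180)
  # u = a v1 + b v2 + g w with w = unit(v1 x v2)
  M <- matrix(c(1, c12, c12, 1), 2, 2)
  ab <- solve(M, c(b1, b2))
  q <- ab[1] * v1 + ab[2] * v2
  g2 <- 1 - (ab[1]^2 + ab[2]^2 + 2 * ab[1] * ab[2] * c12)
  if (g2 < 0) g2 <- 0
  w <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3], v1[1] * v2[2] - v1[2] * v2[1])
  w <- w / sqrt(sum(w^2))
  q + branch * sqrt(g2) * w
}

SUGAR_BRANCH <- -1  # ring face carrying the base; fixed by the D-chirality tests

# Place a solved ring onto a residue: C1' at `c1_target`, glycosidic bond
# toward `n_target`, then spun about the glycosidic axis so the torsion
# O4'-C1'-N-Cx equals `chi` (degrees, [0, 360)). Returns the placed ring
# (named 5 x 3 matrix).
place_ring <- function(ring, c1_target, n_target, cx_target, chi) {
  ring <- ring - matrix(ring["C1'", ], 5, 3, byrow = TRUE)
  u_local <- glyco_direction(ring, branch = SUGAR_BRANCH)
  u_target <- n_target - c1_target
  u_target <- u_target / sqrt(sum(u_target^2))
  R1 <- rotation_between(u_local, u_target)
  ring <- t(R1 %*% t(ring))
  placed <- ring + matrix(c1_target, 5, 3, byrow = TRUE)
  chi_cur <- dihedral(placed["O4'", ], c1_target, n_target, cx_target, range = "positive")
  delta <- (chi - chi_cur) * pi / 180
  # rotating the sugar about the C1'->N axis advances the torsion by +delta
  R2 <- rotation_about(u_target, delta)
  ring <- t(R2 %*% t(ring))
  placed <- ring + matrix(c1_target, 5, 3, byrow = TRUE)
  rownames(placed) <- RING_ATOMS
  placed
}

#' Sugar pseudorotation phase and amplitude of a residue
#'
#' Computes the five endocyclic furanose torsions and derives the
#' pseudorotation phase angle P and puckering amplitude tau_m via the
#' Altona-Sundaralingam relation. P is reported in (-90, 270] so that the
#' north ((-90, 90]) and south ((90, 270]) classes form a partition.
#'
#' @param structure A `dna_structure`.
#' @param chain Chain id.
#' @param residue Residue index within the chain.
#' @return A list with elements `P` and `tau_m` (degrees).
#' @export
pseudorotation <- function(structure, chain, residue) {
  xyz <- residue_atoms(structure, chain, residue, RING_ATOMS)
  ring <- array(xyz, c(1, 5, 3))
  dimnames(ring)[[2]] <- RING_ATOMS
  m <- measure_rings(ring)
  list(P = m$P, tau_m = m$tau_m)
}

#' Rebuild a residue's sugar ring at a target pucker
#'
#' Replaces the five ring atoms so that [pseudorotation()] on the result
#' returns `(P, tau_m)` to better than 1e-4 degrees. The base is kept fixed
#' (so the glycosidic torsion is preserved exactly) and remaining exocyclic
#' atoms (the phosphate) follow the sugar rigidly. LNA residues are
#' conformationally locked in the north range and reject south targets.
#'
#' @param structure A `dna_structure`.
#' @param chain Chain id.
#' @param residue Residue index.
#' @param P Target pseudorotation phase, degrees in (-90, 270].
#' @param tau_m Target puckering amplitude, degrees (> 0).
#' @return The modified `dna_structure`.
#' @export
set_sugar_pucker <- function(structure, chain, residue, P, tau_m) {
  stopifnot(is_dna_structure(structure))
  idx <- which(structure$chain == chain & structure$residue == residue)
  if (!length(idx)) {
    abort(sprintf("no residue %s/%d", chain, residue), class = "lnahelix_lookup_error")
  }
  base <- structure$base[idx[1]]
  if (is.na(base)) {
    abort(sprintf("residue %s/%d is not a nucleotide", chain, residue),
          class = "lnahelix_value_error")
  }
  chem <- structure$chemistry[idx[1]]
  if (identical(chem, "LNA") && P > 90 && P <= 270) {
    abort(sprintf("locked nucleotide: LNA residue %s/%d cannot take a south pucker (P = %g)",
                  chain, residue, P),
          class = "lnahelix_locked_error")
  }
  xyz_res <- residue_atoms(structure, chain, residue,
                           c("C1'", "O4'", "C2'", glycosidic_n(base), chi_c_atom(base)))
  chi <- dihedral(xyz_res["O4'", ], xyz_res["C1'", ], xyz_res[glycosidic_n(base), ],
                  xyz_res[chi_c_atom(base), ], range = "positive")
  old_frame <- sugar_frame(xyz_res["C1'", ], xyz_res["O4'", ], xyz_res["C2'", ])

  ring <- solve_rings(P, tau_m)[1, , ]
  placed <- place_ring(ring, xyz_res["C1'", ], xyz_res[glycosidic_n(base), ],
                       xyz_res[chi_c_atom(base), ], chi)
  new_frame <- sugar_frame(placed["C1'", ], placed["O4'", ], placed["C2'", ])

  atoms <- structure$atom[idx]
  coords <- as.matrix(structure[idx, c("x", "y", "z")])
  base_atoms <- rownames(base_template(base))
  for (a in RING_ATOMS) {
    j <- which(atoms == a)
    if (length(j)) coords[j, ] <- placed[a, ]
  }
  exo <- which(!atoms %in% c(RING_ATOMS, base_atoms))
  if (length(exo)) {
    local <- t(old_frame$R) %*% (t(coords[exo, , drop = FALSE]) - old_frame$o)
    coords[exo, ] <- t(new_frame$R %*% local + new_frame$o)
  }
  structure$x[idx] <- coords[, 1]
  structure$y[idx] <- coords[, 2]
  structure$z[idx] <- coords[, 3]
  structure
}

# orthonormal frame anchored on the sugar (origin C1')
sugar_frame <- function(c1, o4, c2) {
  e1 <- o4 - c1; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c2 - c1; e2 <- e2 - sum(e2 * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3], e1[1] * e2[2] - e1[2] * e2[1])
  list(R = cbind(e1, e2, e3), o = matrix(c1, 3, 1))
}

# Signed chirality of a sugar: ring-plane normal (Newell, atom order C1',
# C2', C3', C4', O4') dotted with the glycosidic direction. Positive for the
# D-configured sugars this package builds.
sugar_chirality <- function(structure, chain, residue) {
  base <- structure$base[structure$chain == chain & structure$residue == residue][1]
  xyz <- residue_atoms(structure, chain, residue, c(RING_ATOMS, glycosidic_n(base)))
  ring <- xyz[c("C1'", "C2'", "C3'", "C4'", "O4'"), ]
  n <- c(0, 0, 0)
  for (i in 1:5) {
    a <- ring[i, ]; b <- ring[if (i == 5) 1 else i + 1, ]
    n <- n + c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  }
  u <- xyz[glycosidic_n(base), ] - xyz["C1'", ]
  sum(n * u) / sqrt(sum(n^2)) / sqrt(sum(u^2))
}
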