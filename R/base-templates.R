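# Idealized planar base geometries expressed in the standard base reference
# frame (origin near the pair center, x toward the major groove, y along the
# long base-pair axis toward the reference strand C1', z normal). A
# Watson-Crick pair is assembled by taking the reference-strand base as-is
# and the complementary base flipped 180 degrees about x (y -> -y, z -> -z),
# after which the two base frames coincide with the pair frame.

base_template_xy <- function(base) {
  switch(base,
    A = rbind(
      `C1'` = c(-2.479, 5.346), N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897),
      N7 = c(0.877, 3.902), C5 = c(0.071, 2.771), C6 = c(0.369, 1.398),
      N6 = c(1.611, 0.909), N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023),
      N3 = c(-2.320, 2.290), C4 = c(-1.267, 3.124)),
    G = rbind(
      `C1'` = c(-2.477, 5.399), N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962),
      N7 = c(0.870, 3.969), C5 = c(0.071, 2.833), C6 = c(0.424, 1.460),
      O6 = c(1.554, 0.955), N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087),
      N2 = c(-2.949, 0.139), N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177)),
    C = rbind(
      `C1'` = c(-2.477, 5.402), N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158),
      O2 = c(-2.628, 2.709), N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868),
      N4 = c(1.875, 2.027), C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068)),
    T = rbind(
      `C1'` = c(-2.481, 5.354), N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.135),
      O2 = c(-2.562, 2.608), N3 = c(-0.298, 2.407), C4 = c(0.994, 2.897),
      O4 = c(1.944, 2.119), C5 = c(1.106, 4.338), C7 = c(2.466, 4.961),
      C6 = c(-0.024, 5.057)),
    abort(sprintf("no base template for '%s'", base))
  )
}

# 3D coordinates (z = 0 plane) of a base in the standard frame.
base_template <- function(base) {
  xy <- base_template_xy(base)
  cbind(xy, 0)
}

is_purine <- function(base) base %in% c("A", "G")

# ring atoms used for frame fitting
base_ring_atoms <- function(base) {
  if (is_purine(base)) c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

glycosidic_n <- function(base) if (is_purine(base)) "N9" else "N1"
chi_c_atom <- function(base) if (is_purine(base)) "C4" else "C2"

# Flip applied to the complementary (strand II) base so that its standard
# frame maps onto the pair frame: a proper rotation (det +1), so sugar
# chirality is preserved.
PAIR_FLIP <- diag(c(1, -1, -1))

# In-plane placement (rotation angle in radians, translation in Angstroms)
# of the Hoogsteen third-strand pyrimidine relative to the pair frame of the
# purine it reads. Fitted so the N7(purine)-N3(TFO) and second hydrogen bond
# (N6-O4 for T.A, O6-N4 for C+.G) are both 2.90 Angstroms with a near-linear
# donor geometry, and the TFO C1' points into the major groove.
HG_PLACEMENT <- list(
  `T` = list(theta = 3.280847, t = c(0.342867, 3.345895, 0)),
  `C` = list(theta = 3.299725, t = c(0.187277, 3.323089, 0))
)

# Coordinates of a Hoogsteen TFO base in the pair frame of its target pair.
hg_base_template <- function(tfo_base) {
  if (!tfo_base %in% c("T", "C")) {
    abort(sprintf("no Hoogsteen triad template for TFO base '%s'", tfo_base))
  }
  pl <- HG_PLACEMENT[[tfo_base]]
  xyz <- base_template(tfo_base)
  t(rot_z(pl$theta) %*% t(xyz)) + matrix(pl$t, nrow(xyz), 3, byrow = TRUE)
}

# Strand-I phosphate position in the standard base frame, calibrated so a
# canonical B fiber (twist 36, rise 3.38) reproduces textbook cross-strand
# P-P groove separations (11.7 minor / 17.2 major before the 5.8 correction).
PHOSPHATE_LOCAL <- c(-1.4328, 8.7940, -0.8105)

WC_PARTNER <- c(A = "T", T = "A", G = "C", C = "G")
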