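# Base-pair-step helical parameters (mid-frame CEHS convention) with a local
# helical-axis decomposition for x-displacement and inclination, groove
# widths from cross-strand phosphate separations, and the duplex
# conformation call (B / A / LirA / intermediate).

#' Reference frame of one base
#'
#' Least-squares (Kabsch) fit of the residue's base ring atoms to the
#' idealized planar base geometry yields the base's standard reference
#' frame: origin near the pair center, x toward the major groove, y along
#' the long pair axis, z normal.
#'
#' @param structure A `dna_structure`.
#' @param chain Chain id.
#' @param residue Residue index.
#' @param max_rmsd Fit tolerance in Angstroms; a worse fit means a deformed
#'   or misnamed base and raises an error.
#' @return A `base_frame`: list with `origin` (length 3) and `R` (3x3,
#'   columns are the x/y/z axes).
#' @export
base_reference_frame <- function(structure, chain, residue, max_rmsd = 0.5) {
  sel <- structure$chain == chain & structure$residue == residue
  if (!any(sel)) abort(sprintf("no residue %s/%s", chain, residue), class = "lnahelix_lookup_error")
  base <- structure$base[sel][1]
  ring <- base_ring_atoms(base)
  obs <- residue_atoms(structure, chain, residue, ring)
  tmpl <- base_template(base)[ring, ]
  fit <- kabsch_fit(tmpl, obs)
  if (fit$rmsd > max_rmsd) {
    abort(sprintf("base fit RMSD %.2f A exceeds %.2f for %s/%s (deformed or misnamed base)",
                  fit$rmsd, max_rmsd, chain, residue),
          class = "lnahelix_fit_error")
  }
  structure(list(origin = fit$t, R = fit$R,
                 rmsd = fit$rmsd),
            class = "base_frame")
}

# frame of a base pair: average of the strand-I frame and the flipped
# strand-II frame (rotation mean via the half rotation)
pair_frame <- function(f1, f2) {
  R2f <- f2$R %*% PAIR_FLIP
  Rm <- f1$R %*% rotation_half(t(f1$R) %*% R2f)
  list(origin = (f1$origin + f2$origin) / 2, R = Rm)
}

# mid frame between two pair frames
mid_frame <- function(p1, p2) {
  Rm <- p1$R %*% rotation_half(t(p1$R) %*% p2$R)
  list(origin = (p1$origin + p2$origin) / 2, R = Rm)
}

signed_angle_about <- function(a, b, axis) {
  atan2(sum(axis * c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                     a[1] * b[2] - a[2] * b[1])), sum(a * b)) * 180 / pi
}

# CEHS mid-frame step parameters plus local helical decomposition for one
# step between pair frames p1 (5') and p2 (3').
step_between <- function(p1, p2) {
  z1 <- p1$R[, 3]; z2 <- p2$R[, 3]
  cz <- sum(z1 * z2)
  gamma <- acos(pmin(1, pmax(-1, cz))) * 180 / pi
  if (gamma > 1e-9) {
    hinge <- c(z1[2] * z2[3] - z1[3] * z2[2], z1[3] * z2[1] - z1[1] * z2[3],
               z1[1] * z2[2] - z1[2] * z2[1])
    hinge <- hinge / sqrt(sum(hinge^2))
    Rh <- rotation_about(hinge, gamma / 2 * pi / 180)
    R1p <- Rh %*% p1$R
    R2p <- t(rotation_about(hinge, gamma / 2 * pi / 180)) %*% p2$R
  } else {
    hinge <- p1$R[, 2]
    R1p <- p1$R; R2p <- p2$R
  }
  zm <- R1p[, 3]
  twist <- signed_angle_about(R1p[, 1], R2p[, 1], zm)
  xm <- R1p[, 1] + R2p[, 1]; xm <- xm / sqrt(sum(xm^2))
  ym <- c(zm[2] * xm[3] - zm[3] * xm[2], zm[3] * xm[1] - zm[1] * xm[3],
          zm[1] * xm[2] - zm[2] * xm[1])
  phase <- signed_angle_about(hinge, ym, zm)
  roll <- gamma * cos(phase * pi / 180)
  tilt <- gamma * sin(phase * pi / 180)
  do <- p2$origin - p1$origin
  shift <- sum(do * xm); slide <- sum(do * ym); rise <- sum(do * zm)

  # local helical decomposition
  Rstep <- p2$R %*% t(p1$R)
  aa <- rotation_axis_angle(Rstep)
  h <- aa$axis
  if (sum(h * zm) < 0) h <- -h
  h_twist <- aa$angle * 180 / pi
  h_rise <- sum(do * h)
  if (aa$angle > 1e-6) {
    # screw axis: (I - Rstep) p = t_perp, solved in the plane normal to h
    t_full <- p2$origin - as.vector(Rstep %*% p1$origin)
    t_perp <- t_full - sum(t_full * h) * h
    A <- diag(3) - Rstep
    # basis of the plane normal to h
    e1 <- if (abs(h[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * h) * h; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(h[2] * e1[3] - h[3] * e1[2], h[3] * e1[1] - h[1] * e1[3], h[1] * e1[2] - h[2] * e1[1])
    B <- cbind(e1, e2)
    sol <- solve(t(B) %*% A %*% B, as.vector(t(B) %*% t_perp))
    p_axis <- as.vector(B %*% sol)
    xdisp_of <- function(pf) {
      v <- pf$origin - p_axis
      v_perp <- v - sum(v * h) * h
      xh <- pf$R[, 1] - sum(pf$R[, 1] * h) * h
      xh <- xh / sqrt(sum(xh^2))
      sum(v_perp * xh)
    }
    x_disp <- (xdisp_of(p1) + xdisp_of(p2)) / 2
  } else {
    x_disp <- NA_real_
  }
  inclination <- asin(pmin(1, pmax(-1, sum(ym * h)))) * 180 / pi
  tip <- asin(pmin(1, pmax(-1, sum(xm * h)))) * 180 / pi

  tibble(twist = twist, roll = roll, tilt = tilt,
         shift = shift, slide = slide, rise = rise,
         x_disp = x_disp, inclination = inclination, tip = tip,
         helical_twist = h_twist, helical_rise = h_rise)
}

#' Base-pair-step helical parameters
#'
#' Computes mid-frame (CEHS-style) step parameters -- twist, roll, tilt,
#' shift, slide, rise -- for every consecutive Watson-Crick base-pair step,
#' plus x-displacement and inclination from the local helical-axis
#' decomposition of each step. Terminal steps are flagged and excluded from
#' summaries by default, consistent with the end-exclusion rule used
#' elsewhere.
#'
#' @param structure A `dna_structure` with chains W and C.
#' @param exclude_terminal Flag terminal steps for exclusion (default TRUE).
#' @return A `step_params`: tibble with one row per step (columns `step`,
#'   `res5`, `res3`, the parameters above, `terminal`), carrying the
#'   summary-ready subset as attribute behaviour via [tidy()]/[glance()].
#' @export
step_parameters <- function(structure, exclude_terminal = TRUE) {
  stopifnot(is_dna_structure(structure))
  pairs <- pair_registry(structure)
  wc <- pairs[pairs$kind == "WC", ]
  # order along the W strand
  resW <- ifelse(wc$chain1 == "W", wc$res1, wc$res2)
  wc <- wc[order(resW), ]
  resW <- sort(resW)
  n <- nrow(wc)
  if (n < 2) abort("need at least 2 base pairs for step parameters", class = "lnahelix_value_error")
  frames <- vector("list", n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    fW <- try(base_reference_frame(structure, "W", resW[i]), silent = TRUE)
    fC <- try(base_reference_frame(structure, "C",
                                   wc$res2[i] * (wc$chain2[i] == "C") +
                                   wc$res1[i] * (wc$chain1[i] == "C")), silent = TRUE)
    if (inherits(fW, "try-error") || inherits(fC, "try-error")) {
      warn(sprintf("skipping unpaired/deformed position W/%d", resW[i]))
      ok[i] <- FALSE
      next
    }
    # strand I frame is the W-chain base; flip the C-chain base
    frames[[i]] <- pair_frame(fW, fC)
  }
  keep <- which(ok)
  steps <- vector("list", 0)
  for (j in seq_along(keep)[-1]) {
    i1 <- keep[j - 1]; i2 <- keep[j]
    if (i2 != i1 + 1) next
    row <- step_between(frames[[i1]], frames[[i2]])
    row$step <- i1
    row$res5 <- resW[i1]
    row$res3 <- resW[i2]
    steps[[length(steps) + 1]] <- row
  }
  out <- bind_rows(steps)
  out$terminal <- out$step == min(out$step) | out$step == max(out$step)
  out <- out[, c("step", "res5", "res3", "twist", "roll", "tilt",
                 "shift", "slide", "rise", "x_disp", "inclination", "tip",
                 "helical_twist", "helical_rise", "terminal")]
  attr(out, "exclude_terminal") <- exclude_terminal
  class(out) <- c("step_params", class(out))
  out
}

#' Summary means of step parameters over interior steps
#'
#' @param steps A `step_params` tibble.
#' @return One-row tibble of means (terminal steps excluded when flagged).
#' @export
step_means <- function(steps) {
  use <- if (isTRUE(attr(steps, "exclude_terminal"))) steps[!steps$terminal, ] else steps
  dplyr::summarise(use, dplyr::across(c("twist", "roll", "tilt", "shift", "slide",
                                        "rise", "x_disp", "inclination", "tip"),
                                      ~ mean(.x, na.rm = TRUE)),
                   n_steps = dplyr::n())
}

#' Groove widths from cross-strand phosphate separations
#'
#' For each interior phosphate level, the minor and major groove widths are
#' the minimum cross-strand P-P distances on either side of the level,
#' minus a 5.8 Angstrom correction for the phosphate radii. Levels without
#' a defined partner on one side are omitted.
#'
#' @param structure A `dna_structure` with chains W and C carrying P atoms.
#' @return Tibble with `level`, `minor`, `major` (Angstroms).
#' @export
groove_widths <- function(structure) {
  stopifnot(is_dna_structure(structure))
  getP <- function(chain) {
    sub <- structure[structure$chain == chain & structure$atom == "P", ]
    if (!nrow(sub)) {
      abort(sprintf("chain %s has no phosphate atoms", chain),
            class = "lnahelix_missing_atom_error")
    }
    sub <- sub[order(sub$residue), ]
    list(res = sub$residue, xyz = as.matrix(sub[, c("x", "y", "z")]))
  }
  W <- getP("W"); C <- getP("C")
  n <- max(W$res)
  out <- list()
  for (ii in seq_along(W$res)) {
    i <- W$res[ii]
    lev_C <- n + 1 - C$res          # level of each C phosphate
    delta <- lev_C - i
    d <- sqrt(colSums((t(C$xyz) - W$xyz[ii, ])^2))
    # the two grooves lie on opposite sides of the level (by registry shift)
    side_minus <- delta <= -2
    side_plus <- delta >= 2
    if (!any(side_minus) || !any(side_plus)) next
    d_minus <- min(d[side_minus]); d_plus <- min(d[side_plus])
    out[[length(out) + 1]] <- tibble(
      level = i,
      minor = min(d_minus, d_plus) - 5.8,
      major = max(d_minus, d_plus) - 5.8
    )
  }
  if (!length(out)) return(tibble(level = integer(), minor = numeric(), major = numeric()))
  bind_rows(out)
}

#' Default thresholds for the duplex conformation call
#'
#' B-form requires near-axis base pairs and full twist; the A-like family
#' requires strongly negative x-displacement and slide with reduced twist,
#' split into classical A (substantial inclination or roll) and LirA
#' ("low inclination and roll A-like": A-like displacement, slide and twist
#' with base pairs still nearly perpendicular to the axis).
#'
#' @return Named list of thresholds (Angstroms / degrees).
#' @export
helix_call_thresholds <- function() {
  list(
    b_xdisp_min = -1.5, b_twist_min = 34,
    a_xdisp_max = -3.0, a_slide_max = -1.0, a_twist_max = 32,
    a_inclination_min = 12, a_roll_min = 8,
    lira_inclination_max = 8, lira_roll_max = 8
  )
}

#' Classify duplex conformation from mean step parameters
#'
#' @param x_disp,slide,twist,inclination,roll Mean parameters over interior
#'   steps (Angstroms / degrees). Alternatively pass a `step_params` tibble
#'   as the first argument and leave the rest missing.
#' @param thresholds See [helix_call_thresholds()].
#' @return A `helix_call`: list with `label` (one of B, A, LirA,
#'   intermediate), `evidence` (the mean tuple) and `thresholds`.
#' @examples
#' classify_helix(-0.8, 0, 36, 2, 2)$label   # "B"
#' classify_helix(-4.3, -1.6, 30, 2, 2)$label # "LirA"
#' @export
classify_helix <- function(x_disp, slide, twist, inclination, roll,
                           thresholds = helix_call_thresholds()) {
  if (inherits(x_disp, "step_params")) {
    steps <- x_disp
    use <- steps[!steps$terminal, ]
    if (nrow(use) < 4) {
      abort("need at least 4 interior steps for a conformation call",
            class = "lnahelix_value_error")
    }
    m <- step_means(steps)
    return(classify_helix(m$x_disp, m$slide, m$twist, m$inclination, m$roll, thresholds))
  }
  th <- thresholds
  label <- if (x_disp >= th$b_xdisp_min && twist >= th$b_twist_min) {
    "B"
  } else if (x_disp <= th$a_xdisp_max && slide <= th$a_slide_max && twist <= th$a_twist_max) {
    if (inclination >= th$a_inclination_min || roll >= th$a_roll_min) "A"
    else if (inclination < th$lira_inclination_max && roll < th$lira_roll_max) "LirA"
    else "intermediate"
  } else {
    "intermediate"
  }
  structure(
    list(label = label,
         evidence = tibble(x_disp = x_disp, slide = slide, twist = twist,
                           inclination = inclination, roll = roll),
         thresholds = th),
    class = "helix_call"
  )
}

#' @export
print.helix_call <- function(x, ...) {
  e <- x$evidence
  cat(sprintf("<helix_call> %s (x-disp %.2f A, slide %.2f A, twist %.1f deg, inclination %.1f deg, roll %.1f deg)\n",
              x$label, e$x_disp, e$slide, e$twist, e$inclination, e$roll))
  invisible(x)
}
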