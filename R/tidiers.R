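# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @method tidy conformation_profile
#' @export
tidy.conformation_profile <- function(x, ...) {
  tidyr::pivot_longer(x$fractions,
                      cols = c("syn", "low_anti", "mid_anti", "high_anti", "other",
                               "north", "south"),
                      names_to = "class", values_to = "fraction") %>%
    mutate(family = ifelse(.data$class %in% c("north", "south"), "pucker", "chi"))
}

#' @method glance conformation_profile
#' @export
glance.conformation_profile <- function(x, ...) {
  tibble(
    n_residues = nrow(x$fractions),
    n_frames = x$n_frames,
    exclude_ends = x$exclude_ends,
    mean_north = mean(x$fractions$north),
    mean_low_anti = mean(x$fractions$low_anti)
  )
}

#' @method tidy pair_persistence
#' @export
tidy.pair_persistence <- function(x, ...) paired_fractions(x)

#' @method glance pair_persistence
#' @export
glance.pair_persistence <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$paired),
    n_frames = ncol(x$paired),
    cutoff = x$cutoff,
    paired_fraction = mean(x$paired),
    wc_fraction = mean(x$paired[x$pairs$kind == "WC", , drop = FALSE]),
    hg_fraction = if (any(x$pairs$kind == "HG"))
      mean(x$paired[x$pairs$kind == "HG", , drop = FALSE]) else NA_real_
  )
}

#' @method tidy step_params
#' @export
tidy.step_params <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("twist", "roll", "tilt", "shift", "slide", "rise",
                               "x_disp", "inclination"),
                      names_to = "parameter", values_to = "value")
}

#' @method glance step_params
#' @export
glance.step_params <- function(x, ...) step_means(x)

#' @method tidy helix_call
#' @export
tidy.helix_call <- function(x, ...) {
  out <- tidyr::pivot_longer(x$evidence, dplyr::everything(),
                             names_to = "parameter", values_to = "value")
  out$label <- x$label
  out
}

#' @method glance helix_call
#' @export
glance.helix_call <- function(x, ...) {
  dplyr::bind_cols(tibble(label = x$label), x$evidence)
}

# ---- plots ------------------------------------------------------------------

#' @method autoplot conformation_profile
#' @export
autoplot.conformation_profile <- function(object, which = c("pucker", "chi"), ...) {
  which <- match.arg(which)
  if (which == "pucker") {
    dat <- object$p_hist
    xlab <- "pseudorotation phase P (deg)"
  } else {
    dat <- object$chi_hist
    xlab <- expression("glycosidic torsion" ~ chi ~ "(deg)")
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_mid, y = .data$fraction)) +
    ggplot2::geom_col(width = object$bin_width, fill = "steelblue") +
    ggplot2::facet_wrap(~ paste0(chain, residue)) +
    ggplot2::labs(x = xlab, y = "fraction of frames") +
    ggplot2::theme_minimal()
}

#' @method autoplot pair_persistence
#' @export
autoplot.pair_persistence <- function(object, ...) {
  long <- as_tibble(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps, y = .data$pair_id,
                                     fill = .data$paired)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "white")) +
    ggplot2::labs(x = "time (ps)", y = NULL, fill = "paired") +
    ggplot2::theme_minimal()
}

#' @method autoplot step_params
#' @export
autoplot.step_params <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ parameter, scales = "free_y") +
    ggplot2::labs(x = "base-pair step", y = NULL) +
    ggplot2::theme_minimal()
}
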