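# End-to-end pipeline runs and the command-line front end. All defaults
# match the analysis conventions used throughout the package: 3.5 A
# hydrogen-bond cutoff, two excluded terminal nucleotides per strand, 40 ps
# frame interval.

default_run_config <- function() {
  list(
    cutoff = DEFAULT_HBOND_CUTOFF,
    exclude_ends = 2,
    bin_width = 5,
    frame_interval = 40,
    form = "B",
    frames = 150,
    seed = 42,
    preset = "3prime-reduced"
  )
}

#' Read / write a pipeline run configuration
#'
#' Plain-text `key: value` (YAML) configuration. Unknown keys are rejected;
#' missing keys take the documented defaults. The effective configuration is
#' dumped alongside outputs so a run can be reproduced from its own
#' artifacts.
#'
#' @param path Config file path.
#' @return Named list of options.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "lnahelix_config_error")
  }
  validate_run_config(modifyList(defaults, cfg))
}

#' @rdname read_run_config
#' @param config Named list of options.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_run_config <- function(config) {
  if (config$cutoff <= 0) abort("cutoff must be positive", class = "lnahelix_config_error")
  if (config$exclude_ends < 0) abort("exclude_ends must be >= 0", class = "lnahelix_config_error")
  if (config$bin_width <= 0) abort("bin_width must be positive", class = "lnahelix_config_error")
  if (!config$form %in% c("A", "B")) abort("form must be A or B", class = "lnahelix_config_error")
  config
}

resolve_duplex <- function(name_or_notation) {
  tab <- paper_targets()
  if (name_or_notation %in% tab$name) return(get_target(name_or_notation))
  duplex_target(name_or_notation)
}

resolve_oligo <- function(name_or_notation) {
  tab <- paper_oligos()
  if (name_or_notation %in% tab$name) return(get_oligo(name_or_notation))
  parse_mixmer(name_or_notation)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a model and write it to PDB
#'
#' @param duplex Duplex name (resolved against the shipped fixtures first)
#'   or notation string.
#' @param tfo Optional TFO name or notation; when given, a triplex is built.
#' @param form Fiber form, `"B"` or `"A"`.
#' @param out Output PDB path.
#' @return The output path, invisibly.
#' @export
run_build <- function(duplex, tfo = NULL, form = "B", out = "model.pdb") {
  dx <- resolve_duplex(duplex)
  spec <- helix_spec(form)
  s <- if (is.null(tfo)) build_duplex(dx, spec) else build_triplex(dx, resolve_oligo(tfo), spec)
  write_pdb(s, out)
  message(sprintf("wrote %s (%d atoms, chains %s)", out, nrow(s),
                  paste(structure_chains(s), collapse = "")))
  invisible(out)
}

#' Run all analyses on a structure or trajectory
#'
#' Computes the conformational profile, pair persistence (with occupancy
#' summary, long-format export and text mosaic), per-frame step parameters
#' and the duplex conformation call, writing TSV artifacts to `out_dir`.
#'
#' @param x A `dna_structure`, `dna_trajectory`, or path to a PDB file.
#' @param out_dir Output directory (created if needed).
#' @param cutoff Hydrogen-bond distance cutoff, A.
#' @param exclude_ends Terminal nucleotides excluded per strand end.
#' @param bin_width Histogram bin width, degrees.
#' @return A list with the computed objects (`profile`, `persistence`,
#'   `steps`, `call`) and `files` (paths written).
#' @export
run_analyze <- function(x, out_dir = ".", cutoff = DEFAULT_HBOND_CUTOFF,
                        exclude_ends = 2, bin_width = 5) {
  if (is.character(x)) x <- read_pdb(x)
  traj <- as_trajectory(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  prof <- conformation_profile(traj, exclude_ends = exclude_ends, bin_width = bin_width)
  files["fractions"] <- write_tsv(prof$fractions, file.path(out_dir, "conformation_fractions.tsv"))
  files["chi_hist"] <- write_tsv(prof$chi_hist, file.path(out_dir, "chi_histogram.tsv"))
  files["p_hist"] <- write_tsv(prof$p_hist, file.path(out_dir, "pucker_histogram.tsv"))

  pers <- NULL
  chains <- structure_chains(traj$topology)
  if (all(c("W", "C") %in% chains)) {
    pers <- persistence_matrix(traj, cutoff = cutoff)
    long <- as_tibble(pers)
    files["persistence"] <- write_tsv(long, file.path(out_dir, "persistence.tsv"))
    files["occupancy"] <- write_tsv(paired_fractions(pers), file.path(out_dir, "occupancy.tsv"))
    mos <- utils::capture.output(persistence_mosaic(pers))
    writeLines(mos, file.path(out_dir, "persistence_mosaic.txt"))
    files["mosaic"] <- file.path(out_dir, "persistence_mosaic.txt")
  }

  steps <- NULL; call <- NULL
  if (all(c("W", "C") %in% chains)) {
    per_frame <- purrr::map_dfr(seq_len(n_frames(traj)), function(f) {
      st <- step_parameters(trajectory_frame(traj, f))
      st$frame <- f
      st
    })
    files["steps"] <- write_tsv(per_frame, file.path(out_dir, "step_parameters.tsv"))
    steps <- step_parameters(trajectory_frame(traj, 1))
    interior <- per_frame[!per_frame$terminal, ]
    means <- dplyr::summarise(interior, dplyr::across(c("twist", "roll", "tilt", "shift",
                                                        "slide", "rise", "x_disp",
                                                        "inclination"), mean))
    call <- classify_helix(means$x_disp, means$slide, means$twist,
                           means$inclination, means$roll)
    summary_lines <- c(
      sprintf("frames: %d", n_frames(traj)),
      sprintf("mean twist: %.2f deg", means$twist),
      sprintf("mean rise: %.3f A", means$rise),
      sprintf("mean slide: %.3f A", means$slide),
      sprintf("mean x-displacement: %.3f A", means$x_disp),
      sprintf("mean inclination: %.2f deg", means$inclination),
      sprintf("mean roll: %.2f deg", means$roll),
      sprintf("helix call: %s", call$label)
    )
    if (!is.null(pers)) {
      summary_lines <- c(summary_lines,
                         sprintf("overall paired fraction: %.4f", mean(pers$paired)))
    }
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    files["summary"] <- file.path(out_dir, "summary.txt")
  }

  invisible(list(profile = prof, persistence = pers, steps = steps, call = call,
                 files = files))
}

#' Seeded end-to-end demonstration run
#'
#' Builds the named preset scenario, generates a synthetic trajectory, runs
#' all analyses and writes every artifact plus the effective configuration
#' into `out_dir`. Fully deterministic for a given seed.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param frames Number of frames.
#' @param preset Preset scenario name (see [preset_scenario()]).
#' @return Invisible list of analysis objects and file paths.
#' @export
run_demo <- function(out_dir = "demo_out", seed = 42, frames = 150,
                     preset = "3prime-reduced") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- preset_scenario(preset, n_frames = frames, seed = seed)
  gen <- generate_trajectory(sc$structure, sc$traj_spec)
  write_pdb(sc$structure, file.path(out_dir, "model.pdb"))
  write_pdb(gen$trajectory, file.path(out_dir, "trajectory.pdb"))
  write_tsv(gen$ground_truth$pucker, file.path(out_dir, "ground_truth_pucker.tsv"))
  write_tsv(gen$ground_truth$pairs, file.path(out_dir, "ground_truth_pairs.tsv"))
  res <- run_analyze(gen$trajectory, out_dir)
  pers <- res$persistence
  lost <- lost_pairs(pers)
  write_tsv(lost, file.path(out_dir, "lost_pairs.tsv"))
  cfg <- modifyList(default_run_config(),
                    list(seed = as.integer(seed), frames = as.integer(frames), preset = preset))
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  message(sprintf("demo complete: %d artifacts in %s", length(dir(out_dir)), out_dir))
  invisible(c(res, list(lost = lost, scenario = sc)))
}

# ---- command line front end -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: lnahelix-tools <subcommand> [options]",
    "subcommands:",
    "  build    --duplex NAME [--tfo NAME] [--form B|A] [--out FILE]",
    "  synth    --preset NAME [--frames N] [--seed N] [--out FILE]",
    "  analyze  --in FILE [--out-dir DIR] [--cutoff A] [--exclude-ends N] [--config FILE]",
    "  demo     [--out-dir DIR] [--seed N] [--frames N] [--preset NAME]",
    "  fixtures (list shipped sequences)",
    sep = "\n"
  )
}

cli_opts <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort(sprintf("unexpected argument '%s'", a), class = "lnahelix_cli_error")
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      abort(sprintf("option --%s needs a value", key), class = "lnahelix_cli_error")
    }
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `build`, `synth`, `analyze`, `demo` and
#' `fixtures`. Used by the installed `exec/lnahelix-tools` script; callable
#' in-process for testing.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
triplex_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv)) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- argv[1]
    opts <- cli_opts(argv[-1])
    cfg <- default_run_config()
    if (!is.null(opts$config)) cfg <- read_run_config(opts$config)
    num <- function(key, default) if (!is.null(opts[[key]])) as.numeric(opts[[key]]) else default
    if (cmd == "build") {
      if (is.null(opts$duplex)) abort("build needs --duplex", class = "lnahelix_cli_error")
      run_build(opts$duplex, tfo = opts$tfo, form = opts$form %||% cfg$form,
                out = opts$out %||% "model.pdb")
    } else if (cmd == "synth") {
      sc <- preset_scenario(opts$preset %||% cfg$preset,
                            n_frames = num("frames", cfg$frames),
                            seed = num("seed", cfg$seed))
      gen <- generate_trajectory(sc$structure, sc$traj_spec)
      write_pdb(gen$trajectory, opts$out %||% "trajectory.pdb")
      message(sprintf("wrote %s (%d frames)", opts$out %||% "trajectory.pdb",
                      n_frames(gen$trajectory)))
    } else if (cmd == "analyze") {
      if (is.null(opts[["in"]])) abort("analyze needs --in", class = "lnahelix_cli_error")
      cutoff <- num("cutoff", cfg$cutoff)
      if (cutoff <= 0) abort("cutoff must be positive", class = "lnahelix_cli_error")
      run_analyze(opts[["in"]], out_dir = opts[["out-dir"]] %||% ".",
                  cutoff = cutoff,
                  exclude_ends = num("exclude-ends", cfg$exclude_ends),
                  bin_width = num("bin-width", cfg$bin_width))
    } else if (cmd == "demo") {
      run_demo(out_dir = opts[["out-dir"]] %||% "demo_out",
               seed = num("seed", cfg$seed), frames = num("frames", cfg$frames),
               preset = opts$preset %||% cfg$preset)
    } else if (cmd == "fixtures") {
      tab <- paper_oligos()
      message(paste(sprintf("%-26s %2d nt  %s", tab$name, tab$length, tab$notation),
                    collapse = "\n"))
      tab2 <- paper_targets()
      message(paste(sprintf("%-26s %2d bp  site [%d,%d]", tab2$name, tab2$length,
                            tab2$site_start, tab2$site_end), collapse = "\n"))
    } else {
      abort(sprintf("unknown subcommand '%s'\n%s", cmd, cli_usage()),
            class = "lnahelix_cli_error")
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' @method as_tibble pair_persistence
#' @export
as_tibble.pair_persistence <- function(x, ...) {
  nf <- ncol(x$paired)
  tibble(
    pair_id = rep(x$pairs$pair_id, nf),
    kind = rep(x$pairs$kind, nf),
    frame = rep(seq_len(nf), each = nrow(x$pairs)),
    time_ps = rep((seq_len(nf) - 1) * x$frame_interval, each = nrow(x$pairs)),
    distance = as.vector(x$distance),
    paired = as.vector(x$paired)
  )
}
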