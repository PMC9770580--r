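.config_defaults <- function() {
  list(
    windows_dir = NULL,
    scheme_file = NULL,
    scheme = NULL,
    reference_frame = NULL,
    temperature = 298.15,
    equilibration = 300,
    time_unit = "ps",
    output_dir = ".",
    jackknife = TRUE,
    wham = list(n_bins = 200L, z_min = NULL, z_max = NULL,
                tolerance = 1e-6, max_iter = 100000L, anchor_width = 0.3),
    diffusion = list(max_lag = NULL, method = "truncate"))
}

.check_keys <- function(supplied, known, where) {
  unknown <- setdiff(names(supplied), known)
  if (!length(unknown)) return(invisible())
  msgs <- vapply(unknown, function(k) {
    hit <- agrep(k, known, max.distance = 2, value = TRUE)
    if (length(hit)) sprintf("'%s'%s (did you mean '%s'?)", k, where, hit[1L])
    else sprintf("'%s'%s", k, where)
  }, "")
  stop(sprintf("configuration error: unknown key(s) %s",
               paste(msgs, collapse = "; ")), call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads an analysis configuration from YAML, fills defaults (temperature
#' 298.15 K, 300 ns equilibration discard, WHAM tolerance 1e-6 kJ/mol) and
#' rejects unknown keys with a nearest-match suggestion.  Temperature,
#' equilibration and WHAM settings are validated; scheme definitions may be
#' inline (\code{scheme:} with \code{regions}/\code{reference_frame}) or a
#' separate file (\code{scheme_file:}).
#'
#' @param path YAML file path.
#' @return a validated configuration list of class \code{"run_config"}.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("configuration error: not a YAML mapping",
                        call. = FALSE)
  defaults <- .config_defaults()
  .check_keys(y, names(defaults), "")
  if (!is.null(y$wham)) .check_keys(y$wham, names(defaults$wham), " in wham")
  if (!is.null(y$diffusion))
    .check_keys(y$diffusion, names(defaults$diffusion), " in diffusion")
  cfg <- utils::modifyList(defaults, y)
  problems <- character(0)
  if (is.null(cfg$windows_dir))
    problems <- c(problems, "windows_dir is required")
  if (!is.numeric(cfg$temperature) || cfg$temperature <= 0)
    problems <- c(problems, "temperature must be positive")
  if (!is.numeric(cfg$equilibration) || cfg$equilibration < 0)
    problems <- c(problems, "equilibration must be >= 0")
  if (cfg$wham$tolerance <= 0)
    problems <- c(problems, "wham tolerance must be positive")
  if (!cfg$diffusion$method %in% c("truncate", "expfit"))
    problems <- c(problems, "diffusion method must be truncate or expfit")
  if (!cfg$time_unit %in% c("ps", "ns"))
    problems <- c(problems, "time_unit must be ps or ns")
  if (length(problems))
    stop(sprintf("configuration error(s): %s",
                 paste(problems, collapse = "; ")), call. = FALSE)
  structure(cfg, class = c("run_config", "list"), source = path)
}

#' Write a run configuration back to YAML
#'
#' @param config a \code{"run_config"}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- config
  attributes(out) <- list(names = names(config))
  out <- out[!vapply(out, is.null, TRUE)]
  out$wham <- out$wham[!vapply(out$wham, is.null, TRUE)]
  out$diffusion <- out$diffusion[!vapply(out$diffusion, is.null, TRUE)]
  yaml::write_yaml(out, path)
  invisible(path)
}

## resolve the scheme named by a config
.config_scheme <- function(cfg) {
  if (!is.null(cfg$scheme_file)) return(read_scheme_yaml(cfg$scheme_file))
  if (!is.null(cfg$scheme)) {
    regions <- lapply(cfg$scheme$regions, function(r)
      scheme_region(r$z_min, r$z_max, r$spacing, r$force_constant))
    frame <- if (is.null(cfg$scheme$reference_frame)) "bilayer_center"
             else cfg$scheme$reference_frame
    return(build_scheme(regions, reference_frame = frame))
  }
  stop("configuration error: no scheme or scheme_file given", call. = FALSE)
}

#' Read a windows directory into a replicate set
#'
#' Expects one xvg per window per replicate, named
#' \code{rep<r>_win<ww>.xvg} (1-based indices, window zero-padded to two
#' digits, ordered as in the scheme).  Window centers and force constants
#' come from the scheme, matched by filename index.
#'
#' @param dir directory of xvg files.
#' @param scheme an \code{\link{umbrella_scheme}}.
#' @param equilibration_time ns discarded downstream.
#' @param time_unit time unit of the xvg files.
#' @return a \code{\link{replicate_set}}.
#' @export
read_windows_dir <- function(dir, scheme, equilibration_time = 0,
                             time_unit = "ps") {
  stopifnot(dir.exists(dir), inherits(scheme, "umbrella_scheme"))
  nwin <- nrow(scheme$windows)
  nrep <- 0L
  while (file.exists(file.path(dir, sprintf("rep%d_win01.xvg", nrep + 1L))))
    nrep <- nrep + 1L
  if (nrep == 0L)
    stop(sprintf("no window files (rep1_win01.xvg ...) found in %s", dir),
         call. = FALSE)
  reps <- lapply(seq_len(nrep), function(r) {
    lapply(seq_len(nwin), function(w) {
      f <- file.path(dir, sprintf("rep%d_win%02d.xvg", r, w))
      if (!file.exists(f))
        stop(sprintf("missing window file: %s (window %d of replicate %d)",
                     f, w, r), call. = FALSE)
      read_pull_xvg(f, scheme$windows$center[w],
                    scheme$windows$force_constant[w], time_unit = time_unit)
    })
  })
  replicate_set(reps, equilibration_time)
}

#' Write a simulated replicate set as a windows directory
#'
#' Inverse of \code{\link{read_windows_dir}}: one
#' \code{rep<r>_win<ww>.xvg} per window per replicate.
#'
#' @param reps a \code{\link{replicate_set}}.
#' @param dir output directory (created if needed).
#' @param time_unit time unit for the files.
#' @return the directory, invisibly.
#' @export
write_windows_dir <- function(reps, dir, time_unit = "ps") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(reps$replicates)) {
    for (w in seq_along(reps$replicates[[r]])) {
      write_pull_xvg(reps$replicates[[r]][[w]],
                     file.path(dir, sprintf("rep%d_win%02d.xvg", r, w)),
                     time_unit = time_unit)
    }
  }
  invisible(dir)
}

#' Run the full analysis pipeline from a configuration
#'
#' read windows -> WHAM -> diffusion -> (mirror if monolayer frame) ->
#' resistance -> permeability -> barriers -> jackknife errors, writing
#' \code{pmf.xvg}, \code{dz.tsv}, \code{resistance.tsv},
#' \code{result.json} and \code{analysis.log} (stage timings and WHAM
#' residual) into the configured output directory.
#'
#' @param config a \code{"run_config"} from \code{\link{load_run_config}},
#'   or a path to one.
#' @return the \code{\link{analyze_system}} result, invisibly; file paths
#'   in attribute \code{"files"}.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(.prov_header(prefix = "#", config = unclass(config)),
                 sprintf("# started %s", format(Sys.time())))
  tick <- function(msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%8.2f s] %s", proc.time()[["elapsed"]] - t0,
                            msg))
  }

  scheme <- .config_scheme(config)
  frame <- if (!is.null(config$reference_frame)) config$reference_frame
           else scheme$reference_frame
  thermo <- make_thermo(config$temperature)
  tick(sprintf("scheme: %d windows, frame %s", nrow(scheme$windows), frame))

  reps <- read_windows_dir(config$windows_dir, scheme,
                           equilibration_time = config$equilibration,
                           time_unit = config$time_unit)
  tick(sprintf("read %d replicate(s) x %d windows from %s",
               n_replicates(reps), length(reps$centers),
               config$windows_dir))

  wc <- config$wham
  z_min <- if (is.null(wc$z_min)) min(scheme$windows$center) else wc$z_min
  z_max <- if (is.null(wc$z_max)) max(scheme$windows$center) else wc$z_max
  cfg <- wham_config(z_min, z_max, n_bins = wc$n_bins,
                     tolerance = wc$tolerance, max_iter = wc$max_iter,
                     anchor_region = c(z_max - wc$anchor_width, z_max))
  res <- analyze_system(reps, thermo, cfg, reference_frame = frame,
                        max_lag = config$diffusion$max_lag,
                        jackknife = isTRUE(config$jackknife) &&
                          n_replicates(reps) >= 2L)
  tick(sprintf("WHAM converged in %d iterations (residual %.3g kJ/mol)",
               attr(res$pmf, "iterations"), attr(res$pmf, "residual")))
  tick(sprintf("permeability %.6g cm/s, dG_entry %.4g kcal/mol, dG_exit %.4g kcal/mol",
               res$permeability, res$dg_entry, res$dg_exit))

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- c(pmf = file.path(out, "pmf.xvg"),
             dz = file.path(out, "dz.tsv"),
             resistance = file.path(out, "resistance.tsv"),
             result = file.path(out, "result.json"),
             log = file.path(out, "analysis.log"))
  write_pmf_xvg(res$pmf_full, files[["pmf"]])
  write_diffusion_tsv(res$diffusion, files[["dz"]])
  writeLines(c("position_nm\tresistance_s_cm2",
               sprintf("%.6f\t%.9g", res$resistance_positions,
                       res$resistance)), files[["resistance"]])
  report <- list(
    permeability_cm_s = res$permeability,
    dg_entry_kcal_mol = res$dg_entry,
    dg_exit_kcal_mol = res$dg_exit,
    standard_errors = as.list(res$standard_errors),
    n_replicates = res$n_replicates,
    n_windows = length(reps$centers),
    reference_frame = frame,
    equilibration_ns = config$equilibration,
    wham_iterations = attr(res$pmf, "iterations"),
    wham_residual_kj_mol = attr(res$pmf, "residual"))
  jsonlite::write_json(report, files[["result"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tick("outputs written")
  writeLines(log_lines, files[["log"]])
  attr(res, "files") <- files
  invisible(res)
}
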