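## provenance header lines for all text writers
.prov_header <- function(prefix = "#", inputs = character(0),
                         config = NULL) {
  ver <- as.character(utils::packageVersion("pmfperm"))
  lines <- c(sprintf("%s created by pmfperm %s", prefix, ver))
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    writeLines(yaml::as.yaml(config), tf)
    lines <- c(lines, sprintf("%s config md5: %s", prefix,
                              unname(tools::md5sum(tf))))
  }
  for (f in inputs) {
    if (file.exists(f))
      lines <- c(lines, sprintf("%s input %s md5: %s", prefix, basename(f),
                                unname(tools::md5sum(f))))
  }
  lines
}

#' Read a pull-output xvg time series
#'
#' Parses the two-column time/coordinate dialect of pull output: comment
#' and directive lines starting with \code{#} or \code{@} are skipped,
#' remaining lines must hold a time and a coordinate.  Malformed rows are
#' skipped with a warning naming their line numbers.  Window metadata
#' (center, force constant) is not parsed from legends - it must be
#' supplied, typically from the scheme configuration matched by filename.
#'
#' @param path file path.
#' @param center,force_constant window metadata (nm, kJ/mol/nm^2).
#' @param time_unit unit of the first column, \code{"ps"} (default,
#'   converted to ns) or \code{"ns"}.
#' @param label window label; default the file base name.
#' @return an \code{\link{umbrella_window}}.
#' @export
read_pull_xvg <- function(path, center, force_constant,
                          time_unit = c("ps", "ns"), label = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  parsed <- lapply(rows, function(r) suppressWarnings(as.numeric(r[1:2])))
  bad <- vapply(parsed, function(p) anyNA(p), TRUE) |
    vapply(rows, length, 0L) < 2L
  if (any(bad)) {
    warning(sprintf("skipping %d malformed row(s) at line(s) %s of %s",
                    sum(bad), paste(lineno[bad], collapse = ", "),
                    basename(path)), call. = FALSE)
    parsed <- parsed[!bad]
  }
  if (length(parsed) < 2L)
    stop(sprintf("empty file: %s has fewer than 2 data rows", path),
         call. = FALSE)
  times <- vapply(parsed, `[[`, 0, 1L)
  pos <- vapply(parsed, `[[`, 0, 2L)
  if (any(diff(times) <= 0))
    stop(sprintf("format error: non-monotonic time column in %s", path),
         call. = FALSE)
  if (time_unit == "ps") times <- times / 1000
  umbrella_window(center, force_constant, times, pos,
                  label = if (is.null(label))
                    sub("\\.xvg$", "", basename(path)) else label)
}

#' Write a window time series as pull-output xvg
#'
#' @param window an \code{\link{umbrella_window}}.
#' @param path output path.
#' @param time_unit unit for the written time column.
#' @return the path, invisibly.
#' @export
write_pull_xvg <- function(window, path, time_unit = c("ps", "ns")) {
  time_unit <- match.arg(time_unit)
  t_out <- if (time_unit == "ps") window$times * 1000 else window$times
  lines <- c(.prov_header(prefix = "#"),
             sprintf("# umbrella center %.6f nm, Kf %g kJ/mol/nm^2",
                     window$center, window$force_constant),
             "@    title \"Pull COM\"",
             sprintf("@    xaxis  label \"Time (%s)\"", time_unit),
             "@    yaxis  label \"Position (nm)\"",
             sprintf("%.6f\t%.9f", t_out, window$positions))
  writeLines(lines, path)
  invisible(path)
}

#' Write a PMF profile as two-column xvg text
#'
#' Position (nm) and free energy (kcal/mol, the reporting unit) with a
#' \code{#} metadata header.
#'
#' @param pmf a \code{\link{pmf_profile}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pmf_xvg <- function(pmf, path) {
  p <- convert_pmf_units(pmf, "kcal/mol")
  lines <- c(.prov_header(prefix = "#"),
             sprintf("# reference frame: %s; anchor: %s", p$reference_frame,
                     p$anchor),
             "# position_nm  free_energy_kcal_mol",
             sprintf("%.6f\t%s", p$bin_centers,
                     ifelse(is.na(p$free_energy), "nan",
                            sprintf("%.9f", p$free_energy))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PMF profile written by \code{\link{write_pmf_xvg}}
#'
#' @param path file path.
#' @param reference_frame frame tag for the profile.
#' @return a \code{\link{pmf_profile}} in kcal/mol.
#' @export
read_pmf_xvg <- function(path, reference_frame = c("bilayer_center",
                                                   "closest_p_layer")) {
  reference_frame <- match.arg(reference_frame)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", raw) & nzchar(trimws(raw))
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  z <- vapply(rows, function(r) as.numeric(r[1L]), 0)
  g <- vapply(rows, function(r) suppressWarnings(as.numeric(r[2L])), 0)
  pmf_profile(z, g, units = "kcal/mol", reference_frame = reference_frame)
}

#' Write a diffusion profile as TSV
#'
#' Columns: position (nm), D (nm^2/ns), variance (nm^2), tau (ns).
#'
#' @param dprof a \code{"diffusion_profile"}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_diffusion_tsv <- function(dprof, path) {
  lines <- c(.prov_header(prefix = "#"),
             "position_nm\tD_nm2_ns\tvariance_nm2\ttau_ns",
             sprintf("%.6f\t%.15g\t%.15g\t%.15g", dprof$positions,
                     dprof$diffusion, dprof$variance, dprof$corr_time))
  writeLines(lines, path)
  invisible(path)
}

#' Read a diffusion profile TSV
#'
#' @param path file written by \code{\link{write_diffusion_tsv}}.
#' @return a \code{"diffusion_profile"}.
#' @export
read_diffusion_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_diffusion_profile(d$position_nm, d$D_nm2_ns, d$variance_nm2,
                        d$tau_ns)
}

#' Write an umbrella scheme as a windows TSV
#'
#' @param scheme an \code{\link{umbrella_scheme}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scheme_tsv <- function(scheme, path) {
  lines <- c(.prov_header(prefix = "#"),
             sprintf("# reference frame: %s", scheme$reference_frame),
             "center_nm\tforce_constant_kj_mol_nm2",
             sprintf("%.6f\t%g", scheme$windows$center,
                     scheme$windows$force_constant))
  writeLines(lines, path)
  invisible(path)
}

#' Read an umbrella scheme from YAML
#'
#' Expected structure: a \code{reference_frame} entry and a \code{regions}
#' list whose elements carry \code{z_min}, \code{z_max}, \code{spacing},
#' \code{force_constant}.
#'
#' @param path YAML file.
#' @return an \code{\link{umbrella_scheme}}.
#' @export
read_scheme_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$regions))
    stop("configuration error: scheme YAML needs a 'regions' list",
         call. = FALSE)
  regions <- lapply(y$regions, function(r) {
    miss <- setdiff(c("z_min", "z_max", "spacing", "force_constant"),
                    names(r))
    if (length(miss))
      stop(sprintf("configuration error: region missing field(s) %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    scheme_region(r$z_min, r$z_max, r$spacing, r$force_constant)
  })
  frame <- if (is.null(y$reference_frame)) "bilayer_center"
           else y$reference_frame
  build_scheme(regions, reference_frame = frame)
}
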