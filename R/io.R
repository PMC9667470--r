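#' Read and write umbrella window tables
#'
#' Window time series are plain-text two-column tables (time ps, coordinate
#' nm) with `#`-prefixed header lines recording the restraint center, spring
#' constant and temperature -- the dialect the WHAM reader consumes. A
#' directory of such files, or an explicit metadata table listing
#' `(filename, center, spring)` for externally produced pull-coordinate
#' tables, round-trips to a [window_set()].
#'
#' @param window an [umbrella_window()].
#' @param path output file.
#' @param times optional time stamps, ps.
#' @export
write_window_table <- function(window, path, times = NULL) {
  stopifnot(inherits(window, "umbrella_window"))
  if (is.null(times)) times <- seq_along(window$samples) - 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center %.17g", window$center),
               sprintf("# spring %.17g", window$spring_constant)), con)
  writeLines(sprintf("%.17g\t%.17g", times, window$samples), con)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
    if (length(m) != 1L) stop("malformed header in ", path, ": expected one '# ", key, "' line")
    as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "", m))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) stop("malformed data line ", bad[1] + sum(grepl("^#", lines)), " in ", path)
  vals <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2L, byrow = TRUE)
  if (any(!is.finite(vals))) stop("non-numeric field in ", path)
  umbrella_window(get("center"), get("spring"), vals[, 2])
}

#' @rdname write_window_table
#' @param ws a [window_set()].
#' @param dir output directory (created if needed); writes `window_###.dat`
#'   plus a `windows.tsv` metadata table.
#' @export
write_window_set <- function(ws, dir) {
  stopifnot(inherits(ws, "window_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.dat", seq_along(ws$windows))
  for (i in seq_along(ws$windows)) {
    write_window_table(ws$windows[[i]], file.path(dir, files[i]))
  }
  meta <- data.frame(filename = files,
                     center = vapply(ws$windows, `[[`, numeric(1), "center"),
                     spring = vapply(ws$windows, `[[`, numeric(1), "spring_constant"),
                     temperature = ws$temperature)
  utils::write.table(meta, file.path(dir, "windows.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "windows.tsv"))
}

#' @rdname write_window_table
#' @param metadata path to a `windows.tsv` metadata table, or a directory
#'   containing one.
#' @param temperature used when the metadata table has no temperature
#'   column.
#' @export
read_window_set <- function(metadata, temperature = 310) {
  if (dir.exists(metadata)) metadata <- file.path(metadata, "windows.tsv")
  meta <- utils::read.table(metadata, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("filename", "center", "spring")
  if (!all(need %in% names(meta))) {
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  }
  if ("temperature" %in% names(meta)) temperature <- meta$temperature[1]
  windows <- lapply(seq_len(nrow(meta)), function(i) {
    w <- read_window_table(file.path(dirname(metadata), meta$filename[i]))
    if (abs(w$center - meta$center[i]) > 1e-9 ||
        abs(w$spring_constant - meta$spring[i]) > 1e-9) {
      stop("metadata row ", i, " disagrees with the header of ", meta$filename[i])
    }
    w
  })
  window_set(windows, temperature = temperature)
}

#' XYZ configuration I/O
#'
#' Writes/reads particle configurations in plain XYZ format; the comment
#' line carries the box edges as `box <lx> <ly> <lz>`. Multi-frame files
#' concatenate frames.
#'
#' @param config a [particle_config()] or a list of them.
#' @param path file path.
#' @param element atom label used for every particle.
#' @export
write_xyz <- function(config, path, element = "C") {
  frames <- if (inherits(config, "particle_config")) list(config) else config
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    stopifnot(inherits(f, "particle_config"))
    writeLines(c(as.character(nrow(f$positions)),
                 sprintf("box %.17g %.17g %.17g", f$box[1], f$box[2], f$box[3])), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", element,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @return `read_xyz`: a list of [particle_config()] (length one for a
#'   single-frame file).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ atom count at line ", i, " in ", path)
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec(
      "box\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", comment))[[1]]
    if (length(m) != 4L) stop("missing 'box lx ly lz' in comment at line ", i + 1L, " in ", path)
    box <- as.numeric(m[2:4])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad)) stop("malformed XYZ coordinate line ", i + 1L + bad[1], " in ", path)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- particle_config(pos, box, periodic = TRUE)
    i <- i + 2L + n
  }
  frames
}

#' Release curve CSV I/O
#'
#' Columns `time_h`, `fraction` and optionally `stderr`. Reading validates
#' the physical range and names the offending row on failure.
#'
#' @param curve a [release_curve()].
#' @param path file path.
#' @export
write_release_curve <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  df <- data.frame(time_h = curve$times, fraction = curve$fraction_released)
  if (!is.null(curve$stderr)) df$stderr <- curve$stderr
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_release_curve
#' @export
read_release_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "fraction") %in% names(df))) {
    stop("release curve CSV must have columns time_h, fraction")
  }
  bad <- which(!is.finite(df$fraction) | df$fraction < 0 | df$fraction > 1)
  if (length(bad)) stop("invalid fraction at row ", bad[1], " of ", path)
  bad_t <- which(!is.finite(df$time_h) | df$time_h < 0)
  if (length(bad_t)) stop("invalid time at row ", bad_t[1], " of ", path)
  release_curve(df$time_h, df$fraction, if ("stderr" %in% names(df)) df$stderr)
}

#' Free-energy profile TSV I/O
#'
#' Columns `z_nm`, `G_kJ_per_mol`, `stderr`; unpopulated bins are written
#' as `NA` and stay flagged on read.
#'
#' @param pmf a `pmf_profile` from [wham()].
#' @param path file path.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  utils::write.table(data.frame(z_nm = pmf$z_grid, G_kJ_per_mol = pmf$free_energy,
                                stderr = pmf$stderr),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @return `read_pmf`: a data.frame with the three columns above.
#' @export
read_pmf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("z_nm", "G_kJ_per_mol") %in% names(df))) {
    stop("PMF table must have columns z_nm, G_kJ_per_mol")
  }
  df
}
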