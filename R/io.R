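#' @title Whitespace-column text formats
#' @description
#' All on-disk formats are plain whitespace-separated text with `#` and
#' `@` comment/header lines, deliberately compatible with common
#' pull-coordinate and profile output layouts.  Numbers are written with
#' 17 significant digits so write -> read round-trips are exact to
#' double precision.
#' @name transloc-io
NULL

# read a text file, keep data lines, remember original line numbers
read_data_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|@|$)", lines)
  if (!any(keep)) {
    abort(sprintf("No data lines in %s (comments/blank only).", path))
  }
  out <- lines[keep]
  attr(out, "lineno") <- which(keep)
  out
}

header_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[grepl("^\\s*[#@]", lines)]
}

parse_table <- function(lines, col_names, numeric_cols = col_names,
                        path = "<text>") {
  lineno <- attr(lines, "lineno") %||% seq_along(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield != length(col_names))
  if (length(bad)) {
    abort(sprintf("Malformed row in %s at line %d: expected %d fields, got %d.",
                  path, lineno[bad[1]], length(col_names), nfield[bad[1]]))
  }
  m <- do.call(rbind, fields)
  df <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE),
                  .name_repair = "minimal")
  names(df) <- col_names
  for (cn in intersect(numeric_cols, col_names)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("Malformed value in %s at line %d, column '%s'.",
                    path, lineno[bad], cn))
    }
    df[[cn]] <- v
  }
  df
}

fmt_num <- function(x) sprintf("%.17g", x)

provenance_header <- function(extra = character()) {
  c(sprintf("# created-by: transloc %s",
            as.character(packageVersion("transloc"))),
    extra)
}

#' Write / read a free-energy profile
#'
#' Three whitespace columns `z G err` (two when no error band), with a
#' `#` header recording the reference convention and any solver metadata.
#'
#' @param p A [fep] profile.
#' @param path File path.
#' @param extra_header Additional `# key: value` header lines.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a [fep].
#' @export
write_profile <- function(p, path, extra_header = character()) {
  stopifnot(is_fep(p))
  has_err <- "err" %in% names(p)
  hdr <- provenance_header(c(
    sprintf("# reference: %s", attr(p, "reference") %||% "unreferenced"),
    if (!is.null(attr(p, "kT"))) sprintf("# kT: %s", fmt_num(attr(p, "kT"))),
    extra_header,
    sprintf("# columns: z[nm] G[kJ/mol]%s", if (has_err) " err[kJ/mol]" else ""))
  )
  rows <- if (has_err) {
    paste(fmt_num(p$z), fmt_num(p$G), fmt_num(p$err))
  } else {
    paste(fmt_num(p$z), fmt_num(p$G))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- read_data_lines(path)
  n <- length(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  if (!n %in% 2:3) {
    abort(sprintf("Profile file %s must have 2 or 3 columns.", path))
  }
  cols <- c("z", "G", if (n == 3) "err")
  df <- parse_table(lines, cols, path = path)
  hdr <- header_lines(path)
  ref <- sub("^#\\s*reference:\\s*", "",
             grep("^#\\s*reference:", hdr, value = TRUE)[1])
  kT <- sub("^#\\s*kT:\\s*", "", grep("^#\\s*kT:", hdr, value = TRUE)[1])
  fep(df$z, df$G, err = if ("err" %in% names(df)) df$err,
      reference = if (is.na(ref)) "unreferenced" else ref,
      kT = if (length(kT) && !is.na(kT)) as.numeric(kT) else NULL)
}

#' Write / read a window timeseries
#'
#' Two whitespace columns `step z`, with `@` header lines recording the
#' window reference position, force constant, equilibration length and
#' seed -- one file per umbrella window.
#'
#' @param ts A `window_timeseries` from [sample_window()].
#' @param path File path.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns a `window_timeseries` tibble.
#' @export
write_timeseries <- function(ts, path) {
  w <- attr(ts, "window")
  hdr <- c(provenance_header(),
           sprintf("@ z0: %s", fmt_num(w$z0)),
           sprintf("@ k: %s", fmt_num(w$k)),
           sprintf("@ n_equil: %d", attr(ts, "n_equil") %||% 0L),
           sprintf("@ seed: %d", attr(ts, "seed") %||% NA_integer_),
           "@ columns: step z[nm]")
  writeLines(c(hdr, paste(ts$step, fmt_num(ts$z))), path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  lines <- read_data_lines(path)
  df <- parse_table(lines, c("step", "z"), path = path)
  hdr <- header_lines(path)
  take <- function(key) {
    v <- sub(sprintf("^@\\s*%s:\\s*", key), "",
             grep(sprintf("^@\\s*%s:", key), hdr, value = TRUE)[1])
    if (length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
  }
  out <- tibble(step = as.integer(df$step), z = df$z)
  class(out) <- c("window_timeseries", class(out))
  attr(out, "window") <- list(z0 = take("z0"), k = take("k"),
                              label = NA_character_)
  attr(out, "n_equil") <- as.integer(take("n_equil"))
  attr(out, "seed") <- as.integer(take("seed"))
  out
}

#' Write / read a window metadata table
#'
#' Columns `label z0 k n_equil seed file`, one row per umbrella window,
#' pointing at the per-window timeseries files.
#'
#' @param ts_list List of `window_timeseries`.
#' @param files Character vector of per-window file paths (as recorded).
#' @param path Metadata file path.
#' @return `write_window_metadata()` returns `path` invisibly;
#'   `read_window_metadata()` returns a tibble.
#' @export
write_window_metadata <- function(ts_list, files, path) {
  stopifnot(length(ts_list) == length(files))
  rows <- purrr::map2_chr(ts_list, files, function(ts, f) {
    w <- attr(ts, "window")
    paste(w$label %||% "w", fmt_num(w$z0), fmt_num(w$k),
          attr(ts, "n_equil") %||% 0L, attr(ts, "seed") %||% NA_integer_, f)
  })
  writeLines(c(provenance_header("# columns: label z0 k n_equil seed file"),
               rows), path)
  invisible(path)
}

#' @rdname write_window_metadata
#' @export
read_window_metadata <- function(path) {
  lines <- read_data_lines(path)
  df <- parse_table(lines, c("label", "z0", "k", "n_equil", "seed", "file"),
                    numeric_cols = c("z0", "k", "n_equil", "seed"),
                    path = path)
  df$n_equil <- as.integer(df$n_equil)
  df$seed <- as.integer(df$seed)
  df
}

#' Read a stress-tensor profile
#'
#' Four whitespace columns `z sigma_xx sigma_yy sigma_zz` (nm, bar), the
#' tabulated output of a local stress calculation.
#'
#' @param path File path.
#' @return A tibble of class `stress_profile`.
#' @export
read_stress <- function(path) {
  lines <- read_data_lines(path)
  df <- parse_table(lines, c("z", "sigma_xx", "sigma_yy", "sigma_zz"),
                    path = path)
  as_stress_profile(df)
}

#' Read a density profile
#'
#' Two whitespace columns `z rho` (nm, arbitrary density units).
#'
#' @param path File path.
#' @return A tibble with columns `z` and `rho`.
#' @export
read_density <- function(path) {
  lines <- read_data_lines(path)
  df <- parse_table(lines, c("z", "rho"), path = path)
  if (any(df$rho < 0)) abort("Density values must be non-negative.")
  df
}

#' Write a stress-tensor profile
#'
#' @param s A `stress_profile` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stress <- function(s, path) {
  hdr <- provenance_header(c(
    "# columns: z[nm] sigma_xx[bar] sigma_yy[bar] sigma_zz[bar]",
    if (!is.null(attr(s, "gamma_true"))) {
      g <- attr(s, "gamma_true")
      sprintf("# gamma_true: %s %s", fmt_num(g[["gamma_plus"]]),
              fmt_num(g[["gamma_minus"]]))
    }))
  writeLines(c(hdr, paste(fmt_num(s$z), fmt_num(s$sigma_xx),
                          fmt_num(s$sigma_yy), fmt_num(s$sigma_zz))), path)
  invisible(path)
}
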