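#' Read a dose grid from a textgrid file
#'
#' The textgrid format is the package's plain-text interchange format for
#' planar dose distributions: UTF-8, a header of `#`-prefixed `key value`
#' lines (`rows`, `cols`, `row_spacing_mm`, `col_spacing_mm`, `origin_y_mm`,
#' `origin_x_mm`, `mode`) followed by `rows` lines of `cols`
#' whitespace-separated dose values.
#'
#' @param path path to a textgrid file.
#' @return a [dose_grid()].
#' @seealso [write_dose_grid()]
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1) {
    stop("malformed textgrid: header lines (#-prefixed) must lead the file",
         call. = FALSE)
  }
  header <- list()
  for (i in hdr_idx) {
    parts <- strsplit(trimws(sub("^#", "", lines[i])), "[[:space:]]+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed textgrid header line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    header[[parts[1]]] <- parts[2]
  }
  need <- c("rows", "cols", "row_spacing_mm", "col_spacing_mm",
            "origin_y_mm", "origin_x_mm", "mode")
  missing <- setdiff(need, names(header))
  if (length(missing) > 0) {
    stop(sprintf("malformed textgrid header: missing %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(header[[key]]))
    if (is.na(v)) {
      stop(sprintf("malformed textgrid header: '%s' is not numeric (%s)",
                   key, header[[key]]), call. = FALSE)
    }
    v
  }
  nr <- as.integer(num("rows"))
  nc <- as.integer(num("cols"))
  body <- lines[-hdr_idx]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    stop(sprintf("textgrid body has %d data lines, header declares %d rows",
                 length(body), nr), call. = FALSE)
  }
  vals <- t(vapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                              "[[:space:]]+")[[1]]))
    if (length(v) != nc || anyNA(v)) {
      stop(sprintf("malformed textgrid data line %d", i), call. = FALSE)
    }
    v
  }, numeric(nc)))
  if (nc == 1) vals <- matrix(vals, nrow = nr)
  mode <- header[["mode"]]
  if (!mode %in% c("absolute", "relative")) {
    stop(sprintf("malformed textgrid header: unknown mode '%s'", mode),
         call. = FALSE)
  }
  dose_grid(vals,
            spacing = c(num("row_spacing_mm"), num("col_spacing_mm")),
            origin = c(num("origin_y_mm"), num("origin_x_mm")),
            mode = mode)
}

#' Write a dose grid to a textgrid file
#'
#' Serializes with 17 significant digits so that a read/write round trip
#' reproduces the grid to within 1e-9.
#'
#' @param grid a [dose_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  assert_dose_grid(grid)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  on.exit(close(con))
  v <- grid$values
  writeLines(c(
    sprintf("# rows %d", nrow(v)),
    sprintf("# cols %d", ncol(v)),
    sprintf("# row_spacing_mm %.17g", grid$spacing[1]),
    sprintf("# col_spacing_mm %.17g", grid$spacing[2]),
    sprintf("# origin_y_mm %.17g", grid$origin[1]),
    sprintf("# origin_x_mm %.17g", grid$origin[2]),
    sprintf("# mode %s", grid$mode)
  ), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  }
  invisible(path)
}
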