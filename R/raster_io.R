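# ESRI ASCII grid read/write and landscape (de)serialization. Grids are
# written row-major from the top row, matching the in-memory matrix layout.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m Numeric, integer or logical matrix (row 1 = top of the map).
#' @param path Output file path.
#' @param origin Lower-left corner `(x0, y0)` in meters.
#' @param resolution_m Cell size in meters.
#' @param nodata NODATA sentinel value.
#' @export
write_ascii_grid <- function(m, path, origin = c(0, 0), resolution_m = 30,
                             nodata = -9999) {
  v <- m
  if (is.logical(v)) v <- v * 1L
  v[is.na(v)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", origin[1]),
    sprintf("yllcorner %.10g", origin[2]),
    sprintf("cellsize %.10g", resolution_m),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] or any conforming grid.
#' @return List with `m` (numeric matrix), `origin`, `resolution_m`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2])
  names(vals) <- tolower(kv[, 1])
  ncols <- as.integer(vals["ncols"])
  nrows <- as.integer(vals["nrows"])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != ncols * nrows) err_format("ASCII grid size mismatch")
  m <- matrix(body, nrows, ncols, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA
  list(m = m, origin = unname(vals[c("xllcorner", "yllcorner")]),
       resolution_m = unname(vals["cellsize"]))
}

#' Write a landscape stack to a directory of ASCII grids
#'
#' Writes `cover.asc`, `pa_mask.asc`, one `linear_<class>.asc` per linear
#' class, and `schema.csv`.
#'
#' @param stack A `landscape_stack`.
#' @param dir Output directory (created if missing).
#' @export
write_landscape <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wg <- function(m, name) {
    write_ascii_grid(m, file.path(dir, name), stack$origin, stack$resolution_m)
  }
  wg(stack$cover, "cover.asc")
  wg(stack$pa_mask, "pa_mask.asc")
  for (cl in names(stack$linear_masks)) {
    wg(stack$linear_masks[[cl]], paste0("linear_", cl, ".asc"))
  }
  write.csv(as.data.frame(stack$schema), file.path(dir, "schema.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a landscape stack written by [write_landscape()]
#'
#' @param dir Directory containing the grids and `schema.csv`.
#' @return A `landscape_stack`.
#' @export
read_landscape <- function(dir) {
  schema <- feature_schema(read.csv(file.path(dir, "schema.csv"),
                                    stringsAsFactors = FALSE))
  cov <- read_ascii_grid(file.path(dir, "cover.asc"))
  pa <- read_ascii_grid(file.path(dir, "pa_mask.asc"))
  linear_masks <- lapply(linear_classes(schema), function(cl) {
    read_ascii_grid(file.path(dir, paste0("linear_", cl, ".asc")))$m > 0
  })
  names(linear_masks) <- linear_classes(schema)
  structure(list(
    cover = matrix(as.integer(cov$m), nrow(cov$m), ncol(cov$m)),
    pa_mask = pa$m > 0, linear_masks = linear_masks,
    origin = cov$origin, resolution_m = cov$resolution_m, schema = schema
  ), class = "landscape_stack")
}
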