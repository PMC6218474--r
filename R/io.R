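#' Read a raster from an Esri ASCII grid file
#'
#' Plain-text single-band raster format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' top row first. Integer rasters round-trip exactly.
#'
#' @param path file to read.
#' @param epoch optional epoch label to attach.
#' @return an \code{hfp_raster}.
#' @export
read_asc <- function(path, epoch = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("raster header missing required fields: ", paste(missing, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("raster body has ", length(vals), " values, expected ",
         hdr$nrows * hdr$ncols)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_layer(m, hfp_grid(hdr$nrows, hdr$ncols, hdr$cellsize,
                           hdr$xllcorner, hdr$yllcorner), epoch = epoch)
}

#' Write a raster to an Esri ASCII grid file
#'
#' @param r an \code{hfp_raster}.
#' @param path output file.
#' @param nodata value used to encode \code{NA} cells.
#' @param digits significant digits for non-integer rasters (\code{NA} cells
#'   and integer-valued rasters are written exactly).
#' @return \code{path}, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(r, "hfp_raster"))
  g <- r$grid
  m <- r$values
  if (any(m == nodata, na.rm = TRUE))
    stop("raster contains the nodata sentinel value ", nodata)
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xmin), sprintf("yllcorner %.10g", g$ymin),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(row)
    paste(formatC(row, format = "g", digits = digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a species range set to GeoJSON
#'
#' @param ranges named list (names = species ids) of polygons; each polygon is
#'   a two-column matrix of x/y vertex coordinates (unclosed ring).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ranges_geojson <- function(ranges, path) {
  stopifnot(is.list(ranges), !is.null(names(ranges)))
  feats <- lapply(names(ranges), function(id) {
    ring <- ranges[[id]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    list(type = "Feature",
         properties = list(species_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, 1:2]))))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a species range set from GeoJSON
#'
#' Reads a FeatureCollection of single-ring Polygon features keyed by a
#' \code{species_id} property.
#'
#' @param path GeoJSON file.
#' @return named list of two-column vertex matrices (closing vertex dropped).
#' @export
read_ranges_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in fc$features) {
    id <- f$properties$species_id
    if (is.null(id)) stop("feature without species_id property")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    out[[as.character(id)]] <- m
  }
  out
}

#' Write a labelled transition-count matrix to CSV
#' @param mat square count matrix with dimnames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(initial = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled transition-count matrix written by \code{write_matrix_csv}
#' @param path CSV file.
#' @return matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
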