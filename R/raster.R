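#' Landscape resistance rasters
#'
#' A `resistance_raster` is a regular square-pixel grid of movement
#' resistance values in \[0, 1\]: 0 means the cell poses no resistance to
#' movement (full conductance), 1 means the cell is impassable.  The grid is
#' georeferenced by the map coordinates of its lower-left corner and a cell
#' size in map units; pixels are half-open, cell (r, c) covering
#' `[x0 + (c-1)*cs, x0 + c*cs) x [y0 + (nrow-r)*cs, y0 + (nrow-r+1)*cs)`,
#' with row 1 the top row of the grid (file order).  An optional CRS string
#' is carried through unchanged; no reprojection is ever attempted, so
#' rasters and shapes must share one coordinate system.
#'
#' @param values numeric matrix of resistance values in \[0, 1\]; row 1 is
#'   the northernmost row.  `NA` cells are replaced by 1 (unknown terrain is
#'   treated as impassable).
#' @param xll,yll map coordinates of the lower-left corner of the grid.
#' @param cellsize side of a (square) pixel in map units; must be positive.
#' @param crs free-form coordinate reference tag, stored verbatim.
#' @return an object of class `resistance_raster`.
#' @examples
#' r <- resistance_raster(matrix(0, 10, 10), 0, 0, 10)
#' resistance_at(r, 55, 55)
#' @export
resistance_raster <- function(values, xll = 0, yll = 0, cellsize = 1, crs = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[is.na(values)] <- 1
  if (any(values < 0) || any(values > 1)) {
    rng <- range(values)
    stop(sprintf(
      "resistance values must lie in [0, 1]; found range [%g, %g]",
      rng[1], rng[2]
    ))
  }
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("'cellsize' must be a single positive number")
  structure(
    list(
      values = values, xll = as.numeric(xll), yll = as.numeric(yll),
      cellsize = as.numeric(cellsize), crs = as.character(crs)
    ),
    class = "resistance_raster"
  )
}

#' @export
print.resistance_raster <- function(x, ...) {
  cat(sprintf(
    "<resistance_raster> %d x %d cells, cell size %g\n  extent x: [%g, %g]  y: [%g, %g]\n  resistance range: [%g, %g]%s\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xll, x$xll + ncol(x$values) * x$cellsize,
    x$yll, x$yll + nrow(x$values) * x$cellsize,
    min(x$values), max(x$values),
    if (nzchar(x$crs)) paste0("\n  crs: ", x$crs) else ""
  ))
  invisible(x)
}

#' Extent of a raster
#'
#' @param raster a `resistance_raster`.
#' @return named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
raster_extent <- function(raster) {
  c(
    xmin = raster$xll,
    xmax = raster$xll + ncol(raster$values) * raster$cellsize,
    ymin = raster$yll,
    ymax = raster$yll + nrow(raster$values) * raster$cellsize
  )
}

#' Point lookup of resistance
#'
#' Returns the resistance of the pixel containing each point.  Any point
#' outside the raster extent returns 1: the world beyond the mapped
#' landscape is impassable, which is what keeps simulated walkers inside
#' the raster.  Cells are half-open (a point exactly on an interior cell
#' edge belongs to the cell to its right/above in map coordinates).
#'
#' @param raster a `resistance_raster`, or `NULL` for homogeneous
#'   zero-resistance space.
#' @param x,y numeric vectors of map coordinates (recycled to a common
#'   length).
#' @return numeric vector of resistance values in \[0, 1\].
#' @export
resistance_at <- function(raster, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  if (is.null(raster)) return(numeric(n))
  col <- floor((x - raster$xll) / raster$cellsize) + 1
  row <- nrow(raster$values) - floor((y - raster$yll) / raster$cellsize)
  out <- rep(1, n)
  ok <- col >= 1 & col <= ncol(raster$values) &
    row >= 1 & row <= nrow(raster$values)
  if (any(ok)) out[ok] <- raster$values[cbind(row[ok], col[ok])]
  out
}

#' Vector shapes for rasterization
#'
#' A shape couples a geometry with the resistance value it imprints on the
#' landscape.  Polygons fill their interior; lines are buffered into
#' corridors of total width `2 * buffer` (the set of points within `buffer`
#' map units of the polyline).
#'
#' @param coords two-column matrix (or data frame) of x, y vertices.  For
#'   polygons the ring is closed automatically.
#' @param resistance resistance value in \[0, 1\] imprinted by the shape.
#' @param buffer for lines, the half-width of the rasterized corridor in map
#'   units (non-negative).
#' @return a `shape_spec` object.
#' @export
shape_polygon <- function(coords, resistance) {
  new_shape("polygon", coords, resistance, buffer = 0)
}

#' @rdname shape_polygon
#' @export
shape_line <- function(coords, resistance, buffer) {
  if (!is.numeric(buffer) || length(buffer) != 1 || buffer < 0)
    stop("'buffer' must be a single non-negative number")
  new_shape("line", coords, resistance, buffer = buffer)
}

new_shape <- function(type, coords, resistance, buffer) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || nrow(coords) < 2)
    stop("'coords' must be a two-column matrix with at least two vertices")
  storage.mode(coords) <- "double"
  if (!is.numeric(resistance) || length(resistance) != 1 ||
      resistance < 0 || resistance > 1)
    stop("shape 'resistance' must be a single value in [0, 1]")
  structure(
    list(type = type, coords = coords, resistance = as.numeric(resistance),
         buffer = as.numeric(buffer)),
    class = "shape_spec"
  )
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
# Vertices on an edge are resolved by the half-open crossing rule, which is
# deterministic (good enough for cell-center tests).
points_in_polygon <- function(px, py, coords) {
  vx <- coords[, 1]; vy <- coords[, 2]
  if (vx[1] != vx[length(vx)] || vy[1] != vy[length(vy)]) {
    vx <- c(vx, vx[1]); vy <- c(vy, vy[1])
  }
  inside <- logical(length(px))
  for (i in seq_len(length(vx) - 1)) {
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[i + 1]; y2 <- vy[i + 1]
    crosses <- ((y1 <= py) != (y2 <= py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
  }
  inside
}

# Minimum distance from points to a polyline, vectorized over points.
points_dist_to_line <- function(px, py, coords) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1)) {
    ax <- coords[i, 1]; ay <- coords[i, 2]
    bx <- coords[i + 1, 1]; by <- coords[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    ex <- ax + t * dx - px
    ey <- ay + t * dy - py
    d2 <- pmin(d2, ex * ex + ey * ey)
  }
  sqrt(d2)
}

#' Build a resistance raster from vector shapes
#'
#' Rasterizes an ordered list of shapes onto a background.  Each cell takes
#' the resistance of the last shape in the list that covers its center
#' ("last wins", the usual GIS overlay semantics); cells covered by no shape
#' keep `background`.  Lines are buffered into corridors of total width
#' `2 * buffer`.  Rasterization is deterministic: the same inputs always
#' produce the same raster.
#'
#' @param shapes list of `shape_spec` objects (may be empty).
#' @param background background resistance in \[0, 1\].
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`; must be non-degenerate.
#' @param cellsize pixel size in map units.
#' @param crs optional CRS tag stored on the result.
#' @return a `resistance_raster` covering `extent` (extent is expanded to a
#'   whole number of cells if needed).
#' @examples
#' river <- shape_line(cbind(c(0, 1000), c(500, 500)), resistance = 0, buffer = 50)
#' r <- raster_from_shapes(list(river), background = 1,
#'                         extent = c(0, 1000, 0, 1000), cellsize = 10)
#' @export
raster_from_shapes <- function(shapes, background, extent, cellsize, crs = "") {
  if (length(extent) != 4) stop("'extent' must be c(xmin, xmax, ymin, ymax)")
  xmin <- extent[1]; xmax <- extent[2]; ymin <- extent[3]; ymax <- extent[4]
  if (!(xmax > xmin && ymax > ymin)) stop("'extent' is degenerate")
  if (cellsize <= 0) stop("'cellsize' must be positive")
  nc <- ceiling((xmax - xmin) / cellsize - 1e-9)
  nr <- ceiling((ymax - ymin) / cellsize - 1e-9)
  vals <- matrix(background, nr, nc)
  # cell centers, in matrix (row-major-by-column) order
  cx <- xmin + (seq_len(nc) - 0.5) * cellsize
  cy <- ymin + (nr - seq_len(nr) + 0.5) * cellsize  # row 1 = top
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)
  for (sh in shapes) {
    if (!inherits(sh, "shape_spec")) stop("'shapes' must be shape_spec objects")
    bb <- apply(sh$coords, 2, range)
    pad <- if (sh$type == "line") sh$buffer else 0
    if (bb[2, 1] + pad < xmin || bb[1, 1] - pad > xmax ||
        bb[2, 2] + pad < ymin || bb[1, 2] - pad > ymax) {
      warning("shape entirely outside the raster extent; ignored")
      next
    }
    covered <- if (sh$type == "polygon") {
      points_in_polygon(px, py, sh$coords)
    } else {
      points_dist_to_line(px, py, sh$coords) <= sh$buffer
    }
    vals[covered] <- sh$resistance
  }
  resistance_raster(vals, xll = xmin, yll = ymin, cellsize = cellsize, crs = crs)
}

#' Read and write resistance rasters
#'
#' Two on-disk formats are supported, chosen by file extension:
#' * `.asc` — ESRI ASCII grid, read and written natively.  `NODATA_value`
#'   cells become resistance 1 on read (unknown terrain is impassable).
#' * `.tif` / `.tiff` — 32-bit float TIFF via the \pkg{tiff} package, with
#'   georeferencing (origin and cell size) carried in an ESRI world file
#'   (`.tfw`) written alongside.
#'
#' Values outside \[0, 1\] after NoData substitution are a validation error:
#' rasters scaled e.g. 0–255 are rejected rather than silently rescaled.
#' A write/read round trip reproduces values, origin and cell size to the
#' format's precision (exactly, for ASCII grids written by this package).
#'
#' @param path file path ending in `.asc`, `.tif` or `.tiff`.
#' @param raster a `resistance_raster`.
#' @return `read_raster` returns a `resistance_raster`; `write_raster`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = read_ascii_grid(path),
    tif = ,
    tiff = read_tiff_raster(path),
    stop("unsupported raster format '.", ext, "' (use .asc or .tif)")
  )
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "resistance_raster"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = write_ascii_grid(raster, path),
    tif = ,
    tiff = write_tiff_raster(raster, path),
    stop("unsupported raster format '.", ext, "' (use .asc or .tif)")
  )
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header in ", path)
  if (!is.null(hdr$xllcenter)) hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if (!is.null(hdr$yllcenter)) hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, hdr$ncols * hdr$nrows, length(vals)))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  bad <- !is.na(m) & (m < 0 | m > 1)
  if (any(bad)) {
    rng <- range(m[bad])
    stop(sprintf(
      "raster %s holds values outside [0, 1] (offending range [%g, %g]); refusing to rescale",
      path, rng[1], rng[2]
    ))
  }
  resistance_raster(m, xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
                    cellsize = hdr$cellsize)
}

write_ascii_grid <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(raster$values)),
    sprintf("nrows %d", nrow(raster$values)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cellsize),
    "NODATA_value -9999"
  ), con)
  writeLines(apply(raster$values, 1, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
}

world_file_path <- function(path) sub("\\.[^.]+$", ".tfw", path)

read_tiff_raster <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF rasters requires the 'tiff' package")
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) {
    if (dim(m)[3] != 1) stop("multi-band TIFF rasters are not supported")
    m <- m[, , 1]
  }
  wf <- world_file_path(path)
  if (file.exists(wf)) {
    w <- scan(wf, quiet = TRUE)
    cellsize <- w[1]
    # world file stores the CENTER of the top-left pixel
    xll <- w[5] - cellsize / 2
    yll <- (w[6] + cellsize / 2) - nrow(m) * cellsize
  } else {
    cellsize <- 1; xll <- 0; yll <- 0
  }
  bad <- !is.na(m) & (m < 0 | m > 1)
  if (any(bad)) {
    rng <- range(m[bad])
    stop(sprintf(
      "raster %s holds values outside [0, 1] (offending range [%g, %g]); refusing to rescale",
      path, rng[1], rng[2]
    ))
  }
  resistance_raster(m, xll = xll, yll = yll, cellsize = cellsize)
}

write_tiff_raster <- function(raster, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF rasters requires the 'tiff' package")
  tiff::writeTIFF(raster$values, path, bits.per.sample = 32L,
                  compression = "none")
  cs <- raster$cellsize
  writeLines(format(c(
    cs, 0, 0, -cs,
    raster$xll + cs / 2,
    raster$yll + nrow(raster$values) * cs - cs / 2
  ), digits = 17, trim = TRUE, scientific = FALSE), world_file_path(path))
}

#' Read shapes from a GeoJSON file
#'
#' Reads `Polygon` and `LineString` features from a GeoJSON
#' FeatureCollection.  Per-feature properties `resistance` (required, in
#' \[0, 1\]) and `buffer` (lines only, default 0) control rasterization.
#' Coordinates are taken as-is; no reprojection.
#'
#' @param path path to a GeoJSON file.
#' @return list of `shape_spec` objects in file order.
#' @export
read_shapes_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  lapply(feats, function(f) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    props <- f$properties %||% list()
    res <- props$resistance
    if (is.null(res)) stop("GeoJSON feature lacks a 'resistance' property")
    co <- function(ring) do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    switch(geom$type,
      Polygon = shape_polygon(co(geom$coordinates[[1]]), res),
      LineString = shape_line(co(geom$coordinates), res,
                              buffer = as.numeric(props$buffer %||% 0)),
      stop("unsupported GeoJSON geometry type: ", geom$type)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
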