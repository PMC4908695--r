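#' Resistance raster
#'
#' A rectangular grid of positive resistance (cost) values with a map-space
#' anchor. Rows are stored north-to-south (row 1 is the top of the map, as in
#' the ESRI ASCII grid format); `origin` is the map coordinate of the
#' lower-left corner.
#'
#' @param values rows x cols numeric matrix; non-nodata values must be > 0
#'   (shortest paths need positive costs).
#' @param origin numeric xy of the lower-left corner.
#' @param cell_size cell edge length in map units (> 0).
#' @param nodata nodata marker value (default -9999).
#' @return A `resistance_raster` object.
#' @export
resistance_raster <- function(values, origin = c(0, 0), cell_size = 1,
                              nodata = -9999) {
  values <- as.matrix(values)
  if (cell_size <= 0) stop("cell_size must be positive")
  live <- values != nodata & !is.na(values)
  if (any(values[live] <= 0)) stop("non-nodata resistance values must be positive")
  structure(
    list(values = values, origin = as.numeric(origin[1:2]),
         cell_size = as.numeric(cell_size), nodata = nodata),
    class = "resistance_raster"
  )
}

#' @export
print.resistance_raster <- function(x, ...) {
  live <- x$values != x$nodata
  cat(sprintf(
    "resistance_raster: %d x %d cells (size %g), range [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$cell_size,
    min(x$values[live]), max(x$values[live])
  ))
  invisible(x)
}

# map coordinates of every cell center, as a (rows*cols) x 2 matrix in
# column-major cell order (cell id = row + (col - 1) * nrows)
cell_centers <- function(r) {
  nr <- nrow(r$values)
  nc <- ncol(r$values)
  row <- rep(seq_len(nr), nc)
  col <- rep(seq_len(nc), each = nr)
  cbind(
    x = r$origin[1] + (col - 0.5) * r$cell_size,
    y = r$origin[2] + (nr - row + 0.5) * r$cell_size
  )
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text grid exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from north
#' to south.
#'
#' @param path file path.
#' @return [read_esri_ascii()]: a [resistance_raster()].
#' @export
read_esri_ascii <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"]) {
    stop("grid body does not match header dimensions")
  }
  resistance_raster(m,
    origin = c(vals["xllcorner"], vals["yllcorner"]),
    cell_size = vals["cellsize"],
    nodata = if (is.na(vals["nodata_value"])) -9999 else vals["nodata_value"]
  )
}

#' @rdname read_esri_ascii
#' @param r a [resistance_raster()].
#' @export
write_esri_ascii <- function(r, path) {
  stopifnot(inherits(r, "resistance_raster"))
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", r$nodata)
  )
  body <- apply(r$values, 1, function(row) paste(format(row, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert habitat suitability to a resistance surface
#'
#' Resistance is the reciprocal of suitability (movement cost falls as
#' habitat quality rises), linearly rescaled to `[1, r_max]`. The
#' `"complement"` method (`1 - suitability`, same rescaling) is offered as an
#' alternative reading of "inverse"; both are monotone decreasing in
#' suitability.
#'
#' @param suitability a [resistance_raster()]-like grid or plain matrix with
#'   values in (0, 1] (nodata cells allowed).
#' @param r_max maximum resistance after rescaling (default 100).
#' @param method `"reciprocal"` (default) or `"complement"`.
#' @return A [resistance_raster()].
#' @export
invert_suitability <- function(suitability, r_max = 100,
                               method = c("reciprocal", "complement")) {
  method <- match.arg(method)
  if (inherits(suitability, "resistance_raster")) {
    m <- suitability$values
    nodata <- suitability$nodata
    origin <- suitability$origin
    cs <- suitability$cell_size
  } else {
    m <- as.matrix(suitability)
    nodata <- -9999
    origin <- c(0, 0)
    cs <- 1
  }
  live <- m != nodata & !is.na(m)
  if (any(m[live] <= 0)) stop("suitability must be positive (reciprocal undefined at 0)")
  if (any(m[live] > 1)) stop("suitability values must lie in (0, 1]")
  raw <- m
  raw[live] <- switch(method,
    reciprocal = 1 / m[live],
    complement = 1 - m[live]
  )
  rng <- range(raw[live])
  out <- m
  out[live] <- if (diff(rng) < 1e-12) {
    1
  } else {
    1 + (raw[live] - rng[1]) / diff(rng) * (r_max - 1)
  }
  resistance_raster(out, origin = origin, cell_size = cs, nodata = nodata)
}

#' Barrier feature set
#'
#' Linear barrier features (roads, power lines) given as line segments in map
#' units, with a buffer radius and a permeability tier: permeable barriers
#' take the maximum environmental resistance, low-permeable barriers take
#' 10^4 times the maximum.
#'
#' @param lines data.frame with columns `x1, y1, x2, y2` (one segment per
#'   row); may be empty.
#' @param buffer_radius buffer distance in map units (default 100).
#' @param permeability `"permeable"` or `"low_permeable"`.
#' @return A `barrier_set` object.
#' @export
barrier_set <- function(lines = NULL, buffer_radius = 100,
                        permeability = c("permeable", "low_permeable")) {
  permeability <- match.arg(permeability)
  if (is.null(lines)) {
    lines <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
  }
  stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(lines)), buffer_radius >= 0)
  structure(
    list(lines = lines, buffer_radius = buffer_radius, permeability = permeability),
    class = "barrier_set"
  )
}

# minimum distance from points (m x 2) to a segment
dist_point_segment <- function(pts, x1, y1, x2, y2) {
  vx <- x2 - x1
  vy <- y2 - y1
  len2 <- vx^2 + vy^2
  if (len2 < 1e-300) {
    return(sqrt((pts[, 1] - x1)^2 + (pts[, 2] - y1)^2))
  }
  t <- pmin(pmax(((pts[, 1] - x1) * vx + (pts[, 2] - y1) * vy) / len2, 0), 1)
  sqrt((pts[, 1] - (x1 + t * vx))^2 + (pts[, 2] - (y1 + t * vy))^2)
}

#' Impose movement barriers on a resistance surface
#'
#' Every cell whose center lies within the buffer radius of any barrier
#' segment is set to the maximum environmental resistance (permeable mode) or
#' to 10^4 times that maximum (low-permeable mode); other cells are
#' unchanged. An empty barrier set is the identity.
#'
#' @param resistance a [resistance_raster()].
#' @param barriers a [barrier_set()].
#' @return A [resistance_raster()].
#' @export
apply_barriers <- function(resistance, barriers) {
  stopifnot(inherits(resistance, "resistance_raster"), inherits(barriers, "barrier_set"))
  if (nrow(barriers$lines) == 0) {
    return(resistance)
  }
  m <- resistance$values
  live <- m != resistance$nodata & !is.na(m)
  rmax <- max(m[live])
  target <- if (barriers$permeability == "permeable") rmax else rmax * 1e4
  ctr <- cell_centers(resistance)
  hit <- rep(FALSE, nrow(ctr))
  for (s in seq_len(nrow(barriers$lines))) {
    ln <- barriers$lines[s, ]
    d <- dist_point_segment(ctr, ln$x1, ln$y1, ln$x2, ln$y2)
    hit <- hit | d <= barriers$buffer_radius
  }
  hitm <- matrix(hit, nrow(m), ncol(m))
  m[hitm & live] <- target
  resistance_raster(m,
    origin = resistance$origin, cell_size = resistance$cell_size,
    nodata = resistance$nodata
  )
}
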