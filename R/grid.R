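# Lightweight gridded-field container with plain-text (ESRI ASCII grid)
# I/O and GeoJSON polygon support. Grids are row-major from the top-left
# (row 1 = northernmost), half-open cell convention, cell membership by
# cell centre.

#' Create a gridded climate/suitability field
#'
#' @param values Numeric matrix; row 1 is the top (northern) row. `NA`
#'   marks nodata.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (grid is equal-area; same units as
#'   coordinates, conventionally metres).
#' @param crs Free-text CRS tag carried through operations.
#' @return A `climate_grid` object.
#' @export
climate_grid <- function(values, xll = 0, yll = 0, cellsize = 250,
                         crs = "local") {
  stopifnot(is.matrix(values))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("<climate_grid> ", nrow(x$values), " x ", ncol(x$values),
      " cells, cellsize ", x$cellsize, ", origin (", x$xll, ", ", x$yll,
      "), ", sum(is.na(x$values)), " nodata\n", sep = "")
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

.grid_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize)))
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `climate_grid`.
#' @return Tibble with `row`, `col`, `x`, `y` for every cell, row-major
#'   from the top-left.
#' @export
grid_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  tibble::tibble(
    row = rows, col = cols,
    x = grid$xll + (cols - 0.5) * grid$cellsize,
    y = grid$yll + (nr - rows + 0.5) * grid$cellsize
  )
}

#' Bundle per-period AT and RF grids
#'
#' @param at,rf `climate_grid`s of mean air temperature (degC) and mean
#'   daily rainfall (mm/day) sharing geometry; nodata masks must match.
#' @param period Length-2 vector labelling the averaging window (e.g.
#'   start/end dates or years).
#' @return A `climate_stack`.
#' @export
climate_stack <- function(at, rf, period = c(NA, NA)) {
  stopifnot(inherits(at, "climate_grid"), inherits(rf, "climate_grid"))
  if (!.grid_compatible(at, rf)) stop("at and rf grids differ in geometry")
  if (!identical(is.na(at$values), is.na(rf$values))) {
    stop("nodata masks differ between at and rf")
  }
  structure(list(at = at, rf = rf, period = period),
            class = "climate_stack")
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path Text file with the standard 6-line header (`ncols`,
#'   `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#'   followed by rows top-to-bottom.
#' @param crs CRS tag to attach.
#' @return A `climate_grid`.
#' @export
read_asc <- function(path, crs = "local") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
              byrow = TRUE)
  if ("nodata_value" %in% keys) m[m == vals[["nodata_value"]]] <- NA
  climate_grid(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
               cellsize = vals[["cellsize"]], crs = crs)
}

#' Write a grid as an ESRI ASCII grid (.asc)
#'
#' @param grid A `climate_grid`.
#' @param path Output file.
#' @param nodata Sentinel written for `NA` cells.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", grid$xll),
    paste("yllcorner", grid$yll),
    paste("cellsize", grid$cellsize),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read polygons from a GeoJSON file
#'
#' Supports Polygon and MultiPolygon geometries (FeatureCollection,
#' Feature, or bare geometry). Only outer rings are used; holes are
#' ignored.
#'
#' @param path GeoJSON file.
#' @return List of two-column (x, y) ring matrices.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  geoms <- if (identical(g$type, "FeatureCollection")) {
    lapply(g$features, `[[`, "geometry")
  } else if (identical(g$type, "Feature")) {
    list(g$geometry)
  } else list(g)
  rings <- list()
  ring_mat <- function(r) {
    do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
  }
  for (gm in geoms) {
    if (identical(gm$type, "Polygon")) {
      rings[[length(rings) + 1]] <- ring_mat(gm$coordinates[[1]])
    } else if (identical(gm$type, "MultiPolygon")) {
      for (p in gm$coordinates) {
        rings[[length(rings) + 1]] <- ring_mat(p[[1]])
      }
    } else {
      stop("unsupported geometry type: ", gm$type)
    }
  }
  rings
}

#' Write polygons to a GeoJSON file
#'
#' @param polygons List of two-column (x, y) ring matrices.
#' @param path Output file.
#' @export
write_geojson_polygons <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    p <- close_ring(p)
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(i) p[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

#' Point-in-polygon test against a set of polygons
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param polygons List of (x, y) ring matrices; a point is inside if it
#'   falls within any ring.
#' @return Logical vector.
#' @export
points_in_polygons <- function(x, y, polygons) {
  pts <- cbind(x, y)
  inside <- rep(FALSE, length(x))
  for (p in polygons) {
    inside <- inside | mgcv::in.out(close_ring(p), pts)
  }
  inside
}

# minimum distance from points to a polygon boundary (0 if inside)
.dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Distance from points to the nearest polygon
#'
#' Euclidean distance to the nearest polygon edge; points inside any
#' polygon get distance 0.
#'
#' @inheritParams points_in_polygons
#' @return Numeric vector of distances.
#' @export
distance_to_polygons <- function(x, y, polygons) {
  d <- rep(Inf, length(x))
  for (p in polygons) {
    p <- close_ring(p)
    for (i in seq_len(nrow(p) - 1)) {
      d <- pmin(d, .dist_point_segment(x, y, p[i, 1], p[i, 2],
                                       p[i + 1, 1], p[i + 1, 2]))
    }
  }
  d[points_in_polygons(x, y, polygons)] <- 0
  d
}
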