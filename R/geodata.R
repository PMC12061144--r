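#' Georeferenced raster grid
#'
#' Constructs a single-band georeferenced grid on a geographic (WGS84
#' longitude/latitude) lattice. Rows run north to south; cells follow the
#' pixel-is-area convention with half-open intervals `[west, east)` in
#' longitude and `(south, north]` in latitude. `origin_lon` / `origin_lat`
#' locate the *top-left corner* of the grid (west edge, north edge).
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param origin_lon,origin_lat degrees of the top-left grid corner.
#' @param cell_size cell edge length in degrees (square cells).
#' @param nodata_mask optional logical matrix, `TRUE` where nodata; merged
#'   with `is.na(values)`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_lon, origin_lat, cell_size,
                        nodata_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata_mask)) {
    nodata_mask <- is.na(values)
  } else {
    stopifnot(identical(dim(nodata_mask), dim(values)))
    nodata_mask <- nodata_mask | is.na(values)
  }
  values[nodata_mask] <- NA_real_
  if (cell_size <= 0) stop_invrisk("cell_size must be positive")
  west <- origin_lon
  east <- origin_lon + ncol(values) * cell_size
  south <- origin_lat - nrow(values) * cell_size
  if (west < -180 || east > 360 || origin_lat > 90 || south < -90) {
    stop_invrisk("grid extent outside valid geographic coordinates")
  }
  structure(
    list(values = values, nodata_mask = nodata_mask,
         origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, crs = "WGS84 lon/lat"),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid: %d rows x %d cols @ %.6g deg\n", d[1], d[2],
              x$cell_size))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              x$origin_lon, x$origin_lon + d[2] * x$cell_size,
              x$origin_lat - d[1] * x$cell_size, x$origin_lat))
  cat(sprintf("  valid cells: %d / %d\n", sum(!x$nodata_mask), length(x$values)))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a `raster_grid`.
#' @return `grid_lons()`/`grid_lats()` give the center longitude of each
#'   column / latitude of each row; `grid_coords()` gives an `n x 2` matrix
#'   of (lon, lat) centers in column-major order, matching
#'   `as.vector(grid$values)`.
#' @export
grid_lons <- function(grid) {
  grid$origin_lon + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size
}

#' @rdname grid_lons
#' @export
grid_lats <- function(grid) {
  grid$origin_lat - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size
}

#' @rdname grid_lons
#' @export
grid_coords <- function(grid) {
  lon <- grid_lons(grid)
  lat <- grid_lats(grid)
  cbind(lon = rep(lon, each = length(lat)), lat = rep(lat, times = length(lon)))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Read and write rasters as ESRI ASCII grids
#'
#' The package stores rasters in the ESRI ASCII grid format: a plain-text,
#' single-band georeferenced format with an explicit `NODATA_value` tag,
#' readable by every mainstream GIS. Values are written with 17 significant
#' digits so a write-then-read round trip reproduces the grid exactly.
#' Only geographic (lon/lat) grids are supported; files whose header implies
#' a projected CRS (coordinates outside degree ranges) are rejected with an
#' instruction to reproject.
#'
#' @param path file path of the `.asc` grid.
#' @return `read_raster()` returns a [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop_invrisk("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_invrisk("missing georeferencing in ", path, ": header must contain ",
                 paste(need, collapse = ", "))
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- hdr$xllcorner; yll <- hdr$yllcorner
  if (xll < -180 || xll + ncols * cs > 360 || yll < -90 ||
      yll + nrows * cs > 90 + 1e-9) {
    stop_invrisk("grid in ", path, " is not geographic WGS84 lon/lat; ",
                 "reproject to geographic coordinates before loading")
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  if (length(vals) != nrows * ncols) {
    stop_invrisk("expected ", nrows * ncols, " values in ", path,
                 ", found ", length(vals))
  }
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, origin_lon = xll, origin_lat = yll + nrows * cs,
              cell_size = cs)
}

#' @rdname read_raster
#' @param grid a `raster_grid` to write.
#' @param nodata numeric value standing for nodata cells in the file.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  d <- dim(grid$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.17g", grid$origin_lon),
    sprintf("yllcorner %.17g", grid$origin_lat - d[1] * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata))
  m <- grid$values
  m[is.na(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Predictor stack
#'
#' An ordered collection of aligned [raster_grid()] layers, each assigned to
#' a predictor category (`climate`, `landuse`, or `topography`). All layers
#' must share geometry (origin, cell size, shape).
#'
#' @param grids named list of `raster_grid` objects.
#' @param category named character vector mapping each predictor to one of
#'   `"climate"`, `"landuse"`, `"topography"`.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(grids, category) {
  stopifnot(length(grids) >= 1, !is.null(names(grids)),
            !anyDuplicated(names(grids)))
  if (is.null(names(category))) names(category) <- names(grids)
  category <- category[names(grids)]
  ok <- category %in% c("climate", "landuse", "topography")
  if (any(!ok | is.na(category))) {
    stop_invrisk("unknown predictor category for: ",
                 paste(names(grids)[!ok | is.na(category)], collapse = ", "))
  }
  tmpl <- grids[[1]]
  for (nm in names(grids)) {
    if (!same_geometry(grids[[nm]], tmpl)) {
      stop_invrisk("layer '", nm, "' is not aligned with '", names(grids)[1], "'")
    }
  }
  structure(list(grids = grids, category = category),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers (%s)\n", length(x$grids),
              paste(sprintf("%s: %d", names(table(x$category)),
                            as.integer(table(x$category))), collapse = ", ")))
  print(x$grids[[1]])
  invisible(x)
}

#' @export
names.predictor_stack <- function(x) names(x$grids)

stack_template <- function(stack) stack$grids[[1]]

# Combined validity mask: a cell is valid only if no layer is nodata there.
stack_valid_mask <- function(stack) {
  valid <- !stack$grids[[1]]$nodata_mask
  for (g in stack$grids[-1]) valid <- valid & !g$nodata_mask
  valid
}

# Cell-major (column-stacked) design matrix over all grid cells; invalid
# cells carry NA rows.
stack_matrix <- function(stack) {
  X <- vapply(stack$grids, function(g) as.vector(g$values),
              numeric(length(stack$grids[[1]]$values)))
  colnames(X) <- names(stack$grids)
  X
}

#' Resample one grid onto the geometry of a template
#'
#' Bilinear interpolation for continuous layers or nearest-neighbour for
#' fraction/categorical layers. Nodata propagates: a bilinear output cell is
#' nodata if any contributing source cell is nodata. Template cell centers
#' outside the source extent become nodata; a template that does not overlap
#' the source at all is an error.
#'
#' @param grid source `raster_grid`.
#' @param template `raster_grid` whose geometry the output adopts.
#' @param method `"bilinear"` or `"nearest"`.
#' @return a `raster_grid` on the template geometry.
#' @export
resample_grid <- function(grid, template, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (same_geometry(grid, template)) {
    return(raster_grid(grid$values, template$origin_lon, template$origin_lat,
                       template$cell_size))
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- grid_lons(template); lat <- grid_lats(template)
  LON <- matrix(lon, nrow = length(lat), ncol = length(lon), byrow = TRUE)
  LAT <- matrix(lat, nrow = length(lat), ncol = length(lon))
  # fractional source index of each template center, 0-based at first center
  fx <- (LON - grid$origin_lon) / grid$cell_size - 0.5
  fy <- (grid$origin_lat - LAT) / grid$cell_size - 0.5
  inside <- fx > -0.5 & fx < nc - 0.5 & fy > -0.5 & fy < nr - 0.5
  if (!any(inside)) {
    stop_invrisk("source grid and template extents do not overlap")
  }
  out <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  if (method == "nearest") {
    ix <- pmin(pmax(round(fx), 0), nc - 1)
    iy <- pmin(pmax(round(fy), 0), nr - 1)
    idx <- cbind(as.vector(iy) + 1L, as.vector(ix) + 1L)
    out[] <- grid$values[idx]
  } else {
    x0 <- pmin(pmax(floor(fx), 0), nc - 1); x1 <- pmin(x0 + 1, nc - 1)
    y0 <- pmin(pmax(floor(fy), 0), nr - 1); y1 <- pmin(y0 + 1, nr - 1)
    wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
    v00 <- grid$values[cbind(as.vector(y0) + 1L, as.vector(x0) + 1L)]
    v01 <- grid$values[cbind(as.vector(y0) + 1L, as.vector(x1) + 1L)]
    v10 <- grid$values[cbind(as.vector(y1) + 1L, as.vector(x0) + 1L)]
    v11 <- grid$values[cbind(as.vector(y1) + 1L, as.vector(x1) + 1L)]
    wxv <- as.vector(wx); wyv <- as.vector(wy)
    out[] <- (1 - wyv) * ((1 - wxv) * v00 + wxv * v01) +
      wyv * ((1 - wxv) * v10 + wxv * v11)
  }
  out[!inside] <- NA_real_
  raster_grid(out, template$origin_lon, template$origin_lat,
              template$cell_size)
}

#' Align predictor layers onto a common template
#'
#' Resamples every layer of the input stacks onto the template geometry,
#' bilinearly for continuous categories and by nearest neighbour for
#' fraction/categorical categories (which preserves the `[0, 1]` bounds of
#' land-use fractions exactly).
#'
#' @param stacks a `predictor_stack` or list of them.
#' @param template `raster_grid` defining the output geometry.
#' @param method_by_category named character vector giving the resampling
#'   method per category.
#' @return an aligned `predictor_stack`.
#' @export
align_stack <- function(stacks, template,
                        method_by_category = c(climate = "bilinear",
                                               landuse = "nearest",
                                               topography = "bilinear")) {
  if (inherits(stacks, "predictor_stack")) stacks <- list(stacks)
  grids <- list(); category <- character()
  for (st in stacks) {
    for (nm in names(st$grids)) {
      meth <- method_by_category[[st$category[[nm]]]] %||% "bilinear"
      grids[[nm]] <- tryCatch(
        resample_grid(st$grids[[nm]], template, meth),
        error = function(e) stop_invrisk("layer '", nm, "': ",
                                         conditionMessage(e)))
      category[[nm]] <- st$category[[nm]]
    }
  }
  predictor_stack(grids, category)
}

# Row/column of the cell containing each point under the half-open
# convention [west, east) x (south, north]; NA when outside the grid.
point_cell <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  u <- (grid$origin_lat - lat) / grid$cell_size
  row <- ceiling(u)
  row[u == 0] <- 1L            # north edge belongs to the top row
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1L
  bad <- row < 1 | row > nr | col < 1 | col > nc | u < 0
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract predictor values at occurrence points
#'
#' Looks up the stack cell containing each point (half-open cell intervals)
#' and returns one design-matrix row per point that falls on a cell valid in
#' every layer. Points outside the extent or on nodata cells are dropped and
#' counted.
#'
#' @param points an occurrence data frame with `lon` and `lat` columns (see
#'   [read_occurrences()]).
#' @param stack a `predictor_stack`.
#' @return list with `X` (design matrix), `points` (the retained records),
#'   `cells` (row/col per retained record), and `report` (counts of dropped
#'   points by reason).
#' @export
extract_values <- function(points, stack) {
  stopifnot(length(stack$grids) >= 1)
  tmpl <- stack_template(stack)
  rc <- point_cell(tmpl, points$lon, points$lat)
  outside <- is.na(rc[, 1])
  valid <- stack_valid_mask(stack)
  on_nodata <- rep(FALSE, nrow(points))
  inb <- which(!outside)
  if (length(inb)) {
    on_nodata[inb] <- !valid[rc[inb, , drop = FALSE]]
  }
  keep <- !outside & !on_nodata
  if (!any(keep)) stop_invrisk("no occurrence point falls on a valid cell")
  idx <- rc[keep, , drop = FALSE]
  X <- vapply(stack$grids, function(g) g$values[idx], numeric(sum(keep)))
  X <- matrix(X, nrow = sum(keep),
              dimnames = list(NULL, names(stack$grids)))
  list(X = X, points = points[keep, , drop = FALSE], cells = idx,
       report = c(n_input = nrow(points), n_kept = sum(keep),
                  n_outside = sum(outside), n_nodata = sum(on_nodata)))
}

#' Latitude-dependent spherical cell areas
#'
#' Per-cell area on the sphere, `A = R^2 * d_lambda * (sin(phi_top) -
#' sin(phi_bottom))` with `R = 6371.0088` km, so areas are constant along a
#' row and shrink toward the poles.
#'
#' @param grid a `raster_grid` (values are ignored; geometry is used).
#' @return a `raster_grid` of areas in km^2 (no nodata).
#' @export
cell_area_km2 <- function(grid) {
  d <- dim(grid$values)
  cs <- grid$cell_size
  top <- grid$origin_lat - (seq_len(d[1]) - 1) * cs
  bot <- top - cs
  dlam <- cs * pi / 180
  row_area <- EARTH_RADIUS_KM^2 * dlam *
    (sin(top * pi / 180) - sin(bot * pi / 180))
  raster_grid(matrix(row_area, nrow = d[1], ncol = d[2]),
              grid$origin_lon, grid$origin_lat, cs)
}

#' Read and write occurrence tables
#'
#' Occurrences are CSV files with header `species,lon,lat` and an optional
#' `source` column. Exact duplicate `(species, lon, lat)` triples are dropped
#' at load with a reported count, and coordinates are validated.
#'
#' @param path CSV file path.
#' @return a data frame of class `occurrence_set` with columns `species`,
#'   `lon`, `lat`, `source`; the number of duplicates dropped is attached as
#'   attribute `n_duplicates`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop_invrisk("occurrence CSV must have columns species, lon, lat")
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  occurrence_set(df[, c("species", "lon", "lat", "source")])
}

#' @rdname read_occurrences
#' @param occurrences occurrence data frame to write.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.csv(occurrences[, intersect(c("species", "lon", "lat", "source"),
                                           names(occurrences))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_occurrences
#' @param df data frame with `species`, `lon`, `lat` (and optionally
#'   `source`) columns.
#' @export
occurrence_set <- function(df) {
  if (!"source" %in% names(df)) df$source <- NA_character_
  bad <- df$lon < -180 | df$lon >= 360 | df$lat < -90 | df$lat > 90 |
    is.na(df$lon) | is.na(df$lat)
  if (any(bad)) {
    stop_invrisk(sum(bad), " occurrence record(s) with invalid coordinates")
  }
  dup <- duplicated(df[, c("species", "lon", "lat")])
  out <- df[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  class(out) <- c("occurrence_set", "data.frame")
  out
}
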