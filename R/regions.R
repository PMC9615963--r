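# Region masks: axis-aligned rectangular blocks tiling the analysis grid,
# each carrying a natural-fire dependence class (NFDC) label. Rectangles
# keep every zonal statistic checkable against a brute-force cell list, and
# serialise losslessly as GeoJSON polygons.

NFDC_CLASSES <- c("fire-dependent", "fire-independent", "fire-sensitive")

#' Construct a rectangular region mask
#'
#' @param name Region name.
#' @param nfdc_class One of `"fire-dependent"`, `"fire-independent"`,
#'   `"fire-sensitive"`.
#' @param row_range,col_range Inclusive grid row/column ranges (length-2
#'   integer vectors; rows count from the northern edge).
#' @param grid List with `nrow`, `ncol`, `xll`, `yll`, `cellsize` describing
#'   the host grid.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(name, nfdc_class, row_range, col_range, grid) {
  nfdc_class <- match.arg(nfdc_class, NFDC_CLASSES)
  structure(
    list(name = name, nfdc_class = nfdc_class,
         row_range = as.integer(row_range), col_range = as.integer(col_range),
         grid = grid),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask '%s'> %s, rows %d-%d, cols %d-%d\n",
              x$name, x$nfdc_class, x$row_range[1], x$row_range[2],
              x$col_range[1], x$col_range[2]))
  invisible(x)
}

# Linear cell indices of the region within a layer (or its own grid).
region_cell_index <- function(region, layer = NULL) {
  nr <- if (is.null(layer)) region$grid$nrow else nrow(layer$values)
  rows <- region$row_range[1]:region$row_range[2]
  cols <- region$col_range[1]:region$col_range[2]
  as.vector(outer(rows, (cols - 1L) * nr, `+`))
}

# Geographic bounding box of the region (lon/lat of the rectangle).
region_bbox <- function(region) {
  g <- region$grid
  list(
    xmin = g$xll + (region$col_range[1] - 1L) * g$cellsize,
    xmax = g$xll + region$col_range[2] * g$cellsize,
    ymin = g$yll + (g$nrow - region$row_range[2]) * g$cellsize,
    ymax = g$yll + (g$nrow - region$row_range[1] + 1L) * g$cellsize
  )
}

#' Test whether points fall inside a region
#'
#' @param lon,lat Point coordinates (degrees).
#' @param region A [region_mask()].
#' @return Logical vector.
#' @export
points_in_region <- function(lon, lat, region) {
  b <- region_bbox(region)
  lon >= b$xmin & lon < b$xmax & lat >= b$ymin & lat < b$ymax
}

#' Partition the grid into labelled regions
#'
#' Tiles the grid into `n_regions` axis-aligned blocks (as square an
#' arrangement as divides the grid) and attaches natural-fire dependence
#' class labels. The default composition for six regions is three
#' fire-dependent, one fire-independent and two fire-sensitive regions,
#' mirroring the Brazilian biome classification (Cerrado/Pampa/Pantanal
#' fire-dependent, Caatinga fire-independent, Amazon/Atlantic Forest
#' fire-sensitive).
#'
#' @param grid List with `nrow`, `ncol`, `xll`, `yll`, `cellsize`.
#' @param n_regions Number of regions, >= 2.
#' @param classes Character vector of NFDC labels, recycled/truncated to
#'   `n_regions`. Default for 6 regions: `c(rep("fire-dependent", 3),
#'   "fire-independent", rep("fire-sensitive", 2))`.
#' @param names Region names (default `region_1`, ...).
#' @return List of [region_mask()] objects that tile the grid.
#' @export
gen_regions <- function(grid, n_regions = 6L, classes = NULL, names = NULL) {
  if (n_regions < 2L) stop("need at least 2 regions", call. = FALSE)
  nb_col <- ceiling(sqrt(n_regions))
  nb_row <- ceiling(n_regions / nb_col)
  if (nb_row > grid$nrow || nb_col > grid$ncol) {
    stop("n_regions exceeds grid capacity", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- if (n_regions == 6L) {
      c(rep("fire-dependent", 3), "fire-independent", rep("fire-sensitive", 2))
    } else {
      rep_len(NFDC_CLASSES, n_regions)
    }
  }
  classes <- rep_len(classes, n_regions)
  names <- names %||% paste0("region_", seq_len(n_regions))
  # split rows into nb_row bands and cols into nb_col bands; last block in a
  # band absorbs the remainder; trailing blocks beyond n_regions are merged
  # into the final region's column range
  row_edges <- floor(seq(0L, grid$nrow, length.out = nb_row + 1L))
  col_edges <- floor(seq(0L, grid$ncol, length.out = nb_col + 1L))
  regions <- list()
  k <- 0L
  for (i in seq_len(nb_row)) {
    for (j in seq_len(nb_col)) {
      if (k == n_regions) break
      k <- k + 1L
      cr <- c(col_edges[j] + 1L, col_edges[j + 1L])
      # last region absorbs any leftover blocks in the final band
      if (k == n_regions) cr[2L] <- grid$ncol
      regions[[k]] <- region_mask(
        names[k], classes[k],
        row_range = c(row_edges[i] + 1L, row_edges[i + 1L]),
        col_range = cr, grid = grid
      )
    }
  }
  regions
}

#' Write region masks as GeoJSON
#'
#' Each region becomes a rectangular Polygon feature with `name` and
#' `nfdc_class` properties; the grid geometry travels in a `grid` property
#' so that masks round-trip exactly.
#'
#' @param regions List of [region_mask()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  features <- lapply(regions, function(r) {
    b <- region_bbox(r)
    ring <- list(
      c(b$xmin, b$ymin), c(b$xmax, b$ymin), c(b$xmax, b$ymax),
      c(b$xmin, b$ymax), c(b$xmin, b$ymin)
    )
    list(
      type = "Feature",
      properties = list(
        name = r$name, nfdc_class = r$nfdc_class,
        row_range = r$row_range, col_range = r$col_range, grid = r$grid
      ),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read region masks from GeoJSON
#'
#' @param path GeoJSON path written by [write_regions_geojson()].
#' @return List of [region_mask()] objects.
#' @export
read_regions_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    p <- f$properties
    region_mask(
      name = p$name, nfdc_class = p$nfdc_class,
      row_range = unlist(p$row_range), col_range = unlist(p$col_range),
      grid = lapply(p$grid, function(z) if (is.numeric(z)) z else as.numeric(z))
    )
  })
}
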