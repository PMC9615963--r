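# Minimal georeferenced grid container for bioclim layers.
#
# A climate_layer is a numeric matrix (row 1 = northernmost row) plus the
# lower-left corner, square cell size in degrees and an NA-coded nodata
# convention; a climate_stack is a named list of aligned layers. Layers are
# serialised as ESRI ASCII grids (.asc), a plain-text raster format.

#' Construct a georeferenced grid layer
#'
#' @param values Numeric matrix; row 1 is the northernmost row, `NA` marks
#'   nodata cells.
#' @param xll,yll Longitude/latitude of the lower-left grid corner (degrees).
#' @param cellsize Square cell size in degrees.
#' @param name Layer name (e.g. `"bio1"`).
#' @return An object of class `climate_layer`.
#' @export
climate_layer <- function(values, xll = 0, yll = 0, cellsize = 1,
                          name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         name = name),
    class = "climate_layer"
  )
}

#' @export
print.climate_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<climate_layer '%s'> %d x %d cells (%.4g deg), origin (%.4g, %.4g), range [%.4g, %.4g], %d nodata\n",
    x$name, nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
    sum(!is.finite(x$values))
  ))
  invisible(x)
}

layer_dim <- function(layer) dim(layer$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

# Cell-centre coordinates of every cell, in matrix (row-major by column) order.
layer_coords <- function(layer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(
    lon = layer$xll + (col - 0.5) * layer$cellsize,
    lat = layer$yll + (nr - row + 0.5) * layer$cellsize
  )
}

# Map lon/lat to row/col indices (NA outside the grid).
layer_rowcol <- function(layer, lon, lat) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  col <- floor((lon - layer$xll) / layer$cellsize) + 1
  row <- nr - floor((lat - layer$yll) / layer$cellsize)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at point locations
#'
#' @param layer A [climate_layer()].
#' @param lon,lat Point coordinates (degrees).
#' @return Numeric vector; `NA` outside the grid or at nodata cells.
#' @export
extract_layer <- function(layer, lon, lat) {
  rc <- layer_rowcol(layer, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc$row)
  out[ok] <- layer$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Bundle aligned layers into a climate stack
#'
#' @param layers Named list of [climate_layer()] objects on one grid.
#' @return An object of class `climate_stack` (a named list of layers).
#' @export
climate_stack <- function(layers) {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  ref <- layers[[1L]]
  for (l in layers) {
    if (!same_grid(ref, l)) stop("stack layers are not grid-aligned", call. = FALSE)
  }
  structure(layers, class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d layer(s): %s; %d x %d cells\n",
              length(x), paste(names(x), collapse = ", "),
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}

#' Extract all stack variables at point locations
#'
#' @param stack A [climate_stack()].
#' @param lon,lat Point coordinates.
#' @return Data frame with one column per layer.
#' @export
extract_stack <- function(stack, lon, lat) {
  as.data.frame(lapply(stack, extract_layer, lon = lon, lat = lat))
}

#' Cellwise ensemble mean of climate stacks
#'
#' Averages member stacks (e.g. one per general circulation model) cell by
#' cell and variable by variable. A cell that is nodata in any member is
#' nodata in the mean.
#'
#' @param stacks List of [climate_stack()] objects on identical grids with
#'   identical variable sets.
#' @return A [climate_stack()].
#' @export
gcm_ensemble_mean <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  ref <- stacks[[1L]]
  vars <- names(ref)
  for (s in stacks) {
    if (!identical(sort(names(s)), sort(vars)) || !same_grid(ref[[1]], s[[1]])) {
      stop("member stacks must share grid and variable set", call. = FALSE)
    }
  }
  out <- lapply(vars, function(v) {
    acc <- Reduce(`+`, lapply(stacks, function(s) s[[v]]$values))
    lay <- ref[[v]]
    lay$values <- acc / length(stacks)   # NA propagates through the sum
    lay
  })
  names(out) <- vars
  climate_stack(out)
}

#' Zonal mean and standard deviation of a layer
#'
#' Mean and population SD of the finite cell values inside a region mask.
#'
#' @param layer A [climate_layer()].
#' @param region A `region_mask` (see [gen_regions()]).
#' @return List with `mean`, `sd` (population, i.e. divisor `n`) and
#'   `n_cells`.
#' @export
zonal_mean_sd <- function(layer, region) {
  v <- layer$values[region_cell_index(region, layer)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, n_cells = 0L))
  }
  m <- mean(v)
  list(mean = m, sd = sqrt(mean((v - m)^2)), n_cells = length(v))
}

#' Write a layer as an ESRI ASCII grid
#'
#' @param layer A [climate_layer()].
#' @param path Output `.asc` path.
#' @param nodata Numeric value encoding `NA` on disk (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  v <- layer$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$xll),
    sprintf("yllcorner %.10g", layer$yll),
    sprintf("cellsize %.10g", layer$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @param name Layer name to attach.
#' @return A [climate_layer()] with nodata cells as `NA`.
#' @export
read_ascii_grid <- function(path, name = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  v <- do.call(rbind, vals)
  stopifnot(nrow(v) == hdr$nrows, ncol(v) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA_real_
  climate_layer(v, xll = hdr$xllcorner, yll = hdr$yllcorner,
                cellsize = hdr$cellsize, name = name)
}
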