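# Occurrence handling: the cleaning -> thinning -> subsampling cascade that
# turns a raw fire-point table into modelling presences, with per-point
# provenance flags so every removal is auditable.

FLAG_COLS <- c("duplicate", "outside_boundary", "thinned", "subsampled")

#' Fire-occurrence point set
#'
#' A data frame of points (`lon`, `lat`, `date`) plus logical provenance
#' flags recording why a point was removed at each filtering stage. A point
#' is "active" while all flags are `FALSE`.
#'
#' @param points Data frame with at least `lon` and `lat` (degrees; `date`
#'   optional).
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(points) {
  stopifnot(is.data.frame(points), all(c("lon", "lat") %in% names(points)))
  if (!"date" %in% names(points)) points$date <- NA
  if (any(points$lon < -180 | points$lon > 180, na.rm = TRUE) ||
      any(points$lat < -90 | points$lat > 90, na.rm = TRUE)) {
    stop("coordinates outside [-180,180] x [-90,90]", call. = FALSE)
  }
  for (f in FLAG_COLS) if (!f %in% names(points)) points[[f]] <- FALSE
  structure(list(points = points, log = list()), class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d points, %d active\n",
              nrow(x$points), nrow(active_points(x))))
  for (nm in names(x$log)) cat(sprintf("  %s: %s\n", nm, x$log[[nm]]))
  invisible(x)
}

#' Points that survived every filtering stage
#'
#' @param occ An [occurrence_set()].
#' @return Data frame of unflagged points.
#' @export
active_points <- function(occ) {
  flags <- as.matrix(occ$points[FLAG_COLS])
  occ$points[rowSums(flags) == 0, c("lon", "lat", "date"), drop = FALSE]
}

#' Remove duplicate and out-of-boundary occurrences
#'
#' Collapses exact coordinate duplicates to a single point and flags points
#' falling outside the study boundary; counts of each removal are logged.
#'
#' @param occ An [occurrence_set()].
#' @param boundary A [region_mask()] or list of masks whose union is the
#'   study boundary.
#' @return The filtered [occurrence_set()].
#' @export
clean_occurrences <- function(occ, boundary) {
  pts <- occ$points
  dup <- duplicated(pts[, c("lon", "lat")]) & !pts$duplicate
  pts$duplicate <- pts$duplicate | dup
  if (inherits(boundary, "region_mask")) boundary <- list(boundary)
  inside <- Reduce(`|`, lapply(boundary, function(b) {
    points_in_region(pts$lon, pts$lat, b)
  }))
  out <- !inside & !pts$outside_boundary
  pts$outside_boundary <- pts$outside_boundary | out
  occ$points <- pts
  occ$log$clean <- sprintf("%d duplicate, %d outside boundary removed",
                           sum(dup), sum(out))
  if (nrow(active_points(occ)) == 0L) {
    stop("no occurrences left after cleaning; check boundary and inputs",
         call. = FALSE)
  }
  occ
}

# Great-circle distance (m) between one point and many, haversine on a
# spherical Earth; used for the bounding-box prefiltered greedy thinning.
haversine_m <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  geosphere::distHaversine(c(lon1, lat1), cbind(lon2, lat2), r = r)
}

#' Spatially thin occurrences to a minimum separation
#'
#' Greedy acceptance over a seed-shuffled ordering: a point is kept iff its
#' great-circle (haversine) distance to every previously kept point is at
#' least `min_km`. The retained set therefore certifies the pairwise
#' distance rule by construction.
#'
#' @param occ An [occurrence_set()].
#' @param min_km Minimum pairwise separation in kilometres (> 0).
#' @param seed Integer seed for the acceptance order.
#' @return The thinned [occurrence_set()] (rejections flagged `thinned`).
#' @export
thin_points <- function(occ, min_km = 10, seed = 1L) {
  stopifnot(min_km > 0)
  pts <- occ$points
  act <- which(rowSums(as.matrix(pts[FLAG_COLS])) == 0)
  ord <- with_seed(seed, sample(act))
  min_m <- min_km * 1000
  # bounding-box prefilter: 1 deg latitude ~ 111.2 km; longitude shrinks
  # with cos(lat) -- use the loosest (equatorial) bound, which is safe
  deg_tol <- min_km / 111.2 * 1.05
  keep_lon <- numeric(0); keep_lat <- numeric(0)
  rejected <- integer(0)
  for (i in ord) {
    lo <- pts$lon[i]; la <- pts$lat[i]
    near <- which(abs(keep_lat - la) < deg_tol &
                    abs(keep_lon - lo) < deg_tol / max(cos(la * pi / 180), 0.05))
    ok <- length(near) == 0L ||
      all(haversine_m(lo, la, keep_lon[near], keep_lat[near]) >= min_m)
    if (ok) {
      keep_lon <- c(keep_lon, lo); keep_lat <- c(keep_lat, la)
    } else {
      rejected <- c(rejected, i)
    }
  }
  pts$thinned[rejected] <- TRUE
  occ$points <- pts
  occ$log$thin <- sprintf("%d points removed by %g-km thinning",
                          length(rejected), min_km)
  occ
}

#' Randomly subsample active occurrences
#'
#' Uniform sample without replacement of `round(fraction * n)` active
#' points; the rest are flagged `subsampled`.
#'
#' @param occ An [occurrence_set()].
#' @param fraction Proportion to keep, in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled [occurrence_set()].
#' @export
subsample_occurrences <- function(occ, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  pts <- occ$points
  act <- which(rowSums(as.matrix(pts[FLAG_COLS])) == 0)
  n_keep <- round(fraction * length(act))
  if (n_keep == 0L) stop("subsample would keep zero points", call. = FALSE)
  keep <- with_seed(seed, sample(act, n_keep))
  pts$subsampled[setdiff(act, keep)] <- TRUE
  occ$points <- pts
  occ$log$subsample <- sprintf("kept %d of %d (fraction %g)",
                               n_keep, length(act), fraction)
  occ
}

#' Sample pseudoabsence points
#'
#' Uniform random draw of grid cells with valid climate values, excluding
#' every cell that contains a presence; pseudoabsences sit at cell centres.
#'
#' @param stack A [climate_stack()].
#' @param n Number of pseudoabsences (default 10000), or `"prevalence"` to
#'   match the number of active presences.
#' @param presences An [occurrence_set()] whose active points define the
#'   excluded cells.
#' @param seed Integer seed.
#' @return An [occurrence_set()] of pseudoabsences.
#' @export
sample_pseudoabsences <- function(stack, n = 10000L, presences, seed = 1L) {
  ref <- stack[[1L]]
  pres <- active_points(presences)
  rc <- layer_rowcol(ref, pres$lon, pres$lat)
  pres_cells <- unique((rc$col - 1L) * nrow(ref$values) + rc$row)
  valid <- which(Reduce(`&`, lapply(stack, function(l) is.finite(l$values))))
  candidates <- setdiff(valid, pres_cells)
  if (identical(n, "prevalence")) n <- nrow(pres)
  n <- as.integer(n)
  if (length(candidates) < n) {
    stop(sprintf("only %d candidate cells for %d pseudoabsences",
                 length(candidates), n), call. = FALSE)
  }
  cells <- with_seed(seed, sample(candidates, n))
  coords <- layer_coords(ref)
  occurrence_set(data.frame(lon = coords$lon[cells], lat = coords$lat[cells],
                            date = NA))
}
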