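# Brute-force oracles kept independent of the implementation paths they
# check, plus tiny fixture builders.

# Haversine great-circle distance in metres, written from the formula.
oracle_haversine_m <- function(lon1, lat1, lon2, lat2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Naive per-box DFA fluctuation: explicit loop over forward and backward
# box segmentations, lm() per box.
oracle_fluctuation <- function(profile, s) {
  one_pass <- function(prof) {
    n <- length(prof)
    nb <- n %/% s
    sq <- numeric(0)
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * s + 1):(b * s)
      seg <- prof[idx]
      t <- seq_len(s)
      fit <- stats::lm(seg ~ t)
      sq <- c(sq, stats::residuals(fit)^2)
    }
    mean(sq)
  }
  sqrt((one_pass(profile) + one_pass(rev(profile))) / 2)
}

# Cell-list zonal mean/SD (population SD), explicit loop.
oracle_zonal <- function(layer, region) {
  vals <- c()
  for (row in region$row_range[1]:region$row_range[2]) {
    for (col in region$col_range[1]:region$col_range[2]) {
      v <- layer$values[row, col]
      if (is.finite(v)) vals <- c(vals, v)
    }
  }
  m <- sum(vals) / length(vals)
  list(mean = m, sd = sqrt(sum((vals - m)^2) / length(vals)))
}

# Small aligned constant-valued layer/stack builders.
const_layer <- function(value, nr = 8, nc = 8, name = "x") {
  climate_layer(matrix(value, nr, nc), xll = 0, yll = 0, cellsize = 0.5,
                name = name)
}

const_stack <- function(values = c(bio1 = 20, bio9 = 24, bio12 = 1200,
                                   bio17 = 120), nr = 8, nc = 8) {
  climate_stack(mapply(function(v, nm) const_layer(v, nr, nc, nm),
                       values, names(values), SIMPLIFY = FALSE))
}

toy_grid <- function(nr = 8, nc = 8) {
  list(nrow = nr, ncol = nc, xll = 0, yll = 0, cellsize = 0.5)
}
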