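#' Construct a seascape stack
#'
#' A seascape stack holds co-registered environmental covariate layers on a
#' regular projected grid together with a land mask. Layers are matrices of
#' dimension `nx x ny`; cell `[i, j]` has its centre at
#' `origin + (c(i, j) - 0.5) * cell`. Marine layers carry `NA` on land cells.
#'
#' @param origin numeric length-2, projected coordinates (m) of the grid's
#'   lower-left corner.
#' @param cell cell size in metres.
#' @param layers named list of `nx x ny` matrices. Conventional layer names:
#'   `depth` (m, positive down), `slope` (degrees), `sst` (deg C), `ice`
#'   (concentration fraction, 0--1), `ssh` (m), `dist_shelf` (km),
#'   `dist_glacier` (km), `dist_ice_edge` (km, signed; negative inside the
#'   ice edge).
#' @param land logical `nx x ny` matrix, `TRUE` on land.
#' @param time_layers optional named list of layers that vary by month: each
#'   element is a list of 12 matrices.
#' @return object of class `seascape_stack`.
#' @export
seascape_stack <- function(origin, cell, layers, land,
                           time_layers = NULL) {
  stopifnot(length(origin) == 2, cell > 0, is.list(layers),
            length(layers) >= 1, is.matrix(land), is.logical(land))
  dm <- dim(land)
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dm))
      stop("layer '", nm, "' does not share the grid geometry")
  }
  if (!is.null(layers$ice)) {
    v <- layers$ice[!land]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("ice concentration must lie in [0, 1]")
  }
  if (!is.null(layers$depth)) {
    if (any(layers$depth[!land] < 0, na.rm = TRUE))
      stop("depth must be >= 0 on sea cells")
  }
  structure(list(origin = as.numeric(origin), cell = cell,
                 nx = dm[1], ny = dm[2], layers = layers, land = land,
                 time_layers = time_layers),
            class = "seascape_stack")
}

#' @export
print.seascape_stack <- function(x, ...) {
  cat("seascape_stack:", x$nx, "x", x$ny, "cells of", x$cell, "m\n")
  cat("  origin:", format(x$origin, big.mark = ","), "\n")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  land fraction: %.3f\n", mean(x$land)))
  invisible(x)
}

# separable Gaussian smoothing with edge replication
gauss_smooth <- function(M, sigma) {
  w <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-w, w), sd = sigma)
  k <- k / sum(k)
  sm1 <- function(v) {
    p <- c(rep(v[1], w), v, rep(v[length(v)], w))
    as.numeric(stats::filter(p, k, sides = 2))[(w + 1):(w + length(v))]
  }
  M <- apply(M, 2, sm1)
  t(apply(M, 1, sm1))
}

# Euclidean distance (m) from query cell centres to the nearest member of a
# target cell set; brute force, adequate at the grid sizes used here.
dist_to_set <- function(qx, qy, sx, sy) {
  if (length(sx) == 0) return(rep(NA_real_, length(qx)))
  d2 <- outer(qx, sx, "-")^2 + outer(qy, sy, "-")^2
  sqrt(d2[cbind(seq_along(qx), max.col(-d2, ties.method = "first"))])
}

cell_centres <- function(ss) {
  list(x = ss$origin[1] + (seq_len(ss$nx) - 0.5) * ss$cell,
       y = ss$origin[2] + (seq_len(ss$ny) - 0.5) * ss$cell)
}

# boundary cells of a logical mask: TRUE cells with a 4-neighbour FALSE
mask_boundary <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  nb <- (!pad[1:nx, 2:(ny + 1)]) | (!pad[3:(nx + 2), 2:(ny + 1)]) |
        (!pad[2:(nx + 1), 1:ny]) | (!pad[2:(nx + 1), 3:(ny + 2)])
  m & nb
}

#' Generate a synthetic Arctic seascape
#'
#' Builds spatially autocorrelated covariate fields over a projected grid:
#' a contiguous land block along the western edge with a wiggly coast, a
#' shelf-like depth gradient deepening eastward, a meridional SST ramp
#' (colder north), an ice-concentration field with a definable ice edge
#' (more ice north), sea-surface height anomalies, and derived distance
#' layers (to the 500 m shelf break, to glacier-front coastal cells, and
#' signed distance to the 15% ice-concentration edge, negative inside).
#' All stochastic structure is Gaussian-smoothed noise; the result is
#' deterministic for a given seed.
#'
#' @param nx,ny grid dimension in cells (>= 16).
#' @param cell cell size in metres.
#' @param seed integer RNG seed.
#' @param land_frac target land-cell fraction of the grid (0 to 0.5).
#' @param smoothness smoothing length scale in cells for the noise fields.
#' @param origin grid origin (lower-left corner, projected metres).
#' @param ice_edge_threshold ice concentration defining the ice edge.
#' @return [seascape_stack] with layers `depth`, `slope`, `sst`, `ice`,
#'   `ssh`, `dist_shelf`, `dist_glacier`, `dist_ice_edge`.
#' @export
#' @examples
#' ss <- generate_seascape(nx = 32, ny = 32, cell = 8000, seed = 1)
#' print(ss)
generate_seascape <- function(nx = 64, ny = 64, cell = 8000, seed,
                              land_frac = 0.15, smoothness = 4,
                              origin = c(-256000, -1450000),
                              ice_edge_threshold = 0.15) {
  if (nx < 16 || ny < 16) stop("grid must be at least 16 x 16 cells")
  if (land_frac < 0 || land_frac > 0.5)
    stop("land_frac must lie in [0, 0.5]")
  if (missing(seed)) stop("a seed is required")
  with_seed(seed, {
    xr <- matrix(rep(seq_len(nx) / nx, ny), nx, ny)          # 0..1 west->east
    yr <- matrix(rep(seq_len(ny) / ny, each = nx), nx, ny)   # 0..1 south->north
    noise <- function(amp) amp * {
      z <- gauss_smooth(matrix(rnorm(nx * ny), nx, ny), smoothness)
      z / max(sd(z), 1e-12)
    }

    # land along the west edge: gradient + noise, thresholded at the exact
    # requested land share
    base <- -xr + noise(0.35)
    land <- base > quantile(base, 1 - land_frac)

    # depth: distance-from-coast driven shelf ramp; quadratic mapping keeps a
    # broad shallow shelf before the slope drops to abyssal depths
    elev <- (quantile(base, 1 - land_frac) - base)
    elev[elev < 0] <- 0
    u <- elev / max(elev)
    depth <- 20 + 4200 * u^2 + 150 * abs(noise(1))
    depth[land] <- NA

    # slope (degrees) from centred differences of depth
    dz_dx <- depth * NA; dz_dy <- depth * NA
    dz_dx[2:(nx - 1), ] <- (depth[3:nx, ] - depth[1:(nx - 2), ]) / (2 * cell)
    dz_dy[, 2:(ny - 1)] <- (depth[, 3:ny] - depth[, 1:(ny - 2)]) / (2 * cell)
    slope <- atan(sqrt(ifelse(is.na(dz_dx), 0, dz_dx)^2 +
                       ifelse(is.na(dz_dy), 0, dz_dy)^2)) * 180 / pi
    slope[land] <- NA

    sst <- 5 - 7 * yr + noise(1.2)
    sst[land] <- NA

    ice <- matrix(pmin(1, pmax(0, 1.4 * yr - 0.35 + noise(0.35))), nx, ny)
    ice[land] <- NA

    ssh <- noise(0.12)
    ssh[land] <- NA

    cc <- cell_centres(ss = list(origin = origin, cell = cell, nx = nx,
                                 ny = ny))
    cx <- matrix(rep(cc$x, ny), nx, ny)
    cy <- matrix(rep(cc$y, each = nx), nx, ny)
    sea <- !land

    # distance to shelf break (500 m isobath), km
    deep <- !is.na(depth) & depth >= 500
    brk <- mask_boundary(deep) & sea
    dist_shelf <- matrix(NA_real_, nx, ny)
    dist_shelf[sea] <- dist_to_set(cx[sea], cy[sea], cx[brk], cy[brk]) / 1000

    # glacier fronts: a seeded subset of coastal land cells
    coast <- mask_boundary(land)
    gl_sel <- coast & (noise(1) > 0.3)
    if (!any(gl_sel)) gl_sel <- coast
    dist_glacier <- matrix(NA_real_, nx, ny)
    dist_glacier[sea] <- dist_to_set(cx[sea], cy[sea], cx[gl_sel],
                                     cy[gl_sel]) / 1000

    # signed distance to ice edge, negative inside (ice >= threshold)
    inside <- !is.na(ice) & ice >= ice_edge_threshold
    edge <- mask_boundary(inside) & sea
    dist_ice_edge <- matrix(NA_real_, nx, ny)
    d <- dist_to_set(cx[sea], cy[sea], cx[edge], cy[edge]) / 1000
    dist_ice_edge[sea] <- ifelse(inside[sea], -d, d)

    seascape_stack(origin = origin, cell = cell,
                   layers = list(depth = depth, slope = slope, sst = sst,
                                 ice = ice, ssh = ssh,
                                 dist_shelf = dist_shelf,
                                 dist_glacier = dist_glacier,
                                 dist_ice_edge = dist_ice_edge),
                   land = land)
  })
}

# grid indices for projected coordinates; error on out-of-extent points
# unless clamped to the nearest edge cell
cell_index <- function(ss, x, y, what = "location", clamp = FALSE) {
  i <- floor((x - ss$origin[1]) / ss$cell) + 1L
  j <- floor((y - ss$origin[2]) / ss$cell) + 1L
  if (clamp) {
    i <- pmin(pmax(i, 1L), ss$nx)
    j <- pmin(pmax(j, 1L), ss$ny)
  }
  bad <- which(i < 1L | i > ss$nx | j < 1L | j > ss$ny | !is.finite(x) |
                 !is.finite(y))
  if (length(bad))
    stop(what, " outside raster extent at rows: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  cbind(i, j)
}

is_land_at <- function(ss, x, y) {
  ij <- cell_index(ss, x, y)
  ss$land[ij]
}

#' Extract covariate values at point locations
#'
#' Nearest-cell lookup of one or more seascape layers. Points falling on a
#' land cell are (optionally) assigned the value of the nearest sea cell,
#' which keeps near-coast track locations usable.
#'
#' @param ss a [seascape_stack].
#' @param x,y projected coordinates (metres).
#' @param layers character vector of layer names (default: all).
#' @param month optional month (1--12) to select a time slice for layers
#'   present in `ss$time_layers`.
#' @param nearest_sea logical; substitute the nearest sea cell for land cells.
#' @param clamp logical; snap out-of-extent points to the nearest edge cell
#'   instead of raising an error.
#' @return data.frame, one column per layer.
#' @export
extract_covariates <- function(ss, x, y, layers = names(ss$layers),
                               month = NULL, nearest_sea = TRUE,
                               clamp = FALSE) {
  unknown <- setdiff(layers, names(ss$layers))
  if (length(unknown))
    stop("unknown covariate layer(s): ", paste(unknown, collapse = ", "))
  ij <- cell_index(ss, x, y, clamp = clamp)
  if (nearest_sea) {
    onland <- which(ss$land[ij])
    if (length(onland)) {
      cc <- cell_centres(ss)
      sea_idx <- which(!ss$land, arr.ind = TRUE)
      sx <- cc$x[sea_idx[, 1]]; sy <- cc$y[sea_idx[, 2]]
      for (r in onland) {
        d2 <- (sx - x[r])^2 + (sy - y[r])^2
        ij[r, ] <- sea_idx[which.min(d2), ]
      }
    }
  }
  out <- lapply(layers, function(nm) {
    M <- ss$layers[[nm]]
    if (!is.null(month) && !is.null(ss$time_layers[[nm]]))
      M <- ss$time_layers[[nm]][[month]]
    M[ij]
  })
  names(out) <- layers
  as.data.frame(out)
}

#' Write seascape layers as ESRI ASCII grids
#'
#' One plain-text `.asc` file per layer plus `land.asc` (0/1), readable by
#' standard GIS software.
#'
#' @param ss a [seascape_stack].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_seascape <- function(ss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- c(ss$layers, list(land = ss$land * 1))
  paths <- character(0)
  for (nm in names(lay)) {
    M <- lay[[nm]]
    f <- file.path(dir, paste0(nm, ".asc"))
    con <- file(f, "w")
    writeLines(c(paste("ncols", ss$nx), paste("nrows", ss$ny),
                 paste("xllcorner", ss$origin[1]),
                 paste("yllcorner", ss$origin[2]),
                 paste("cellsize", ss$cell),
                 "NODATA_value -9999"), con)
    # ASCII grid rows run north to south
    for (j in rev(seq_len(ss$ny))) {
      v <- M[, j]
      v[is.na(v)] <- -9999
      writeLines(paste(format(v, trim = TRUE), collapse = " "), con)
    }
    close(con)
    paths <- c(paths, f)
  }
  invisible(paths)
}
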