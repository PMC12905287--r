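## Kernel utilization distributions, ad-hoc bandwidth selection, contour
## areas, Bhattacharyya overlap between UDs, and hotspot condition tests.

#' Kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian kernel density of point locations evaluated at cell
#' centres and renormalized so that `sum(density) * cell^2 = 1`. The grid is
#' the point bounding box padded by four bandwidths, which keeps the
#' truncated kernel mass below the normalization tolerance.
#'
#' @param points data.frame with `x`, `y` (projected metres).
#' @param bandwidth isotropic kernel SD (same units as coordinates).
#' @param cell grid cell size (default 8,000 m).
#' @param pad padding in bandwidths around the bounding box.
#' @return object of class `ud_grid`: `origin`, `cell`, `density`
#'   (nx x ny matrix, probability per unit area), `n_points`, `bandwidth`.
#' @export
kde_ud <- function(points, bandwidth, cell = 8000, pad = 4) {
  if (nrow(points) == 0) stop("no points supplied")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  x <- points$x; y <- points$y
  x0 <- min(x) - pad * bandwidth
  y0 <- min(y) - pad * bandwidth
  nx <- max(2L, ceiling((max(x) + pad * bandwidth - x0) / cell))
  ny <- max(2L, ceiling((max(y) + pad * bandwidth - y0) / cell))
  cx <- x0 + (seq_len(nx) - 0.5) * cell
  cy <- y0 + (seq_len(ny) - 0.5) * cell
  # separable kernel: D[i,j] = (1/n) sum_k dnorm(cx_i; x_k) dnorm(cy_j; y_k)
  A <- vapply(x, function(xk) dnorm(cx, xk, bandwidth), numeric(nx))
  B <- vapply(y, function(yk) dnorm(cy, yk, bandwidth), numeric(ny))
  D <- (A %*% t(B)) / length(x)
  tot <- sum(D) * cell^2
  if (!is.finite(tot) || tot <= 0)
    stop("kernel mass underflow: bandwidth too small for the grid cell size")
  D <- D / tot
  structure(list(origin = c(x0, y0), cell = cell, density = D,
                 n_points = length(x), bandwidth = bandwidth),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("ud_grid: %d x %d cells of %g m, %d points, h = %.1f\n",
              nrow(x$density), ncol(x$density), x$cell, x$n_points,
              x$bandwidth))
  invisible(x)
}

#' @export
plot.ud_grid <- function(x, ...) {
  cx <- x$origin[1] + (seq_len(nrow(x$density)) - 0.5) * x$cell
  cy <- x$origin[2] + (seq_len(ncol(x$density)) - 0.5) * x$cell
  image(cx, cy, x$density, col = hcl.colors(64, "viridis"),
        xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

# label 8-connected components of a logical matrix; returns component count
count_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((p - 1L) %% nx) + 1L
      j <- ((p - 1L) %/% nx) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nx && jj >= 1L && jj <= ny) {
          q <- (jj - 1L) * nx + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  cur
}

# smallest cell set holding at least `level` of the UD mass
# (deterministic tie-break by cell index)
level_cells <- function(ud, level) {
  p <- as.numeric(ud$density) * ud$cell^2
  ord <- order(-p, seq_along(p))
  k <- which(cumsum(p[ord]) >= level)[1]
  ord[seq_len(k)]
}

#' Ad-hoc kernel bandwidth selection by home-range fragmentation
#'
#' Starts from the bivariate normal reference bandwidth
#' `h_ref = sqrt((var_x + var_y)/2) * n^(-1/6)` and evaluates the multipliers
#' 1.0, 0.9, ..., 0.1. At each multiplier the number of 8-connected
#' components of the 95% utilization contour is counted; the selected
#' multiplier is the smallest one before the component count first exceeds
#' the baseline count at 1.0 (i.e. before the otherwise contiguous home
#' range begins to separate). If the home range never fragments the
#' multiplier 0.1 is returned.
#'
#' @param points data.frame with `x`, `y`; at least 30 points.
#' @param cell evaluation grid cell size; default `h_ref / 4`.
#' @param level contour level used to judge fragmentation.
#' @return list: `h_ref`, `multiplier`, `bandwidth`, and `trace`
#'   (data.frame of multiplier, bandwidth, components).
#' @export
select_bandwidth <- function(points, cell = NULL, level = 0.95) {
  n <- nrow(points)
  if (n < 30) stop("at least 30 points are required")
  S <- cov(cbind(points$x, points$y))
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <
      1e-10 * max(diag(S)))
    stop("degenerate (collinear or constant) point configuration")
  h_ref <- sqrt((S[1, 1] + S[2, 2]) / 2) * n^(-1 / 6)
  if (is.null(cell)) cell <- h_ref / 4
  mults <- seq(1, 0.1, by = -0.1)
  comps <- integer(length(mults))
  for (k in seq_along(mults)) {
    ud <- kde_ud(points, bandwidth = mults[k] * h_ref, cell = cell)
    mask <- matrix(FALSE, nrow(ud$density), ncol(ud$density))
    mask[level_cells(ud, level)] <- TRUE
    comps[k] <- count_components(mask)
  }
  baseline <- comps[1]
  sel <- 1L
  for (k in seq_along(mults)) {
    if (comps[k] > baseline) break
    sel <- k
  }
  list(h_ref = h_ref, multiplier = mults[sel],
       bandwidth = mults[sel] * h_ref,
       trace = data.frame(multiplier = mults, bandwidth = mults * h_ref,
                          components = comps))
}

#' Utilization-distribution contour areas
#'
#' For each mass level the smallest set of cells whose summed probability
#' reaches the level (ties broken by cell index); area is cell count times
#' cell area, the component count uses 8-connectivity, and boundary polygons
#' are traced from the binary cell mask.
#'
#' @param ud a [kde_ud()] grid.
#' @param levels mass fractions (default home range 0.95, core 0.50,
#'   hotspot 0.25).
#' @return object of class `contour_set`: `table` (level, n_cells, area_km2,
#'   n_components), `cells` (list of cell index vectors), `polygons` (list
#'   of coordinate rings per level).
#' @export
contour_areas <- function(ud, levels = c(0.95, 0.50, 0.25)) {
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  cells <- list(); polys <- list()
  tab <- data.frame(level = levels, n_cells = NA_integer_,
                    area_km2 = NA_real_, n_components = NA_integer_)
  nx <- nrow(ud$density); ny <- ncol(ud$density)
  cx <- ud$origin[1] + (seq_len(nx) - 0.5) * ud$cell
  cy <- ud$origin[2] + (seq_len(ny) - 0.5) * ud$cell
  for (k in seq_along(levels)) {
    cl <- level_cells(ud, levels[k])
    mask <- matrix(FALSE, nx, ny)
    mask[cl] <- TRUE
    tab$n_cells[k] <- length(cl)
    tab$area_km2[k] <- length(cl) * ud$cell^2 / 1e6
    tab$n_components[k] <- count_components(mask)
    cells[[k]] <- cl
    polys[[k]] <- lapply(contourLines(cx, cy, mask * 1, levels = 0.5),
                         function(l) data.frame(x = l$x, y = l$y))
  }
  names(cells) <- names(polys) <- paste0("p", levels * 100)
  structure(list(table = tab, cells = cells, polygons = polys,
                 cell = ud$cell, origin = ud$origin,
                 dim = c(nx, ny)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Bhattacharyya affinity between two utilization distributions
#'
#' Each UD is masked to its own level contour (cells outside the contour set
#' to zero, and the retained mass normalized to exactly the level, so two
#' identical UDs attain the maximum). The affinity is
#' `BA = sum(sqrt(p_a * p_b))` over cells, bounded by the level, and the
#' rescaled value divides by the level to give a 0--1 index.
#'
#' @param ud_a,ud_b [kde_ud()] grids on identical geometry.
#' @param level masking level (home range 0.95 or core area 0.50).
#' @param labels optional character pair naming the two distributions.
#' @return data.frame: labels, level, `ba` (raw), `ba_rescaled`.
#' @export
bhattacharyya_overlap <- function(ud_a, ud_b, level = 0.95,
                                  labels = c("a", "b")) {
  if (!isTRUE(all.equal(ud_a$origin, ud_b$origin)) ||
      ud_a$cell != ud_b$cell ||
      !identical(dim(ud_a$density), dim(ud_b$density)))
    stop("utilization distributions are on different grids")
  mask_p <- function(ud) {
    p <- as.numeric(ud$density) * ud$cell^2
    keep <- level_cells(ud, level)
    q <- numeric(length(p))
    q[keep] <- p[keep]
    q * (level / sum(q))
  }
  pa <- mask_p(ud_a)
  pb <- mask_p(ud_b)
  ba <- sum(sqrt(pa * pb))
  data.frame(a = labels[1], b = labels[2], level = level, ba = ba,
             ba_rescaled = ba / level)
}

#' Wilcoxon rank-sum test with exact enumeration under ties
#'
#' Two-sided Mann-Whitney test. For `min(n) <= 10` (and a manageable
#' enumeration size) the null distribution of the rank-sum statistic is
#' enumerated exactly over all assignments using midranks, so exact p-values
#' remain valid with ties; otherwise the normal approximation with tie
#' correction is used. The statistic is
#' `W = sum(ranks of x) - n1 (n1 + 1) / 2`.
#'
#' @param x,y numeric samples.
#' @return list: `W`, `p_value`, `method`.
#' @export
wilcox_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (min(n1, n2) <= 10 && choose(N, n1) <= 2e5) {
    cmb <- combn(N, n1)
    ws <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
    method <- "exact enumeration (midranks)"
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(W = W, p_value = p, method = method)
}

# even-odd ray-casting point-in-polygon
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Compare environmental conditions inside vs outside a hotspot
#'
#' Wilcoxon rank-sum comparison of covariate values at locations inside a
#' hotspot contour against those outside it.
#'
#' @param locations data.frame with `x`, `y` and covariate columns.
#' @param hotspot either a polygon data.frame (`x`, `y` ring) or a logical
#'   vector flagging inside locations.
#' @param covariates character vector of covariate column names (default:
#'   all numeric columns except `x`, `y`).
#' @return data.frame per covariate: `n_inside`, `n_outside`,
#'   `median_inside`, `median_outside`, `W`, `p_value`.
#' @export
compare_hotspot_conditions <- function(locations, hotspot,
                                       covariates = NULL) {
  inside <- if (is.logical(hotspot)) hotspot else
    point_in_polygon(locations$x, locations$y, hotspot)
  if (sum(inside) < 2 || sum(!inside) < 2)
    stop("need at least 2 locations on each side of the hotspot boundary")
  if (is.null(covariates)) {
    covariates <- setdiff(names(locations)[vapply(locations, is.numeric,
                                                  TRUE)], c("x", "y"))
  }
  do.call(rbind, lapply(covariates, function(cv) {
    a <- locations[[cv]][inside]
    b <- locations[[cv]][!inside]
    keep_a <- is.finite(a); keep_b <- is.finite(b)
    t <- wilcox_exact(a[keep_a], b[keep_b])
    data.frame(covariate = cv, n_inside = sum(keep_a),
               n_outside = sum(keep_b),
               median_inside = median(a[keep_a]),
               median_outside = median(b[keep_b]),
               W = t$W, p_value = t$p_value)
  }))
}

#' Write a contour set as GeoJSON
#'
#' Emits a FeatureCollection of LineString boundary rings with `level` and
#' `area_km2` properties (planar projected coordinates).
#'
#' @param cs a [contour_areas()] result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_contours_geojson <- function(cs, path) {
  feats <- list()
  for (k in seq_len(nrow(cs$table))) {
    for (ring in cs$polygons[[k]]) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(level = cs$table$level[k],
                          area_km2 = cs$table$area_km2[k]),
        geometry = list(type = "LineString",
                        coordinates = unname(
                          lapply(seq_len(nrow(ring)),
                                 function(i) c(ring$x[i], ring$y[i])))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
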