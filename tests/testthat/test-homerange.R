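gauss_pts <- function(n, sd = 50000, seed = 1) {
  withr::with_seed(seed, data.frame(x = rnorm(n, 0, sd),
                                    y = rnorm(n, 0, sd)))
}

test_that("the UD integrates to one and matches the kernel-sum oracle", {
  pts <- gauss_pts(50, seed = 2)
  ud <- kde_ud(pts, bandwidth = 20000, cell = 12000)
  expect_equal(sum(ud$density) * ud$cell^2, 1, tolerance = 1e-6)
  # brute-force double loop over cells and points
  nx <- nrow(ud$density); ny <- ncol(ud$density)
  D <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    cx <- ud$origin[1] + (i - 0.5) * ud$cell
    cy <- ud$origin[2] + (j - 0.5) * ud$cell
    D[i, j] <- mean(dnorm(cx, pts$x, 20000) * dnorm(cy, pts$y, 20000))
  }
  D <- D / (sum(D) * ud$cell^2)
  expect_equal(ud$density, D, tolerance = 1e-10)
})

test_that("a single point yields the analytic kernel peak", {
  h <- 5000
  ud <- kde_ud(data.frame(x = 0, y = 0), bandwidth = h, cell = 250)
  expect_equal(max(ud$density), 1 / (2 * pi * h^2), tolerance = 1e-3)
  expect_error(kde_ud(data.frame(x = numeric(), y = numeric()), 1), "points")
  expect_error(kde_ud(data.frame(x = 0, y = 0), -1), "bandwidth")
})

test_that("h_ref follows the bivariate normal reference rule", {
  # unit variances, n = 64: h_ref = 64^(-1/6) = 0.5
  pts <- withr::with_seed(3, {
    z <- matrix(rnorm(128), 64, 2)
    z <- scale(z)  # exactly unit sample variance
    data.frame(x = z[, 1], y = z[, 2])
  })
  bw <- select_bandwidth(pts, cell = 0.25)
  expect_equal(bw$h_ref, 64^(-1 / 6), tolerance = 1e-9)
  expect_equal(bw$h_ref, 0.5, tolerance = 1e-9)
})

test_that("a configuration that never fragments selects 0.1 h_ref", {
  # one dominant tight cluster plus two low-density outliers that never
  # enter the 95% mass set: the contour stays a single component at every
  # multiplier, so the shrink runs to the 0.1 h_ref floor
  pts <- withr::with_seed(4, data.frame(
    x = c(rnorm(100, 0, 1), 1000, 0),
    y = c(rnorm(100, 0, 1), 0, 1000)))
  bw <- select_bandwidth(pts)
  expect_equal(bw$multiplier, 0.1)
  expect_true(all(bw$trace$components <= bw$trace$components[1]))
})

test_that("two separated clusters stop the shrink before fragmentation", {
  pts <- withr::with_seed(5, {
    a <- data.frame(x = rnorm(100, 0, 1000), y = rnorm(100, 0, 1000))
    b <- data.frame(x = rnorm(100, 20000, 1000), y = rnorm(100, 0, 1000))
    rbind(a, b)
  })
  bw <- select_bandwidth(pts)
  frag <- bw$trace$multiplier[bw$trace$components >
                                bw$trace$components[1]]
  expect_gt(length(frag), 0)
  expect_gt(bw$multiplier, max(frag))
})

test_that("degenerate point sets are rejected", {
  expect_error(select_bandwidth(data.frame(x = 1:40, y = 1:40)),
               "degenerate")
  expect_error(select_bandwidth(data.frame(x = 1:10, y = rnorm(10))), "30")
})

test_that("contour areas nest and approach the analytic normal ellipse", {
  pts <- gauss_pts(4000, sd = 50000, seed = 6)
  ud <- kde_ud(pts, bandwidth = 5000, cell = 4000)
  cs <- contour_areas(ud, levels = c(0.95, 0.5, 0.25))
  a <- setNames(cs$table$area_km2, cs$table$level)
  expect_lte(a[["0.25"]], a[["0.5"]])
  expect_lte(a[["0.5"]], a[["0.95"]])
  # 95% mass of a bivariate normal: area = pi * qchisq(.95, 2) * sigma^2
  expect_equal(a[["0.95"]], pi * qchisq(0.95, 2) * 50^2, tolerance = 0.1)
  expect_error(contour_areas(ud, levels = 1.5), "levels")
})

test_that("level sets use the smallest cell count with index tie-break", {
  # uniform mass over exactly 100 cells: level 0.5 takes 50 cells
  D <- matrix(0, 20, 20)
  D[1:100] <- 1
  ud <- structure(list(origin = c(0, 0), cell = 1000,
                       density = D / (sum(D) * 1000^2), n_points = 100,
                       bandwidth = 1), class = "ud_grid")
  cl <- bowmove:::level_cells(ud, 0.5)
  expect_length(cl, 50)
  expect_equal(sort(cl), 1:50)
})

test_that("Bhattacharyya affinity honours the masking conventions", {
  ud1 <- kde_ud(gauss_pts(300, seed = 7), bandwidth = 15000, cell = 8000)
  # identical inputs: BA = level, rescaled exactly 1
  same <- bhattacharyya_overlap(ud1, ud1, 0.95)
  expect_equal(same$ba, 0.95, tolerance = 1e-12)
  expect_equal(same$ba_rescaled, 1.0, tolerance = 1e-12)
  # disjoint supports: zero overlap (two uniform UDs on separate cell blocks)
  mk_ud <- function(cells) {
    D <- matrix(0, 10, 10)
    D[cells] <- 1
    structure(list(origin = c(0, 0), cell = 1000,
                   density = D / (sum(D) * 1000^2), n_points = 10,
                   bandwidth = 1), class = "ud_grid")
  }
  expect_equal(bhattacharyya_overlap(mk_ud(1:20), mk_ud(51:70), 0.95)$ba, 0)
  # symmetry
  p3 <- gauss_pts(300, seed = 9)
  p3$x <- p3$x + 40000
  ud3 <- bowmove:::kde_on_grid(p3, ud1, 15000)
  expect_equal(bhattacharyya_overlap(ud1, ud3, 0.50)$ba,
               bhattacharyya_overlap(ud3, ud1, 0.50)$ba, tolerance = 1e-12)
  ba <- bhattacharyya_overlap(ud1, ud3, 0.50)$ba
  expect_gte(ba, 0)
  expect_lte(ba, 0.50)
  # mismatched grids are an error
  ud_small <- kde_ud(gauss_pts(100, seed = 10), 15000, cell = 5000)
  expect_error(bhattacharyya_overlap(ud1, ud_small), "grids")
})

test_that("exact rank-sum enumeration matches the combinatorial oracle", {
  t1 <- wilcox_exact(c(1, 2), c(3, 4))
  expect_equal(t1$W, 0)
  expect_equal(t1$p_value, 1 / 3)
  # identical samples under midranks: p = 1
  t2 <- wilcox_exact(c(5, 5, 5), c(5, 5, 5))
  expect_equal(t2$p_value, 1)
  # agrees with the reference implementation when exact and tie-free
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.4, 6.3, 2.9)
  ref <- wilcox.test(x, y, exact = TRUE)
  t3 <- wilcox_exact(x, y)
  expect_equal(t3$W, unname(ref$statistic))
  expect_equal(t3$p_value, ref$p.value)
  # strongly shifted large samples: decisive normal-approximation p
  withr::with_seed(11, {
    a <- rnorm(200)
    b <- rnorm(200) + 3
  })
  t4 <- wilcox_exact(a, b)
  expect_match(t4$method, "normal")
  expect_lt(t4$p_value, 1e-6)
})

test_that("hotspot condition comparison reports per-covariate tests", {
  withr::with_seed(12, {
    d <- data.frame(x = runif(120), y = runif(120),
                    sst = rnorm(120), depth = rnorm(120))
  })
  inside <- d$x < 0.5
  d$sst[inside] <- d$sst[inside] + 3
  tab <- compare_hotspot_conditions(d, inside)
  expect_equal(nrow(tab), 2)
  expect_lt(tab$p_value[tab$covariate == "sst"], 1e-6)
  expect_gt(tab$p_value[tab$covariate == "depth"], 0.01)
  # polygon interface
  ring <- data.frame(x = c(-1, 0.5, 0.5, -1), y = c(-1, -1, 2, 2))
  tab2 <- compare_hotspot_conditions(d, ring)
  expect_equal(tab2$n_inside, tab$n_inside)
  expect_error(compare_hotspot_conditions(d, rep(TRUE, 120)), "side")
})

test_that("contours serialize to GeoJSON", {
  ud <- kde_ud(gauss_pts(200, seed = 13), bandwidth = 15000, cell = 8000)
  cs <- contour_areas(ud)
  f <- tempfile(fileext = ".geojson")
  write_contours_geojson(cs, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  unlink(f)
})
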