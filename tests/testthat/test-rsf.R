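test_that("the depth spline has 4 columns, natural tails, and matches an
          independent construction", {
  x <- seq(0, 4000, by = 25)
  B <- natural_spline_basis(x, knots = c(220, 500, 2500))
  expect_equal(ncol(B), 4)
  expect_equal(colnames(B), paste0("dpth_", 1:4))
  # second derivative vanishes beyond the boundary knots (linearity)
  withr::with_seed(1, {
    beta <- rnorm(4)
  })
  f <- function(v) as.numeric(natural_spline_basis(
    v, knots = c(220, 500, 2500), boundary = range(x)) %*% beta)
  h <- 1
  for (v0 in c(-300, -100, 4100, 4500)) {
    d2 <- (f(v0 + h) - 2 * f(v0) + f(v0 - h)) / h^2
    expect_lt(abs(d2), 1e-6)
  }
  # same function space as the textbook truncated-power natural basis:
  # projecting our basis onto it reproduces the basis exactly
  probes <- c(10, 150, 220, 340, 500, 900, 1700, 2500, 3100, 3900)
  knots_all <- c(min(x), 220, 500, 2500, max(x))
  TP <- ns_truncpower(x, knots_all)
  coefs <- qr.solve(TP, B)            # exact if B lies in span(TP)
  Bp <- natural_spline_basis(probes, knots = c(220, 500, 2500),
                             boundary = range(x))
  expect_equal(unclass(Bp)[, ], (ns_truncpower(probes, knots_all) %*% coefs)[, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(natural_spline_basis(rep(1, 5)), "distinct")
  expect_error(natural_spline_basis(x, knots = c(500, 220)), "increasing")
})

rsf_fixture <- function(n_seg = 6, n_loc = 30, seed = 1) {
  ss <- toy_seascape()
  used <- list()
  sims <- list()
  for (j in seq_len(n_seg)) {
    ts <- generate_rsf_testset(ss, c(sst = -0.5), n_loc, mode = "movement",
                               seed = seed + j)
    used[[paste0("s", j)]] <- ts$used
    tracks <- lapply(1:20, function(k)
      cbind(time_h = seq_len(n_loc),
            ts$avail_fun(n_loc, seed = seed + 100 * j + k)))
    sims[[paste0("s", j)]] <- structure(
      list(parent = paste0("s", j), tracks = tracks,
           score = rep(0, 20), retained = rep(TRUE, 20), k_keep = 20),
      class = "sim_track_set")
  }
  list(ss = ss, used = used, sims = sims)
}

test_that("the design applies transforms and pooled standardization", {
  fx <- rsf_fixture()
  des <- build_design(fx$used, fx$sims, fx$ss)
  d <- des$design
  expect_setequal(setdiff(names(d), c("use", "segment", "sim")),
                  c(paste0("dpth_", 1:4), "sst", "in_ice", "ice", "ice_sq"))
  expect_equal(mean(d$sst), 0, tolerance = 1e-9)
  expect_equal(sd(d$sst), 1, tolerance = 1e-9)
  expect_true(all(d$use %in% 0:1))
  expect_true(all(d$in_ice %in% 0:1))
  # ice_sq is the standardized square of the standardized ice column
  raw_sq <- d$ice^2
  expect_equal(d$ice_sq, (raw_sq - mean(raw_sq)) / sd(raw_sq),
               tolerance = 1e-9)
  # in_ice reflects the sign of the signed ice-edge distance
  xy <- d[d$use == 1, ]
  sgn <- extract_covariates(fx$ss,
                            fx$used$s1$x, fx$used$s1$y,
                            "dist_ice_edge")$dist_ice_edge
  expect_equal(d$in_ice[d$use == 1 & d$segment == "s1"],
               as.numeric(sgn < 0))
})

test_that("Monte-Carlo aggregation recovers iid-mode truth", {
  # direct construction: used drawn by exp(beta*x) weighting per segment
  mk <- function(n_seg, n_loc, beta, seed) {
    withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_seg), function(j) {
      pool <- rnorm(1500)
      used <- sample(pool, n_loc, prob = exp(beta * pool), replace = TRUE)
      rbind(data.frame(use = 1, segment = paste0("s", j), sim = NA,
                       sst = used),
            do.call(rbind, lapply(1:20, function(s)
              data.frame(use = 0, segment = paste0("s", j), sim = s,
                         sst = sample(pool, n_loc)))))
    })))
  }
  d <- mk(40, 25, 1.0, seed = 2)
  fit <- fit_mc_rsf(list(design = d, terms = list(sst = "sst")),
                    n_fits = 20, seed = 3)
  est <- fit$table$coef[fit$table$covariate == "sst"]
  expect_lt(abs(est - 1.0), 0.15)
  expect_equal(nrow(fit$coef_matrix), 20)
  # deterministic under the seed
  fit2 <- fit_mc_rsf(list(design = d, terms = list(sst = "sst")),
                     n_fits = 20, seed = 3)
  expect_identical(fit$table, fit2$table)
  # wrong simulation count is an error
  expect_error(fit_mc_rsf(list(design = d[d$sim %in% c(NA, 1:19), ],
                               terms = list(sst = "sst")),
                          n_fits = 20, seed = 1), "exactly 20")
})

test_that("zero spread across identical fits is flagged as degenerate", {
  d <- withr::with_seed(5, do.call(rbind, lapply(1:3, function(j) {
    x <- rnorm(40)
    rbind(data.frame(use = 1, segment = paste0("s", j), sim = NA, sst = x),
          do.call(rbind, lapply(1:20, function(s)
            data.frame(use = 0, segment = paste0("s", j), sim = s,
                       sst = x + 0.5))))  # every sim dataset identical
  })))
  expect_warning(
    fit <- fit_mc_rsf(list(design = d, terms = list(sst = "sst")),
                      n_fits = 20, seed = 1, random_effect = FALSE),
    "degenerate")
  expect_true(all(is.na(fit$table$p_value)))
})

test_that("with the random effect off, each fit equals an IRLS oracle", {
  d <- withr::with_seed(7, {
    x <- rnorm(400)
    rbind(data.frame(use = 1, segment = "s1", sim = NA,
                     sst = x + 0.4),
          do.call(rbind, lapply(1:20, function(s)
            data.frame(use = 0, segment = "s1", sim = s, sst = rnorm(400)))))
  })
  fit <- fit_mc_rsf(list(design = d, terms = list(sst = "sst")),
                    n_fits = 20, seed = 2, random_effect = FALSE)
  # hand-rolled IRLS on the first Monte-Carlo dataset
  assign1 <- withr::with_seed(2, sample.int(20))[1]
  dat <- rbind(d[d$use == 1, ], d[d$use == 0 & d$sim == assign1, ])
  X <- cbind(1, dat$sst)
  b <- c(0, 0)
  for (it in 1:50) {
    eta <- X %*% b
    mu <- plogis(eta)
    W <- as.numeric(mu * (1 - mu))
    z <- eta + (dat$use - mu) / W
    b_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(b_new - b)) < 1e-12) break
    b <- as.numeric(b_new)
  }
  expect_equal(unname(fit$coef_matrix[1, ]), b, tolerance = 1e-6)
})

test_that("a balanced null design gives near-zero coefficients", {
  d <- withr::with_seed(9, do.call(rbind, lapply(1:10, function(j) {
    rbind(data.frame(use = 1, segment = paste0("s", j), sim = NA,
                     sst = rnorm(50)),
          do.call(rbind, lapply(1:20, function(s)
            data.frame(use = 0, segment = paste0("s", j), sim = s,
                       sst = rnorm(50)))))
  })))
  fit <- fit_mc_rsf(list(design = d, terms = list(sst = "sst")),
                    n_fits = 20, seed = 4, random_effect = FALSE)
  expect_lt(abs(fit$table$coef[fit$table$covariate == "sst"]), 0.15)
  expect_lt(abs(fit$table$coef[fit$table$covariate == "(Intercept)"]), 0.15)
})

step_fixture <- function(beta_sst = 1, beta_noise = 0, n_seg = 10,
                         n_loc = 40, seed = 1) {
  withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_seg), function(j) {
    pool <- cbind(sst = rnorm(1200), noise = rnorm(1200))
    w <- exp(beta_sst * pool[, 1] + beta_noise * pool[, 2])
    ui <- sample(1200, n_loc, prob = w, replace = TRUE)
    rbind(data.frame(use = 1, segment = paste0("s", j), sim = NA,
                     sst = pool[ui, 1], noise = pool[ui, 2]),
          do.call(rbind, lapply(1:20, function(s) {
            ai <- sample(1200, n_loc)
            data.frame(use = 0, segment = paste0("s", j), sim = s,
                       sst = pool[ai, 1], noise = pool[ai, 2])
          })))
  })))
}

test_that("backward stepwise drops the noise covariate and keeps signal", {
  drops <- vapply(1:5, function(s) {
    d <- step_fixture(seed = s)
    fit <- backward_stepwise(
      list(design = d, terms = list(sst = "sst", noise = "noise")),
      alpha = 0.05, n_fits = 20, seed = 100 + s, random_effect = FALSE)
    identical(fit$dropped, "noise") &&
      "sst" %in% fit$table$covariate &&
      !"noise" %in% fit$table$covariate
  }, TRUE)
  expect_gte(mean(drops), 0.8)
})

test_that("stepwise leaves an all-significant model unchanged", {
  d <- step_fixture(beta_sst = 1, beta_noise = 0.8, seed = 11)
  fit <- backward_stepwise(
    list(design = d, terms = list(sst = "sst", noise = "noise")),
    alpha = 0.05, n_fits = 20, seed = 12, random_effect = FALSE)
  expect_length(fit$dropped, 0)
  expect_setequal(setdiff(fit$table$covariate, "(Intercept)"),
                  c("sst", "noise"))
})
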