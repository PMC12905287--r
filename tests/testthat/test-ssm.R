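test_that("smoothed states match direct joint-Gaussian conditioning", {
  for (model in c("rw", "crw")) {
    seg <- sim_segment(n = 10, seed = 3, model = model)
    fit <- fit_ssm(seg, model)
    a0 <- if (model == "rw") c(seg$x[1], seg$y[1]) else
      c(seg$x[1], 0, seg$y[1], 0)
    sys <- ssm_system(model, fit$par, fit$times, a0)
    orc <- joint_gaussian_oracle(sys, fit$y, fit$Rm)
    posi <- if (model == "rw") c(1, 2) else c(1, 3)
    expect_equal(fit$mu, orc$mean[, posi], tolerance = 1e-6)
    expect_equal(fit$se^2, orc$var[, posi], tolerance = 1e-6)
    expect_equal(fit$logLik, orc$loglik, tolerance = 1e-6)
  }
})

test_that("the filter log-likelihood equals the direct MVN density", {
  seg <- sim_segment(n = 6, seed = 7)
  for (model in c("rw", "crw")) {
    par <- if (model == "rw") c(sigma2_x = 4e5, sigma2_y = 6e5) else
      c(beta = 0.3, sigma2_v = 3e5)
    a0 <- if (model == "rw") c(seg$x[1], seg$y[1]) else
      c(seg$x[1], 0, seg$y[1], 0)
    times <- as.numeric(seg$timestamp - seg$timestamp[1], units = "hours")
    y <- cbind(seg$x, seg$y)
    Rm <- bowmove:::obs_covariances(seg)
    sys <- ssm_system(model, par, times, a0)
    kf <- bowmove:::run_kalman(model, par, times, y, Rm)
    orc <- joint_gaussian_oracle(sys, y, Rm)
    expect_equal(kf$loglik, orc$loglik, tolerance = 1e-8)
  }
})

test_that("per-axis ML diffusion variance matches a brute-force search", {
  # equispaced observations with known isotropic error: the RW likelihood
  # separates by axis, so a 1-D direct-density search is an exact oracle
  seg <- sim_segment(n = 3, dt_h = 4, sigma2 = 3e5, obs_sd = 300, seed = 9,
                     irregular = FALSE)
  fit <- fit_ssm(seg, "rw", min_length = 3)
  times <- fit$times
  grid_opt <- function(yv) {
    f <- function(ls) -rw1d_loglik(exp(ls), times, yv, 300^2 + 1e-6)
    # coarse grid then golden-section refinement
    ls <- seq(log(1e3), log(1e8), length.out = 200)
    v <- vapply(ls, f, 0)
    optimize(f, ls[pmax(which.min(v) + c(-2, 2), 1)], tol = 1e-10)$minimum
  }
  expect_equal(unname(fit$par["sigma2_x"]), exp(grid_opt(seg$x)),
               tolerance = 1e-4)
  expect_equal(unname(fit$par["sigma2_y"]), exp(grid_opt(seg$y)),
               tolerance = 1e-4)
})

test_that("near-zero observation error pins smoothed means to the data", {
  seg <- sim_segment(n = 15, obs_sd = 1e-4, seed = 11)
  fit <- fit_ssm(seg, "rw")
  expect_lt(max(abs(fit$mu - fit$y)), 1)
})

test_that("a straight constant-velocity track drives the CRW to maximal
          velocity autocorrelation", {
  n <- 40
  seg <- data.frame(id = "W1", segment_id = "s1",
                    timestamp = as.POSIXct("2021-09-01", tz = "UTC") +
                      seq(0, by = 4 * 3600, length.out = n),
                    x = seq(0, by = 4000, length.out = n) + rnorm(n, 0, 5),
                    y = rep(0, n) + rnorm(n, 0, 5),
                    lc = "G", smaj_m = 30, smin_m = 30, eor_deg = 0,
                    source = "gps")
  fit <- fit_ssm(seg, "crw")
  # beta at/near its lower bound = velocity autocorrelation at its maximum
  expect_lt(fit$par[["beta"]], 5e-3)
  expect_gt(exp(-fit$par[["beta"]] * 4), 0.98)
})

test_that("regular prediction anchors at the first fix with the right count", {
  seg <- sim_segment(n = 20, seed = 13)
  seg$timestamp <- as.POSIXct("2021-09-01", tz = "UTC") +
    seq(0, by = 2 * 3600, length.out = 20)
  fit <- fit_ssm(seg, "rw")
  pred <- predict_regular(fit, step_hours = 4)
  expect_equal(nrow(pred), 10)  # 0..38 h -> 0,4,...,36
  expect_equal(pred$timestamp[1], seg$timestamp[1])
  # two-fix case: 0 and 8 h -> exactly 3 predictions
  seg2 <- sim_segment(n = 12, seed = 14)
  seg2$timestamp <- as.POSIXct("2021-09-01", tz = "UTC") +
    seq(0, by = 8 * 3600 / 11, length.out = 12)
  fit2 <- fit_ssm(seg2, "rw")
  expect_equal(nrow(predict_regular(fit2, 4)), 3)
})

test_that("an interior RW prediction is the average of its bracketing
          smoothed states, with inflated uncertainty", {
  # symmetric setup: equal obs variances, observation at 0 and 8 h only
  seg <- sim_segment(n = 2, seed = 15)
  seg$timestamp <- as.POSIXct("2021-09-01", tz = "UTC") + c(0, 8) * 3600
  fit <- fit_ssm(seg, "rw", min_length = 2)
  pred <- predict_regular(fit, 4)
  expect_equal(pred$x[2], mean(pred$x[c(1, 3)]), tolerance = 1e-9)
  expect_equal(pred$y[2], mean(pred$y[c(1, 3)]), tolerance = 1e-9)
  expect_gte(pred$se_x[2] + 1e-9, max(pred$se_x[c(1, 3)]))
})

test_that("OSAR of a well-specified RW is standardized white noise", {
  seg <- sim_segment(n = 500, seed = 17)
  fit <- fit_ssm(seg, "rw")
  v <- as.numeric(fit$osar)
  expect_gt(mean(v), -0.15)
  expect_lt(mean(v), 0.15)
  expect_gt(var(v), 0.8)
  expect_lt(var(v), 1.2)
})

test_that("model selection takes the lowest AICc among converged fits", {
  seg <- sim_segment(n = 60, seed = 19)
  f1 <- fit_ssm(seg, "rw")
  f2 <- fit_ssm(seg, "crw")
  sel <- validate_and_select(list(f1, f2), n_replicates = 5, seed = 1)
  expect_equal(sel$fit$AICc, min(sel$diagnostics$AICc))
  expect_length(sel$replicates, 5)
  expect_equal(nrow(sel$replicates[[1]]), nrow(seg))
})

test_that("simulated replicate tracks reproduce the fitted step variance", {
  seg <- sim_segment(n = 120, dt_h = 4, sigma2 = 5e5, obs_sd = 100,
                     seed = 23, irregular = FALSE)
  fit <- fit_ssm(seg, "rw")
  sims <- simulate(fit, nsim = 1000, seed = 2)
  # empirical process variance of simulated increments vs fitted sigma2
  dt <- diff(fit$times)
  v <- mean(vapply(sims, function(s)
    mean(diff(s$x)^2 / dt), 0))
  expect_lt(abs(v - fit$par[["sigma2_x"]]) / fit$par[["sigma2_x"]], 0.10)
})

test_that("availability simulation retains k most-similar tracks", {
  seg <- sim_segment(n = 50, seed = 29)
  fit <- fit_ssm(seg, "rw")
  pred <- predict_regular(fit, 4)
  sts <- simulate_and_filter(fit, pred, n_sim = 100, k_keep = 20, seed = 3)
  expect_equal(sum(sts$retained), 20)
  expect_length(sts$tracks, 100)
  expect_true(all(vapply(sts$tracks, nrow, 0L) == nrow(pred)))
  expect_error(simulate_and_filter(fit, pred, n_sim = 10, k_keep = 20),
               "exceed")
})

test_that("the parent track ranks first and ties break by index", {
  seg <- sim_segment(n = 40, seed = 31)
  fit <- fit_ssm(seg, "rw")
  pred <- predict_regular(fit, 4)
  tracks <- with_seed_tracks <- lapply(1:9, function(s)
    withr::with_seed(s, data.frame(time_h = pred$timestamp,
                                   x = cumsum(rnorm(nrow(pred), 0, 2000)),
                                   y = cumsum(rnorm(nrow(pred), 0, 2000)))))
  parent_as_candidate <- data.frame(time_h = pred$timestamp,
                                    x = pred$x, y = pred$y)
  score <- bowmove:::sim_similarity(c(list(parent_as_candidate), tracks),
                                    pred)
  expect_equal(which.max(score), 1L)
  # all-identical candidates: first k retained by index
  same <- replicate(5, parent_as_candidate, simplify = FALSE)
  sc <- bowmove:::sim_similarity(same, pred)
  ord <- order(-sc, seq_along(sc))
  expect_equal(ord[1:3], 1:3)
})

test_that("simulation with a land barrier stays off land", {
  ss <- toy_seascape()
  seg <- sim_segment(n = 60, seed = 37, sigma2 = 5e6)
  # place the segment inside the seascape
  st <- sea_start(ss, 0.7, 0.5)
  seg$x <- seg$x - seg$x[1] + st[1]
  seg$y <- seg$y - seg$y[1] + st[2]
  fit <- fit_ssm(seg, "rw")
  pred <- predict_regular(fit, 4)
  sts <- simulate_and_filter(fit, pred, n_sim = 50, k_keep = 10,
                             barrier = ss, seed = 5)
  for (tr in sts$tracks)
    expect_false(any(bowmove:::is_land_at(ss, tr$x, tr$y)))
})

test_that("re-routing moves deep-inland points only", {
  ss <- toy_seascape()
  cc <- bowmove:::cell_centres(ss)
  land_idx <- which(ss$land, arr.ind = TRUE)
  sea_idx <- which(!ss$land, arr.ind = TRUE)
  d_inland <- bowmove:::dist_to_set(cc$x[land_idx[, 1]], cc$y[land_idx[, 2]],
                                    cc$x[sea_idx[, 1]], cc$y[sea_idx[, 2]])
  deep <- which.max(d_inland)
  expect_gt(d_inland[deep], 10000)  # fixture guarantees a deep-inland cell
  band <- which(d_inland > 1000 & d_inland < 9000)[1]
  at_sea <- sea_idx[which.max(sea_idx[, 1]), ]
  tr <- data.frame(
    x = c(cc$x[land_idx[deep, 1]], cc$x[land_idx[band, 1]],
          cc$x[at_sea[1]]),
    y = c(cc$y[land_idx[deep, 2]], cc$y[land_idx[band, 2]],
          cc$y[at_sea[2]]))
  out <- reroute(tr, ss, buffer_m = 10000)
  expect_equal(out$rerouted, c(TRUE, FALSE, FALSE))
  expect_false(out$x[1] == tr$x[1] && out$y[1] == tr$y[1])
  expect_equal(out$x[2:3], tr$x[2:3])
})
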