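## Continuous-time state-space models for error-prone, irregularly sampled
## tracks. Two process models: "rw" (Brownian position, diffusion variance per
## axis) and "crw" (integrated Ornstein-Uhlenbeck velocity, the standard
## continuous-time correlated random walk). Time unit: hours; space: metres.

# prior variance of the initial position about the first fix: vague on the
# movement scale (SD ~32 km) while keeping the filter well conditioned
DIFFUSE_POS_VAR <- 1e9

# exact discretization of the per-axis CRW (position, velocity) block
crw_block <- function(beta, s2, dt) {
  u <- beta * dt
  xi <- exp(-u)
  one_m_xi <- -expm1(-u)
  A <- matrix(c(1, 0, one_m_xi / beta, xi), 2, 2)
  t1 <- if (u < 1e-3) (2 / 3) * u^3 * (1 - 0.75 * u) else
    2 * u - 3 + 4 * xi - xi^2
  Q <- matrix(c(s2 / beta^2 * t1,
                s2 / beta * one_m_xi^2,
                s2 / beta * one_m_xi^2,
                s2 * (1 - xi^2)), 2, 2)
  list(A = A, Q = Q)
}

#' System matrices of a track state-space model
#'
#' Returns the transition/innovation matrices over a time grid, the
#' observation matrix and the initial state distribution. Exposed so the
#' smoothing recursions can be checked against direct joint-Gaussian
#' conditioning built from the same matrices.
#'
#' @param model `"rw"` or `"crw"`.
#' @param par named parameters: RW `sigma2_x`, `sigma2_y` (m^2/h);
#'   CRW `beta` (1/h), `sigma2_v` (stationary velocity variance, (m/h)^2).
#' @param times numeric times in hours (sorted).
#' @param a0 initial state mean; for `"rw"` length 2 (x, y), for `"crw"`
#'   length 4 (x, vx, y, vy).
#' @return list `Tm`, `Qm` (arrays m x m x (n-1)), `H`, `a0`, `P0`.
#' @export
ssm_system <- function(model, par, times, a0) {
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  if (model == "rw") {
    m <- 2L
    H <- diag(2)
    Tm <- array(diag(2), c(2, 2, max(n - 1, 1)))
    Qm <- array(0, c(2, 2, max(n - 1, 1)))
    for (k in seq_len(n - 1)) {
      Qm[, , k] <- diag(c(par[["sigma2_x"]], par[["sigma2_y"]]) * dt[k])
    }
    P0 <- diag(rep(DIFFUSE_POS_VAR, 2))
  } else if (model == "crw") {
    m <- 4L
    H <- matrix(0, 2, 4)
    H[1, 1] <- 1
    H[2, 3] <- 1
    Tm <- array(0, c(4, 4, max(n - 1, 1)))
    Qm <- array(0, c(4, 4, max(n - 1, 1)))
    for (k in seq_len(n - 1)) {
      b <- crw_block(par[["beta"]], par[["sigma2_v"]], dt[k])
      Tm[1:2, 1:2, k] <- b$A
      Tm[3:4, 3:4, k] <- b$A
      Qm[1:2, 1:2, k] <- b$Q
      Qm[3:4, 3:4, k] <- b$Q
    }
    P0 <- diag(c(DIFFUSE_POS_VAR, par[["sigma2_v"]],
                 DIFFUSE_POS_VAR, par[["sigma2_v"]]))
  } else stop("unknown model: ", model)
  list(Tm = Tm, Qm = Qm, H = H, a0 = a0, P0 = P0, m = m)
}

# per-fix 2x2 observation covariances
obs_covariances <- function(seg) {
  n <- nrow(seg)
  Rm <- array(0, c(2, 2, n))
  ctab <- argos_class_table
  for (i in seq_len(n)) {
    if (!is.na(seg$smaj_m[i]) && !is.na(seg$smin_m[i]) &&
        !is.na(seg$eor_deg[i]) && seg$smaj_m[i] > 0) {
      Rm[, , i] <- ellipse_cov(seg$smaj_m[i], seg$smin_m[i], seg$eor_deg[i])
    } else {
      k <- match(seg$lc[i], ctab$lc)
      if (is.na(k)) stop("no class fallback for location class ", seg$lc[i])
      Rm[, , i] <- diag(c(ctab$smaj_m[k], ctab$smaj_m[k]))^2
    }
    # guard against exactly singular ellipses
    Rm[, , i] <- Rm[, , i] + diag(1e-6, 2)
  }
  Rm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_kalman <- function(model, par, times, y, Rm) {
  a0 <- if (model == "rw") as.numeric(y[1, ]) else
    c(y[1, 1], 0, y[1, 2], 0)
  sys <- ssm_system(model, par, times, a0)
  .kalman_smooth(y, sys$Tm, sys$Qm, sys$H, Rm, sys$a0, sys$P0)
}

par_from_theta <- function(model, theta) {
  if (model == "rw") {
    c(sigma2_x = exp(theta[1]), sigma2_y = exp(theta[2]))
  } else {
    c(beta = min(max(exp(theta[1]), 1e-4), 10), sigma2_v = exp(theta[2]))
  }
}

#' Fit a state-space model to a track segment
#'
#' Maximum-likelihood fit of a random-walk or correlated-random-walk
#' state-space model by Kalman filtering over the exact irregular-interval
#' discretization. Each fix contributes a 2x2 observation covariance built
#' from its error ellipse (rotated to the coordinate axes) or, when ellipse
#' metadata is missing, from the per-class fallback in [argos_class_table].
#' Smoothed states come from fixed-interval (RTS) smoothing. Optimization is
#' quasi-Newton-free Nelder-Mead on log-transformed parameters with
#' deterministic restarts; non-convergence yields a flagged fit, not an
#' error.
#'
#' @param seg segment data.frame (from [filter_and_segment()]), columns
#'   `timestamp`, `x`, `y`, `lc`, `smaj_m`, `smin_m`, `eor_deg`.
#' @param model `"rw"` or `"crw"`.
#' @param n_restarts deterministic optimizer restarts.
#' @param min_length minimum number of fixes.
#' @return object of class `ssm_fit`: parameters on natural scale, smoothed
#'   state means/SDs at observation times, log-likelihood, AICc,
#'   standardized one-step-ahead residuals (`osar`), convergence flag.
#' @export
fit_ssm <- function(seg, model = c("rw", "crw"), n_restarts = 2,
                    min_length = 10) {
  model <- match.arg(model)
  if (nrow(seg) < min_length)
    stop("segment shorter than ", min_length, " fixes")
  times <- as.numeric(seg$timestamp - seg$timestamp[1], units = "hours")
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing")
  y <- cbind(seg$x, seg$y)
  Rm <- obs_covariances(seg)

  # moment-based starting values
  dt <- diff(times)
  v2 <- (diff(seg$x)^2 + diff(seg$y)^2) / dt
  if (model == "rw") {
    s0 <- max(mean(v2) / 2, 1)
    theta0 <- log(c(s0, s0))
  } else {
    sp2 <- max(mean(v2 / dt), 1e-2)  # squared speed scale (m/h)^2
    theta0 <- log(c(1 / 6, sp2))
  }
  nll <- function(theta) {
    par <- par_from_theta(model, theta)
    out <- tryCatch(run_kalman(model, par, times, y, Rm),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$loglik)) 1e10 else -out$loglik
  }
  starts <- list(theta0)
  if (n_restarts >= 2) starts <- c(starts, list(theta0 + c(1.5, -1.5)))
  if (n_restarts >= 3) starts <- c(starts, list(theta0 + c(-1.5, 1.5)))
  best <- NULL
  for (th in starts) {
    op <- optim(th, nll, method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  # quasi-Newton polish from the simplex solution
  pol <- tryCatch(optim(best$par, nll, method = "BFGS",
                        control = list(maxit = 100, reltol = 1e-12)),
                  error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value)
    best <- pol
  par <- par_from_theta(model, best$par)
  conv <- best$convergence == 0 && best$value < 1e9
  out <- run_kalman(model, par, times, y, Rm)
  posi <- if (model == "rw") c(1, 2) else c(1, 3)
  k <- 2L
  n <- nrow(seg)
  fit <- structure(list(
    model = model, par = par, logLik = out$loglik,
    AICc = AICc.default(out$loglik, k = k, n = n),
    converged = conv, n = n, k = k,
    times = times, y = y, Rm = Rm,
    t0 = seg$timestamp[1],
    segment_id = seg$segment_id[1] %||% "s1",
    animal_id = seg$id[1] %||% "W1",
    mu = out$ahat[, posi, drop = FALSE],
    se = sqrt(cbind(out$Phat[posi[1], posi[1], ],
                    out$Phat[posi[2], posi[2], ])),
    osar = out$vstd), class = "ssm_fit")
  fit
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("ssm_fit [%s] segment %s: %d fixes\n", x$model, x$segment_id,
              x$n))
  cat("  parameters:", paste(names(x$par), signif(x$par, 4), sep = " = ",
                             collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f  AICc %.2f  converged: %s\n", x$logLik,
              x$AICc, x$converged))
  invisible(x)
}

#' @export
coef.ssm_fit <- function(object, ...) object$par

#' @export
logLik.ssm_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
AICc.ssm_fit <- function(object, ...) object$AICc

#' @export
summary.ssm_fit <- function(object, ...) {
  ac <- apply(object$osar, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3) return(NA_real_)
    acf(v, plot = FALSE, lag.max = 1)$acf[2]
  })
  out <- list(model = object$model, par = object$par,
              logLik = object$logLik, AICc = object$AICc,
              converged = object$converged, n = object$n,
              osar_mean = colMeans(object$osar, na.rm = TRUE),
              osar_var = apply(object$osar, 2, var, na.rm = TRUE),
              osar_lag1 = ac)
  class(out) <- "summary.ssm_fit"
  out
}

#' @export
print.summary.ssm_fit <- function(x, ...) {
  cat(sprintf("%s state-space model, %d fixes, logLik %.2f, AICc %.2f\n",
              toupper(x$model), x$n, x$logLik, x$AICc))
  cat("  OSAR mean:", signif(x$osar_mean, 3), " var:",
      signif(x$osar_var, 3), " lag-1 acf:", signif(x$osar_lag1, 3), "\n")
  invisible(x)
}

#' Predict regular-interval locations from a fitted state-space model
#'
#' Smoothed state means and standard errors on a regular grid (default four
#' hours) anchored at the first observation time, obtained by running the
#' smoother over the union of observation and grid times with the grid-only
#' times treated as missing observations.
#'
#' @param fit a converged [fit_ssm()] object.
#' @param step_hours prediction interval.
#' @return data.frame of class `predicted_track`: `segment`, `animal`,
#'   `timestamp`, `date`, `x`, `y`, `se_x`, `se_y`, `rerouted`.
#' @export
predict_regular <- function(fit, step_hours = 4) {
  if (!fit$converged) stop("cannot predict from an unconverged fit")
  tgrid <- seq(0, max(fit$times), by = step_hours)
  allt <- sort(unique(c(fit$times, tgrid)))
  yfull <- matrix(NA_real_, length(allt), 2)
  Rfull <- array(diag(2), c(2, 2, length(allt)))
  oi <- match(fit$times, allt)
  yfull[oi, ] <- fit$y
  Rfull[, , oi] <- fit$Rm
  out <- run_kalman(fit$model, fit$par, allt, yfull, Rfull)
  posi <- if (fit$model == "rw") c(1, 2) else c(1, 3)
  gi <- match(tgrid, allt)
  pred <- data.frame(
    segment = fit$segment_id, animal = fit$animal_id,
    timestamp = fit$t0 + tgrid * 3600,
    x = out$ahat[gi, posi[1]], y = out$ahat[gi, posi[2]],
    se_x = sqrt(out$Phat[posi[1], posi[1], gi]),
    se_y = sqrt(out$Phat[posi[2], posi[2], gi]),
    rerouted = FALSE)
  attr(pred, "step_hours") <- step_hours
  attr(pred, "model") <- fit$model
  attr(pred, "par") <- fit$par
  class(pred) <- c("predicted_track", "data.frame")
  pred
}

#' @export
#' @rdname predict_regular
#' @param object a `ssm_fit`.
#' @param ... ignored.
predict.ssm_fit <- function(object, step_hours = 4, ...) {
  predict_regular(object, step_hours = step_hours)
}

#' Simulate replicate tracks from the joint smoothing distribution
#'
#' Draws replicate state trajectories consistent with the fitted model and
#' the observed fixes (forward-filter backward-sampling), used to assess
#' track uncertainty.
#'
#' @param object a converged `ssm_fit`.
#' @param nsim number of replicate tracks.
#' @param seed integer RNG seed.
#' @param ... ignored.
#' @return list of data.frames (`time_h`, `x`, `y`), one per replicate.
#' @export
simulate.ssm_fit <- function(object, nsim = 100, seed = 1, ...) {
  a0 <- if (object$model == "rw") as.numeric(object$y[1, ]) else
    c(object$y[1, 1], 0, object$y[1, 2], 0)
  sys <- ssm_system(object$model, object$par, object$times, a0)
  posi <- if (object$model == "rw") c(1, 2) else c(1, 3)
  cube <- with_seed(seed, .kalman_ffbs(object$y, sys$Tm, sys$Qm, sys$H,
                                       object$Rm, sys$a0, sys$P0, nsim))
  lapply(seq_len(nsim), function(s)
    data.frame(time_h = object$times, x = cube[, posi[1], s],
               y = cube[, posi[2], s]))
}

#' Validate candidate fits for one segment and select one
#'
#' Computes one-step-ahead residual (OSAR) diagnostics and AICc for each
#' candidate fit, selects the converged fit with the lowest AICc, and applies
#' an over-smoothing guard: when the CRW's OSAR lag-1 autocorrelation is
#' worse than the RW's by more than 0.1 the RW is preferred regardless of
#' AICc. Also returns replicate tracks simulated from the joint smoothing
#' distribution of the selected fit for uncertainty assessment.
#'
#' @param fits list of `ssm_fit` objects for the same segment.
#' @param n_replicates replicate track count.
#' @param seed RNG seed for the replicate simulation.
#' @return list: `fit` (selected), `diagnostics` (data.frame per candidate:
#'   model, converged, logLik, AICc, osar mean/var/lag-1 acf per axis),
#'   `replicates` (list of simulated tracks).
#' @export
validate_and_select <- function(fits, n_replicates = 100, seed = 1) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(conv)) stop("no converged fit for this segment")
  diag_tab <- do.call(rbind, lapply(fits, function(f) {
    s <- summary(f)
    data.frame(model = f$model, converged = f$converged,
               logLik = f$logLik, AICc = f$AICc,
               osar_mean_x = s$osar_mean[1], osar_mean_y = s$osar_mean[2],
               osar_var_x = s$osar_var[1], osar_var_y = s$osar_var[2],
               osar_lag1_x = s$osar_lag1[1], osar_lag1_y = s$osar_lag1[2])
  }))
  cand <- which(conv)
  sel <- cand[which.min(diag_tab$AICc[cand])]
  models <- vapply(fits, `[[`, "", "model")
  if (models[sel] == "crw" && any(models[cand] == "rw")) {
    rwi <- cand[models[cand] == "rw"][1]
    a_crw <- mean(abs(c(diag_tab$osar_lag1_x[sel], diag_tab$osar_lag1_y[sel])),
                  na.rm = TRUE)
    a_rw <- mean(abs(c(diag_tab$osar_lag1_x[rwi], diag_tab$osar_lag1_y[rwi])),
                 na.rm = TRUE)
    if (is.finite(a_crw) && is.finite(a_rw) && a_crw - a_rw > 0.1)
      sel <- rwi
  }
  reps <- simulate(fits[[sel]], nsim = n_replicates, seed = seed)
  list(fit = fits[[sel]], diagnostics = diag_tab, replicates = reps)
}

# simulate the unconditional movement process at given times from a start
simulate_process <- function(model, par, times, start, barrier = NULL,
                             max_try = 50) {
  n <- length(times)
  dt <- diff(times)
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- start
  ok_at <- function(x, y) {
    if (is.null(barrier)) return(TRUE)
    inside <- x > barrier$origin[1] &&
      x < barrier$origin[1] + barrier$nx * barrier$cell &&
      y > barrier$origin[2] &&
      y < barrier$origin[2] + barrier$ny * barrier$cell
    inside && !is_land_at(barrier, x, y)
  }
  if (model == "rw") {
    sx <- sqrt(par[["sigma2_x"]]) ; sy <- sqrt(par[["sigma2_y"]])
    for (t in 2:n) {
      for (try in seq_len(max_try)) {
        cand <- pos[t - 1, ] + c(sx, sy) * sqrt(dt[t - 1]) * rnorm(2)
        if (ok_at(cand[1], cand[2])) break
        if (try == max_try) cand <- pos[t - 1, ]
      }
      pos[t, ] <- cand
    }
  } else {
    vel <- sqrt(par[["sigma2_v"]]) * rnorm(2)
    for (t in 2:n) {
      b <- crw_block(par[["beta"]], par[["sigma2_v"]], dt[t - 1])
      L <- chol(b$Q + diag(1e-10, 2))
      for (try in seq_len(max_try)) {
        ex <- as.numeric(t(L) %*% rnorm(2))
        ey <- as.numeric(t(L) %*% rnorm(2))
        nx_ <- b$A %*% c(pos[t - 1, 1], vel[1]) + ex
        ny_ <- b$A %*% c(pos[t - 1, 2], vel[2]) + ey
        if (ok_at(nx_[1], ny_[1])) break
        if (try == max_try) {
          nx_ <- c(pos[t - 1, 1], -vel[1] * 0.5)
          ny_ <- c(pos[t - 1, 2], -vel[2] * 0.5)
        }
      }
      pos[t, ] <- c(nx_[1], ny_[1])
      vel <- c(nx_[2], ny_[2])
    }
  }
  pos
}

#' Simulate availability tracks and retain the most similar
#'
#' Simulates `n_sim` tracks from the fitted movement process, started at the
#' parent track's start location and sharing its timestamps, with land as a
#' barrier (barrier-aware step proposal against a seascape land mask). Each
#' simulation is scored by the negative standardized Euclidean distance to
#' the parent in (net displacement, net bearing), and the `k_keep` highest
#' scores are retained (deterministic index tie-break). The retained tracks
#' represent habitat available in the absence of selection.
#'
#' @param fit a converged `ssm_fit`.
#' @param predicted the parent [predict_regular()] track.
#' @param n_sim simulations (default 100).
#' @param k_keep how many to retain (default 20).
#' @param barrier optional [seascape_stack] whose land mask blocks movement.
#' @param seed integer RNG seed.
#' @return object of class `sim_track_set`: `parent` id, `tracks` (list of
#'   data.frames `time_h, x, y`), `score`, `retained` (logical), `k_keep`.
#' @export
simulate_and_filter <- function(fit, predicted, n_sim = 100, k_keep = 20,
                                barrier = NULL, seed = 1) {
  if (k_keep > n_sim) stop("k_keep cannot exceed n_sim")
  if (!fit$converged) stop("cannot simulate from an unconverged fit")
  times <- as.numeric(predicted$timestamp - predicted$timestamp[1],
                      units = "hours")
  start <- c(predicted$x[1], predicted$y[1])
  tracks <- with_seed(seed, lapply(seq_len(n_sim), function(s) {
    pos <- simulate_process(fit$model, fit$par, times, start, barrier)
    data.frame(time_h = times, x = pos[, 1], y = pos[, 2])
  }))
  score <- sim_similarity(tracks, predicted)
  ord <- order(-score, seq_along(score))
  retained <- logical(n_sim)
  retained[ord[seq_len(k_keep)]] <- TRUE
  structure(list(parent = fit$segment_id, tracks = tracks, score = score,
                 retained = retained, k_keep = k_keep),
            class = "sim_track_set")
}

# similarity of candidate tracks to the parent in (net displacement, bearing)
sim_similarity <- function(tracks, predicted) {
  n <- length(tracks)
  disp <- vapply(tracks, function(d)
    sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2), 0)
  brg <- vapply(tracks, function(d)
    atan2(d$y[nrow(d)] - d$y[1], d$x[nrow(d)] - d$x[1]), 0)
  pd <- sqrt((predicted$x[nrow(predicted)] - predicted$x[1])^2 +
               (predicted$y[nrow(predicted)] - predicted$y[1])^2)
  pb <- atan2(predicted$y[nrow(predicted)] - predicted$y[1],
              predicted$x[nrow(predicted)] - predicted$x[1])
  sdd <- sd(disp)
  db <- angle_diff(brg, pb)
  sdb <- sd(db)
  zd <- if (is.na(sdd) || sdd < 1e-12) ifelse(disp == pd, 0, Inf) else
    (disp - pd) / sdd
  zb <- if (is.na(sdb) || sdb < 1e-12) ifelse(abs(db) < 1e-12, 0, Inf) else
    db / sdb
  -sqrt(zd^2 + zb^2)
}

#' @export
print.sim_track_set <- function(x, ...) {
  cat(sprintf("sim_track_set: %d simulations of segment %s, %d retained\n",
              length(x$tracks), x$parent, sum(x$retained)))
  invisible(x)
}

#' Re-route locations around land
#'
#' Land is eroded inward by `buffer_m`: a land cell belongs to the eroded
#' interior when its distance to the nearest sea cell exceeds the buffer.
#' Points falling in the eroded interior are moved to the centre of the
#' nearest non-interior cell (coastal band or sea) and flagged; points in
#' the buffer band -- e.g. inside fjord arms narrower than the buffer -- and
#' points at sea are left in place.
#'
#' @param track data.frame with `x`, `y` (and optionally `rerouted`).
#' @param land a [seascape_stack] providing the land mask, or a logical
#'   matrix land mask with attributes taken from `geometry`.
#' @param buffer_m erosion buffer in metres (default 10,000).
#' @return the track with updated `x`, `y` and a logical `rerouted` column.
#' @export
reroute <- function(track, land, buffer_m = 10000) {
  ss <- land
  if (!inherits(ss, "seascape_stack"))
    stop("land must be a seascape_stack")
  cc <- cell_centres(ss)
  land_idx <- which(ss$land, arr.ind = TRUE)
  if (nrow(land_idx) == 0) {
    track$rerouted <- FALSE
    return(track)
  }
  sea_idx <- which(!ss$land, arr.ind = TRUE)
  d_inland <- dist_to_set(cc$x[land_idx[, 1]], cc$y[land_idx[, 2]],
                          cc$x[sea_idx[, 1]], cc$y[sea_idx[, 2]])
  eroded <- matrix(FALSE, ss$nx, ss$ny)
  eroded[land_idx] <- d_inland > buffer_m
  ij <- cell_index(ss, track$x, track$y, what = "track location",
                   clamp = TRUE)
  inside <- eroded[ij]
  track$rerouted <- inside
  if (any(inside)) {
    tgt <- which(!eroded, arr.ind = TRUE)
    tx <- cc$x[tgt[, 1]]
    ty <- cc$y[tgt[, 2]]
    for (r in which(inside)) {
      k <- which.min((tx - track$x[r])^2 + (ty - track$y[r])^2)
      track$x[r] <- tx[k]
      track$y[r] <- ty[k]
    }
  }
  track
}
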