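# Independent oracles used across tests. These deliberately avoid the
# package's recursive algorithms: joint-Gaussian conditioning by direct
# matrix algebra, multivariate normal densities by Cholesky, and a textbook
# truncated-power natural-spline construction.

dmvnorm_log <- function(y, mu, S) {
  L <- chol(S)
  w <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
}

# Build the joint distribution of all states from the system matrices and
# condition on the observations: returns smoothed means/covariances at every
# time and the marginal log-likelihood of the observations.
joint_gaussian_oracle <- function(sys, y, Rm) {
  n <- nrow(y)
  m <- sys$m
  mu <- matrix(0, n, m)
  mu[1, ] <- sys$a0
  C <- matrix(0, n * m, n * m)
  blk <- function(i) ((i - 1) * m + 1):(i * m)
  C[blk(1), blk(1)] <- sys$P0
  for (t in seq_len(n - 1)) {
    Tt <- sys$Tm[, , t]
    mu[t + 1, ] <- Tt %*% mu[t, ]
    for (s in 1:t) C[blk(t + 1), blk(s)] <- Tt %*% C[blk(t), blk(s)]
    C[blk(t + 1), blk(t + 1)] <-
      Tt %*% C[blk(t), blk(t)] %*% t(Tt) + sys$Qm[, , t]
    for (s in 1:t) C[blk(s), blk(t + 1)] <- t(C[blk(t + 1), blk(s)])
  }
  obs <- which(is.finite(y[, 1]))
  p <- ncol(y)
  Hbig <- matrix(0, length(obs) * p, n * m)
  Rbig <- matrix(0, length(obs) * p, length(obs) * p)
  for (k in seq_along(obs)) {
    rows <- ((k - 1) * p + 1):(k * p)
    Hbig[rows, blk(obs[k])] <- sys$H
    Rbig[rows, rows] <- Rm[, , obs[k]]
  }
  yv <- as.numeric(t(y[obs, , drop = FALSE]))
  muY <- as.numeric(Hbig %*% as.numeric(t(mu)))
  SY <- Hbig %*% C %*% t(Hbig) + Rbig
  CXY <- C %*% t(Hbig)
  K <- CXY %*% solve(SY)
  post_mean <- as.numeric(t(mu)) + K %*% (yv - muY)
  post_cov <- C - K %*% t(CXY)
  list(mean = matrix(post_mean, n, m, byrow = TRUE),
       cov = post_cov,
       var = t(vapply(seq_len(n), function(t) diag(post_cov[blk(t), blk(t)]),
                      numeric(m))),
       loglik = dmvnorm_log(yv, muY, SY))
}

# 1-D random-walk profile likelihood oracle for one axis (diagonal R): direct
# multivariate-normal density of that axis' observations
rw1d_loglik <- function(sigma2, times, yv, r_var, p0 = 1e9) {
  n <- length(yv)
  cum <- c(0, cumsum(sigma2 * diff(times)))
  C <- outer(seq_len(n), seq_len(n), function(i, j) p0 + cum[pmin(i, j)])
  dmvnorm_log(yv, rep(yv[1], n), C + diag(r_var, n))
}

# textbook natural cubic spline basis (truncated power construction,
# e.g. Hastie, Tibshirani & Friedman eq. 5.4-5.5), normalized differently
# from splines::ns; agreement is checked through fitted function values.
ns_truncpower <- function(x, knots_all) {
  K <- length(knots_all)
  d <- function(j) {
    (pmax(x - knots_all[j], 0)^3 - pmax(x - knots_all[K], 0)^3) /
      (knots_all[K] - knots_all[j])
  }
  cbind(1, x, vapply(seq_len(K - 2), function(j) d(j) - d(K - 1),
                     numeric(length(x))))
}

# small test seascape shared by several files
toy_seascape <- function(seed = 42, nx = 32, ny = 32) {
  generate_seascape(nx = nx, ny = ny, cell = 8000, seed = seed,
                    land_frac = 0.15, smoothness = 3)
}

sea_start <- function(ss, fx = 0.6, fy = 0.5) {
  c(ss$origin[1] + ss$nx * ss$cell * fx,
    ss$origin[2] + ss$ny * ss$cell * fy)
}

# straight constant-velocity track with a trace of jitter
straight_track <- function(n = 200, step = 4000, jitter = 5, seed = 1) {
  withr::with_seed(seed, data.frame(
    x = cumsum(rep(step, n)) + rnorm(n, 0, jitter),
    y = cumsum(rep(step / 2, n)) + rnorm(n, 0, jitter)))
}

white_noise_track <- function(n = 200, sd = 5000, seed = 1) {
  withr::with_seed(seed, data.frame(x = rnorm(n, 0, sd),
                                    y = rnorm(n, 0, sd)))
}

sim_segment <- function(n = 20, dt_h = 2, sigma2 = 5e5, obs_sd = 800,
                        seed = 1, model = "rw", beta = 0.2, s2v = 4e5,
                        irregular = TRUE) {
  withr::with_seed(seed, {
    dt <- if (irregular) dt_h * runif(n - 1, 0.4, 1.6) else rep(dt_h, n - 1)
    times <- c(0, cumsum(dt))
    if (model == "rw") {
      x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
      y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
    } else {
      x <- y <- numeric(n)
      vx <- rnorm(1, 0, sqrt(s2v)); vy <- rnorm(1, 0, sqrt(s2v))
      for (k in 2:n) {
        b <- bowmove:::crw_block(beta, s2v, dt[k - 1])
        L <- chol(b$Q + diag(1e-9, 2))
        ex <- as.numeric(t(L) %*% rnorm(2)); ey <- as.numeric(t(L) %*% rnorm(2))
        sx <- b$A %*% c(x[k - 1], vx) + ex
        sy <- b$A %*% c(y[k - 1], vy) + ey
        x[k] <- sx[1]; vx <- sx[2]; y[k] <- sy[1]; vy <- sy[2]
      }
    }
    data.frame(id = "W1", segment_id = "s1",
               timestamp = as.POSIXct("2021-09-01", tz = "UTC") +
                 times * 3600,
               x = x + rnorm(n, 0, obs_sd), y = y + rnorm(n, 0, obs_sd),
               lc = "G", smaj_m = obs_sd, smin_m = obs_sd, eor_deg = 0,
               source = "gps")
  })
}

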