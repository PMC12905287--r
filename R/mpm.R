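## Time-varying move persistence: first differences of regular-step locations
## follow d_t = gamma_t d_{t-1} + N(0, sigma_d^2 I), with logit(gamma_t) a
## latent Gaussian random walk whose innovation variance is pooled across all
## tracks in a joint fit. Estimated by marginal maximum likelihood with a
## Laplace approximation over the latent series (inner Newton smoother on a
## tridiagonal Hessian).

# solve tridiagonal system (sub, diag, super) x = b  (Thomas algorithm)
thomas_solve <- function(dl, dd, du, b) {
  n <- length(dd)
  cp <- numeric(n); bp <- numeric(n)
  cp[1] <- du[1] / dd[1]
  bp[1] <- b[1] / dd[1]
  for (i in 2:n) {
    m <- dd[i] - dl[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) du[i] / m else 0
    bp[i] <- (b[i] - dl[i - 1] * bp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  x
}

# log-determinant of a symmetric tridiagonal matrix; NA if not PD
tridiag_logdet <- function(dl, dd) {
  n <- length(dd)
  d <- numeric(n)
  d[1] <- dd[1]
  if (d[1] <= 0) return(NA_real_)
  for (i in 2:n) {
    d[i] <- dd[i] - dl[i - 1]^2 / d[i - 1]
    if (d[i] <= 0) return(NA_real_)
  }
  sum(log(d))
}

# per-track sufficient statistics for the persistence likelihood
mpm_stats <- function(xy) {
  d <- diff(as.matrix(xy))
  a <- d[-nrow(d), , drop = FALSE]   # d_{t-1}
  b <- d[-1, , drop = FALSE]         # d_t
  list(aa = rowSums(a * a), ab = rowSums(a * b), bb = rowSums(b * b),
       L = nrow(a))
}

# inner Newton smoother for one track; returns mode, objective value parts,
# Hessian bands and log-determinant
mpm_inner <- function(st, sigma2_d, sigma2_g, g0 = NULL) {
  L <- st$L
  g <- if (is.null(g0) || length(g0) != L) rep(0, L) else g0
  offd <- rep(-1 / sigma2_g, L - 1)
  rw_diag <- c(1 / sigma2_g, rep(2 / sigma2_g, max(L - 2, 0)),
               if (L > 1) 1 / sigma2_g)
  if (L == 1) rw_diag <- 0
  obj <- function(g) {
    gam <- plogis(g)
    r <- st$bb - 2 * gam * st$ab + gam^2 * st$aa
    sum(r) / (2 * sigma2_d) + L * log(2 * pi * sigma2_d) +
      if (L > 1) sum(diff(g)^2) / (2 * sigma2_g) +
        (L - 1) / 2 * log(2 * pi * sigma2_g) else 0
  }
  f <- obj(g)
  for (it in 1:100) {
    gam <- plogis(g)
    w <- gam * (1 - gam)
    resid_dir <- st$ab - gam * st$aa       # a . e
    grad <- -w * resid_dir / sigma2_d
    if (L > 1) {
      grad <- grad + c(g[1] - g[2], if (L > 2) 2 * g[2:(L - 1)] -
                         g[1:(L - 2)] - g[3:L], g[L] - g[L - 1]) / sigma2_g
    }
    wp <- w * (1 - 2 * gam)
    hobs <- (-wp * resid_dir + w^2 * st$aa) / sigma2_d
    hobs_gn <- (w^2 * st$aa) / sigma2_d
    dd <- hobs + rw_diag
    if (any(dd <= 0) || is.na(tridiag_logdet(offd, dd)))
      dd <- hobs_gn + rw_diag
    step <- if (L == 1) grad / dd else thomas_solve(offd, dd, offd, grad)
    if (any(!is.finite(step))) break
    alpha <- 1
    repeat {
      gn <- pmin(pmax(g - alpha * step, -15), 15)
      fn <- obj(gn)
      if (is.finite(fn) && fn <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { gn <- g; fn <- f; break }
    }
    moved <- max(abs(g - gn))
    g <- gn
    f <- fn
    if (moved < 1e-9) break
  }
  gam <- plogis(g)
  w <- gam * (1 - gam)
  resid_dir <- st$ab - gam * st$aa
  wp <- w * (1 - 2 * gam)
  dd <- (-wp * resid_dir + w^2 * st$aa) / sigma2_d + rw_diag
  ld <- if (L == 1) log(max(dd, 1e-12)) else tridiag_logdet(offd, dd)
  if (is.na(ld)) {
    dd <- (w^2 * st$aa) / sigma2_d + rw_diag
    ld <- if (L == 1) log(max(dd, 1e-12)) else tridiag_logdet(offd, dd)
  }
  list(g = g, f = f, logdet = ld, dd = dd, offd = offd)
}

#' Jointly estimate time-varying move persistence across tracks
#'
#' Fits a hierarchical move-persistence model to one or more regular-step
#' predicted tracks: step vectors follow a first-difference autoregression
#' whose coefficient `gamma_t` in (0,1) is the move persistence, and
#' `logit(gamma_t)` evolves as a Gaussian random walk. Both the step-noise
#' variance and the latent random-walk variance are single pooled parameters
#' shared by all tracks, estimated by Laplace-approximated marginal maximum
#' likelihood; the smoothed `gamma_t` series carries pointwise standard
#' errors from the curvature of the Laplace objective.
#'
#' @param tracks a single data.frame or a list of data.frames with columns
#'   `x`, `y` (regular time step), e.g. [predict_regular()] outputs.
#' @param min_length tracks with fewer locations are excluded (warning).
#' @return object of class `mpm_fit`: pooled `sigma2_d` (m^2) and `sigma2_g`
#'   (logit-scale), marginal log-likelihood, and per-track data.frames with
#'   `gamma`, `gamma_se`, `gamma_logit`, `gamma_logit_se` aligned to the
#'   track's locations (end locations repeat the nearest interior estimate).
#' @export
fit_mpm_joint <- function(tracks, min_length = 10) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  ids <- names(tracks) %||% paste0("track", seq_along(tracks))
  keep <- vapply(tracks, nrow, 0L) >= min_length
  if (!all(keep)) {
    warning(sum(!keep), " track(s) shorter than ", min_length,
            " locations excluded")
    tracks <- tracks[keep]
    ids <- ids[keep]
  }
  if (!length(tracks)) stop("no usable tracks")
  stats <- lapply(tracks, function(d) mpm_stats(d[, c("x", "y")]))
  warm <- new.env()
  nll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 40)) return(1e10)
    s2d <- exp(theta[1]); s2g <- exp(theta[2])
    tot <- 0
    for (k in seq_along(stats)) {
      sol <- mpm_inner(stats[[k]], s2d, s2g,
                       g0 = warm[[as.character(k)]])
      warm[[as.character(k)]] <- sol$g
      if (is.na(sol$logdet)) return(1e10)
      tot <- tot + sol$f + 0.5 * sol$logdet -
        stats[[k]]$L / 2 * log(2 * pi)
    }
    if (!is.finite(tot)) 1e10 else tot
  }
  step_scale <- mean(unlist(lapply(stats, function(s) s$bb))) / 2
  theta0 <- c(log(max(step_scale, 1)), log(0.1))
  op <- optim(theta0, nll, method = "Nelder-Mead",
              control = list(maxit = 300, reltol = 1e-9))
  s2d <- exp(op$par[1]); s2g <- exp(op$par[2])
  per_track <- vector("list", length(stats))
  for (k in seq_along(stats)) {
    sol <- mpm_inner(stats[[k]], s2d, s2g, g0 = warm[[as.character(k)]])
    L <- stats[[k]]$L
    # pointwise latent SEs from the (regularized) tridiagonal curvature
    dd <- pmax(sol$dd, 1e-8)
    H <- diag(dd, L)
    if (L > 1) {
      H[cbind(1:(L - 1), 2:L)] <- sol$offd
      H[cbind(2:L, 1:(L - 1))] <- sol$offd
    }
    se_g <- tryCatch(sqrt(pmax(diag(solve(H)), 0)),
                     error = function(e) 1 / sqrt(dd))
    gam <- plogis(sol$g)
    se_gam <- gam * (1 - gam) * se_g
    Tn <- nrow(tracks[[k]])
    # gamma_t indexes interior locations 2..T-1; pad the ends
    idx <- c(1, seq_len(L), L)
    per_track[[k]] <- data.frame(
      track = ids[k], location = seq_len(Tn),
      gamma = gam[idx], gamma_se = se_gam[idx],
      gamma_logit = sol$g[idx], gamma_logit_se = se_g[idx])
  }
  names(per_track) <- ids
  structure(list(sigma2_d = s2d, sigma2_g = s2g,
                 logLik = -op$value, converged = op$convergence == 0,
                 tracks = per_track, n_tracks = length(per_track)),
            class = "mpm_fit")
}

#' @export
print.mpm_fit <- function(x, ...) {
  cat(sprintf(
    "mpm_fit: %d track(s), pooled sigma_d = %.1f m, sigma_g = %.3f\n",
    x$n_tracks, sqrt(x$sigma2_d), sqrt(x$sigma2_g)))
  cat(sprintf("  marginal logLik %.2f, converged: %s\n", x$logLik,
              x$converged))
  invisible(x)
}

#' @export
coef.mpm_fit <- function(object, ...) {
  c(sigma2_d = object$sigma2_d, sigma2_g = object$sigma2_g)
}

#' @export
fitted.mpm_fit <- function(object, ...) {
  do.call(rbind, object$tracks)
}

#' @export
summary.mpm_fit <- function(object, ...) {
  g <- unlist(lapply(object$tracks, `[[`, "gamma"))
  cat(sprintf(
    "move persistence over %d locations: mean %.3f, range [%.3f, %.3f]\n",
    length(g), mean(g), min(g), max(g)))
  invisible(object)
}

#' Normalize move-persistence series for cross-individual display
#'
#' Min--max rescaling of `gamma_t` to the unit interval, either with a single global
#' minimum/maximum across all supplied individuals (so the most and least
#' persistent locations anywhere map to 1 and 0) or per individual.
#' A constant input maps to 0.5 everywhere with a warning.
#'
#' @param series named list of numeric `gamma_t` vectors (one per
#'   individual), or a single numeric vector.
#' @param mode `"global"` or `"individual"`.
#' @return same shape as the input, rescaled.
#' @export
normalize_gamma <- function(series, mode = c("global", "individual")) {
  mode <- match.arg(mode)
  single <- !is.list(series)
  if (single) series <- list(series)
  rescale <- function(v, lo, hi) {
    if (hi - lo < 1e-12) {
      warning("constant move-persistence series; returning 0.5")
      return(rep(0.5, length(v)))
    }
    (v - lo) / (hi - lo)
  }
  out <- if (mode == "global") {
    lo <- min(unlist(series)); hi <- max(unlist(series))
    lapply(series, rescale, lo = lo, hi = hi)
  } else {
    lapply(series, function(v) rescale(v, min(v), max(v)))
  }
  if (single) out[[1]] else out
}
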