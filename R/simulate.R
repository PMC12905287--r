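#' Simulate a whale track with known behaviour and observe it with error
#'
#' Generates a true movement path at a fine (default hourly) step from a
#' first-difference correlated walk whose move persistence `gamma_t` is driven
#' by environmental covariates plus AR1 noise on the logit scale:
#' `logit(gamma_t) = beta0 + sum_k beta_k x_k(s_t) + z_t`,
#' `z_t = phi z_{t-1} + N(0, (1 - phi^2) sigma_z^2)`, and steps
#' `d_t = gamma_t d_{t-1} + N(0, sigma_step^2 I)`. Land (and the grid edge)
#' acts as a barrier: steps into it are re-proposed, then reversed. The true
#' path is then thinned to irregular observation times with optional dropout
#' gaps, and fixes are perturbed by Argos class-dependent elliptical Gaussian
#' error (or small circular GPS error).
#'
#' @param ss a [seascape_stack].
#' @param start projected start coordinates (m); must be at sea.
#' @param duration_days track duration (>= 2).
#' @param behaviour list: `beta0` (logit-scale intercept), `beta` (named
#'   vector of covariate coefficients applied to raw layer values; may be
#'   empty), `phi` (AR1 parameter of the latent logit-persistence noise),
#'   `sigma_z` (its stationary SD), `sigma_step` (step innovation SD, m).
#' @param obs list: `model` one of `"argos"`, `"gps"`, `"none"`; `p_keep`
#'   retention probability per fine-step time; `n_gaps`, `gap_hours` dropout
#'   gaps; `jitter_hours` uniform time jitter; `class_probs` named Argos class
#'   probabilities; `class_table` per-class ellipse scale overrides;
#'   `gps_sd_m` circular GPS error SD.
#' @param seed integer RNG seed.
#' @param step_hours fine simulation step (default 1 h).
#' @param id animal id string for the emitted fixes.
#' @param start_time POSIXct of the first location.
#' @return list with components `truth` (true path, true `gamma_t` and latent
#'   series, the generating parameters, the seed) and `fixes` (data.frame of
#'   observed fixes: id, deployment, timestamp, lon, lat, x, y, lc, smaj_m,
#'   smin_m, eor_deg, source).
#' @export
simulate_observed_track <- function(ss, start, duration_days = 30,
                                    behaviour = list(), obs = list(),
                                    seed, step_hours = 1, id = "W1",
                                    start_time = as.POSIXct(
                                      "2021-08-01 00:00:00", tz = "UTC")) {
  if (missing(seed)) stop("a seed is required")
  if (duration_days < 2) stop("duration must be at least 2 days")
  if (is_land_at(ss, start[1], start[2])) stop("start location is on land")

  beh <- modifyList(list(beta0 = 1.5, beta = c(), phi = 0.8, sigma_z = 1,
                         sigma_step = 1500), behaviour)
  ob <- modifyList(list(model = "argos", p_keep = 0.45, n_gaps = 2,
                        gap_hours = 24, jitter_hours = 0.4,
                        class_probs = c("3" = 0.009, "2" = 0.020,
                                        "1" = 0.051, "0" = 0.113,
                                        "A" = 0.168, "B" = 0.639),
                        class_table = NULL, gps_sd_m = 30), obs)
  unknown <- setdiff(names(beh$beta), names(ss$layers))
  if (length(unknown))
    stop("unknown covariate name(s) in beta: ",
         paste(unknown, collapse = ", "))

  with_seed(seed, {
    n <- round(duration_days * 24 / step_hours)
    pos <- matrix(NA_real_, n + 1, 2)
    pos[1, ] <- start
    gam <- numeric(n)
    zser <- numeric(n)
    d_prev <- beh$sigma_step * rnorm(2)
    z <- rnorm(1) * beh$sigma_z
    for (t in seq_len(n)) {
      z <- beh$phi * z + sqrt(1 - beh$phi^2) * beh$sigma_z * rnorm(1)
      lin <- beh$beta0
      if (length(beh$beta)) {
        xv <- extract_covariates(ss, pos[t, 1], pos[t, 2],
                                 layers = names(beh$beta))
        lin <- lin + sum(unlist(xv) * beh$beta)
      }
      g <- plogis(lin + z)
      gam[t] <- g
      zser[t] <- z
      ok <- FALSE
      for (try in 1:50) {
        d <- g * d_prev + beh$sigma_step * rnorm(2)
        cand <- pos[t, ] + d
        inside <- cand[1] > ss$origin[1] &&
          cand[1] < ss$origin[1] + ss$nx * ss$cell &&
          cand[2] > ss$origin[2] &&
          cand[2] < ss$origin[2] + ss$ny * ss$cell
        if (inside && !is_land_at(ss, cand[1], cand[2])) { ok <- TRUE; break }
      }
      if (!ok) { d <- -d_prev; cand <- pos[t, ] + d }
      pos[t + 1, ] <- cand
      d_prev <- d
    }
    times <- start_time + seq(0, n) * step_hours * 3600
    truth <- list(path = data.frame(time = times, x = pos[, 1], y = pos[, 2]),
                  gamma = gam, z = zser, behaviour = beh, seed = seed)

    keep <- runif(n + 1) <= ob$p_keep
    keep[1] <- TRUE
    if (ob$model == "none" && is.null(obs$p_keep)) keep[] <- TRUE
    if (ob$n_gaps > 0 && ob$model != "none") {
      for (gpos in sort(sample(seq(2, n - ob$gap_hours), ob$n_gaps))) {
        keep[gpos:(gpos + round(ob$gap_hours / step_hours))] <- FALSE
      }
    }
    idx <- which(keep)
    tt <- as.numeric(times[idx] - start_time, units = "hours")
    if (ob$model != "none" && ob$jitter_hours > 0) {
      tt <- tt + runif(length(tt), -ob$jitter_hours, ob$jitter_hours)
      o <- order(tt)
      idx <- idx[o]; tt <- sort(tt)
      dup <- c(FALSE, diff(tt) < 1 / 60)
      idx <- idx[!dup]; tt <- tt[!dup]
    }
    m <- length(idx)
    ctab <- argos_class_table
    if (!is.null(ob$class_table)) {
      for (r in seq_len(nrow(ob$class_table))) {
        k <- match(ob$class_table$lc[r], ctab$lc)
        ctab[k, c("smaj_m", "smin_m")] <-
          ob$class_table[r, c("smaj_m", "smin_m")]
      }
    }
    if (ob$model == "argos") {
      lc <- sample(names(ob$class_probs), m, replace = TRUE,
                   prob = ob$class_probs)
      sc <- ctab[match(lc, ctab$lc), ]
      sdlog <- 0.3
      smaj <- exp(rnorm(m, log(sc$smaj_m) - sdlog^2 / 2, sdlog))
      smin <- pmin(exp(rnorm(m, log(sc$smin_m) - sdlog^2 / 2, sdlog)), smaj)
      eor <- runif(m, 0, 180)
      err <- t(vapply(seq_len(m), function(i) {
        L <- chol(ellipse_cov(smaj[i], smin[i], eor[i]))
        as.numeric(t(L) %*% rnorm(2))
      }, numeric(2)))
      src <- "argos_kf"
    } else if (ob$model == "gps") {
      lc <- rep("G", m)
      smaj <- smin <- rep(ob$gps_sd_m, m)
      eor <- rep(0, m)
      err <- matrix(rnorm(2 * m, 0, ob$gps_sd_m), m, 2)
      src <- "gps"
    } else {
      lc <- rep("G", m)
      smaj <- smin <- rep(0, m)
      eor <- rep(0, m)
      err <- matrix(0, m, 2)
      src <- "gps"
    }
    ox <- pos[idx, 1] + err[, 1]
    oy <- pos[idx, 2] + err[, 2]
    ll <- unproject_polar(ox, oy)
    fixes <- data.frame(id = id, deployment = paste0(id, "-d1"),
                        timestamp = start_time + tt * 3600,
                        lon = ll$lon, lat = ll$lat, x = ox, y = oy,
                        lc = lc, smaj_m = smaj, smin_m = smin,
                        eor_deg = eor, source = src,
                        stringsAsFactors = FALSE)
    list(truth = truth, fixes = fixes)
  })
}

#' Generate a used/available test set with known selection coefficients
#'
#' Ground-truth generator for exercising the resource-selection machinery.
#' In `iid` mode, used points are drawn from the sea-cell candidate pool with
#' probability proportional to `exp(beta' x)` (coefficients apply to raw layer
#' values), so a plain logistic regression of used vs uniformly-drawn
#' available points recovers `beta` asymptotically. In `movement` mode a
#' habitat-biased track is produced by per-step choice among candidate steps
#' weighted by `exp(beta' x)`; recovery is then approximate but
#' sign-consistent.
#'
#' @param ss a [seascape_stack].
#' @param beta named numeric vector of selection coefficients (names must be
#'   layers of `ss`).
#' @param n_used number of used locations.
#' @param mode `"iid"` or `"movement"`.
#' @param seed integer RNG seed.
#' @param n_candidates per-step candidate count in movement mode.
#' @param sigma_step movement-mode step SD (m).
#' @return list with `used` (data.frame x, y), `avail_fun(n, seed)` drawing
#'   available points uniformly over sea cells, and `truth` (beta, mode,
#'   seed).
#' @export
generate_rsf_testset <- function(ss, beta, n_used, mode = c("iid", "movement"),
                                 seed, n_candidates = 15,
                                 sigma_step = 4000) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required")
  unknown <- setdiff(names(beta), names(ss$layers))
  if (length(unknown))
    stop("unknown covariate name(s) in beta: ",
         paste(unknown, collapse = ", "))
  cc <- cell_centres(ss)
  sea_idx <- which(!ss$land, arr.ind = TRUE)
  sx <- cc$x[sea_idx[, 1]]
  sy <- cc$y[sea_idx[, 2]]
  X <- vapply(names(beta), function(nm) ss$layers[[nm]][sea_idx],
              numeric(nrow(sea_idx)))
  eta <- if (length(beta)) as.numeric(X %*% beta) else rep(0, length(sx))
  w <- exp(eta - max(eta))
  jit <- function(n) runif(n, -ss$cell / 2, ss$cell / 2)

  avail_fun <- function(n, seed = NULL) {
    draw <- function() {
      k <- sample.int(length(sx), n, replace = TRUE)
      data.frame(x = sx[k] + jit(n), y = sy[k] + jit(n))
    }
    if (is.null(seed)) draw() else with_seed(seed, draw())
  }

  used <- with_seed(seed, {
    if (mode == "iid") {
      k <- sample.int(length(sx), n_used, replace = TRUE, prob = w)
      data.frame(x = sx[k] + jit(n_used), y = sy[k] + jit(n_used))
    } else {
      # habitat-biased correlated walk: pick among candidate steps by weight
      pos <- matrix(NA_real_, n_used, 2)
      pos[1, ] <- c(sx[which.max(w)], sy[which.max(w)])
      head_ang <- runif(1, 0, 2 * pi)
      for (t in 2:n_used) {
        ang <- head_ang + rnorm(n_candidates, 0, 1.2)
        len <- abs(rnorm(n_candidates, sigma_step, sigma_step / 2))
        cx <- pos[t - 1, 1] + len * cos(ang)
        cy <- pos[t - 1, 2] + len * sin(ang)
        okx <- cx > ss$origin[1] & cx < ss$origin[1] + ss$nx * ss$cell &
          cy > ss$origin[2] & cy < ss$origin[2] + ss$ny * ss$cell
        okx[okx] <- !is_land_at(ss, cx[okx], cy[okx])
        if (!any(okx)) { pos[t, ] <- pos[t - 1, ]; next }
        cxv <- cx[okx]; cyv <- cy[okx]; angv <- ang[okx]
        xv <- extract_covariates(ss, cxv, cyv, layers = names(beta))
        et <- as.numeric(as.matrix(xv) %*% beta)
        p <- exp(et - max(et))
        pick <- sample.int(length(cxv), 1, prob = p)
        pos[t, ] <- c(cxv[pick], cyv[pick])
        head_ang <- angv[pick]
      }
      data.frame(x = pos[, 1], y = pos[, 2])
    }
  })
  list(used = used, avail_fun = avail_fun,
       truth = list(beta = beta, mode = mode, seed = seed))
}
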