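#' Assemble the behaviour-model design at track locations
#'
#' Extracts environmental covariates at each location of one or more
#' gamma-annotated tracks, applies the depth spline and pooled
#' standardization, and returns a modelling data.frame for
#' [fit_lmm_ar1()].
#'
#' @param tracks named list (by segment id) of data.frames with `x`, `y`,
#'   `gamma_logit` and an `animal` column.
#' @param ss a [seascape_stack].
#' @param knots depth-spline interior knots (m).
#' @param covariates raw layers to include alongside the depth spline.
#' @return data.frame: `individual`, `segment`, `gamma_logit`, `dpth_1` ..
#'   `dpth_4` and standardized covariate columns.
#' @export
build_behaviour_design <- function(tracks, ss, knots = c(220, 500, 2500),
                                   covariates = c("slope", "dist_shelf",
                                                  "dist_glacier", "sst",
                                                  "ssh")) {
  d <- do.call(rbind, lapply(names(tracks), function(sid) {
    tr <- tracks[[sid]]
    data.frame(individual = tr$animal %||% sid, segment = sid,
               gamma_logit = tr$gamma_logit, x = tr$x, y = tr$y)
  }))
  cv <- extract_covariates(ss, d$x, d$y,
                           layers = union("depth", covariates),
                           clamp = TRUE)
  B <- natural_spline_basis(cv$depth, knots = knots)
  for (j in seq_len(ncol(B))) {
    v <- B[, j]
    d[[colnames(B)[j]]] <- (v - mean(v)) / sd(v)
  }
  for (nm in covariates) {
    v <- cv[[nm]]
    d[[nm]] <- (v - mean(v)) / sd(v)
  }
  d
}

#' Run the full telemetry analysis chain on synthetic whales
#'
#' Convenience driver wiring every stage together on generated data:
#' seascape generation, track simulation with known behaviour, fix
#' filtering/segmentation, state-space model fitting and selection,
#' regular-step prediction with land re-routing, joint move-persistence
#' estimation, kernel home range with contour areas (and seasonal overlap
#' when the tracks span seasons), availability simulation with the
#' similarity filter, the Monte-Carlo resource-selection fit, and the
#' AR1 mixed model of behaviour against the environment. Deterministic for
#' a given seed.
#'
#' @param seed integer master seed.
#' @param n_whales number of simulated animals.
#' @param duration_days tracking duration per animal.
#' @param behaviour true behaviour parameters passed to
#'   [simulate_observed_track()].
#' @param rsf_covariates covariate spec for [build_design()].
#' @param n_sim,k_keep availability simulation settings.
#' @param min_length minimum segment length (fixes).
#' @param h_mult kernel bandwidth multiplier of `h_ref`.
#' @param run_loocv run leave-one-out cross-validation of the behaviour
#'   model (slowest step; off by default).
#' @return list with components `seascape`, `truths`, `segments`, `fits`,
#'   `predicted` (named list), `mpm`, `ud`, `contours`, `overlap`, `sims`,
#'   `rsf`, `behaviour_data`, `lmm`, `cv`.
#' @export
run_pipeline <- function(seed, n_whales = 10, duration_days = 30,
                         behaviour = list(beta0 = 0.8,
                                          beta = c(sst = -0.4),
                                          phi = 0.7, sigma_z = 0.8,
                                          sigma_step = 1800),
                         rsf_covariates = c("depth_spline", "sst",
                                            "in_ice", "ice", "ice_sq"),
                         n_sim = 100, k_keep = 20, min_length = 54,
                         h_mult = 0.6, run_loocv = FALSE) {
  ss <- generate_seascape(seed = seed)
  cc <- cell_centres(ss)
  sea_idx <- which(!ss$land, arr.ind = TRUE)
  # start whales well inside the sea area
  starts <- with_seed(seed + 1, {
    far <- sea_idx[sea_idx[, 1] > ss$nx * 0.35, , drop = FALSE]
    k <- sample(nrow(far), n_whales)
    cbind(cc$x[far[k, 1]], cc$y[far[k, 2]])
  })
  truths <- list()
  fixes <- list()
  for (w in seq_len(n_whales)) {
    sim <- simulate_observed_track(
      ss, start = starts[w, ], duration_days = duration_days,
      behaviour = behaviour, seed = seed + 10 + w,
      id = sprintf("GW%02d", w),
      start_time = as.POSIXct("2021-08-01", tz = "UTC") +
        (w - 1) * 86400 * 10)
    truths[[w]] <- sim$truth
    fixes[[w]] <- sim$fixes
  }
  fx <- read_fixes(do.call(rbind, fixes))
  prep <- filter_and_segment(fx, min_length = min_length)

  fits <- list(); predicted <- list()
  for (sid in names(prep$segments)) {
    seg <- prep$segments[[sid]]
    cand <- list(fit_ssm(seg, "rw"), fit_ssm(seg, "crw"))
    sel <- validate_and_select(cand, n_replicates = 20, seed = seed + 2)
    fits[[sid]] <- sel$fit
    pr <- predict_regular(sel$fit, step_hours = 4)
    predicted[[sid]] <- reroute(pr, ss)
  }

  mpm <- fit_mpm_joint(predicted)
  for (sid in names(predicted)) {
    predicted[[sid]]$gamma <- mpm$tracks[[sid]]$gamma
    predicted[[sid]]$gamma_logit <- mpm$tracks[[sid]]$gamma_logit
  }

  all_pred <- do.call(rbind, predicted)
  S <- cov(cbind(all_pred$x, all_pred$y))
  h_ref <- sqrt((S[1, 1] + S[2, 2]) / 2) * nrow(all_pred)^(-1 / 6)
  ud <- kde_ud(all_pred[, c("x", "y")], bandwidth = h_mult * h_ref,
               cell = ss$cell)
  contours <- contour_areas(ud)
  seas <- season_of(all_pred$timestamp)
  overlap <- NULL
  st <- table(seas)
  have <- names(st)[st >= 50]
  if (length(have) >= 2) {
    uds <- lapply(have, function(s) {
      p <- all_pred[seas == s, c("x", "y")]
      # shared bandwidth and grid for comparability
      kde_on_grid(p, ud, bandwidth = h_mult * h_ref)
    })
    pairs <- combn(length(have), 2)
    overlap <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      rbind(bhattacharyya_overlap(uds[[i]], uds[[j]], 0.95,
                                  labels = have[c(i, j)]),
            bhattacharyya_overlap(uds[[i]], uds[[j]], 0.50,
                                  labels = have[c(i, j)]))
    }))
  }

  sims <- list()
  for (sid in names(predicted)) {
    sims[[sid]] <- simulate_and_filter(fits[[sid]], predicted[[sid]],
                                       n_sim = n_sim, k_keep = k_keep,
                                       barrier = ss, seed = seed + 3)
  }
  des <- build_design(predicted, sims, ss, covariates = rsf_covariates,
                      clamp = TRUE)
  rsf <- fit_mc_rsf(des, n_fits = k_keep, seed = seed + 4)

  bdat <- build_behaviour_design(predicted, ss)
  lmm <- fit_lmm_ar1(
    gamma_logit ~ dpth_1 + dpth_2 + dpth_3 + dpth_4 + slope +
      dist_shelf + dist_glacier + sst + ssh,
    bdat, groups = "individual", segments = "segment", mode = "REML")
  cv <- if (run_loocv) loocv(lmm) else NULL

  list(seascape = ss, truths = truths, segments = prep$segments,
       audit = prep$audit, fits = fits, predicted = predicted, mpm = mpm,
       h_ref = h_ref, ud = ud, contours = contours, overlap = overlap,
       sims = sims, design = des, rsf = rsf, behaviour_data = bdat,
       lmm = lmm, cv = cv)
}

# evaluate a KDE on an existing ud's grid (shared geometry for overlap)
kde_on_grid <- function(points, ud, bandwidth) {
  nx <- nrow(ud$density); ny <- ncol(ud$density)
  cx <- ud$origin[1] + (seq_len(nx) - 0.5) * ud$cell
  cy <- ud$origin[2] + (seq_len(ny) - 0.5) * ud$cell
  A <- vapply(points$x, function(xk) dnorm(cx, xk, bandwidth), numeric(nx))
  B <- vapply(points$y, function(yk) dnorm(cy, yk, bandwidth), numeric(ny))
  D <- (A %*% t(B)) / nrow(points)
  D <- D / (sum(D) * ud$cell^2)
  structure(list(origin = ud$origin, cell = ud$cell, density = D,
                 n_points = nrow(points), bandwidth = bandwidth),
            class = "ud_grid")
}

#' Write predicted tracks as CSV
#'
#' @param predicted named list of [predict_regular()] tracks (possibly with
#'   `gamma` columns appended).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_predicted_csv <- function(predicted, path) {
  d <- do.call(rbind, predicted)
  ll <- unproject_polar(d$x, d$y)
  d$lon <- ll$lon
  d$lat <- ll$lat
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
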