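#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` where `k` is the number of estimated
#' parameters and `n` the number of observations. Defined as a generic so the
#' package's fitted-model classes can supply their own `n` and `k`.
#'
#' @param object a fitted model object, or a numeric log-likelihood.
#' @param ... passed to methods; for the default method, `k` and `n`.
#' @return the AICc value (numeric scalar).
#' @export
AICc <- function(object, ...) UseMethod("AICc")

#' @rdname AICc
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @export
AICc.default <- function(object, k, n, ...) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * as.numeric(object) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
AICc.logLik <- function(object, ...) {
  k <- attr(object, "df")
  n <- attr(object, "nobs")
  AICc.default(as.numeric(object), k = k, n = n)
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

#' Map month numbers to oceanographic seasons
#'
#' Seasons follow the meteorological convention used throughout the package:
#' spring = March--May, summer = June--August, fall = September--November,
#' winter = December--February.
#'
#' @param month integer month (1--12), or a `POSIXt`/`Date` vector.
#' @return factor with levels `winter`, `spring`, `summer`, `fall`.
#' @export
#' @examples
#' season_of(c(1, 4, 7, 10))
season_of <- function(month) {
  if (inherits(month, "POSIXt") || inherits(month, "Date"))
    month <- as.integer(format(month, "%m"))
  stopifnot(all(month %in% 1:12))
  s <- c("winter", "winter", "spring", "spring", "spring",
         "summer", "summer", "summer", "fall", "fall", "fall", "winter")
  factor(s[month], levels = c("winter", "spring", "summer", "fall"))
}

#' Argos location-class error table
#'
#' Default semi-major/semi-minor error-ellipse axes (1-sigma, metres) per Argos
#' location class, used both by the track simulator and as the isotropic
#' fallback for least-squares fixes without ellipse metadata. Magnitudes are
#' synthetic defaults in the range of published Argos accuracy studies; real
#' Kalman-filtered deployments carry per-fix ellipses that override them.
#'
#' @format data.frame with columns `lc`, `smaj_m`, `smin_m`.
#' @export
argos_class_table <- data.frame(
  lc = c("3", "2", "1", "0", "A", "B", "G"),
  smaj_m = c(250, 500, 1500, 5000, 4000, 8000, 30),
  smin_m = c(150, 300, 750, 2500, 2000, 4000, 30),
  stringsAsFactors = FALSE
)

# quality ordering for duplicate-fix resolution (best first)
.lc_quality <- c("G", "3", "2", "1", "0", "A", "B")

#' Project lon/lat to planar metres (north polar stereographic)
#'
#' Spherical polar stereographic projection centred on the north pole with a
#' true-scale latitude, adequate for the planar movement arithmetic this
#' package performs on Arctic tracks. Not a geodesy-grade implementation.
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0 central meridian (degrees).
#' @param lat_ts latitude of true scale (degrees).
#' @return data.frame with columns `x`, `y` in metres.
#' @export
project_polar <- function(lon, lat, lon0 = 0, lat_ts = 71) {
  R_E <- 6371000
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  # rho = 2 R k0 tan(pi/4 - phi/2); k0 chosen so scale is true at lat_ts
  k0 <- (1 + sin(lat_ts * pi / 180)) / 2
  rho <- 2 * R_E * k0 * tan(pi / 4 - phi / 2)
  data.frame(x = rho * sin(lam), y = -rho * cos(lam))
}

#' Inverse of [project_polar()]
#' @param x,y projected coordinates (metres).
#' @inheritParams project_polar
#' @return data.frame with columns `lon`, `lat` (degrees).
#' @export
unproject_polar <- function(x, y, lon0 = 0, lat_ts = 71) {
  R_E <- 6371000
  k0 <- (1 + sin(lat_ts * pi / 180)) / 2
  rho <- sqrt(x^2 + y^2)
  phi <- pi / 2 - 2 * atan(rho / (2 * R_E * k0))
  lam <- atan2(x, -y)
  data.frame(lon = lam * 180 / pi + lon0, lat = phi * 180 / pi)
}

# run expr with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# 2x2 observation covariance from an error ellipse (orientation in degrees
# clockwise from north, axes = 1-sigma metres)
ellipse_cov <- function(smaj, smin, eor_deg) {
  th <- eor_deg * pi / 180
  u <- c(sin(th), cos(th))   # unit vector along semi-major axis
  v <- c(cos(th), -sin(th))
  smaj^2 * tcrossprod(u) + smin^2 * tcrossprod(v)
}

# wrap angle difference to (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}
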