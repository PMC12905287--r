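#' Read telemetry fixes from CSV
#'
#' Parses a fix table with columns `id, timestamp, lon, lat, lc, smaj_m,
#' smin_m, eor_deg, source` (optional: `deployment`, `x`, `y`). Rows are
#' sorted by (animal, deployment, timestamp); duplicate timestamps within a
#' deployment collapse to the higher-quality fix (quality order G, 3, 2, 1,
#' 0, A, B). Projected coordinates are attached via [project_polar()] when
#' not supplied.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param lon0,lat_ts projection parameters (see [project_polar()]).
#' @return data.frame of fixes with projected `x`, `y`.
#' @export
read_fixes <- function(path, lon0 = 0, lat_ts = 71) {
  d <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "lon", "lat", "lc")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$deployment)) d$deployment <- paste0(d$id, "-d1")
  if (is.null(d$source)) d$source <- "argos_kf"
  parse_ts <- function(v) {
    if (inherits(v, "POSIXct")) return(v)
    fmts <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
              "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
    out <- as.POSIXct(rep(NA_real_, length(v)), tz = "UTC")
    for (f in fmts) {
      miss <- is.na(out)
      if (!any(miss)) break
      out[miss] <- as.POSIXct(strptime(v[miss], f, tz = "UTC"))
    }
    out
  }
  ts <- parse_ts(d$timestamp)
  bad <- which(is.na(ts) & !is.na(d$timestamp))
  if (length(bad))
    stop("unparseable timestamp at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  d$timestamp <- ts
  d$lc <- as.character(d$lc)
  bad <- which(!d$lc %in% .lc_quality)
  if (length(bad))
    stop("unknown location class '", d$lc[bad[1]], "' at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  if (is.null(d$x) || is.null(d$y)) {
    xy <- project_polar(d$lon, d$lat, lon0 = lon0, lat_ts = lat_ts)
    d$x <- xy$x
    d$y <- xy$y
  }
  if (is.null(d$smaj_m)) d$smaj_m <- NA_real_
  if (is.null(d$smin_m)) d$smin_m <- NA_real_
  if (is.null(d$eor_deg)) d$eor_deg <- NA_real_
  if (any(!is.na(d$smaj_m) & !is.na(d$smin_m) & d$smaj_m < d$smin_m))
    stop("error ellipse semi-major axis smaller than semi-minor axis")
  d <- d[order(d$id, d$deployment, d$timestamp,
               match(d$lc, .lc_quality)), ]
  dup <- duplicated(d[, c("id", "deployment", "timestamp")])
  d <- d[!dup, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Quality-filter fixes and split them into track segments
#'
#' A forward-pass speed filter removes fixes implying a speed above
#' `max_speed` relative to the last retained fix (planar distance / elapsed
#' time), then tracks are split wherever the gap between consecutive retained
#' fixes exceeds `max_gap_h`, and segments shorter than `min_length` fixes
#' are dropped. The default minimum of 54 locations is the shortest segment
#' length that reliably supports state-space model fitting in this pipeline.
#'
#' @param fixes data.frame from [read_fixes()].
#' @param max_speed maximum plausible speed, m/s.
#' @param max_gap_h maximum within-segment gap, hours.
#' @param min_length minimum segment length, fixes.
#' @return list with `segments` (list of fix data.frames, each carrying a
#'   `segment_id` attribute and column) and `audit` (named counts:
#'   `retained`, `removed_speed`, `removed_short_segment`).
#' @export
filter_and_segment <- function(fixes, max_speed = 2, max_gap_h = 72,
                               min_length = 54) {
  if (max_speed <= 0 || max_gap_h <= 0 || min_length <= 0)
    stop("thresholds must be positive")
  segs <- list()
  n_speed <- 0L
  n_short <- 0L
  for (key in unique(paste(fixes$id, fixes$deployment, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    d <- fixes[fixes$id == parts[1] & fixes$deployment == parts[2], ,
               drop = FALSE]
    d <- d[order(d$timestamp), , drop = FALSE]
    # forward-pass speed filter against the last retained fix
    keep <- logical(nrow(d))
    keep[1] <- TRUE
    last <- 1L
    for (i in seq_len(nrow(d))[-1]) {
      dt <- as.numeric(d$timestamp[i] - d$timestamp[last], units = "secs")
      dist <- sqrt((d$x[i] - d$x[last])^2 + (d$y[i] - d$y[last])^2)
      if (dt > 0 && dist / dt <= max_speed) {
        keep[i] <- TRUE
        last <- i
      }
    }
    n_speed <- n_speed + sum(!keep)
    d <- d[keep, , drop = FALSE]
    # split at gaps
    gaps <- c(0, as.numeric(diff(d$timestamp), units = "hours"))
    grp <- cumsum(gaps > max_gap_h)
    for (g in unique(grp)) {
      s <- d[grp == g, , drop = FALSE]
      if (nrow(s) < min_length) {
        n_short <- n_short + nrow(s)
      } else {
        sid <- sprintf("%s_%s_s%d", parts[1], parts[2], g + 1L)
        s$segment_id <- sid
        rownames(s) <- NULL
        attr(s, "segment_id") <- sid
        segs[[sid]] <- s
      }
    }
  }
  retained <- sum(vapply(segs, nrow, 0L))
  list(segments = segs,
       audit = c(retained = retained, removed_speed = n_speed,
                 removed_short_segment = n_short))
}

#' Truncate temporally overlapping tracks on one animal
#'
#' When one animal carries several tags whose tracks overlap in time, only
#' the highest-priority track's fixes are retained inside each overlapping
#' window; non-overlapping portions are untouched. Priority 1 is highest.
#'
#' @param tracks list of fix data.frames (each time-sorted, one per tag).
#' @param priority integer vector, one rank per track (1 = keep in overlap).
#' @return list of tracks, same order, overlapping fixes removed from
#'   lower-priority tracks. Tracks emptied entirely are kept as zero-row
#'   data.frames and flagged with a message.
#' @export
truncate_overlap <- function(tracks, priority) {
  if (length(priority) != length(tracks))
    stop("one priority rank per track is required")
  if (anyNA(priority)) stop("missing priority for an overlapping pair")
  spans <- lapply(tracks, function(d) range(d$timestamp))
  out <- tracks
  for (i in seq_along(tracks)) {
    for (j in seq_along(tracks)) {
      if (i == j || priority[j] >= priority[i]) next
      # j has higher priority (smaller rank): drop i's fixes inside j's span
      ov_lo <- max(spans[[i]][1], spans[[j]][1])
      ov_hi <- min(spans[[i]][2], spans[[j]][2])
      if (ov_lo <= ov_hi) {
        d <- out[[i]]
        out[[i]] <- d[d$timestamp < ov_lo | d$timestamp > ov_hi, ,
                      drop = FALSE]
      }
    }
    if (nrow(out[[i]]) == 0 && nrow(tracks[[i]]) > 0)
      message("track ", i, " removed entirely by overlap truncation")
  }
  out
}
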