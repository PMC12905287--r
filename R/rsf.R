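## Modified resource-selection function: used (predicted) vs available
## (simulated) locations, fitted as 20 Monte-Carlo logistic regressions with
## a per-segment random intercept and aggregated across fits.

#' Natural cubic spline basis for depth
#'
#' Natural cubic spline basis with the supplied interior knots and boundary
#' knots at the data range, linear beyond the boundaries. With the default
#' three interior knots (220, 500, 2500 m) this yields four basis columns,
#' `dpth_1` .. `dpth_4`.
#'
#' @param values numeric vector (depths in metres).
#' @param knots strictly increasing interior knots.
#' @param boundary optional boundary knots (default data range).
#' @param prefix column-name prefix.
#' @return matrix with `length(knots) + 1` columns; attributes `knots` and
#'   `boundary` allow re-evaluating the same basis on new data.
#' @export
natural_spline_basis <- function(values, knots = c(220, 500, 2500),
                                 boundary = range(values, na.rm = TRUE),
                                 prefix = "dpth_") {
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (missing(boundary) && length(unique(values[is.finite(values)])) < 2)
    stop("need at least 2 distinct values to set boundary knots")
  # interior knots must lie strictly inside the boundary; when the data do
  # not span a knot (e.g. a shelf-only track set and the 2500 m knot) the
  # boundary is widened to keep the basis well defined
  if (min(knots) <= boundary[1])
    boundary[1] <- min(knots) - 0.01 * diff(range(knots))
  if (max(knots) >= boundary[2])
    boundary[2] <- max(knots) + 0.01 * diff(range(knots))
  B <- splines::ns(values, knots = knots, Boundary.knots = boundary)
  B <- unclass(B)[, , drop = FALSE]
  colnames(B) <- paste0(prefix, seq_len(ncol(B)))
  attr(B, "knots") <- knots
  attr(B, "boundary") <- boundary
  B
}

#' Build the used/available design for resource selection
#'
#' Assembles one row per used (predicted) and available (retained simulated)
#' location, attaches covariates by nearest-cell lookup, applies the
#' transforms (depth spline, inside-ice-edge indicator from the sign of the
#' distance to the ice edge, squared standardized ice concentration) and
#' standardizes continuous columns on the pooled used+available rows. The
#' scaling record is returned for reuse on new data.
#'
#' @param used named list (by segment id) of used-location data.frames with
#'   `x`, `y` (e.g. [predict_regular()] outputs).
#' @param sims named list (by segment id) of [simulate_and_filter()] results
#'   (only retained simulations enter the design).
#' @param ss a [seascape_stack].
#' @param covariates character vector of raw layers and/or the derived terms
#'   `"depth_spline"`, `"in_ice"`, `"ice_sq"`.
#' @param knots interior knots of the depth spline (metres).
#' @param clamp snap out-of-extent locations to the nearest edge cell instead
#'   of raising an error.
#' @return list: `design` (data.frame `use`, `segment`, `sim`, covariate
#'   columns), `scaling` (centres/scales and spline knots), `terms` (term ->
#'   column mapping used by the stepwise procedure).
#' @export
build_design <- function(used, sims, ss,
                         covariates = c("depth_spline", "sst", "in_ice",
                                        "ice", "ice_sq"),
                         knots = c(220, 500, 2500), clamp = FALSE) {
  segs <- names(used)
  if (is.null(segs)) stop("`used` must be a named list keyed by segment id")
  rows <- list()
  for (sid in segs) {
    u <- used[[sid]]
    rows[[length(rows) + 1]] <-
      data.frame(use = 1, segment = sid, sim = NA_integer_,
                 x = u$x, y = u$y)
    if (!is.null(sims[[sid]])) {
      ret <- which(sims[[sid]]$retained)
      for (r in seq_along(ret)) {
        s <- sims[[sid]]$tracks[[ret[r]]]
        rows[[length(rows) + 1]] <-
          data.frame(use = 0, segment = sid, sim = r, x = s$x, y = s$y)
      }
    }
  }
  d <- do.call(rbind, rows)
  need <- intersect(covariates, names(ss$layers))
  if ("depth_spline" %in% covariates) need <- union(need, "depth")
  if ("in_ice" %in% covariates) need <- union(need, "dist_ice_edge")
  if ("ice_sq" %in% covariates) need <- union(need, "ice")
  cv <- extract_covariates(ss, d$x, d$y, layers = need, clamp = clamp)
  bad <- which(!complete.cases(cv))
  if (length(bad))
    stop("covariates unavailable at rows: ",
         paste(head(bad, 10), collapse = ", "))

  out <- d[, c("use", "segment", "sim")]
  center <- c(); scale_ <- c()
  std <- function(v, nm) {
    mu <- mean(v); sdv <- sd(v)
    if (sdv < 1e-12) stop("covariate '", nm, "' is constant")
    center[nm] <<- mu; scale_[nm] <<- sdv
    (v - mu) / sdv
  }
  spline_info <- NULL
  ice_std <- NULL
  for (cvn in covariates) {
    if (cvn == "depth_spline") {
      B <- natural_spline_basis(cv$depth, knots = knots)
      spline_info <- list(knots = attr(B, "knots"),
                          boundary = attr(B, "boundary"))
      for (j in seq_len(ncol(B)))
        out[[colnames(B)[j]]] <- std(B[, j], colnames(B)[j])
    } else if (cvn == "in_ice") {
      out$in_ice <- as.numeric(cv$dist_ice_edge < 0)
    } else if (cvn == "ice_sq") {
      if (is.null(ice_std)) ice_std <- std(cv$ice, "ice")
      out$ice_sq <- std(ice_std^2, "ice_sq")
    } else if (cvn == "ice") {
      if (is.null(ice_std)) ice_std <- std(cv$ice, "ice")
      out$ice <- ice_std
    } else {
      out[[cvn]] <- std(cv[[cvn]], cvn)
    }
  }
  terms <- list()
  for (cvn in covariates) {
    terms[[cvn]] <- if (cvn == "depth_spline")
      grep("^dpth_", names(out), value = TRUE) else cvn
  }
  list(design = out,
       scaling = list(center = center, scale = scale_,
                      spline = spline_info),
       terms = terms)
}

fit_one_logistic <- function(dat, cols, random_effect = TRUE) {
  rhs <- if (length(cols)) paste(sprintf("`%s`", cols), collapse = " + ")
    else "1"
  sep_flag <- FALSE
  if (random_effect && length(unique(dat$segment)) > 1) {
    f <- as.formula(paste("use ~", rhs, "+ (1 | segment)"))
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(f, data = dat, family = binomial)))
    re_var <- as.numeric(lme4::VarCorr(fit)$segment[1])
    if (re_var < 1e-8) {
      fit <- glm(as.formula(paste("use ~", rhs)), data = dat,
                 family = binomial)
      beta <- coef(fit)
    } else {
      beta <- lme4::fixef(fit)
    }
  } else {
    fit <- suppressWarnings(glm(as.formula(paste("use ~", rhs)), data = dat,
                                family = binomial))
    beta <- coef(fit)
    re_var <- 0
  }
  if (any(!is.finite(beta)) || max(abs(beta[-1])) > 20) sep_flag <- TRUE
  names(beta) <- sub("^`|`$", "", names(beta))
  list(beta = beta, re_var = re_var, separated = sep_flag)
}

#' Monte-Carlo aggregated resource-selection fit
#'
#' Builds `n_fits` model datasets, each containing every used location plus
#' one simulated availability track per segment (simulations assigned to
#' datasets without replacement, i.e. a random permutation per segment),
#' fits each as a logistic regression with a per-segment random intercept
#' (Laplace approximation via lme4; plain logistic when the estimated
#' random-effect variance collapses), and aggregates: the reported
#' coefficient is the mean across fits, its SE the SD across fits, the CI
#' mean +/- 1.96 SE, and the p-value a two-sided normal test of mean/SE.
#' This Monte-Carlo aggregation counters the variance deflation caused by
#' autocorrelated used and available locations.
#'
#' @param design a [build_design()] result (or its `design` data.frame plus
#'   a `terms` list).
#' @param n_fits number of Monte-Carlo datasets (default 20).
#' @param seed integer RNG seed for the random assignment.
#' @param random_effect include the per-segment random intercept.
#' @param columns optional subset of covariate columns to fit.
#' @return object of class `mc_rsf`: `table` (covariate, lower, coef, upper,
#'   p), `coef_matrix` (n_fits x p), `re_var`, `excluded` fit indices,
#'   `terms`, `seed`.
#' @export
fit_mc_rsf <- function(design, n_fits = 20, seed, random_effect = TRUE,
                       columns = NULL) {
  if (missing(seed)) stop("a seed is required")
  d <- design$design %||% design
  terms <- design$terms
  cols <- columns %||% setdiff(names(d), c("use", "segment", "sim"))
  segs <- unique(d$segment)
  n_sims <- vapply(segs, function(s)
    length(unique(na.omit(d$sim[d$segment == s & d$use == 0]))), 0L)
  if (any(n_sims != n_fits))
    stop("every segment must have exactly ", n_fits,
         " retained simulations (found ",
         paste(unique(n_sims), collapse = ","), ")")
  used <- d[d$use == 1, , drop = FALSE]
  avail <- d[d$use == 0, , drop = FALSE]
  fits <- with_seed(seed, {
    assign_tab <- lapply(segs, function(s) sample.int(n_fits))
    names(assign_tab) <- segs
    lapply(seq_len(n_fits), function(k) {
      pick <- do.call(rbind, lapply(segs, function(s)
        avail[avail$segment == s & avail$sim == assign_tab[[s]][k], ,
              drop = FALSE]))
      dat <- rbind(used, pick)
      fit_one_logistic(dat, cols, random_effect)
    })
  })
  excluded <- which(vapply(fits, `[[`, TRUE, "separated"))
  if (length(excluded))
    warning(length(excluded),
            " Monte-Carlo fit(s) showed separation and were excluded")
  ok <- setdiff(seq_len(n_fits), excluded)
  if (!length(ok)) stop("all Monte-Carlo fits failed")
  cm <- do.call(rbind, lapply(fits[ok], `[[`, "beta"))
  mu <- colMeans(cm)
  se <- apply(cm, 2, sd)
  if (any(se < 1e-12)) {
    warning("degenerate aggregation: zero coefficient spread across fits")
    se[se < 1e-12] <- NA_real_
  }
  p <- 2 * pnorm(-abs(mu / se))
  tab <- data.frame(covariate = names(mu), lower = mu - 1.96 * se,
                    coef = mu, upper = mu + 1.96 * se, se = se,
                    p_value = p, row.names = NULL)
  structure(list(table = tab, coef_matrix = cm,
                 re_var = vapply(fits[ok], `[[`, 0, "re_var"),
                 excluded = excluded, n_fits = n_fits, seed = seed,
                 columns = cols, terms = terms,
                 random_effect = random_effect),
            class = "mc_rsf")
}

#' @export
print.mc_rsf <- function(x, digits = 3, ...) {
  cat(sprintf("Monte-Carlo resource selection: %d fits (%d excluded)\n",
              x$n_fits, length(x$excluded)))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mc_rsf <- function(object, ...) {
  setNames(object$table$coef, object$table$covariate)
}

#' @export
summary.mc_rsf <- function(object, ...) {
  cat(sprintf("random-intercept variance across fits: %.4g (median)\n",
              median(object$re_var)))
  print(object)
  invisible(object)
}

# p-value per term: spline block scored by its smallest column p
term_pvalues <- function(fit) {
  tab <- fit$table
  vapply(names(fit$terms), function(tm) {
    cols <- fit$terms[[tm]]
    min(tab$p_value[tab$covariate %in% cols], na.rm = TRUE)
  }, 0)
}

#' Backward stepwise selection over the Monte-Carlo RSF
#'
#' Iteratively drops the term with the largest p-value above `alpha` and
#' refits the full Monte-Carlo procedure with fresh random assignment under
#' a derived seed. The depth spline columns form one term, droppable only
#' when all of them exceed `alpha`. Ties drop the term later in declaration
#' order. Stops when every retained term has p <= alpha.
#'
#' @param design a [build_design()] result.
#' @param alpha retention threshold (default 0.05).
#' @inheritParams fit_mc_rsf
#' @return the final `mc_rsf`, with a `dropped` character vector attribute
#'   of dropped terms in order.
#' @export
backward_stepwise <- function(design, alpha = 0.05, n_fits = 20, seed,
                              random_effect = TRUE) {
  if (missing(seed)) stop("a seed is required")
  terms <- design$terms
  active <- names(terms)
  dropped <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cols <- unlist(terms[active], use.names = FALSE)
    if (!length(cols)) {
      warning("all covariates dropped; returning intercept-only result")
      fit <- fit_mc_rsf(design, n_fits = n_fits, seed = seed + iter,
                        random_effect = random_effect,
                        columns = character(0))
      break
    }
    fit <- fit_mc_rsf(design, n_fits = n_fits, seed = seed + iter,
                      random_effect = random_effect, columns = cols)
    fit$terms <- terms[active]
    pv <- term_pvalues(fit)
    droppable <- names(pv)[!is.na(pv) & pv > alpha]
    if (!length(droppable)) break
    # largest p; ties resolved toward the later term in declaration order
    worst <- droppable[order(pv[droppable],
                             match(droppable, names(terms)))]
    worst <- worst[length(worst)]
    active <- setdiff(active, worst)
    dropped <- c(dropped, worst)
  }
  fit$dropped <- dropped
  fit
}
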