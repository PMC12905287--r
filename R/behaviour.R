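## Linear mixed-effects model for logit move persistence against
## environmental covariates: per-individual random intercept plus AR1
## residual correlation within individuals (correlation resets across track
## segments of one individual). Marginal ML/REML authored via analytic AR1
## whitening and a rank-one Woodbury identity, so each likelihood evaluation
## is O(n) per individual.

# innovation-form whitening of a vector/matrix under AR1(phi); `starts` marks
# the first observation of each independent run
ar1_whiten <- function(v, phi, starts) {
  v <- as.matrix(v)
  if (abs(phi) < 1e-14) return(v)
  n <- nrow(v)
  lag <- rbind(0, v[-n, , drop = FALSE])
  w <- (v - phi * lag) / sqrt(1 - phi^2)
  w[starts, ] <- v[starts, , drop = FALSE]
  w
}

# profiled deviance pieces for given variance parameters
lmm_ar1_core <- function(y, X, ind, starts, phi, sigma2, V,
                         reml = FALSE) {
  p <- ncol(X)
  yw <- ar1_whiten(y, phi, starts)
  Xw <- ar1_whiten(X, phi, starts)
  ow <- ar1_whiten(matrix(1, length(y), 1), phi, starts)
  ids <- unique(ind)
  XtSX <- matrix(0, p, p)
  XtSy <- numeric(p)
  stats <- vector("list", length(ids))
  logdet <- 0
  for (k in seq_along(ids)) {
    r <- which(ind == ids[k])
    Xi <- Xw[r, , drop = FALSE]
    yi <- yw[r]
    oi <- ow[r]
    s <- list(Sxx = crossprod(Xi), sxo = as.numeric(crossprod(Xi, oi)),
              soo = sum(oi^2), sxy = as.numeric(crossprod(Xi, yi)),
              soy = sum(oi * yi), syy = sum(yi^2), n = length(r),
              nseg = sum(starts[r]))
    ci <- s$soo / sigma2
    fi <- V / (1 + V * ci) / sigma2^2
    XtSX <- XtSX + s$Sxx / sigma2 - fi * tcrossprod(s$sxo)
    XtSy <- XtSy + s$sxy / sigma2 - fi * s$sxo * s$soy
    logdet <- logdet + s$n * log(sigma2) +
      (s$n - s$nseg) * log(1 - phi^2) + log1p(V * ci)
    stats[[k]] <- c(s, list(fi = fi))
  }
  beta <- tryCatch(solve(XtSX, XtSy), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  q <- 0
  for (s in stats) {
    q <- q + (s$syy - 2 * sum(beta * s$sxy) +
                as.numeric(t(beta) %*% s$Sxx %*% beta)) / sigma2 -
      s$fi * (s$soy - sum(beta * s$sxo))^2
  }
  N <- length(y)
  ll <- -0.5 * (N * log(2 * pi) + logdet + q)
  if (reml) {
    ll <- -0.5 * ((N - p) * log(2 * pi) + logdet + q +
                    determinant(XtSX, logarithm = TRUE)$modulus)
  }
  list(logLik = as.numeric(ll), beta = beta, XtSX = XtSX)
}

#' Mixed-effects model with AR1 residuals for logit move persistence
#'
#' Fits `y = X beta + b_ind + e` where `b_ind` is a per-individual random
#' intercept (variance `V`) and `e` within each individual follows an AR1
#' process (`phi`, innovation structure indexed by observation order;
#' correlation resets between track segments of one individual). The
#' marginal likelihood is maximized (ML or REML) with fixed effects profiled
#' out; fixed-effect SEs come from the information matrix and p-values from
#' the normal approximation.
#'
#' @param formula model formula, e.g. `gamma_logit ~ sst + ssh`.
#' @param data data.frame, time-ordered within individual.
#' @param groups name of the individual-id column.
#' @param segments optional name of a segment column (AR1 resets at segment
#'   boundaries).
#' @param mode `"ML"` or `"REML"`.
#' @param ar1 estimate the AR1 parameter (otherwise fixed at 0).
#' @param random_intercept estimate the individual variance (otherwise 0).
#' @param n_restarts deterministic optimizer restarts.
#' @return object of class `lmm_ar1` with coefficient table, `phi`,
#'   `sigma2`, `V`, `logLik`, `AICc`, and the ingredients needed for
#'   diagnostics and refits.
#' @export
fit_lmm_ar1 <- function(formula, data, groups = "individual",
                        segments = NULL, mode = c("ML", "REML"),
                        ar1 = TRUE, random_intercept = TRUE,
                        n_restarts = 3) {
  mode <- match.arg(mode)
  mf <- model.frame(formula, data, na.action = na.omit)
  X <- model.matrix(formula, mf)
  y <- mf[[1]]
  ind <- data[[groups]][as.integer(rownames(mf))]
  if (is.null(ind)) stop("grouping column '", groups, "' not found")
  seg <- if (!is.null(segments)) data[[segments]][as.integer(rownames(mf))]
    else rep(1, length(y))
  # drop individuals with too few observations
  tabn <- table(ind)
  bad <- names(tabn)[tabn < 3]
  if (length(bad)) {
    warning("excluding ", length(bad), " individual(s) with < 3 observations")
    keep <- !ind %in% bad
    X <- X[keep, , drop = FALSE]; y <- y[keep]
    ind <- ind[keep]; seg <- seg[keep]
  }
  ord <- order(match(ind, unique(ind)))  # keep within-individual order
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  ind <- ind[ord]; seg <- seg[ord]
  starts <- !duplicated(paste(ind, seg, sep = "\r"))

  r0 <- residuals(lm.fit(X, y))
  s2_0 <- max(var(r0), 1e-8)
  make_theta <- function(phi, s2, V) {
    th <- c()
    if (ar1) th <- c(th, atanh(phi))
    th <- c(th, log(s2))
    if (random_intercept) th <- c(th, log(V))
    th
  }
  unpack <- function(th) {
    i <- 1
    phi <- 0
    if (ar1) { phi <- tanh(th[i]); i <- i + 1 }
    s2 <- exp(th[i]); i <- i + 1
    V <- if (random_intercept) exp(th[i]) else 0
    list(phi = phi, sigma2 = s2, V = V)
  }
  nll <- function(th) {
    pr <- unpack(th)
    if (abs(pr$phi) > 0.9999) return(1e10)
    out <- lmm_ar1_core(y, X, ind, starts, pr$phi, pr$sigma2, pr$V,
                        reml = (mode == "REML"))
    if (is.null(out) || !is.finite(out$logLik)) 1e10 else -out$logLik
  }
  starts_list <- list(make_theta(0.3, s2_0, s2_0 / 4))
  if (n_restarts >= 2)
    starts_list <- c(starts_list, list(make_theta(0.7, s2_0 / 2, s2_0 / 2)))
  if (n_restarts >= 3)
    starts_list <- c(starts_list, list(make_theta(0.0, s2_0 * 2, s2_0 / 10)))
  best <- NULL
  for (th in starts_list) {
    op <- if (length(th) == 1) {
      optim(th, nll, method = "Brent", lower = th - 20, upper = th + 20)
    } else {
      optim(th, nll, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-10))
    }
    if (is.null(best) || op$value < best$value) best <- op
  }
  pr <- unpack(best$par)
  out <- lmm_ar1_core(y, X, ind, starts, pr$phi, pr$sigma2, pr$V,
                      reml = (mode == "REML"))
  vc <- solve(out$XtSX)
  se <- sqrt(diag(vc))
  beta <- out$beta
  names(beta) <- colnames(X)
  pv <- 2 * pnorm(-abs(beta / se))
  N <- length(y)
  k <- ncol(X) + 1 + as.integer(ar1) + as.integer(random_intercept)
  ml_ll <- if (mode == "ML") out$logLik else
    lmm_ar1_core(y, X, ind, starts, pr$phi, pr$sigma2, pr$V,
                 reml = FALSE)$logLik
  structure(list(
    coefficients = beta, se = se, p_value = pv, vcov = vc,
    phi = pr$phi, sigma2 = pr$sigma2, V = pr$V,
    logLik = out$logLik, logLik_ml = ml_ll,
    AICc = AICc.default(ml_ll, k = k, n = N),
    mode = mode, converged = best$convergence == 0 && best$value < 1e9,
    n = N, k = k, formula = formula, groups = groups, segments = segments,
    ar1 = ar1, random_intercept = random_intercept,
    X = X, y = y, ind = ind, seg = seg, starts = starts,
    data = data), class = "lmm_ar1")
}

#' @export
print.lmm_ar1 <- function(x, digits = 4, ...) {
  cat(sprintf("lmm_ar1 (%s): %d obs, %d individuals\n", x$mode, x$n,
              length(unique(x$ind))))
  cat(sprintf("  phi = %.3f, sigma2 = %.4g, V = %.4g\n", x$phi, x$sigma2,
              x$V))
  cat(sprintf("  logLik %.2f, AICc %.2f\n", x$logLik, x$AICc))
  tab <- data.frame(coef = round(x$coefficients, digits),
                    se = round(x$se, digits),
                    p = signif(x$p_value, 3))
  print(tab)
  invisible(x)
}

#' @export
coef.lmm_ar1 <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ar1 <- function(object, ...) object$vcov

#' @export
logLik.lmm_ar1 <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
AICc.lmm_ar1 <- function(object, ...) object$AICc

#' @export
predict.lmm_ar1 <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else
    model.matrix(object$formula[-2], newdata)
  as.numeric(X %*% object$coefficients)
}

#' Whitened residuals of an AR1 mixed model
#'
#' Residuals transformed by the inverse Cholesky factor of the fitted
#' per-individual covariance (`V` plus AR1), which should be approximately
#' iid standard normal under a correct model.
#'
#' @param object a [fit_lmm_ar1()] fit.
#' @param ... ignored.
#' @return numeric vector of whitened residuals.
#' @export
residuals.lmm_ar1 <- function(object, ...) {
  r <- object$y - as.numeric(object$X %*% object$coefficients)
  out <- numeric(length(r))
  for (id in unique(object$ind)) {
    rows <- which(object$ind == id)
    n <- length(rows)
    st <- object$starts[rows]
    lagd <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j))
    runid <- cumsum(st)
    sameseg <- outer(runid, runid, "==")
    Rm <- object$phi^lagd * sameseg
    Sig <- object$V + object$sigma2 * Rm
    L <- chol(Sig)
    out[rows] <- backsolve(L, r[rows], transpose = TRUE)
  }
  out
}

#' @export
summary.lmm_ar1 <- function(object, ...) {
  print(object)
  w <- residuals(object)
  cat(sprintf("whitened residuals: mean %.3f, var %.3f\n", mean(w), var(w)))
  invisible(object)
}

#' Fit candidate models, rank by AICc, refit the winner by REML
#'
#' All candidates are fitted by maximum likelihood and ranked by AICc; the
#' best-supported model is refitted by REML for reporting. The ranking table
#' records each candidate's AICc, and the inclusion table counts how many
#' candidates (and how many of the top half) contain each term.
#'
#' @param formulas list of model formulas.
#' @param data,groups,segments as in [fit_lmm_ar1()].
#' @param ... further arguments to [fit_lmm_ar1()].
#' @return list: `fit` (REML refit of the winner), `ranking` (data.frame),
#'   `inclusion` (term counts).
#' @export
select_candidates <- function(formulas, data, groups = "individual",
                              segments = NULL, ...) {
  if (length(formulas) < 2) stop("need at least 2 candidate formulas")
  fits <- lapply(formulas, function(f)
    tryCatch(fit_lmm_ar1(f, data, groups = groups, segments = segments,
                         mode = "ML", ...),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE) &
    vapply(fits, function(f) is.null(f) || f$converged, TRUE)
  if (!any(ok)) stop("no candidate model converged")
  aicc <- vapply(fits, function(f) if (is.null(f)) Inf else f$AICc, 0)
  aicc[!ok] <- Inf
  ranking <- data.frame(
    formula = vapply(formulas, function(f) deparse1(f), ""),
    AICc = aicc, converged = ok)
  ranking <- ranking[order(ranking$AICc), ]
  ranking$rank <- seq_len(nrow(ranking))
  terms_all <- lapply(formulas, function(f) attr(terms(f), "term.labels"))
  all_terms <- unique(unlist(terms_all))
  inclusion <- data.frame(
    term = all_terms,
    n_candidates = vapply(all_terms, function(tm)
      sum(vapply(terms_all, function(tl) tm %in% tl, TRUE)), 0L))
  win <- which.min(aicc)
  fit <- fit_lmm_ar1(formulas[[win]], data, groups = groups,
                     segments = segments, mode = "REML", ...)
  list(fit = fit, ranking = ranking, inclusion = inclusion)
}

#' Collinearity, residual and partial-response diagnostics
#'
#' Variance inflation factors per term (the depth-spline columns are scored
#' jointly with a generalized, determinant-based VIF), a whitened-residual
#' summary (mean, variance, pooled lag-1 autocorrelation), and partial
#' response curves per fixed-effect column (covariate varied over its
#' observed range, all others held at their means, with 95% CI bands).
#'
#' @param fit a [fit_lmm_ar1()] fit.
#' @param spline_prefix columns sharing this prefix form one VIF term.
#' @return list: `vif` (data.frame term, df, gvif), `residual_summary`,
#'   `partial` (list of data.frames value/response/lo/hi per column).
#' @export
diagnostics <- function(fit, spline_prefix = "dpth_") {
  X <- fit$X[, colnames(fit$X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 1) stop("no fixed-effect columns to diagnose")
  # exact collinearity check with offender names
  cc <- cor(X)
  up <- which(upper.tri(cc) & abs(cc) > 1 - 1e-10, arr.ind = TRUE)
  if (nrow(up))
    stop("exactly collinear columns: ",
         paste(colnames(X)[up[1, 1]], "and", colnames(X)[up[1, 2]]))
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient design")
  is_spl <- startsWith(colnames(X), spline_prefix)
  groups <- ifelse(is_spl, "depth_spline", colnames(X))
  vif <- do.call(rbind, lapply(unique(groups), function(g) {
    j <- which(groups == g)
    gv <- det(cc[j, j, drop = FALSE]) *
      det(cc[-j, -j, drop = FALSE]) / det(cc)
    data.frame(term = g, df = length(j), gvif = gv)
  }))
  w <- residuals(fit)
  # pooled within-individual lag-1 autocorrelation of whitened residuals
  num <- 0; den <- 0
  for (id in unique(fit$ind)) {
    v <- w[fit$ind == id]
    v <- v - mean(v)
    num <- num + sum(v[-1] * v[-length(v)])
    den <- den + sum(v^2)
  }
  res_sum <- c(mean = mean(w), var = var(w), lag1 = num / den)
  partial <- lapply(setNames(colnames(X), colnames(X)), function(j)
    partial_response(fit, j))
  list(vif = vif, residual_summary = res_sum, partial = partial)
}

#' Partial response of the fitted model to one design column
#'
#' @param fit a [fit_lmm_ar1()] fit.
#' @param column design column name.
#' @param n grid size.
#' @return data.frame: `value`, `response`, `lo`, `hi`.
#' @export
partial_response <- function(fit, column, n = 50) {
  X <- fit$X
  if (!column %in% colnames(X)) stop("unknown design column: ", column)
  grid <- seq(min(X[, column]), max(X[, column]), length.out = n)
  Xp <- matrix(rep(colMeans(X), each = n), n, ncol(X),
               dimnames = list(NULL, colnames(X)))
  Xp[, column] <- grid
  est <- as.numeric(Xp %*% fit$coefficients)
  sev <- sqrt(rowSums((Xp %*% fit$vcov) * Xp))
  data.frame(value = grid, response = est, lo = est - 1.96 * sev,
             hi = est + 1.96 * sev)
}

#' Leave-one-individual-out cross-validation
#'
#' Refits the model once per left-out individual and summarizes coefficient
#' stability: the 5% and 95% quantiles of each coefficient across refits,
#' and the estimated trend -- the percentage of refits whose coefficient
#' falls inside the full model's 95% confidence interval.
#'
#' @param fit a [fit_lmm_ar1()] fit (the full model).
#' @return object of class `cv_report`: data.frame per coefficient with
#'   `q5`, `q95`, `trend`; attribute `n_refits`, `failed`.
#' @export
loocv <- function(fit) {
  ids <- unique(fit$ind)
  if (length(ids) < 3) stop("need at least 3 individuals")
  coefs <- list()
  failed <- character(0)
  for (id in ids) {
    sub <- fit$data[fit$data[[fit$groups]] != id, , drop = FALSE]
    rf <- tryCatch(
      fit_lmm_ar1(fit$formula, sub, groups = fit$groups,
                  segments = fit$segments, mode = fit$mode,
                  ar1 = fit$ar1, random_intercept = fit$random_intercept,
                  n_restarts = 1),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) {
      failed <- c(failed, as.character(id))
      next
    }
    coefs[[length(coefs) + 1]] <- rf$coefficients
  }
  if (length(failed))
    warning("refit failed for individual(s): ",
            paste(failed, collapse = ", "))
  cm <- do.call(rbind, coefs)
  lo <- fit$coefficients - 1.96 * fit$se
  hi <- fit$coefficients + 1.96 * fit$se
  tab <- data.frame(
    coefficient = colnames(cm),
    q5 = apply(cm, 2, quantile, probs = 0.05),
    q95 = apply(cm, 2, quantile, probs = 0.95),
    trend = vapply(seq_len(ncol(cm)), function(j)
      100 * mean(cm[, j] >= lo[j] & cm[, j] <= hi[j]), 0),
    row.names = NULL)
  structure(tab, class = c("cv_report", "data.frame"),
            n_refits = nrow(cm), failed = failed)
}
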