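#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from the ordinary regression (with intercept)
#' of predictor j on all the others; exact collinearity is reported as
#' `Inf`.
#'
#' @param X numeric matrix or data.frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif_scores <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (p < 2) rip_stop("need >= 2 predictors")
  if (nrow(X) <= p) rip_stop("need more rows than predictors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    rip_stop("constant predictor column(s): ",
             paste(colnames(X)[sds == 0], collapse = ", "))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Stepwise collinearity filter on VIF
#'
#' Repeatedly removes the single predictor with the highest VIF while
#' any VIF is at or above `threshold`; the loop stops with a warning if
#' fewer than two predictors would remain.
#'
#' @param X predictor matrix/data.frame.
#' @param threshold removal threshold (default 4).
#' @return `X` restricted to the retained columns, with a `removed`
#'   attribute (data.frame of dropped predictors and their VIF at
#'   removal time).
#' @export
stepwise_vif_filter <- function(X, threshold = 4) {
  X <- as.data.frame(X)
  removed <- data.frame(predictor = character(), vif = numeric())
  repeat {
    if (ncol(X) < 2) {
      rip_warn("fewer than 2 predictors remain; stopping VIF filter")
      break
    }
    v <- vif_scores(X)
    if (all(v < threshold)) break
    worst <- names(v)[which.max(v)]
    removed <- rbind(removed, data.frame(predictor = worst, vif = max(v)))
    X <- X[, setdiff(names(X), worst), drop = FALSE]
  }
  attr(X, "removed") <- removed
  X
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2 k + 2 k (k + 1) / (n - k - 1).
#'
#' @param loglik maximized log-likelihood.
#' @param kp number of estimated parameters (fixed effects + variances).
#' @param n sample size; must exceed `kp + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, kp, n) {
  if (n <= kp + 1) rip_stop("AICc undefined: n must exceed kp + 1")
  -2 * loglik + 2 * kp + 2 * kp * (kp + 1) / (n - kp - 1)
}

# ---- fast profiled-ML Gaussian LMM with one random intercept ----------
#
# V(theta) = sigma^2 (I + theta Z Z'); eigen-decomposing Z Z' once makes
# every candidate fixed-effect subset a weighted least-squares problem in
# the rotated coordinates, with one scalar profile optimization over
# theta. Shared across the 2^p all-subsets enumeration.

lmm_context <- function(y, X, group) {
  group <- factor(group)
  n <- length(y)
  Z <- stats::model.matrix(~ group - 1)
  E <- eigen(tcrossprod(Z), symmetric = TRUE)
  U <- E$vectors
  list(yt = drop(crossprod(U, y)), Xt = crossprod(U, cbind(`(Intercept)` = 1, X)),
       d = pmax(E$values, 0), n = n)
}

lmm_fit_subset <- function(ctx, cols) {
  Xs <- ctx$Xt[, c(1L, cols + 1L), drop = FALSE]
  n <- ctx$n
  dev_at <- function(theta) {
    w <- 1 / (1 + theta * ctx$d)
    fit <- stats::lm.wfit(Xs, ctx$yt, w)
    rss <- sum(w * fit$residuals^2)
    sig2 <- rss / n
    n * log(2 * pi * sig2) + sum(log1p(theta * ctx$d)) + n
  }
  op <- stats::optimize(function(u) dev_at(exp(u)), interval = c(-12, 12))
  cand <- c(0, exp(op$minimum))
  devs <- vapply(cand, dev_at, numeric(1))
  theta <- cand[which.min(devs)]
  w <- 1 / (1 + theta * ctx$d)
  fit <- stats::lm.wfit(Xs, ctx$yt, w)
  rss <- sum(w * fit$residuals^2)
  sig2 <- rss / n
  XtWX <- crossprod(Xs * sqrt(w))
  vc <- tryCatch(solve(XtWX) * sig2, error = function(e) NULL)
  if (is.null(vc)) return(NULL)
  beta <- fit$coefficients
  list(loglik = -min(devs) / 2, beta = beta, se = sqrt(diag(vc)),
       theta = theta, sigma2 = sig2)
}

#' All-subsets mixed-model ranking by AICc
#'
#' Fits every subset of the (z-standardized) predictors, including the
#' intercept-only model, as a Gaussian linear mixed model with a random
#' intercept for `group` (river identity), estimated by maximum
#' likelihood. Models are ranked by AICc with Delta-AICc and Akaike
#' weights over the full candidate set.
#'
#' @param y numeric response over sites.
#' @param X data.frame/matrix of numeric predictors (<= 15 columns).
#' @param group random-intercept grouping factor (one value per site).
#' @param standardize z-score the predictors first (default TRUE).
#' @return object of class `rip_model_set`: a data.frame of ranked model
#'   records (`model`, `k`, `logLik`, `AICc`, `delta`, `weight`) with the
#'   per-model coefficient tables stored in attribute `fits` and the
#'   predictor names in `predictors`.
#' @export
all_subsets_fit <- function(y, X, group, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (p > 15) rip_stop("more than 15 predictors: 2^p model set too large")
  if (standardize) X <- scale(X)
  ok <- stats::complete.cases(y, X)
  if (!all(ok)) {
    rip_warn("dropping ", sum(!ok), " site(s) with missing response/predictors")
    y <- y[ok]; X <- X[ok, , drop = FALSE]; group <- group[ok]
  }
  ctx <- lmm_context(y, X, group)
  n <- ctx$n
  n_models <- 2^p
  recs <- vector("list", n_models)
  fits <- vector("list", n_models)
  for (m in seq_len(n_models) - 1L) {
    cols <- which(bitwAnd(m, 2^(seq_len(p) - 1L)) > 0L)
    f <- lmm_fit_subset(ctx, cols)
    kp <- length(cols) + 1L + 2L      # fixed effects + intercept + 2 variances
    if (is.null(f) || !is.finite(f$loglik)) {
      rip_warn("model ", m, " failed to fit; excluded")
      next
    }
    label <- if (length(cols)) paste(colnames(X)[cols], collapse = " + ")
             else "(Intercept)"
    recs[[m + 1L]] <- data.frame(model = label, k = kp, logLik = f$loglik,
                                 AICc = aicc(f$loglik, kp, n))
    fits[[m + 1L]] <- data.frame(predictor = names(f$beta),
                                 estimate = unname(f$beta),
                                 se = unname(f$se))
  }
  keep <- !vapply(recs, is.null, logical(1))
  records <- do.call(rbind, recs[keep])
  fits <- fits[keep]
  o <- order(records$AICc)
  records <- records[o, ]
  fits <- fits[o]
  records$delta <- records$AICc - records$AICc[1]
  rel <- exp(-records$delta / 2)
  records$weight <- rel / sum(rel)
  rownames(records) <- NULL
  structure(records, fits = fits, predictors = colnames(X), n = n,
            class = c("rip_model_set", "data.frame"))
}

#' Multimodel averaging over the Delta-AICc top set
#'
#' Restricts the ranked model set to models with Delta-AICc <= `delta`,
#' renormalizes their Akaike weights, and averages coefficients. With
#' `method = "full"` (default) a predictor absent from a model
#' contributes an estimate of 0 to the average (zero substitution);
#' `"conditional"` averages only over the models that contain it.
#' Unconditional standard errors combine within-model variance and
#' between-model spread
#' (SE = sum_i w_i sqrt(se_i^2 + (b_i - b_bar)^2)); p-values use the
#' normal approximation. Relative importance is the summed renormalized
#' weight of top-set models containing the predictor.
#'
#' @param records a `rip_model_set` from [all_subsets_fit()].
#' @param delta Delta-AICc cutoff defining the top set (default 2).
#' @param method `"full"` or `"conditional"` averaging.
#' @return data.frame with columns `predictor`, `estimate`, `se`, `z`,
#'   `p`, `importance`; attribute `n_models` gives the top-set size.
#' @export
average_top_set <- function(records, delta = 2, method = c("full", "conditional")) {
  method <- match.arg(method)
  fits <- attr(records, "fits")
  top <- which(records$delta <= delta)
  w <- records$weight[top]
  w <- w / sum(w)
  fits <- fits[top]
  preds <- unique(unlist(lapply(fits, `[[`, "predictor")))
  rows <- lapply(preds, function(pj) {
    b <- vapply(fits, function(f) {
      i <- match(pj, f$predictor); if (is.na(i)) 0 else f$estimate[i]
    }, numeric(1))
    s <- vapply(fits, function(f) {
      i <- match(pj, f$predictor); if (is.na(i)) 0 else f$se[i]
    }, numeric(1))
    has <- vapply(fits, function(f) pj %in% f$predictor, logical(1))
    if (method == "full") {
      est <- sum(w * b)
      se <- sum(w * sqrt(s^2 + (b - est)^2))
    } else {
      wc <- w[has] / sum(w[has])
      est <- sum(wc * b[has])
      se <- sum(wc * sqrt(s[has]^2 + (b[has] - est)^2))
    }
    z <- est / se
    data.frame(predictor = pj, estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               importance = sum(w[has]))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_models") <- length(top)
  attr(out, "method") <- method
  out
}

#' Environmental-driver inference for one response
#'
#' The full driver workflow behind the averaged-coefficient table:
#' stepwise VIF filtering of the environmental predictors, all-subsets
#' AICc-ranked mixed-model fitting (random intercept for `river_id`),
#' and multimodel averaging over the Delta-AICc top set.
#'
#' @param y named numeric response over sites.
#' @param sites site table containing `river_id` and the environmental
#'   columns.
#' @param env_vars predictor column names (default [rip_env_vars]
#'   intersected with the site table).
#' @param vif_threshold stepwise VIF removal threshold (default 4).
#' @param delta Delta-AICc cutoff (default 2).
#' @param method averaging method, see [average_top_set()].
#' @return list with `averaged` (coefficient table), `models` (the
#'   ranked `rip_model_set`), `retained` (predictors surviving the VIF
#'   filter) and `vif_removed`.
#' @export
infer_drivers <- function(y, sites, env_vars = NULL, vif_threshold = 4,
                          delta = 2, method = "full") {
  env_vars <- env_vars %||% intersect(rip_env_vars, names(sites))
  if (!is.null(names(y)) && !is.null(rownames(sites)))
    sites <- sites[names(y), , drop = FALSE]
  X <- stepwise_vif_filter(sites[, env_vars, drop = FALSE],
                           threshold = vif_threshold)
  models <- all_subsets_fit(y, X, group = sites$river_id)
  averaged <- average_top_set(models, delta = delta, method = method)
  list(averaged = averaged, models = models, retained = names(X),
       vif_removed = attr(X, "removed"))
}
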