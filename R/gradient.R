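#' Penalized-spline elevation smooth with river-level random intercepts
#'
#' Gaussian additive mixed model of a per-site response on elevation: a
#' penalized cubic regression spline (basis dimension `k`) plus shrunken
#' random intercepts for `river_id` and `river_direction`, estimated in
#' one penalized least-squares problem with the smoothing parameters
#' selected by REML (GCV fallback on convergence failure). The fitted
#' population-level curve (random effects excluded) is evaluated on a
#' 1-metre elevation grid with a pointwise 95% interval.
#'
#' @param y named numeric response over sites (NAs dropped with a
#'   warning).
#' @param sites site table with `elevation`, `river_id`,
#'   `river_direction`; rows matched to `names(y)` when available.
#' @param k spline basis dimension (default 5).
#' @param response_name label stored with the fit.
#' @return object of class `rip_smooth`: list with the `mgcv::gam` fit
#'   (`fit`), the prediction `grid` (elevation, fit, lower, upper),
#'   `edf` of the elevation smooth, and `response_name`.
#' @export
fit_elevation_smooth <- function(y, sites, k = 5, response_name = "y") {
  if (!is.null(names(y)) && !is.null(rownames(sites)))
    sites <- sites[names(y), , drop = FALSE]
  if (nrow(sites) != length(y)) rip_stop("y and sites do not align")
  dat <- data.frame(y = as.numeric(y),
                    elevation = sites$elevation,
                    river_id = factor(sites$river_id),
                    river_direction = factor(sites$river_direction))
  if (anyNA(dat$y)) {
    rip_warn("dropping ", sum(is.na(dat$y)), " site(s) with undefined response")
    dat <- dat[!is.na(dat$y), ]
  }
  if (length(unique(dat$elevation)) < 2) rip_stop("elevation is constant")
  if (nrow(dat) < k + 2) rip_stop("need at least k + 2 sites")
  form <- y ~ s(elevation, k = k, bs = "cr")
  re_terms <- character()
  if (nlevels(droplevels(dat$river_id)) > 1) {
    form <- stats::update(form, . ~ . + s(river_id, bs = "re"))
    re_terms <- c(re_terms, "s(river_id)")
  }
  if (nlevels(droplevels(dat$river_direction)) > 1) {
    form <- stats::update(form, . ~ . + s(river_direction, bs = "re"))
    re_terms <- c(re_terms, "s(river_direction)")
  }
  dat$river_id <- droplevels(dat$river_id)
  dat$river_direction <- droplevels(dat$river_direction)
  fit <- tryCatch(
    mgcv::gam(form, data = dat, method = "REML"),
    error = function(e) mgcv::gam(form, data = dat, method = "GCV.Cp"))
  grid <- data.frame(elevation = seq(min(dat$elevation), max(dat$elevation),
                                     by = 1),
                     river_id = dat$river_id[1],
                     river_direction = dat$river_direction[1])
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE,
                          exclude = re_terms,
                          newdata.guaranteed = TRUE)
  grid$fit <- as.numeric(pr$fit)
  grid$lower <- grid$fit - 1.96 * as.numeric(pr$se.fit)
  grid$upper <- grid$fit + 1.96 * as.numeric(pr$se.fit)
  edf <- sum(fit$edf[grepl("elevation", names(stats::coef(fit)))])
  structure(list(fit = fit,
                 grid = grid[, c("elevation", "fit", "lower", "upper")],
                 edf = edf, k = k, response_name = response_name),
            class = "rip_smooth")
}

#' @export
print.rip_smooth <- function(x, ...) {
  pk <- peak_location(x)
  cat("rip_smooth for", x$response_name, "- edf:", round(x$edf, 2),
      "- peak:", round(pk$elevation, 1), "m (", pk$classification, ")\n")
  invisible(x)
}

#' Locate the elevation of maximal fitted diversity
#'
#' Argmax of the fitted curve over the observed elevation range (1-metre
#' grid, ties broken to the lowest elevation). A maximum at either end
#' of the range is classified `"monotone"`; an internal maximum is
#' `"interior"` (hump-shaped).
#'
#' @param fit a `rip_smooth`.
#' @return list with `elevation` (m) and `classification`
#'   (`"interior"`/`"monotone"`).
#' @export
peak_location <- function(fit) {
  g <- fit$grid
  i <- which.max(g$fit)
  cls <- if (i == 1L || i == nrow(g)) "monotone" else "interior"
  list(elevation = g$elevation[i], classification = cls)
}

#' Polynomial Gaussian GLM of CVI on elevation
#'
#' Fits CVI as a Gaussian GLM with polynomial elevation terms up to
#' `degree` and evaluates the curve with a pointwise 95% interval on a
#' 1-metre grid.
#'
#' @param cvi named per-site CVI values.
#' @param sites site table with `elevation`.
#' @param degree polynomial degree (default 2).
#' @return list with `fit` (the glm), `coefficients`, and `grid`
#'   (elevation, fit, lower, upper).
#' @export
fit_cvi_glm <- function(cvi, sites, degree = 2) {
  if (!is.null(names(cvi)) && !is.null(rownames(sites)))
    sites <- sites[names(cvi), , drop = FALSE]
  dat <- data.frame(cvi = as.numeric(cvi), elevation = sites$elevation)
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < degree + 2) rip_stop("need at least degree + 2 sites")
  fit <- stats::glm(cvi ~ poly(elevation, degree, raw = TRUE), data = dat,
                    family = stats::gaussian())
  if (fit$rank < degree + 1) rip_stop("rank-deficient polynomial fit")
  grid <- data.frame(elevation = seq(min(dat$elevation), max(dat$elevation),
                                     by = 1))
  pr <- stats::predict(fit, newdata = grid, se.fit = TRUE)
  grid$fit <- as.numeric(pr$fit)
  grid$lower <- grid$fit - 1.96 * as.numeric(pr$se.fit)
  grid$upper <- grid$fit + 1.96 * as.numeric(pr$se.fit)
  co <- stats::coef(fit)
  names(co) <- c("(Intercept)", paste0("elevation^", seq_len(degree)))
  list(fit = fit, coefficients = co, grid = grid)
}
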