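test_that("VIF matches closed forms and the car implementation", {
  set.seed(1)
  # centered mutually orthogonal predictors: all VIF = 1
  Xo <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40, 3))))[, 2:4]
  colnames(Xo) <- c("a", "b", "c")
  expect_equal(unname(vif_scores(Xo)), rep(1, 3), tolerance = 1e-10)

  # two predictors with correlation exactly 0.6: VIF = 1/(1-0.36)
  n <- 200
  z <- scale(matrix(rnorm(n * 2), n, 2))
  z[, 2] <- residuals(lm(z[, 2] ~ z[, 1]))
  x1 <- z[, 1] / sd(z[, 1])
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * z[, 2] / sd(z[, 2])
  X <- cbind(x1 = x1, x2 = x2)
  expect_equal(unname(vif_scores(X)), rep(1.5625, 2), tolerance = 1e-6)

  # exact collinearity flagged as infinite
  X3 <- cbind(X, x3 = x1 + x2)
  expect_identical(unname(vif_scores(X3)[3]), Inf)

  # agreement with car::vif on a random design
  Xr <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  Xr[, 2] <- Xr[, 1] + rnorm(50, 0, 0.5)
  y <- rnorm(50)
  expect_equal(vif_scores(Xr),
               car::vif(lm(y ~ ., data = data.frame(y = y, Xr))),
               tolerance = 1e-8)
})

test_that("stepwise VIF filter removes collinear predictors until all VIF < 4", {
  set.seed(6)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, letters[1:4]))
  out <- stepwise_vif_filter(X)
  expect_identical(names(out), letters[1:4])            # identity when clean
  expect_identical(nrow(attr(out, "removed")), 0L)

  Xdup <- cbind(X, e = X[, 1] + rnorm(60, 0, 0.01))      # near-duplicated pair
  out2 <- stepwise_vif_filter(Xdup)
  expect_identical(ncol(out2), 4L)
  expect_true(attr(out2, "removed")$predictor %in% c("a", "e"))

  for (rep in 1:30) {                                    # post-condition sweep
    L <- matrix(rnorm(16), 4, 4)
    Xc <- matrix(rnorm(50 * 4), 50, 4) %*% L
    colnames(Xc) <- letters[1:4]
    kept <- stepwise_vif_filter(Xc)
    if (ncol(kept) >= 2) expect_true(all(vif_scores(kept) < 4))
  }
})

test_that("AICc arithmetic and weights are exact", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_error(aicc(-10, 3, 4), "n must exceed")
  # two models with equal AICc share weight 0.5; delta = 2 => ratio e^-1
  d <- c(0, 0, 2)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  expect_equal(w[1], w[2])
  expect_equal(w[3] / w[1], exp(-1), tolerance = 1e-12)
})

test_that("the profiled-ML mixed model matches lme4 on a real subset", {
  ds <- generate_study(sim_config(seed = 3))
  S <- as.numeric(species_richness(ds$community))
  X <- scale(as.matrix(ds$sites[, c("Forest", "H_SD", "Lnum")]))
  ctx <- ripdiv:::lmm_context(S, X, ds$sites$river_id)
  f <- ripdiv:::lmm_fit_subset(ctx, 1:3)
  dat <- data.frame(S = S, X, river_id = ds$sites$river_id)
  lm4 <- suppressMessages(lme4::lmer(S ~ Forest + H_SD + Lnum + (1 | river_id),
                                     data = dat, REML = FALSE))
  expect_equal(f$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(lme4::fixef(lm4)), tolerance = 1e-5)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(lm4))))),
               tolerance = 1e-4)
})

test_that("all-subsets enumeration is complete with weights summing to 1", {
  ds <- generate_study(small_config(seed = 4))
  S <- as.numeric(species_richness(ds$community))
  ms <- all_subsets_fit(S, ds$sites[, c("Forest", "H_SD")], ds$sites$river_id)
  expect_identical(nrow(ms), 4L)                        # 2 predictors -> 4 models
  expect_equal(sum(ms$weight), 1, tolerance = 1e-12)
  expect_equal(ms$delta[1], 0)
  expect_true(all(diff(ms$AICc) >= 0))
})

test_that("model averaging matches a hand-computed toy and zero substitution", {
  # three records with hand-assigned likelihoods
  recs <- data.frame(model = c("x1", "x1 + x2", "(Intercept)"),
                     k = c(4, 5, 3), logLik = c(-10, -9.5, -13))
  n <- 30
  recs$AICc <- mapply(aicc, recs$logLik, recs$k, n)
  fits <- list(
    data.frame(predictor = c("(Intercept)", "x1"), estimate = c(1, 0.8),
               se = c(0.2, 0.3)),
    data.frame(predictor = c("(Intercept)", "x1", "x2"),
               estimate = c(1.1, 0.7, 0.2), se = c(0.2, 0.3, 0.25)),
    data.frame(predictor = "(Intercept)", estimate = 1.4, se = 0.25))
  o <- order(recs$AICc)
  recs <- recs[o, ]; fits <- fits[o]
  recs$delta <- recs$AICc - recs$AICc[1]
  rel <- exp(-recs$delta / 2); recs$weight <- rel / sum(rel)
  attr(recs, "fits") <- fits
  class(recs) <- c("rip_model_set", "data.frame")
  av <- average_top_set(recs, delta = 100)             # include all three
  w <- recs$weight
  b_x1 <- sapply(fits, function(f) {
    i <- match("x1", f$predictor); if (is.na(i)) 0 else f$estimate[i] })
  expect_equal(av$estimate[av$predictor == "x1"], sum(w * b_x1))
  has <- sapply(fits, function(f) "x1" %in% f$predictor)
  expect_equal(av$importance[av$predictor == "x1"], sum(w[has]))

  # two equal-weight models, predictor only in one with estimate 0.8
  recs2 <- data.frame(model = c("x1", "(Intercept)"), k = c(4, 3),
                      logLik = c(-9, -10), AICc = c(20, 20), delta = c(0, 0),
                      weight = c(0.5, 0.5))
  attr(recs2, "fits") <- list(
    data.frame(predictor = c("(Intercept)", "x1"), estimate = c(1, 0.8),
               se = c(0.2, 0.3)),
    data.frame(predictor = "(Intercept)", estimate = 1.2, se = 0.2))
  class(recs2) <- c("rip_model_set", "data.frame")
  av2 <- average_top_set(recs2)
  expect_equal(av2$estimate[av2$predictor == "x1"], 0.4)   # zero substitution
  expect_equal(av2$importance[av2$predictor == "x1"], 0.5)
  av2c <- average_top_set(recs2, method = "conditional")
  expect_equal(av2c$estimate[av2c$predictor == "x1"], 0.8)

  # single model in the top set: averages equal that model
  av3 <- average_top_set(recs, delta = 1e-9)
  top_fit <- fits[[1]]
  expect_equal(av3$estimate, top_fit$estimate)
  expect_true(all(av3$importance == 1))
})

test_that("averaging is invariant to candidate ordering", {
  ds <- generate_study(small_config(seed = 24))
  S <- as.numeric(species_richness(ds$community))
  X <- ds$sites[, c("Forest", "H_SD", "Lnum")]
  a <- average_top_set(all_subsets_fit(S, X, ds$sites$river_id))
  b <- average_top_set(all_subsets_fit(S, X[, c(3, 1, 2)], ds$sites$river_id))
  bb <- b[match(a$predictor, b$predictor), ]
  expect_equal(a$estimate, bb$estimate, tolerance = 1e-8)
  expect_equal(a$importance, bb$importance, tolerance = 1e-8)
})

test_that("a strong single driver is recovered as the best model", {
  set.seed(50)
  hits <- sapply(1:12, function(r) {
    ds <- generate_study(small_config(seed = 900 + r, driver_effects = NULL))
    X <- scale(as.matrix(ds$sites[, c("Forest", "Shrub", "Bar")]))
    y <- 5 + 2 * X[, "Forest"] + rnorm(nrow(X), 0, 1)
    ms <- all_subsets_fit(y, X, ds$sites$river_id)
    grepl("Forest", ms$model[1])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("an intercept-only truth keeps the null model competitive", {
  set.seed(51)
  ok <- sapply(1:12, function(r) {
    ds <- generate_study(small_config(seed = 950 + r, driver_effects = NULL))
    X <- scale(as.matrix(ds$sites[, c("Forest", "Shrub", "Bar")]))
    y <- 5 + rnorm(nrow(X), 0, 1)
    ms <- all_subsets_fit(y, X, ds$sites$river_id)
    ms$delta[ms$model == "(Intercept)"] <= 2
  })
  expect_gte(mean(ok), 0.8)
})
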