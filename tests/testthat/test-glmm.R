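test_that("intercept-only Gamma fit recovers the closed-form log-mean MLE", {
  set.seed(3)
  y <- rgamma(500, shape = 20, rate = 20 / 200)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- burstlink:::glmm_engine(y, X, NULL,
                                list(rel_tol = 1e-8, grad_tol = 1e-5,
                                     eval_max = 2e5))
  expect_equal(fit$coefficients$estimate[1], log(mean(y)), tolerance = 1e-3)
})

test_that("collapsed fit equals the independent IRLS Gamma GLM oracle", {
  d <- simulate_glmm_data(20, 25, sigma_u = 0, shape = 20, seed = 7)
  fit <- fit_gamma_glmm(d, random = FALSE)
  zs <- function(x) (x - mean(x)) / sd(x)
  d$zl <- zs(d$latency); d$zst <- zs(d$strength); d$zc <- zs(d$contrast)
  g <- glm(rt ~ zl + zst + zc + zl:zc + zst:zc, data = d,
           family = Gamma(link = "log"))
  expect_equal(unname(fit$coefficients$estimate), unname(coef(g)),
               tolerance = 1e-4)
})

test_that("near-zero simulated random-effect variance collapses to the GLM fit", {
  d <- simulate_glmm_data(30, 25, sigma_u = 0, shape = 20, seed = 9)
  full <- fit_gamma_glmm(d)
  flat <- fit_gamma_glmm(d, random = FALSE)
  expect_lt(full$sigma_u, 0.05)
  expect_equal(full$coefficients$estimate, flat$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("fixed effects agree with an independent mixed-model implementation", {
  d <- simulate_glmm_data(50, 30, beta = c(latency = 0.05, strength = -0.03,
                                           contrast = -0.06),
                          sigma_u = 0.15, shape = 20, seed = 9)
  fit <- fit_gamma_glmm(d)
  zs <- function(x) as.numeric(scale(x))
  d$zl <- zs(d$latency); d$zst <- zs(d$strength); d$zc <- zs(d$contrast)
  g <- suppressMessages(lme4::glmer(
    rt ~ zl * zc + zst * zc + (1 | neuron), data = d,
    family = Gamma(link = "log"),
    control = lme4::glmerControl(optimizer = "bobyqa")
  ))
  fe <- lme4::fixef(g)
  ours <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  pick <- function(nm) {
    hit <- fe[names(fe) %in% c(nm, paste(rev(strsplit(nm, ":")[[1]]),
                                         collapse = ":"))]
    unname(hit[1])
  }
  map <- c(latency = "zl", strength = "zst", contrast = "zc",
           "latency:contrast" = "zl:zc", "strength:contrast" = "zst:zc")
  for (term in names(map)) {
    expect_lt(abs(ours[[term]] - pick(map[[term]])), 1e-3)
  }
})

test_that("recovered coefficients cover the simulation truth", {
  truth <- c(latency = 0.04, strength = -0.04, contrast = -0.06)
  hits <- 0L
  for (s in 1:10) {
    d <- simulate_glmm_data(60, 30, beta = truth, sigma_u = 0.1, shape = 25,
                            seed = 100 + s)
    fit <- fit_gamma_glmm(d)
    co <- fit$coefficients
    ok <- vapply(names(truth), function(term) {
      row <- co[co$term == term, ]
      abs(row$estimate - truth[[term]]) <= 2 * row$se
    }, logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits, 9L)
})

test_that("single-term deletion removes the right parameter counts", {
  d <- simulate_glmm_data(30, 20, sigma_u = 0.1, shape = 20, seed = 15)
  fit <- fit_gamma_glmm(d)
  expect_equal(single_term_deletion(fit, "latency")$df, 2)
  expect_equal(single_term_deletion(fit, "strength")$df, 2)
  expect_equal(single_term_deletion(fit, "contrast")$df, 3)
  # AIC bookkeeping is internally consistent
  expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$logLik)
  # deleting a strong true effect decisively worsens the model
  del <- single_term_deletion(fit, "contrast")
  expect_lt(del$p, 1e-4)
  expect_gt(del$AIC_reduced, del$AIC_full)
})

test_that("deleting a pure-noise predictor usually raises AIC", {
  worse <- vapply(1:6, function(s) {
    d <- simulate_glmm_data(30, 20,
                            beta = c(latency = 0.05, strength = 0,
                                     contrast = -0.06),
                            sigma_u = 0.1, shape = 20, seed = 200 + s)
    fit <- fit_gamma_glmm(d)
    del <- single_term_deletion(fit, "strength")
    del$AIC_reduced < del$AIC_full   # dropping noise should *improve* AIC
  }, logical(1))
  expect_gte(sum(worse), 4L)
})

test_that("coefficients are invariant to predictor rescaling", {
  d <- simulate_glmm_data(30, 20, sigma_u = 0.1, shape = 20, seed = 17)
  f1 <- fit_gamma_glmm(d)
  d2 <- d
  d2$latency <- d2$latency * 1000   # ms -> microseconds
  d2$strength <- d2$strength / 50
  f2 <- fit_gamma_glmm(d2)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-5)
})

test_that("degenerate inputs are rejected", {
  d <- simulate_glmm_data(5, 10, seed = 1)
  expect_error(fit_gamma_glmm(d[1:5, ]), "at least 10 trials")
  d$rt[1] <- -5
  expect_error(fit_gamma_glmm(d), "strictly positive")
  d2 <- simulate_glmm_data(1, 40, seed = 1)
  expect_error(fit_gamma_glmm(d2), "at least 2 neurons")
})
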