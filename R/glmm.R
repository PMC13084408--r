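#' Gamma log-link mixed model of saccadic reaction time
#'
#' Fits, by maximum likelihood with a Laplace approximation over the
#' neuron-level random intercepts, the model
#'
#'   RT ~ latency * contrast + strength * contrast + (1 | neuron)
#'
#' with `RT ~ Gamma(shape, mean = mu)`, `log(mu) = X beta + u_neuron`,
#' `u ~ N(0, sigma_u^2)`. The three predictors (trial-wise visual response
#' onset latency, baseline-subtracted visual response strength, and stimulus
#' contrast as numeric percent) are treated as continuous and z-scored over
#' the fitted dataset before entering the design matrix, so coefficients are
#' per-SD effects on log reaction time.
#'
#' The marginal likelihood integrates the random intercepts out per neuron:
#' an inner Newton solve finds each neuron's conditional mode (the integrand
#' is strictly log-concave in `u`, so the mode is unique), and the Laplace
#' correction uses the negative curvature at the mode. The outer optimization
#' runs over `(beta, log sigma_u, log shape)` with `stats::nlminb`. Wald
#' standard errors come from the inverse of a central-difference Hessian of
#' the Laplace log-likelihood at the optimum; AIC counts every estimated
#' parameter (fixed effects + random-intercept SD + Gamma shape).
#'
#' @param data Data frame with columns `rt` (ms, strictly positive),
#'   `latency`, `strength`, `contrast` and `neuron` (factor or id).
#'   Rows with NA in any of these are dropped.
#' @param random Include the neuron random intercept? `FALSE` collapses the
#'   model to a plain Gamma GLM (still fitted by the same engine; useful for
#'   boundary checks).
#' @param control List of convergence controls: `rel_tol` (relative
#'   log-likelihood change, default 1e-8), `grad_tol` (inner-mode gradient
#'   infinity norm, default 1e-5), `eval_max` (objective evaluation cap,
#'   default 2e5).
#' @return Object of class `"bl_glmm"`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `z`, `p`), `sigma_u`, `shape`, `logLik`,
#'   `AIC`, `n_params`, `convergence` (0 = converged), `u` (conditional
#'   modes), plus the internals needed for refits.
#' @seealso [single_term_deletion()], [simulate_glmm_data()]
#' @export
fit_gamma_glmm <- function(data, random = TRUE, control = list()) {
  ctl <- utils::modifyList(
    list(rel_tol = 1e-8, grad_tol = 1e-5, eval_max = 2e5), control
  )
  need <- c("rt", "latency", "strength", "contrast", "neuron")
  if (!all(need %in% names(data))) {
    stop("data needs columns ", paste(need, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  if (any(data$rt <= 0)) stop("reaction times must be strictly positive")
  if (nrow(data) < 10) stop("need at least 10 trials")
  group <- as.integer(factor(data$neuron))
  if (random && max(group) < 2) stop("need at least 2 neurons")
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  zl <- zs(data$latency)
  zst <- zs(data$strength)
  zc <- zs(data$contrast)
  X <- cbind(
    "(Intercept)" = 1, latency = zl, strength = zst, contrast = zc,
    "latency:contrast" = zl * zc, "strength:contrast" = zst * zc
  )
  fit <- glmm_engine(data$rt, X, if (random) group else NULL, ctl)
  fit$data <- data
  fit$scaling <- list(
    latency = c(mean(data$latency), stats::sd(data$latency)),
    strength = c(mean(data$strength), stats::sd(data$strength)),
    contrast = c(mean(data$contrast), stats::sd(data$contrast))
  )
  fit
}

# Core engine: y response, X design (already scaled), group integer vector or
# NULL for a fixed-effects-only Gamma GLM. Laplace-approximate ML.
glmm_engine <- function(y, X, group, ctl) {
  p <- ncol(X)
  n <- length(y)
  random <- !is.null(group)
  ngrp <- if (random) max(group) else 0L
  logy_sum <- sum(log(y))
  u_warm <- new.env(parent = emptyenv())
  u_warm$u <- numeric(ngrp)

  inner_modes <- function(off, alpha, sig2) {
    # maximize per-group  sum_j [-alpha*eta - alpha*y*exp(-eta)] - u^2/(2*sig2)
    u <- u_warm$u
    nj <- tabulate(group, ngrp)
    for (it in 1:100) {
      eta <- off + u[group]
      w <- y * exp(-eta)
      sw <- rowsum_vec(w, group, ngrp)
      g1 <- alpha * (sw - nj) - u / sig2
      g2 <- -alpha * sw - 1 / sig2
      step <- g1 / g2
      step <- pmax(pmin(step, 4), -4)  # damp huge first steps
      u <- u - step
      if (max(abs(g1)) < ctl$grad_tol * max(1, alpha)) break
    }
    u_warm$u <- u
    u
  }

  nll <- function(par) {
    beta <- par[seq_len(p)]
    alpha <- exp(par[[length(par)]])
    off <- drop(X %*% beta)
    ll_const <- n * (alpha * log(alpha) - lgamma(alpha)) +
      (alpha - 1) * logy_sum
    if (!random) {
      eta <- off
      ll <- ll_const + sum(-alpha * eta - alpha * y * exp(-eta))
      return(-ll)
    }
    sig2 <- exp(2 * par[[p + 1L]])
    u <- inner_modes(off, alpha, sig2)
    eta <- off + u[group]
    w <- y * exp(-eta)
    ll_obs <- ll_const + sum(-alpha * eta - alpha * w)
    ll_pen <- sum(-u^2 / (2 * sig2)) - ngrp * 0.5 * log(2 * pi * sig2)
    curv <- alpha * rowsum_vec(w, group, ngrp) + 1 / sig2
    ll_lap <- ngrp * 0.5 * log(2 * pi) - 0.5 * sum(log(curv))
    -(ll_obs + ll_pen + ll_lap)
  }

  # start from the independence Gamma GLM
  glm0 <- stats::glm.fit(X, y, family = stats::Gamma(link = "log"))
  beta0 <- glm0$coefficients
  disp0 <- sum((y / exp(drop(X %*% beta0)) - 1)^2) / (n - p)
  start <- c(beta0, if (random) log(0.1), log(1 / max(disp0, 1e-6)))
  opt <- stats::nlminb(
    start, nll,
    control = list(rel.tol = ctl$rel_tol * 1e-2, eval.max = ctl$eval_max,
                   iter.max = 1000)
  )
  par <- opt$par
  ll <- -opt$objective
  k <- length(par)
  H <- num_hessian(nll, par)
  se_all <- rep(NA_real_, k)
  V <- try(solve(H), silent = TRUE)
  if (!inherits(V, "try-error")) {
    dg <- diag(V)
    se_all[dg > 0] <- sqrt(dg[dg > 0])
  }
  beta <- par[seq_len(p)]
  se <- se_all[seq_len(p)]
  zstat <- beta / se
  coef_tab <- data.frame(
    term = colnames(X), estimate = beta, se = se, z = zstat,
    p = 2 * stats::pnorm(-abs(zstat)), row.names = NULL
  )
  structure(
    list(
      coefficients = coef_tab,
      sigma_u = if (random) exp(par[[p + 1L]]) else 0,
      shape = exp(par[[k]]),
      logLik = ll,
      n_params = k,
      AIC = 2 * k - 2 * ll,
      convergence = opt$convergence,
      message = opt$message,
      u = if (random) u_warm$u else NULL,
      y = y, X = X, group = group, random = random, control = ctl
    ),
    class = "bl_glmm"
  )
}

rowsum_vec <- function(x, group, ngrp) {
  out <- numeric(ngrp)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

# Central-difference Hessian (objective-only; the objective is cheap).
num_hessian <- function(f, par, h = 1e-4) {
  k <- length(par)
  hh <- h * pmax(1, abs(par))
  H <- matrix(0, k, k)
  f0 <- f(par)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        pp <- pm <- par
        pp[i] <- par[i] + hh[i]
        pm[i] <- par[i] - hh[i]
        H[i, i] <- (f(pp) - 2 * f0 + f(pm)) / hh[i]^2
      } else {
        ppp <- ppm <- pmp <- pmm <- par
        ppp[c(i, j)] <- par[c(i, j)] + hh[c(i, j)]
        ppm[i] <- par[i] + hh[i]; ppm[j] <- par[j] - hh[j]
        pmp[i] <- par[i] - hh[i]; pmp[j] <- par[j] + hh[j]
        pmm[c(i, j)] <- par[c(i, j)] - hh[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(ppp) - f(ppm) - f(pmp) + f(pmm)) / (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

#' @export
print.bl_glmm <- function(x, ...) {
  cat("Gamma log-link mixed model (Laplace ML)\n")
  cat(sprintf("logLik %.2f  AIC %.1f  shape %.3f  sigma_u %.4f\n",
              x$logLik, x$AIC, x$shape, x$sigma_u))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Single-term deletion analysis for the reaction-time GLMM
#'
#' Removes one predictor together with all its interactions, refits the
#' reduced model, and reports the likelihood-ratio test against the full fit:
#' removing `latency` or `strength` deletes 2 fixed-effect parameters (main
#' effect + its contrast interaction), removing `contrast` deletes 3 (main
#' effect + both interactions).
#'
#' @param fit A `"bl_glmm"` from [fit_gamma_glmm()].
#' @param term One of `"latency"`, `"strength"`, `"contrast"`.
#' @return List with `chisq` (`2 * (logLik_full - logLik_reduced)`), `df`,
#'   `p`, `AIC_full`, `AIC_reduced`, and the reduced `fit`.
#' @export
single_term_deletion <- function(fit, term = c("latency", "strength",
                                               "contrast")) {
  term <- match.arg(term)
  stopifnot(inherits(fit, "bl_glmm"))
  drop_cols <- switch(term,
    latency = c("latency", "latency:contrast"),
    strength = c("strength", "strength:contrast"),
    contrast = c("contrast", "latency:contrast", "strength:contrast")
  )
  keep <- !(colnames(fit$X) %in% drop_cols)
  Xr <- fit$X[, keep, drop = FALSE]
  red <- glmm_engine(fit$y, Xr, fit$group, fit$control)
  if (red$convergence != 0 && red$logLik < fit$logLik - 1e6) {
    stop("reduced model failed to converge: ", red$message)
  }
  chisq <- max(0, 2 * (fit$logLik - red$logLik))
  df <- sum(!keep)
  list(
    term = term, chisq = chisq, df = df,
    p = stats::pchisq(chisq, df, lower.tail = FALSE),
    AIC_full = fit$AIC, AIC_reduced = red$AIC, fit = red
  )
}

#' Simulate reaction-time data directly from the mixed-model specification
#'
#' Draws trial predictors (latency, strength, contrast), z-scores them,
#' forms `log(mu) = X beta + u_neuron` with `u ~ N(0, sigma_u^2)`, and draws
#' `rt ~ Gamma(shape, mean = mu)`. Used for parameter-recovery and
#' null-calibration checks of [fit_gamma_glmm()].
#'
#' @param n_neurons,n_trials Neurons and trials per neuron.
#' @param beta Named fixed-effect vector on the z-scored scale; names from
#'   `c("(Intercept)", "latency", "strength", "contrast",
#'   "latency:contrast", "strength:contrast")`; missing names default to 0
#'   (the intercept defaults to `log(180)`).
#' @param sigma_u Random-intercept SD (log scale).
#' @param shape Gamma shape parameter.
#' @param contrasts Contrast levels sampled uniformly per trial.
#' @param seed Integer seed.
#' @return Data frame with `rt`, `latency`, `strength`, `contrast`, `neuron`
#'   plus the true `u` per neuron as an attribute `"u"`.
#' @export
simulate_glmm_data <- function(n_neurons = 100, n_trials = 40,
                               beta = c("(Intercept)" = log(180),
                                        latency = 0.04, strength = -0.04,
                                        contrast = -0.06),
                               sigma_u = 0.1, shape = 25,
                               contrasts = c(10, 20, 50, 100), seed = 1L) {
  set.seed(as.integer(seed))
  terms <- c("(Intercept)", "latency", "strength", "contrast",
             "latency:contrast", "strength:contrast")
  b <- stats::setNames(numeric(length(terms)), terms)
  b["(Intercept)"] <- log(180)
  b[names(beta)] <- beta
  n <- n_neurons * n_trials
  neuron <- rep(seq_len(n_neurons), each = n_trials)
  latency <- stats::rnorm(n, 60, 8)
  strength <- stats::rnorm(n, 5, 2)
  contrast <- sample(contrasts, n, replace = TRUE)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  zl <- zs(latency)
  zst <- zs(strength)
  zc <- zs(contrast)
  X <- cbind(1, zl, zst, zc, zl * zc, zst * zc)
  u <- stats::rnorm(n_neurons, 0, sigma_u)
  mu <- exp(drop(X %*% b) + u[neuron])
  rt <- stats::rgamma(n, shape = shape, rate = shape / mu)
  out <- data.frame(rt = rt, latency = latency, strength = strength,
                    contrast = contrast, neuron = neuron)
  attr(out, "u") <- u
  attr(out, "beta") <- b
  out
}
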