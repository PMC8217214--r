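#' Group summary statistics
#'
#' @param mean Group mean.
#' @param se Standard error of the mean (> 0).
#' @param n Group size (>= 2).
#' @return A `group_summary`.
#' @export
group_summary <- function(mean, se, n) {
  stopifnot(is.numeric(mean), se > 0, n >= 2)
  structure(list(mean = mean, se = se, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.4g SE (n = %d)\n", x$mean, x$se, x$n))
  invisible(x)
}

new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "stormcross_test")
}

#' @export
print.stormcross_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-sample t-test from published summary statistics
#'
#' Reconstructs the two-sample t statistic from group means, standard
#' errors of the mean, and sizes (sd_i = se_i * sqrt(n_i)). The pooled
#' variant uses the classic pooled variance with df = n1 + n2 - 2; the
#' Welch variant uses the Welch-Satterthwaite df. Two-tailed p.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `stormcross_test`.
#' @export
t_test_from_summary <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  sd1 <- g1$se * sqrt(g1$n); sd2 <- g2$se * sqrt(g2$n)
  if (variant == "pooled") {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * sd1^2 + (g2$n - 1) * sd2^2) / df
    tstat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- sd1^2 / g1$n; v2 <- sd2^2 / g2$n
    tstat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  new_test_result(tstat, df, p,
                  sprintf("Two-sample t-test from summaries (%s)", variant))
}

#' G-test of independence with Yates continuity correction on a 2x2 table
#'
#' Expected counts from the margins; each observed count is moved 0.5
#' toward its expectation (never past it); G = 2 * sum O' log(O'/E) on 1
#' degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply the Yates adjustment (default TRUE).
#' @return A `stormcross_test`.
#' @export
g_test_yates <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  O <- table
  if (correct) O <- O + sign(E - O) * pmin(0.5, abs(E - O))
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  new_test_result(G, 1, stats::pchisq(G, 1, lower.tail = FALSE),
                  if (correct) "G-test with Yates correction" else "G-test")
}

# Gauss-Hermite nodes/weights for weight exp(-z^2), by Golub-Welsch
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = (sqrt(pi) * e$vectors[1, idx]^2))
}

# marginal log-likelihood of a random-intercept logistic model by adaptive
# Gauss-Hermite quadrature. beta: fixed effects; sigma: RE sd; X model
# matrix; y 0/1; g integer group index.
agh_loglik <- function(beta, sigma, y, X, g, gh) {
  eta0 <- drop(X %*% beta)
  ngrp <- max(g)
  if (sigma < 1e-8) {
    return(sum(y * stats::plogis(eta0, log.p = TRUE) +
                 (1 - y) * stats::plogis(-eta0, log.p = TRUE)))
  }
  ll <- 0
  for (j in seq_len(ngrp)) {
    idx <- which(g == j)
    e0 <- eta0[idx]; yj <- y[idx]
    # Newton for the mode of h(u) = sum log p(y|e0 + sigma u) + log phi(u)
    u <- 0
    for (it in 1:50) {
      p <- stats::plogis(e0 + sigma * u)
      g1 <- sigma * sum(yj - p) - u
      g2 <- -sigma^2 * sum(p * (1 - p)) - 1
      step <- g1 / g2
      u <- u - step
      if (abs(step) < 1e-10) break
    }
    p <- stats::plogis(e0 + sigma * u)
    tau <- 1 / sqrt(sigma^2 * sum(p * (1 - p)) + 1)
    zk <- u + sqrt(2) * tau * gh$nodes
    hk <- vapply(zk, function(uu) {
      eta <- e0 + sigma * uu
      sum(yj * stats::plogis(eta, log.p = TRUE) +
            (1 - yj) * stats::plogis(-eta, log.p = TRUE)) +
        stats::dnorm(uu, log = TRUE)
    }, numeric(1))
    m <- max(hk + gh$nodes^2)
    ll <- ll + log(sum(gh$weights * exp(hk + gh$nodes^2 - m))) + m +
      log(sqrt(2) * tau)
  }
  ll
}

#' Random-intercept logistic regression by adaptive Gauss-Hermite quadrature
#'
#' Maximum marginal likelihood for a binary outcome with fixed effects and
#' one Gaussian random intercept (e.g. journey outcome ~ population with a
#' year intercept). The group intercepts are integrated out with adaptive
#' Gauss-Hermite quadrature (default 25 nodes); standard errors come from
#' the observed information at the optimum. A variance estimate at the zero
#' boundary is flagged as a singular fit.
#'
#' @param outcomes 0/1 vector (logicals accepted).
#' @param fixed Design matrix including the intercept column, or a formula
#'   with `data`.
#' @param groups Grouping labels (the random-intercept factor).
#' @param data Optional data.frame when `fixed` is a formula.
#' @param quad_points Number of quadrature nodes (default 25).
#' @param singular_tol Variance at or below this is a boundary (singular)
#'   fit; default 1e-6.
#' @return A `mixed_logit` object with `print`, `summary`, `coef`,
#'   `logLik`, `vcov` and `predict` methods.
#' @export
fit_logistic_random_intercept <- function(outcomes, fixed, groups,
                                          data = NULL, quad_points = 25L,
                                          singular_tol = 1e-6) {
  if (inherits(fixed, "formula")) {
    X <- stats::model.matrix(fixed, data = data)
  } else {
    X <- as.matrix(fixed)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  }
  if (nrow(X) != length(outcomes))
    stop("design matrix must have one row per outcome")
  y <- as.numeric(outcomes)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary")
  gf <- factor(groups)
  if (nlevels(gf) < 2L) stop("need at least 2 groups")
  g <- as.integer(gf)
  gh <- gauss_hermite(quad_points)

  # start from the fixed-effects-only fit
  glm0 <- suppressWarnings(stats::glm.fit(X, y,
                                          family = stats::binomial()))
  beta0 <- glm0$coefficients
  if (any(!is.finite(beta0))) stop("initial logistic fit failed")
  negll <- function(th) {
    b <- th[seq_len(ncol(X))]
    s <- exp(th[length(th)])
    -agh_loglik(b, s, y, X, g, gh)
  }
  th0 <- c(beta0, log(0.5))
  opt <- stats::optim(th0, negll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-10))
  if (opt$convergence != 0)
    stop("mixed-logit optimizer failed to converge: code ", opt$convergence)
  beta <- opt$par[seq_len(ncol(X))]
  if (any(abs(beta) > 30))
    stop("complete (or quasi-complete) separation on covariate '",
         colnames(X)[which.max(abs(beta))], "'")
  sigma <- unname(exp(opt$par[length(opt$par)]))
  ll <- -opt$value
  # boundary comparison: if the zero-variance fit is (numerically) as good,
  # the MLE sits on the boundary and the fit is singular
  opt_b <- stats::optim(beta, function(b) -agh_loglik(b, 0, y, X, g, gh),
                        method = "BFGS", control = list(reltol = 1e-12))
  singular <- sigma^2 <= singular_tol || -opt_b$value >= ll - 1e-6
  if (singular) {
    beta <- opt_b$par
    sigma <- 0
    ll <- -opt_b$value
  }
  # observed information: full (beta, log sigma) Hessian, fixed-effect block
  vc <- if (singular) {
    hess <- stats::optimHess(beta, function(b)
      -agh_loglik(b, 0, y, X, g, gh))
    tryCatch(solve(hess), error = function(e)
      matrix(NA_real_, length(beta), length(beta)))
  } else {
    hess <- stats::optimHess(c(beta, log(sigma)), negll)
    tryCatch(solve(hess)[seq_len(ncol(X)), seq_len(ncol(X)), drop = FALSE],
             error = function(e)
               matrix(NA_real_, length(beta), length(beta)))
  }
  dvc <- diag(vc)
  dvc[!is.na(dvc) & dvc <= 0] <- NA_real_   # non-PD information: no Wald SE
  se <- sqrt(dvc)
  k <- ncol(X) + 1L   # fixed effects + RE variance
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 z = stats::setNames(beta / se, colnames(X)),
                 sigma2 = sigma^2,
                 logLik = ll, n_obs = length(y), k_params = k,
                 aicc = aicc(ll, k, length(y)),
                 singular = singular,
                 quad_points = quad_points,
                 X = X, y = y, groups = gf,
                 vcov = vc),
            class = "mixed_logit")
}

#' @export
print.mixed_logit <- function(x, ...) {
  cat("Random-intercept logistic regression (adaptive Gauss-Hermite,",
      x$quad_points, "nodes)\n")
  print(round(cbind(Estimate = x$coefficients, `Std.Error` = x$se,
                    z = x$z), 4))
  cat(sprintf("Random-intercept variance: %.4g%s\n", x$sigma2,
              if (x$singular) "  (singular: boundary fit)" else ""))
  cat(sprintf("logLik %.3f | AICc %.3f | n = %d\n", x$logLik, x$aicc, x$n_obs))
  invisible(x)
}

#' @export
summary.mixed_logit <- function(object, ...) {
  p <- 2 * stats::pnorm(-abs(object$z))
  out <- cbind(Estimate = object$coefficients, `Std.Error` = object$se,
               z = object$z, `Pr(>|z|)` = p)
  structure(list(coefficients = out, sigma2 = object$sigma2,
                 singular = object$singular, logLik = object$logLik,
                 aicc = object$aicc, n_obs = object$n_obs),
            class = "summary.mixed_logit")
}

#' @export
print.summary.mixed_logit <- function(x, ...) {
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Random-intercept variance %.4g%s | logLik %.3f | AICc %.3f | n %d\n",
              x$sigma2, if (x$singular) " (singular)" else "",
              x$logLik, x$aicc, x$n_obs))
  invisible(x)
}

#' @export
coef.mixed_logit <- function(object, ...) object$coefficients

#' @export
logLik.mixed_logit <- function(object, ...) {
  structure(object$logLik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.mixed_logit <- function(object, ...) object$vcov

#' @export
predict.mixed_logit <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  eta <- drop(X %*% object$coefficients)   # population-level (RE at 0)
  if (type == "response") stats::plogis(eta) else eta
}

#' Small-sample-corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1); requires n > k + 1.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc needs n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Ascending AICc with deltas; models within 2 of the best are flagged as
#' competitive. When `nested_within` names, for a model, the larger model
#' it is nested in, the larger model's extra parameter is flagged
#' uninformative if its delta to the nested model is under 2 and the extra
#' coefficient's |z| is under 2 (flagged, never auto-removed).
#'
#' @param fits Named list of `mixed_logit` fits.
#' @param nested_within Optional named character vector: for a larger
#'   model's name, the name of the model nested in it.
#' @return data.frame: model, k, logLik, AICc, delta_aicc, competitive,
#'   uninformative_extra.
#' @export
rank_models <- function(fits, nested_within = NULL) {
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) f$k_params, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$delta_aicc <- tab$AICc - tab$AICc[1]
  tab$competitive <- tab$delta_aicc < 2
  tab$uninformative_extra <- FALSE
  if (!is.null(nested_within)) {
    for (big in names(nested_within)) {
      small <- nested_within[[big]]
      if (!(big %in% tab$model) || !(small %in% tab$model)) next
      d <- tab$AICc[tab$model == big] - tab$AICc[tab$model == small]
      extra <- setdiff(names(fits[[big]]$coefficients),
                       names(fits[[small]]$coefficients))
      zmax <- if (length(extra))
        max(abs(fits[[big]]$z[extra]), na.rm = TRUE) else Inf
      if (abs(d) < 2 && zmax < 2)
        tab$uninformative_extra[tab$model == big] <- TRUE
    }
  }
  rownames(tab) <- NULL
  tab
}
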