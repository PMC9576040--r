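# Separation-robust generalized linear mixed models.
#
# Maximum a-posteriori fit: independent zero-mean normal priors (sd =
# prior_sd) on every fixed-effect coefficient regularize the likelihood so
# the fit stays finite under complete or quasi-complete separation (factor
# levels with all-zero responses), and normal random intercepts per grouping
# factor are integrated out by a Laplace approximation.  With prior_sd = Inf
# and negligible random variance the fit coincides with an ordinary GLM.

glmm_family <- function(family) {
  switch(family,
    "binomial" = list(
      ll = function(y, m, eta, sigma) {
        mu <- stats::plogis(eta)
        sum(y * log(pmax(mu, 1e-300)) + (m - y) * log(pmax(1 - mu, 1e-300)))
      },
      grad = function(y, m, eta, sigma) y - m * stats::plogis(eta),
      wts = function(y, m, eta, sigma) {
        mu <- stats::plogis(eta); pmax(m * mu * (1 - mu), 1e-10)
      }),
    "poisson" = list(
      ll = function(y, m, eta, sigma) sum(y * eta - exp(eta) - lgamma(y + 1)),
      grad = function(y, m, eta, sigma) y - exp(eta),
      wts = function(y, m, eta, sigma) pmax(exp(eta), 1e-10)),
    "gaussian" = list(
      ll = function(y, m, eta, sigma)
        sum(stats::dnorm(y, eta, sigma, log = TRUE)),
      grad = function(y, m, eta, sigma) (y - eta) / sigma^2,
      wts = function(y, m, eta, sigma) rep(1 / sigma^2, length(eta))),
    stop("unknown family: ", family, call. = FALSE))
}

# mode of the random-effect vector given beta and variance components
glmm_inner_mode <- function(fam, y, m, Xb, Z, dinv, sigma) {
  b <- numeric(ncol(Z))
  for (it in 1:50) {
    eta <- Xb + as.vector(Z %*% b)
    g <- as.vector(crossprod(Z, fam$grad(y, m, eta, sigma))) - dinv * b
    W <- fam$wts(y, m, eta, sigma)
    H <- crossprod(Z * W, Z)
    diag(H) <- diag(H) + dinv
    step <- solve(H, g)
    # step halving for stability
    f0 <- fam$ll(y, m, eta, sigma) - 0.5 * sum(dinv * b^2)
    lambda <- 1
    repeat {
      b_new <- b + lambda * step
      f1 <- fam$ll(y, m, Xb + as.vector(Z %*% b_new), sigma) -
        0.5 * sum(dinv * b_new^2)
      if (f1 >= f0 - 1e-10 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    conv <- max(abs(lambda * step)) < 1e-8
    b <- b_new
    if (conv) break
  }
  eta <- Xb + as.vector(Z %*% b)
  W <- fam$wts(y, m, eta, sigma)
  H <- crossprod(Z * W, Z)
  diag(H) <- diag(H) + dinv
  list(b = b, H = H, eta = eta)
}

#' Fit a Bayesian-regularized GLMM by MAP + Laplace
#'
#' @param data data.frame holding the response, fixed-effect predictors and
#'   grouping columns.
#' @param response name of the response column.  For the binomial family the
#'   response is the success count (0/1 for Bernoulli); pass \code{trials}
#'   for grouped counts.
#' @param fixed character vector of fixed-effect column names (factors or
#'   numerics); an intercept is always included, and \code{NULL} fits an
#'   intercept-only model.
#' @param groups character vector of grouping-factor column names, each
#'   contributing independent normal random intercepts; may be empty.
#' @param family \code{"binomial"} (logit), \code{"poisson"} (log) or
#'   \code{"gaussian"} (identity).
#' @param prior_sd standard deviation of the zero-mean normal prior on each
#'   fixed-effect coefficient (link scale; default 2.5, a standard weakly
#'   informative choice; \code{Inf} disables the prior).
#' @param trials optional name of the binomial trials column.
#' @return object of class \code{glmm_fit}: coefficients, SEs, vcov
#'   (conditional on variance components, as usual for Laplace fits),
#'   per-factor random-intercept SDs, convergence flag, and design metadata
#'   used by [wald_factor_test()] and [pairwise_comparisons()].
#' @export
fit_glmm <- function(data, response, fixed = NULL, groups = character(0),
                     family = c("binomial", "poisson", "gaussian"),
                     prior_sd = 2.5, trials = NULL) {
  family <- match.arg(family)
  fam <- glmm_family(family)
  y <- data[[response]]
  m <- if (!is.null(trials)) data[[trials]] else rep(1, nrow(data))
  if (family == "binomial" && any(y < 0 | y > m))
    stop("binomial response must lie in [0, trials]", call. = FALSE)
  for (f in fixed)
    if (is.character(data[[f]])) data[[f]] <- factor(data[[f]])
  form <- if (length(fixed)) stats::reformulate(fixed) else
    stats::as.formula("~ 1")
  X <- stats::model.matrix(form, data)
  p <- ncol(X)
  # random-effect design: one indicator block per grouping factor
  glist <- lapply(groups, function(g) factor(data[[g]]))
  zlev <- lapply(glist, levels)
  q_per <- vapply(zlev, length, 0L)
  Z <- if (length(groups)) {
    do.call(cbind, lapply(glist, function(g)
      vapply(levels(g), function(l) as.numeric(g == l),
             numeric(length(g)))))
  } else matrix(0, nrow(data), 0)
  fac_of <- rep(seq_along(groups), q_per)
  nq <- length(groups)
  pen <- if (is.finite(prior_sd)) 0.5 / prior_sd^2 else 0

  obj <- function(par) {
    beta <- par[seq_len(p)]
    log_sd <- par[p + seq_len(nq)]
    sigma <- if (family == "gaussian") exp(par[length(par)]) else 1
    Xb <- as.vector(X %*% beta)
    if (nq) {
      dinv <- 1 / exp(2 * log_sd)[fac_of]
      inner <- glmm_inner_mode(fam, y, m, Xb, Z, dinv, sigma)
      ld <- determinant(inner$H, logarithm = TRUE)$modulus
      lmarg <- fam$ll(y, m, inner$eta, sigma) -
        0.5 * sum(dinv * inner$b^2) - sum(log_sd[fac_of]) - 0.5 * ld
    } else {
      lmarg <- fam$ll(y, m, Xb, sigma)
    }
    -(lmarg - pen * sum(beta^2))
  }

  init <- numeric(p + nq + (family == "gaussian"))
  if (family == "gaussian") {
    init[length(init)] <- log(stats::sd(y) + 1e-6)
    init[1] <- mean(y)
  }
  lower <- c(rep(-Inf, p), rep(-7, nq),
             if (family == "gaussian") -10)
  upper <- c(rep(Inf, p), rep(3, nq), if (family == "gaussian") 10)
  opt <- stats::optim(init, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 1000, factr = 1e3,
                                     pgtol = 1e-10))
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  theta_hat <- opt$par
  # covariance of beta conditional on the variance components
  obj_beta <- function(b) obj(c(b, theta_hat[-seq_len(p)]))
  Hb <- stats::optimHess(beta, obj_beta)
  V <- tryCatch(solve(Hb), error = function(e) matrix(NA_real_, p, p))
  dimnames(V) <- list(colnames(X), colnames(X))
  converged <- opt$convergence == 0 && all(is.finite(beta)) &&
    all(is.finite(V))
  random_sd <- stats::setNames(exp(theta_hat[p + seq_len(nq)]), groups)
  structure(list(
    family = family, coefficients = beta, se = sqrt(pmax(diag(V), 0)),
    vcov = V, random_sd = random_sd,
    sigma = if (family == "gaussian") exp(theta_hat[length(theta_hat)]) else NA_real_,
    prior_sd = prior_sd, converged = converged, n_obs = nrow(data),
    logpost = -opt$value,
    terms = stats::terms(form), assign = attr(X, "assign"),
    xlevels = lapply(Filter(function(f) is.factor(data[[f]]), fixed),
                     function(f) levels(data[[f]])) |>
      stats::setNames(Filter(function(f) is.factor(data[[f]]), fixed)),
    fixed = fixed,
    fixed_data = data[, fixed, drop = FALSE]
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("MAP GLMM (%s), n = %d, prior sd = %g, converged: %s\n",
              x$family, x$n_obs, x$prior_sd, x$converged))
  print(data.frame(estimate = x$coefficients, se = x$se))
  if (length(x$random_sd))
    cat("random-intercept SD:",
        paste(sprintf("%s = %.3f", names(x$random_sd), x$random_sd),
              collapse = ", "), "\n")
  invisible(x)
}

factor_block <- function(fit, factor) {
  labs <- attr(fit$terms, "term.labels")
  k <- match(factor, labs)
  if (is.na(k)) stop("factor '", factor, "' not in the fit", call. = FALSE)
  which(fit$assign == k)
}

#' Wald chi-square test for the overall effect of a factor
#'
#' Computes \code{c' V^-1 c} over the factor's coefficient block with df
#' equal to the block size.
#'
#' @param fit a converged [fit_glmm()] object.
#' @param factor name of a fixed-effect factor in the fit.
#' @return one-row data.frame \code{statistic_name,statistic_value,df,
#'   p_value}.
#' @export
wald_factor_test <- function(fit, factor) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  idx <- factor_block(fit, factor)
  cc <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  rc <- rcond(V)
  if (!is.finite(rc) || rc < 1e-12)
    stop(sprintf("singular coefficient covariance (rcond = %.3g)", rc),
         call. = FALSE)
  stat <- as.numeric(t(cc) %*% solve(V, cc))
  data.frame(statistic_name = "Wald chi-square", statistic_value = stat,
             df = length(idx),
             p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Adjusted pairwise comparisons of factor levels
#'
#' All level pairs on the link scale, at the reference grid (other factors at
#' their first level, numeric covariates at their mean).  The default
#' adjustment is the single-step multivariate-normal method over the contrast
#' correlation matrix (the Tukey-style adjustment for possibly correlated
#' contrasts); Bonferroni and no adjustment are available.  Simultaneous
#' confidence bounds use the equicoordinate normal quantile consistent with
#' the adjusted alpha.
#'
#' @param fit a converged [fit_glmm()] object.
#' @param factor factor name with at least 2 levels.
#' @param adjust \code{"single-step"}, \code{"bonferroni"} or \code{"none"}.
#' @param level simultaneous confidence level (default 0.95).
#' @return data.frame \code{contrast,estimate,se,z,p_adjusted,lower,upper}.
#' @export
pairwise_comparisons <- function(fit, factor,
                                 adjust = c("single-step", "bonferroni",
                                            "none"),
                                 level = 0.95) {
  adjust <- match.arg(adjust)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  levs <- fit$xlevels[[factor]]
  if (is.null(levs) || length(levs) < 2L)
    stop("factor must have at least 2 levels", call. = FALSE)
  grid <- fit$fixed_data[rep(1, length(levs)), , drop = FALSE]
  for (f in fit$fixed) {
    col <- fit$fixed_data[[f]]
    if (is.numeric(col)) grid[[f]] <- mean(col)
    else grid[[f]] <- factor(levels(factor(col))[1],
                             levels = levels(factor(col)))
  }
  grid[[factor]] <- factor(levs, levels = levs)
  L <- stats::model.matrix(stats::delete.response(fit$terms), grid)
  pairs <- utils::combn(length(levs), 2)
  C <- t(apply(pairs, 2, function(ij) L[ij[1], ] - L[ij[2], ]))
  est <- as.vector(C %*% fit$coefficients)
  Vc <- C %*% fit$vcov %*% t(C)
  se <- sqrt(pmax(diag(Vc), 0))
  z <- est / se
  k <- length(z)
  R <- stats::cov2cor(Vc)
  p_adj <- switch(adjust,
    "none" = 2 * stats::pnorm(-abs(z)),
    "bonferroni" = pmin(1, k * 2 * stats::pnorm(-abs(z))),
    "single-step" = vapply(abs(z), function(a) {
      1 - mvtnorm::pmvnorm(lower = rep(-a, k), upper = rep(a, k),
                           sigma = R)[1]
    }, 0))
  crit <- switch(adjust,
    "none" = stats::qnorm(1 - (1 - level) / 2),
    "bonferroni" = stats::qnorm(1 - (1 - level) / (2 * k)),
    "single-step" = mvtnorm::qmvnorm(level, tail = "both.tails",
                                     sigma = R)$quantile)
  data.frame(
    contrast = apply(pairs, 2, function(ij)
      paste(levs[ij[1]], "-", levs[ij[2]])),
    estimate = est, se = se, z = z, p_adjusted = pmin(pmax(p_adj, 0), 1),
    lower = est - crit * se, upper = est + crit * se,
    stringsAsFactors = FALSE)
}
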