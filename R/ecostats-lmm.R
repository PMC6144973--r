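#' Random-intercept mixed models by profiled likelihood
#'
#' Gaussian models y = X beta + Z1 b1 + ... + Zm bm + e with b_j ~
#' N(0, sigma2_eps * theta_j I) and e ~ N(0, sigma2_eps I). The marginal
#' covariance is sigma2_eps * V0 with V0 = I + sum theta_j Z_j Z_j'.
#' For each candidate theta the generalized-least-squares beta and the
#' profiled sigma2_eps are closed-form, leaving a low-dimensional
#' optimization over log(theta). Site random intercepts and penalized
#' smooth terms are both variance components in this scheme.
#'
#' @name ecostats-lmm
NULL

# Core evaluator: given theta vector, return profiled quantities.
mixed_profile <- function(theta, y, X, Zlist, criterion) {
  n <- length(y); p <- ncol(X)
  V0 <- diag(n)
  for (j in seq_along(Zlist)) {
    Zj <- Zlist[[j]]
    V0 <- V0 + theta[j] * tcrossprod(Zj)
  }
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  logdetV0 <- 2 * sum(log(diag(R)))
  Xi <- backsolve(R, X, transpose = TRUE)   # R^-T X
  yi <- backsolve(R, y, transpose = TRUE)
  A <- crossprod(Xi)
  Ar <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ar)) return(list(loglik = -Inf))
  beta <- backsolve(Ar, backsolve(Ar, crossprod(Xi, yi), transpose = TRUE))
  r <- yi - Xi %*% beta
  q <- sum(r^2)
  if (criterion == "ML") {
    sigma2 <- q / n
    loglik <- -0.5 * (n * log(2 * pi * sigma2) + n + logdetV0)
  } else {
    sigma2 <- q / (n - p)
    logdetA <- 2 * sum(log(diag(Ar)))
    loglik <- -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) + logdetV0 + logdetA)
  }
  vcov_beta <- sigma2 * chol2inv(Ar)
  list(loglik = loglik, beta = drop(beta), sigma2 = sigma2,
       vcov_beta = vcov_beta, V0_chol = R)
}

#' Fit a Gaussian mixed model with variance-component ratios profiled out
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (including the intercept).
#' @param Zlist list of random-effect design matrices, each carrying one
#'   variance ratio theta_j = sigma2_j / sigma2_eps.
#' @param criterion "ML" or "REML".
#' @param labels optional names for the variance components.
#' @return list with the optimum: `beta`, `se`, `vcov_beta`, `sigma2_eps`,
#'   `theta`, `loglik`, `boundary` (logical per component), `criterion`.
#' @keywords internal
fit_gauss_mixed <- function(y, X, Zlist, criterion = c("ML", "REML"), labels = NULL) {
  criterion <- match.arg(criterion)
  n <- length(y); p <- ncol(X)
  if (n <= p + 2) stop("too few observations for the fixed design")
  if (qr(X)$rank < p) stop("singular fixed-effect design (collinear covariates)")
  m <- length(Zlist)
  obj <- function(lt) {
    v <- -mixed_profile(exp(lt), y, X, Zlist, criterion)$loglik
    if (!is.finite(v)) 1e10 else v
  }
  if (m == 0) {
    lt_opt <- numeric(0)
  } else if (m == 1) {
    op <- stats::optimize(obj, interval = c(-15, 10), tol = 1e-9)
    lt_opt <- op$minimum
  } else {
    op <- stats::optim(rep(0, m), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    # polish each coordinate once
    for (j in seq_len(m)) {
      f1 <- function(v) { lt <- op$par; lt[j] <- v; obj(lt) }
      o1 <- stats::optimize(f1, interval = c(op$par[j] - 3, op$par[j] + 3), tol = 1e-8)
      if (o1$objective < op$value) { op$par[j] <- o1$minimum; op$value <- o1$objective }
    }
    lt_opt <- op$par
  }
  theta <- exp(lt_opt)
  boundary <- theta < 1e-6
  theta[boundary] <- 0
  res <- mixed_profile(theta, y, X, Zlist, criterion)
  if (!is.null(labels) && length(labels) == m) names(theta) <- labels
  list(beta = res$beta, se = sqrt(diag(res$vcov_beta)), vcov_beta = res$vcov_beta,
       sigma2_eps = res$sigma2, theta = theta,
       sigma2_components = res$sigma2 * theta,
       loglik = res$loglik, boundary = boundary, criterion = criterion)
}

#' Fit a random-intercept linear mixed model
#'
#' The single-variance-component case: y = X beta + site intercept + e,
#' fitted by 1-D profiled (restricted) maximum likelihood over the variance
#' ratio sigma2_site / sigma2_eps. At the boundary theta = 0 the fit is
#' valid and flagged "random effect at boundary"; beta then equals ordinary
#' least squares.
#'
#' @param y response vector.
#' @param X fixed design matrix including the intercept column.
#' @param site factor or character vector of site identifiers (>= 2 sites).
#' @param criterion "ML" or "REML".
#' @return an object of class `ovo_lmm`: coefficient estimates with SE and
#'   approximate t-based p-values (residual df = n - k), variance components
#'   `sigma2_alpha` and `sigma2_eps`, `loglik`, parameter count `k` (fixed
#'   coefficients + 2 variance parameters), `n`, and `fitted_fixed`.
#' @export
fit_lmm <- function(y, X, site, criterion = c("ML", "REML")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  site <- factor(site)
  if (nlevels(site) < 2) stop("at least 2 sites are required for the random intercept")
  Z <- stats::model.matrix(~ site - 1)
  fit <- fit_gauss_mixed(y, X, list(site = Z), criterion, labels = "site")
  k <- ncol(X) + 2L
  new_ovo_lmm(fit, y = y, X = X, Zlist = list(site = Z), k = k,
              label = "lmm", response = deparse(substitute(y)),
              site_component = 1L)
}

new_ovo_lmm <- function(fit, y, X, Zlist, k, label, response,
                        site_component = NA_integer_, smooth_info = list()) {
  n <- length(y)
  sigma2_alpha <- if (!is.na(site_component)) fit$sigma2_components[site_component] else 0
  fitted_fixed <- drop(X %*% fit$beta)
  tval <- fit$beta / fit$se
  pval <- 2 * stats::pt(-abs(tval), df = max(1, n - k))
  coef_tab <- data.frame(term = colnames(X) %||% paste0("b", seq_along(fit$beta)),
                         estimate = fit$beta, se = fit$se, t = tval,
                         p_approx = pval, row.names = NULL)
  structure(list(label = label, response = response,
                 coefficients = coef_tab, beta = fit$beta, se = fit$se,
                 vcov_beta = fit$vcov_beta,
                 sigma2_alpha = unname(sigma2_alpha),
                 sigma2_eps = fit$sigma2_eps,
                 theta = fit$theta, boundary = fit$boundary,
                 loglik = fit$loglik, criterion = fit$criterion,
                 k = k, n = n, X = X, y = y, Zlist = Zlist,
                 site_component = site_component,
                 smooth_info = smooth_info,
                 fitted_fixed = fitted_fixed),
            class = "ovo_lmm")
}

#' @export
print.ovo_lmm <- function(x, ...) {
  cat(sprintf("<ovo_lmm> %s (%s): logLik %.3f, k = %d, n = %d\n", x$label,
              x$criterion, x$loglik, x$k, x$n))
  cat(sprintf("  sigma2_site = %.4g%s, sigma2_eps = %.4g\n", x$sigma2_alpha,
              if (any(x$boundary)) " [random effect at boundary]" else "",
              x$sigma2_eps))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
logLik.ovo_lmm <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik model log-likelihood (ML or REML, consistently within a
#'   comparison).
#' @param k parameter count (fixed coefficients + variance parameters, +1
#'   per smoothing parameter).
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("undefined criterion: n - k - 1 must be positive")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
AIC.ovo_lmm <- function(object, ..., k = 2) -2 * object$loglik + k * object$k

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-component decomposition: with sigma2_f the population variance
#' of the fixed-effect predictions X beta over the data, R2m = sigma2_f /
#' (sigma2_f + sigma2_alpha + sigma2_eps) and R2c = (sigma2_f + sigma2_alpha)
#' / (sigma2_f + sigma2_alpha + sigma2_eps).
#'
#' @param fit an `ovo_lmm`, or a list with elements `fitted_fixed`,
#'   `sigma2_alpha`, `sigma2_eps`.
#' @return named vector c(R2m, R2c).
#' @export
r2_nakagawa <- function(fit) {
  f <- fit$fitted_fixed
  s2f <- mean((f - mean(f))^2)
  denom <- s2f + fit$sigma2_alpha + fit$sigma2_eps
  if (denom <= 0) stop("undefined R-squared: zero total variance")
  c(R2m = s2f / denom, R2c = (s2f + fit$sigma2_alpha) / denom)
}

#' Cubic regression spline basis with a second-difference penalty
#'
#' B-spline basis of dimension at most `max_knots` with interior knots at
#' covariate quantiles, split for mixed-model fitting into an unpenalized
#' linear part (the covariate itself; the constant is absorbed by the model
#' intercept) and a penalized part scaled so its coefficients carry an
#' identity penalty. As the smoothing parameter grows the term collapses
#' exactly onto the least-squares line.
#'
#' @param x covariate vector.
#' @param max_knots basis dimension cap (default 5, guarding against
#'   over-fitting).
#' @return list with `Z` (penalized columns), `transform` (to rebuild the
#'   basis at new covariate values), and `K` (basis dimension used).
#' @keywords internal
smooth_basis <- function(x, max_knots = 5) {
  K <- max_knots
  nu <- length(unique(x))
  if (nu < K + 2) {
    K <- max(3, nu - 2)
    warning(sprintf("fewer distinct covariate values than knots: basis reduced to %d", K))
  }
  if (!requireNamespace("splines", quietly = TRUE)) stop("splines required")
  B <- splines::bs(x, df = K, degree = 3)
  D <- diff(diag(K), differences = 2)
  S <- crossprod(D)
  es <- eigen(S, symmetric = TRUE)
  pen <- es$values > max(es$values) * 1e-8
  U <- es$vectors[, pen, drop = FALSE]
  d <- es$values[pen]
  Zs <- B %*% U %*% diag(1 / sqrt(d), length(d))
  knots <- attr(B, "knots"); bd <- attr(B, "Boundary.knots")
  transform <- function(xnew) {
    Bn <- splines::bs(xnew, knots = knots, Boundary.knots = bd, degree = 3)
    Bn %*% U %*% diag(1 / sqrt(d), length(d))
  }
  list(Z = Zs, transform = transform, K = K)
}

#' Fit a single penalized smooth of one covariate with a site intercept
#'
#' Convenience wrapper: y = intercept + linear(covariate) + penalized smooth
#' deviation + site intercept + error, the smoothing parameter and the site
#' variance both chosen by the profiled (restricted) likelihood.
#'
#' @param y response.
#' @param covariate the smoothed covariate.
#' @param site site identifiers.
#' @param max_knots spline basis cap (default 5).
#' @param criterion "ML" or "REML".
#' @return an `ovo_lmm` whose `smooth_info` records the basis and whose
#'   `edf` element gives the term's equivalent degrees of freedom.
#' @export
fit_smooth_term <- function(y, covariate, site, max_knots = 5,
                            criterion = c("ML", "REML")) {
  criterion <- match.arg(criterion)
  if (length(y) < 20) stop("at least 20 observations are required")
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  site <- factor(site)
  z <- (covariate - mean(covariate)) / stats::sd(covariate)
  sb <- smooth_basis(covariate, max_knots)
  X <- cbind(`(Intercept)` = 1, z = z)
  Z <- stats::model.matrix(~ site - 1)
  fit <- fit_gauss_mixed(y, X, list(site = Z, smooth = sb$Z), criterion,
                         labels = c("site", "smooth"))
  k <- ncol(X) + 3L  # fixed + sigma_site + sigma_eps + one smoothing parameter
  out <- new_ovo_lmm(fit, y = y, X = X, Zlist = list(site = Z, smooth = sb$Z),
                     k = k, label = sprintf("s(%s)", deparse(substitute(covariate))),
                     response = "y", site_component = 1L,
                     smooth_info = list(list(basis = sb, theta_index = 2L,
                                             x_col = 2L)))
  out$edf <- smooth_edf(out)[1]
  out$fitted_smooth <- drop(X[, 2] * fit$beta[2] +
                            sb$Z %*% smooth_coefs(out, 1L))
  out
}

# BLUP coefficients of the idx-th random component.
component_blup <- function(fit, idx) {
  theta <- fit$theta[idx]
  if (theta == 0) return(rep(0, ncol(fit$Zlist[[idx]])))
  n <- fit$n
  V0 <- diag(n)
  for (j in seq_along(fit$Zlist)) V0 <- V0 + fit$theta[j] * tcrossprod(fit$Zlist[[j]])
  r <- fit$y - fit$fitted_fixed
  drop(theta * crossprod(fit$Zlist[[idx]], solve(V0, r)))
}

smooth_coefs <- function(fit, which_smooth) {
  si <- fit$smooth_info[[which_smooth]]
  component_blup(fit, si$theta_index)
}

#' Equivalent degrees of freedom of each smooth term
#'
#' Trace of the term's block of the coefficient influence matrix
#' F = (C'C + P)^-1 C'C, where C stacks all fixed and random columns and P
#' penalizes each random block by 1/theta_j; each smooth's edf sums the
#' diagonal entries over its linear column and its penalized columns.
#'
#' @param fit an `ovo_lmm` with smooth terms.
#' @return numeric vector of edf values, one per smooth term.
#' @export
smooth_edf <- function(fit) {
  if (length(fit$smooth_info) == 0) return(numeric(0))
  C <- fit$X
  pen <- rep(0, ncol(fit$X))
  blocks <- list()
  for (j in seq_along(fit$Zlist)) {
    Zj <- fit$Zlist[[j]]
    blocks[[j]] <- ncol(C) + seq_len(ncol(Zj))
    C <- cbind(C, Zj)
    pen <- c(pen, rep(if (fit$theta[j] > 0) 1 / fit$theta[j] else Inf, ncol(Zj)))
  }
  keep <- is.finite(pen)
  CtC <- crossprod(C)
  Pm <- diag(ifelse(keep, pen, 0))
  # columns with infinite penalty contribute exactly zero edf
  Fm <- matrix(0, ncol(C), ncol(C))
  act <- which(keep | pen == 0)
  Fi <- solve(CtC[act, act] + Pm[act, act], CtC[act, act])
  Fm[act, act] <- Fi
  vapply(fit$smooth_info, function(si) {
    idx <- c(si$x_col, blocks[[si$theta_index]])
    sum(diag(Fm)[idx])
  }, 0)
}

#' Concurvity between two model terms
#'
#' The generalized-additive analogue of collinearity: the fraction of term
#' A's fitted contribution that is explainable by projection onto term B's
#' basis (an R-squared, 0 = none, 1 = total lack of identifiability).
#'
#' @param fit a fitted `ovo_lmm` built by the model-selection machinery
#'   (its design records which columns belong to which term), or NULL when
#'   `fa`/`Bb` are supplied directly.
#' @param term_a,term_b term labels present in the fit.
#' @param fa,Bb alternatively, the fitted contribution of term A and the
#'   basis matrix of term B.
#' @return concurvity value in [0, 1].
#' @export
concurvity <- function(fit = NULL, term_a = NULL, term_b = NULL,
                       fa = NULL, Bb = NULL) {
  if (!is.null(fit)) {
    ta <- term_design(fit, term_a)
    tb <- term_design(fit, term_b)
    fa <- ta$contribution
    Bb <- tb$basis
  }
  if (stats::sd(fa) == 0) stop("undefined concurvity: constant term contribution")
  f <- stats::lm.fit(cbind(1, Bb), fa)$fitted.values
  v <- sum((f - mean(fa))^2) / sum((fa - mean(fa))^2)
  min(max(v, 0), 1)
}

# design columns and fitted contribution of a named term in a selection fit
term_design <- function(fit, term) {
  ti <- fit$term_index
  if (is.null(ti) || !term %in% names(ti)) stop(sprintf("unknown term '%s' in fit", term))
  cols <- ti[[term]]$x_cols
  basis <- fit$X[, cols, drop = FALSE]
  contribution <- drop(basis %*% fit$beta[cols])
  si_id <- ti[[term]]$smooth_id
  if (!is.na(si_id)) {
    Zs <- fit$Zlist[[fit$smooth_info[[si_id]]$theta_index]]
    basis <- cbind(basis, Zs)
    contribution <- contribution + drop(Zs %*% smooth_coefs(fit, si_id))
  }
  list(basis = basis, contribution = contribution)
}
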