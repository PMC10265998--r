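# Maximum-likelihood linear mixed models with a per-site random intercept
# and AR(1) within-site residual correlation: the local estimator behind
# every structural-equation model equation.
#
# Per group g the marginal covariance is
#   V_g = sigma_b2 * J + sigma2 * R_g(phi),   R_g[jk] = phi^|t_j - t_k|,
# with sigma2 the *stationary marginal* AR(1) variance and t the (integer)
# observation years, so survey gaps enter through the lag exponent. R_g is
# the correlation matrix of a Gaussian Markov process, so its inverse is
# tridiagonal and the rank-one intercept term is absorbed with a
# Sherman-Morrison update: every likelihood evaluation is O(n).

# Flat block-tridiagonal layout: rows sorted by (group, time); the
# stacked R^{-1} of all groups is one tridiagonal matrix whose
# off-diagonal is zeroed at group seams. `has_prev[i]` marks a
# within-group adjacency between rows i-1 and i with time gap `dt[i]`.
lmm_structure <- function(group, time) {
  n <- length(group)
  has_prev <- c(FALSE, group[-1] == group[-n])
  dt <- c(NA_real_, diff(time))
  dt[!has_prev] <- NA_real_
  if (any(dt == 0, na.rm = TRUE)) {
    stop("duplicate time points within a group", call. = FALSE)
  }
  gid <- match(group, unique(group))
  list(n = n, has_prev = has_prev, dt = dt, gid = gid,
       n_groups = length(unique(group)))
}

# Profiled negative log-likelihood at (sigma_b2, sigma2, phi); beta is
# solved by generalized least squares at each evaluation. Every step is
# O(n) via the tridiagonal precision and a rank-one (Sherman-Morrison)
# update per group for the random intercept.
lmm_nll <- function(sigma_b2, sigma2, phi, Z, str) {
  n <- str$n
  p <- ncol(Z) - 1L
  ip <- which(str$has_prev)
  a <- numeric(n) # lag correlation of row i with row i-1 (0 at seams)
  if (phi != 0) a[ip] <- phi^str$dt[ip]
  s <- 1 - a^2
  inv_s <- 1 / s
  # diagonal of R^{-1}: (1/s_prev if linked back else 1) +
  #                     (1/s_next if linked forward else 1) - 1
  vprev <- rep(1, n); vprev[ip] <- inv_s[ip]
  vnext <- rep(1, n); vnext[ip - 1L] <- inv_s[ip]
  dm <- vprev + vnext - 1
  off <- numeric(n); off[ip] <- -a[ip] * inv_s[ip]
  W <- Z * dm
  W[ip, ] <- W[ip, , drop = FALSE] + off[ip] * Z[ip - 1L, , drop = FALSE]
  W[ip - 1L, ] <- W[ip - 1L, , drop = FALSE] + off[ip] * Z[ip, , drop = FALSE]
  u <- dm + off
  u[ip - 1L] <- u[ip - 1L] + off[ip]
  u <- u / sigma2                      # (sigma2 R)^{-1} %*% 1
  W <- W / sigma2                      # (sigma2 R)^{-1} %*% Z
  A <- crossprod(Z, W)
  q <- drop(rowsum(u, str$gid, reorder = FALSE))
  ld <- n * log(sigma2) + sum(log(s[ip])) + sum(log1p(sigma_b2 * q))
  if (sigma_b2 > 0) {
    U <- rowsum(Z * u, str$gid, reorder = FALSE) # per-group Z_g' u_g
    cg <- sigma_b2 / (1 + sigma_b2 * q)
    A <- A - crossprod(U, U * cg)
  }
  XtVX <- A[seq_len(p), seq_len(p), drop = FALSE]
  XtVy <- A[seq_len(p), p + 1L]
  yy <- A[p + 1L, p + 1L]
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = 1e10))
  rss <- yy - sum(XtVy * beta)
  list(nll = 0.5 * (n * log(2 * pi) + ld + rss), beta = beta, XtVX = XtVX)
}

#' Fit a linear mixed model with AR(1) residual correlation
#'
#' Maximizes the marginal Gaussian log-likelihood (maximum likelihood,
#' not REML) of a model with fixed effects, an optional per-group random
#' intercept and an optional AR(1) correlation among within-group
#' residuals. `sigma2` parameterizes the stationary marginal variance of
#' the AR(1) process; gaps in the time variable enter the correlation as
#' `phi^|delta t|`. Optimization is over
#' `(log sigma_b2, log sigma2, atanh phi)` with the fixed effects
#' profiled out by generalized least squares, multi-started from three
#' fixed initial points.
#'
#' Coefficient p-values use t statistics with
#' `df = n_obs - n_terms - n_groups` when a random intercept is
#' estimated (a conservative containment-style choice), else
#' `n_obs - n_terms`.
#'
#' @param data Data frame holding all referenced variables.
#' @param response Name of the response column.
#' @param fixed_terms Character vector of fixed-effect terms; pairwise
#'   interactions are written `"a:b"`. Empty means intercept-only.
#' @param group Name of the grouping (site) column.
#' @param time Name of the integer time (year) column; within each group
#'   times must be unique.
#' @param correlation `"ar1"` (default) or `"none"` (phi fixed at 0).
#' @param random_intercept Estimate a per-group intercept variance?
#'   Forced off when fewer than 2 groups are present.
#' @return An object of class `sav_lmm` with elements `coefficients`,
#'   `se`, `t_stats`, `p_values`, `sigma_b2`, `sigma2`, `phi`, `loglik`,
#'   `n_obs`, `n_groups`, `r2_marginal`, `r2_conditional` among others.
#' @seealso [standardize_coefficients()], [r2_nakagawa()],
#'   [residual_lag_correlation()]
#' @examples
#' d <- simulate_lmm_dataset(n_groups = 10, n_years = 8, beta = c(0, 0.5),
#'                           phi = 0.3, sigma_b = 0.2, seed = 1)
#' fit <- fit_lmm(d, "y", "x1", group = "site", time = "year")
#' tidy(fit)
#' @export
fit_lmm <- function(data, response, fixed_terms = character(),
                    group = "site_id", time = "year",
                    correlation = c("ar1", "none"),
                    random_intercept = TRUE) {
  correlation <- match.arg(correlation)
  stopifnot(is.data.frame(data))
  if (response %in% fixed_terms) {
    stop("response cannot appear among the fixed terms", call. = FALSE)
  }
  rhs <- if (length(fixed_terms) == 0) "1" else fixed_terms
  form <- reformulate(rhs, response)
  vars <- unique(c(all.vars(form), group, time))
  check_columns(data, vars, "data")
  data <- arrange(as_tibble(data), .data[[group]], .data[[time]])
  num_vars <- setdiff(all.vars(form), response)
  for (v in c(response, num_vars)) {
    if (!all(is.finite(data[[v]]))) {
      stop("non-finite values in variable '", v, "'", call. = FALSE)
    }
  }
  X <- model.matrix(form, data)
  y <- data[[response]]
  gvec <- as.character(data[[group]])
  tvec <- as.numeric(data[[time]])
  n <- length(y)
  p <- ncol(X)
  n_groups <- length(unique(gvec))
  use_re <- random_intercept && n_groups >= 2
  use_ar <- correlation == "ar1"
  Z <- cbind(X, y)
  str <- lmm_structure(gvec, tvec)

  ols <- stats::lm.fit(X, y)
  rvar <- max(sum(ols$residuals^2) / n, 1e-10)

  if (!use_re && !use_ar) {
    # closed form: GLS with V = sigma2 I is OLS; ML sigma2 = RSS / n
    beta <- ols$coefficients
    sigma2 <- rvar
    final <- lmm_nll(0, sigma2, 0, Z, str)
    theta_hat <- c(sb2 = 0, s2 = sigma2, phi = 0)
    best_val <- final$nll
    converged <- TRUE
  } else {
    pack <- function(sb2, s2, phi) {
      c(if (use_re) log(sb2), log(s2), if (use_ar) atanh(phi))
    }
    unpack <- function(par) {
      i <- 1L
      sb2 <- 0
      if (use_re) { sb2 <- exp(par[i]); i <- i + 1L }
      s2 <- exp(par[i]); i <- i + 1L
      phi <- if (use_ar) tanh(par[i]) else 0
      c(sb2 = sb2, s2 = s2, phi = phi)
    }
    obj <- function(par) {
      th <- unpack(par)
      if (!all(is.finite(th)) || th["s2"] <= 0) return(1e10)
      lmm_nll(th[["sb2"]], th[["s2"]], th[["phi"]], Z, str)$nll
    }
    starts <- list(pack(0.1 * rvar, 0.9 * rvar, 0),
                   pack(0.3 * rvar, 0.7 * rvar, 0.3),
                   pack(0.01 * rvar, rvar, -0.2))
    fits <- lapply(starts, function(s) {
      optim(s, obj, method = "Nelder-Mead",
            control = list(reltol = 1e-10, maxit = 5000))
    })
    vals <- vapply(fits, `[[`, numeric(1), "value")
    if (all(vals >= 1e10)) {
      stop("mixed-model optimization failed to find a finite likelihood; ",
           "last objective values: ", paste(signif(vals, 6), collapse = ", "),
           call. = FALSE)
    }
    best <- fits[[which.min(vals)]]
    theta_hat <- unpack(best$par)
    final <- lmm_nll(theta_hat[["sb2"]], theta_hat[["s2"]],
                     theta_hat[["phi"]], Z, str)
    best_val <- best$value
    converged <- best$convergence == 0
    if (!converged) {
      stop("mixed-model optimization did not converge within the iteration ",
           "budget (objective ", signif(best_val, 8), ", theta = ",
           paste(signif(theta_hat, 6), collapse = ", "), ")", call. = FALSE)
    }
  }

  beta <- as.numeric(final$beta)
  names(beta) <- colnames(X)
  vcov_beta <- solve(final$XtVX)
  se <- sqrt(diag(vcov_beta))
  df_resid <- n - p - if (use_re) n_groups else 0L
  t_stats <- beta / se
  p_values <- 2 * pt(-abs(t_stats), df = max(df_resid, 1L))
  fitted <- drop(X %*% beta)
  var_fixed <- if (n > 1) var(fitted) else 0
  denom <- var_fixed + theta_hat["sb2"] + theta_hat["s2"]

  structure(list(
    coefficients = beta, se = setNames(se, names(beta)),
    t_stats = setNames(t_stats, names(beta)),
    p_values = setNames(p_values, names(beta)),
    vcov = vcov_beta, df_resid = df_resid,
    sigma_b2 = unname(theta_hat["sb2"]), sigma2 = unname(theta_hat["s2"]),
    phi = unname(theta_hat["phi"]),
    loglik = -best_val, n_obs = n, n_groups = n_groups,
    r2_marginal = unname(var_fixed / denom),
    r2_conditional = unname((var_fixed + theta_hat["sb2"]) / denom),
    response = response, fixed_terms = fixed_terms, group = group,
    time = time, correlation = correlation, random_intercept = use_re,
    X = X, y = y, group_vec = gvec, time_vec = tvec, fitted = fitted,
    converged = converged
  ), class = "sav_lmm")
}

#' @export
print.sav_lmm <- function(x, ...) {
  cat("Linear mixed model (ML), response:", x$response, "\n")
  cat(sprintf("  %d obs in %d groups; correlation: %s; random intercept: %s\n",
              x$n_obs, x$n_groups, x$correlation,
              ifelse(x$random_intercept, "yes", "no")))
  cat(sprintf("  logLik %.4f | sigma_b2 %.4g | sigma2 %.4g | phi %.3f\n",
              x$loglik, x$sigma_b2, x$sigma2, x$phi))
  cat(sprintf("  R2 marginal %.3f, conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  print(tidy(x))
  invisible(x)
}

#' @export
logLik.sav_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              object$random_intercept + (object$correlation == "ar1") + 1,
            nobs = object$n_obs, class = "logLik")
}

#' Broom-style coefficient table for a mixed-model fit
#'
#' @param x A `sav_lmm` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy sav_lmm
#' @export
tidy.sav_lmm <- function(x, ...) {
  std <- standardize_coefficients(x)
  tibble(
    term = names(x$coefficients), estimate = unname(x$coefficients),
    std_estimate = std$std_estimate[match(names(x$coefficients), std$term)],
    std.error = unname(x$se), statistic = unname(x$t_stats),
    p.value = unname(x$p_values)
  )
}

#' One-row model summary of a mixed-model fit
#'
#' @param x A `sav_lmm` object.
#' @param ... Unused.
#' @return Tibble with log-likelihood, variance components, AR(1)
#'   parameter, marginal/conditional R-squared and sample sizes.
#' @method glance sav_lmm
#' @export
glance.sav_lmm <- function(x, ...) {
  tibble(
    logLik = x$loglik, sigma_b2 = x$sigma_b2, sigma2 = x$sigma2,
    phi = x$phi, r2_marginal = x$r2_marginal,
    r2_conditional = x$r2_conditional, nobs = x$n_obs,
    n_groups = x$n_groups, df_resid = x$df_resid
  )
}

#' Standardized path coefficients
#'
#' Scales each fixed-effect estimate by the ratio of the sample standard
#' deviation of its realized design column (interactions via the product
#' column) to that of the response, making coefficients comparable
#' across relationships within and among models. Intercepts get NA.
#'
#' @param fit A `sav_lmm` fit.
#' @param data Optional data frame; defaults to the design stored with
#'   the fit.
#' @return Tibble with `term`, `estimate`, `std_estimate`.
#' @export
standardize_coefficients <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "sav_lmm"))
  X <- fit$X
  y <- fit$y
  if (!is.null(data)) {
    rhs <- if (length(fit$fixed_terms) == 0) "1" else fit$fixed_terms
    X <- model.matrix(reformulate(rhs, fit$response), data)
    y <- data[[fit$response]]
  }
  sds <- apply(X, 2, sd)
  sy <- sd(y)
  terms <- names(fit$coefficients)
  is_int <- terms == "(Intercept)"
  zero <- !is_int & sds[terms] == 0
  if (any(zero)) {
    stop("zero-variance predictor(s): ", paste(terms[zero], collapse = ", "),
         call. = FALSE)
  }
  std <- unname(fit$coefficients * sds[terms] / sy)
  std[is_int] <- NA_real_
  tibble(term = terms, estimate = unname(fit$coefficients),
         std_estimate = std)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-partition R-squared: the marginal statistic is the share of
#' total variance attributable to the fixed-effect linear predictor; the
#' conditional statistic adds the random-intercept variance. The
#' residual component enters as the stationary AR(1) marginal variance.
#'
#' @param fit A `sav_lmm` fit.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "sav_lmm"))
  var_fixed <- if (fit$n_obs > 1) var(fit$fitted) else 0
  denom <- var_fixed + fit$sigma_b2 + fit$sigma2
  c(r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + fit$sigma_b2) / denom)
}

#' Residual autocorrelation by time lag
#'
#' Pools within-group residual pairs separated by each time lag and
#' reports their correlation. Whitened (`type = "normalized"`) residuals
#' from a well-specified fit should show no remaining autocorrelation;
#' raw residuals from a fit without correlation structure recover the
#' AR(1) autocorrelation of the data.
#'
#' @param fit A `sav_lmm` fit.
#' @param max_lag Largest time lag to report (at least 1 and no more
#'   than the longest within-group time span).
#' @param type `"normalized"` (residuals whitened by the fitted
#'   per-group covariance) or `"raw"`.
#' @return Tibble with `lag`, `correlation`, `n_pairs`.
#' @export
residual_lag_correlation <- function(fit, max_lag = 5,
                                     type = c("normalized", "raw")) {
  stopifnot(inherits(fit, "sav_lmm"), max_lag >= 1)
  type <- match.arg(type)
  resid <- fit$y - fit$fitted
  idx <- split(seq_along(resid), fit$group_vec)
  span <- max(vapply(idx, function(i) diff(range(fit$time_vec[i])), numeric(1)))
  if (max_lag > span) {
    stop("max_lag (", max_lag, ") exceeds the longest within-group time span (",
         span, ")", call. = FALSE)
  }
  res_list <- lapply(idx, function(i) {
    r <- resid[i]
    if (type == "normalized") {
      t <- fit$time_vec[i]
      m <- length(i)
      R <- fit$phi^abs(outer(t, t, "-"))
      V <- fit$sigma2 * R + fit$sigma_b2
      r <- drop(forwardsolve(t(chol(V)), r))
    }
    list(r = r, t = fit$time_vec[i])
  })
  purrr::map_dfr(seq_len(max_lag), function(lag) {
    xs <- ys <- list()
    for (g in res_list) {
      d <- outer(g$t, g$t, "-")
      pair <- which(d == lag, arr.ind = TRUE)
      if (nrow(pair) > 0) {
        xs[[length(xs) + 1]] <- g$r[pair[, 2]]
        ys[[length(ys) + 1]] <- g$r[pair[, 1]]
      }
    }
    x <- unlist(xs); yv <- unlist(ys)
    tibble(lag = lag,
           correlation = if (length(x) > 2) cor(x, yv) else NA_real_,
           n_pairs = length(x))
  })
}
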