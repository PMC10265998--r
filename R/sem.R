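# Piecewise structural equation modeling: one mixed-model equation per
# endogenous node, d-separation claims tested by augmenting the child's
# model with the claimed-independent variable, and Fisher's C as the
# global goodness-of-fit statistic.

# Fixed-effect terms of the local equation for one endogenous node:
# its parents, plus (main effect + product) for each declared
# lag interaction with the previous-year cover variable.
equation_terms <- function(graph, node) {
  terms <- graph_parents(graph, node)
  lags <- graph$lag_interactions[[node]]
  if (!is.null(lags) && length(lags) > 0) {
    terms <- union(terms, graph$lag_variable)
    terms <- c(terms, paste(sort(lags), graph$lag_variable, sep = ":"))
  }
  terms
}

#' Test the independence claims of a basis set
#'
#' Each claim `indep` _||_ `response` | conditioning set is tested by
#' fitting the response's equation (its declared parents and lag
#' interactions) augmented with the conditioning set and the main
#' effect of the claimed-independent variable, using the graph's
#' grouping variable and AR(1) correlation structure. The recorded
#' p-value is the two-sided coefficient test of the independent
#' variable. p-values are floored at 1e-300 (with a warning) so
#' Fisher's C stays finite.
#'
#' @param claims Basis set as returned by [basis_set()].
#' @param data Analysis table containing every variable, the grouping
#'   column and the time column; zero-run filtering is assumed done.
#' @param graph The validated `causal_graph`.
#' @param time Name of the time column (default `"year"`).
#' @return `claims` with an added `p_value` column.
#' @export
test_claims <- function(claims, data, graph, time = "year") {
  graph <- validate_graph(graph)
  if (nrow(claims) == 0) {
    return(mutate(claims, p_value = numeric(0)))
  }
  p_value <- purrr::pmap_dbl(claims, function(indep, response, conditioning) {
    terms <- union(union(equation_terms(graph, response), conditioning), indep)
    fit <- tryCatch(
      fit_lmm(data, response, terms, group = graph$group, time = time),
      error = function(e) {
        stop("independence claim ", indep, " _||_ ", response,
             " failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    unname(fit$p_values[indep])
  })
  out <- mutate(claims, p_value = p_value)
  if (any(out$p_value < 1e-300)) {
    warning("claim p-value(s) floored at 1e-300 before logging")
    out$p_value <- pmax(out$p_value, 1e-300)
  }
  out
}

#' Fisher's C global goodness-of-fit statistic
#'
#' Combines the independence-claim p-values as
#' `C = -2 * sum(log(p_i))`, chi-square distributed with `2k` degrees
#' of freedom under correct specification; the global p-value is the
#' upper-tail probability. An empty claim list (saturated model) gives
#' `C = 0, df = 0, p = 1` by convention.
#'
#' @param p_values Numeric vector of claim p-values, each in (0, 1\].
#' @return Named list with `fisher_c`, `df`, `p_global`.
#' @examples
#' fishers_c(c(0.5, 0.5)) # C = -4 log 0.5, df = 4
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0) {
    return(list(fisher_c = 0, df = 0L, p_global = 1))
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("claim p-values must lie in (0, 1]; apply the numerical floor ",
         "upstream", call. = FALSE)
  }
  C <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(fisher_c = C, df = df,
       p_global = pchisq(C, df = df, lower.tail = FALSE))
}

#' Fit a piecewise structural equation model
#'
#' Fits one maximum-likelihood mixed model (site random intercept,
#' AR(1) residual correlation) per endogenous node of the causal graph,
#' attaches standardized coefficients and marginal/conditional
#' R-squared per equation, derives the d-separation basis set, tests
#' every claim, and evaluates Fisher's C.
#'
#' @param graph A `causal_graph`.
#' @param data Analysis table with one row per site-year holding every
#'   graph variable plus the grouping and time columns (zero-run
#'   filtered rows already removed).
#' @param time Name of the time column (default `"year"`).
#' @return Object of class `sav_sem`: `equations` (named list of
#'   `sav_lmm` fits), `paths` (tidy coefficient table), `claims`,
#'   `fisher_c`, `df`, `p_global`, `graph`.
#' @examples
#' \donttest{
#' cfg <- scenario_config("subestuary", seed = 1, n_sites = 10, n_years = 12)
#' sim <- generate_subestuary_scenario(cfg)
#' fit <- fit_sem(subestuary_graph(), sim$analysis)
#' glance(fit)
#' }
#' @export
fit_sem <- function(graph, data, time = "year") {
  graph <- validate_graph(graph)
  endo <- graph$topo_order[graph$roles[graph$topo_order] == "endogenous"]
  if (length(endo) == 0) {
    stop("graph has no endogenous node: nothing to fit", call. = FALSE)
  }
  equations <- list()
  for (node in endo) {
    fit <- tryCatch(
      fit_lmm(data, node, equation_terms(graph, node),
              group = graph$group, time = time),
      error = function(e) {
        stop("equation for '", node, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    equations[[node]] <- fit
  }
  paths <- purrr::imap_dfr(equations, function(fit, node) {
    mutate(tidy(fit), equation = node, .before = 1)
  })
  claims <- test_claims(basis_set(graph), data, graph, time = time)
  fc <- fishers_c(claims$p_value)
  structure(list(
    equations = equations, paths = paths, claims = claims,
    fisher_c = fc$fisher_c, df = fc$df, p_global = fc$p_global,
    graph = graph
  ), class = "sav_sem")
}

#' @export
print.sav_sem <- function(x, ...) {
  cat("Piecewise SEM:", length(x$equations), "equation(s),",
      nrow(x$claims), "independence claim(s)\n")
  cat(sprintf("  Fisher's C = %.3f, df = %d, P = %.3f\n",
              x$fisher_c, x$df, x$p_global))
  for (nm in names(x$equations)) {
    f <- x$equations[[nm]]
    cat(sprintf("  %s: R2m %.3f R2c %.3f\n", nm, f$r2_marginal,
                f$r2_conditional))
  }
  invisible(x)
}

#' Tidy path-coefficient table of a piecewise SEM
#'
#' @param x A `sav_sem` fit.
#' @param ... Unused.
#' @return Tibble with `equation`, `term`, `estimate`, `std_estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy sav_sem
#' @export
tidy.sav_sem <- function(x, ...) x$paths

#' One-row global-fit summary of a piecewise SEM
#'
#' @param x A `sav_sem` fit.
#' @param ... Unused.
#' @return Tibble with `fisher_c`, `df`, `p_global`, `n_equations`,
#'   `n_claims`, `nobs`.
#' @method glance sav_sem
#' @export
glance.sav_sem <- function(x, ...) {
  tibble(
    fisher_c = x$fisher_c, df = x$df, p_global = x$p_global,
    n_equations = length(x$equations), n_claims = nrow(x$claims),
    nobs = x$equations[[1]]$n_obs
  )
}

#' JSON-serializable summary of a piecewise SEM fit
#'
#' @param fit A `sav_sem` fit.
#' @return A list (global statistics, per-equation R-squared and
#'   variance components, claims) suitable for
#'   `jsonlite::write_json(..., auto_unbox = TRUE)`.
#' @export
sem_summary <- function(fit) {
  stopifnot(inherits(fit, "sav_sem"))
  list(
    fisher_c = fit$fisher_c, df = fit$df, p_global = fit$p_global,
    equations = lapply(fit$equations, function(f) {
      list(r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional,
           sigma_b2 = f$sigma_b2, sigma2 = f$sigma2, phi = f$phi,
           loglik = f$loglik, n_obs = f$n_obs, n_groups = f$n_groups)
    }),
    claims = lapply(seq_len(nrow(fit$claims)), function(i) {
      list(indep = fit$claims$indep[i], response = fit$claims$response[i],
           conditioning = fit$claims$conditioning[[i]],
           p_value = fit$claims$p_value[i])
    })
  )
}
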