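## Maximum-likelihood estimation. All free quantities are optimized on an
## unconstrained scale (log for mu, relative rates and alpha;
## additive-log-ratio for the root prior) with box bounds, using the PORT
## routines in stats::nlminb. One relative-rate parameter is pinned to 1
## whenever mu is estimated: after calibration only rate ratios are
## identifiable.

MU_BOUNDS <- c(1e-8, 1e4)
REL_BOUNDS <- c(1e-6, 1e6)
ALPHA_BOUNDS <- c(1e-3, 1e3)

alr_inv <- function(z) {
  e <- exp(c(z, 0))
  e / sum(e)
}

pack_bounds <- function(C, nf, est_pi, a, est_alpha) {
  lower <- c(rep(log(MU_BOUNDS[1]), C), rep(log(REL_BOUNDS[1]), nf),
             if (est_pi) rep(-30, a - 1L),
             if (est_alpha) log(ALPHA_BOUNDS[1]))
  upper <- c(rep(log(MU_BOUNDS[2]), C), rep(log(REL_BOUNDS[2]), nf),
             if (est_pi) rep(30, a - 1L),
             if (est_alpha) log(ALPHA_BOUNDS[2]))
  list(lower = lower, upper = upper)
}

unpack_theta <- function(theta, C, nf, est_pi, a, est_alpha, ncat) {
  mu <- exp(theta[seq_len(C)])
  off <- C
  rel <- c(1, exp(theta[off + seq_len(nf)]))
  off <- off + nf
  pi <- if (est_pi) {
    p <- alr_inv(theta[off + seq_len(a - 1L)])
    off <- off + a - 1L
    p
  } else uniform_prior(a)
  gamma <- if (est_alpha) discrete_gamma(exp(theta[off + 1L]), ncat)
  list(mu = mu, rel = rel, pi = pi, gamma = gamma)
}

resolve_options <- function(model, reversible, rootprobability) {
  model <- toupper(model)
  if (model == "GTR") {
    model <- "SYM"; reversible <- TRUE; rootprobability <- TRUE
  }
  list(model = model, reversible = reversible,
       rootprobability = rootprobability)
}

#' Fit an evolutionary-rate model by maximum likelihood
#'
#' Estimates the rate `mu` (one per branch category of the tree), the free
#' relative rates of the transition template, optionally the root prior
#' `pi` and the Gamma shape `alpha`, by maximizing the pruning likelihood
#' of the character matrix on the tree. `model = "GTR"` expands to
#' `SYM + reversible + rootprobability`. Irreversible analyses (asymmetric
#' templates, or an estimated prior without forced reversibility) on an
#' unrooted tree trigger midpoint rooting first.
#'
#' @param tree a `rate_tree`.
#' @param m a `char_matrix` (taxa in rows).
#' @param model model name (see [make_model_spec()]) or `"GTR"`.
#' @param nstates optional upward override of the state count.
#' @param rootprobability estimate the prior root probabilities?
#' @param reversible force reversibility (symmetric templates only).
#' @param zerocorrection condition on site patterns being observable?
#' @param alpha estimate a discrete-Gamma shape for among-site rate
#'   variation?
#' @param ncat number of Gamma categories (default 4).
#' @param simplify collapse the matrix to presence/absence first?
#' @param custom_template template matrix for `model = "CUSTOM"`.
#' @param n_restarts extra jittered starts (default 0: deterministic
#'   single start at mu = 1, rates 1, uniform pi, alpha = 1).
#' @param seed seed for the jittered restarts.
#' @param control passed to [stats::nlminb()] (merged over defaults).
#' @return a `fit_result`: estimates, log-likelihood, parameter count and
#'   convergence diagnostics.
#' @export
fit <- function(tree, m, model = "ER", nstates = NULL,
                rootprobability = FALSE, reversible = FALSE,
                zerocorrection = FALSE, alpha = FALSE, ncat = 4L,
                simplify = FALSE, custom_template = NULL,
                n_restarts = 0L, seed = NULL, control = list()) {
  stopifnot(inherits(m, "char_matrix"))
  opts <- resolve_options(model, reversible, rootprobability)
  if (simplify) m <- simplify_to_binary(m)
  a <- max(n_states(m), nstates %||% 0L)
  spec <- make_model_spec(opts$model, a, custom_template)
  if (opts$reversible && !spec$symmetric)
    stop("reversible = TRUE requires a symmetric template", call. = FALSE)
  irreversible <- !spec$symmetric ||
    (opts$rootprobability && !opts$reversible)
  rooted_note <- FALSE
  if (!is_rooted_tree(tree) && irreversible) {
    message("unrooted tree with an irreversible configuration: ",
            "midpoint rooting applied")
    tree <- midpoint_root(tree)
    rooted_note <- TRUE
  }
  ps <- compress_patterns(m)
  C <- n_branch_categories(tree)
  nf <- max(spec$n_params - 1L, 0L)
  est_pi <- opts$rootprobability
  est_alpha <- alpha
  bounds <- pack_bounds(C, nf, est_pi, a, est_alpha)
  npar <- length(bounds$lower)

  objective <- function(theta) {
    par <- unpack_theta(theta, C, nf, est_pi, a, est_alpha, ncat)
    cfg <- lik_config(spec, mu = par$mu, rel_rates = par$rel, pi = par$pi,
                      gamma = par$gamma, reversible = opts$reversible,
                      zerocorrection = zerocorrection)
    ll <- suppressWarnings(tryCatch(total_loglik(tree, ps, cfg),
                                    error = function(e) -Inf))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start0 <- rep(0, npar)
  ctl <- modifyList(list(rel.tol = 1e-9, iter.max = 1000L,
                         eval.max = 4000L), control)
  starts <- list(start0)
  if (n_restarts > 0L) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts))
      starts[[r + 1L]] <- start0 + runif(npar, -1, 1)
  }
  best <- NULL
  for (s in starts) {
    res <- nlminb(s, objective, lower = bounds$lower,
                  upper = bounds$upper, control = ctl)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  par <- unpack_theta(best$par, C, nf, est_pi, a, est_alpha, ncat)
  at_bound <- any(abs(best$par - bounds$lower) < 1e-9) ||
    any(abs(best$par - bounds$upper) < 1e-9)
  structure(list(
    mu = par$mu,
    rel_rates = par$rel,
    pi_hat = if (est_pi) par$pi else NULL,
    alpha_hat = if (est_alpha) par$gamma$alpha else NULL,
    loglik = -best$objective,
    n_params = npar,
    converged = best$convergence == 0L,
    n_iterations = best$iterations,
    message = best$message,
    at_bound = at_bound,
    midpoint_rooted = rooted_note,
    model = spec$name,
    a = a,
    options = list(rootprobability = est_pi, reversible = opts$reversible,
                   zerocorrection = zerocorrection, alpha = est_alpha,
                   ncat = ncat, simplify = simplify),
    n_sites = sum(ps$weights)
  ), class = "fit_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.fit_result <- function(x, ...) {
  cat("Maximum-likelihood fit:", x$model, "on", x$a, "states\n")
  cat("  mu:", paste(format(x$mu, digits = 4), collapse = " "), "\n")
  if (length(x$rel_rates) > 1)
    cat("  relative rates:",
        paste(format(x$rel_rates, digits = 4), collapse = " "), "\n")
  if (!is.null(x$pi_hat))
    cat("  root prior:",
        paste(format(x$pi_hat, digits = 4), collapse = " "), "\n")
  if (!is.null(x$alpha_hat))
    cat("  gamma shape alpha:", format(x$alpha_hat, digits = 4), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " (", x$n_params, "free parameter(s),",
      if (x$converged) "converged" else "NOT converged",
      if (x$at_bound) ", at bound" else "", ")\n")
  invisible(x)
}

#' Per-site rate estimation
#'
#' Fits `mu` independently for every site (column) under a shared model
#' shape. Identical columns share one fit. Sites whose estimate hits the
#' optimizer bounds are flagged (an invariant all-zero site without
#' zero-correction drives `mu` to the lower bound).
#'
#' @inheritParams fit
#' @param plot_file optional path; writes a simple per-site rate plot
#'   (PNG if the path ends in .png, otherwise PDF).
#' @return a `fit_result` whose `per_site_mu` is a data.frame with one row
#'   per site: `site`, `mu`, `loglik`, `converged`, `at_bound`.
#' @export
fit_per_site <- function(tree, m, model = "ER", nstates = NULL,
                         rootprobability = FALSE, reversible = FALSE,
                         zerocorrection = FALSE, alpha = FALSE, ncat = 4L,
                         simplify = FALSE, custom_template = NULL,
                         control = list(), plot_file = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  if (simplify) m <- simplify_to_binary(m)
  a <- max(n_states(m), nstates %||% 0L)
  ps <- compress_patterns(m)
  fits <- lapply(seq_len(ncol(ps$patterns)), function(j) {
    col <- char_matrix(ps$patterns[, j, drop = FALSE], nstates = a)
    fit(tree, col, model = model, nstates = a,
        rootprobability = rootprobability, reversible = reversible,
        zerocorrection = zerocorrection, alpha = alpha, ncat = ncat,
        simplify = FALSE, custom_template = custom_template,
        control = control)
  })
  idx <- ps$site_index
  tab <- data.frame(
    site = seq_along(idx),
    mu = vapply(fits, function(f) f$mu[1], numeric(1))[idx],
    loglik = vapply(fits, function(f) f$loglik, numeric(1))[idx],
    converged = vapply(fits, function(f) f$converged, logical(1))[idx],
    at_bound = vapply(fits, function(f) f$at_bound, logical(1))[idx])
  out <- fits[[1L]]
  out$per_site_mu <- tab
  out$mu <- tab$mu
  out$loglik <- sum(vapply(fits, function(f) f$loglik, numeric(1)) *
                      tabulate(idx, length(fits)))
  if (!is.null(plot_file)) plot_site_rates(tab, plot_file)
  out
}

#' Plot per-site rate estimates
#'
#' @param tab data.frame with columns `site` and `mu` (as produced by
#'   [fit_per_site()]).
#' @param file output path (`.png` or `.pdf`).
#' @export
plot_site_rates <- function(tab, file) {
  if (grepl("\\.png$", file)) grDevices::png(file, 800, 500)
  else grDevices::pdf(file, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(tab$site, tab$mu, type = "h", lwd = 3,
                 xlab = "site", ylab = expression(hat(mu)),
                 main = "Per-site rate estimates")
  graphics::points(tab$site, tab$mu, pch = 19)
  invisible(file)
}

#' Likelihood-ratio test of nested fits
#'
#' `2 (lnL1 - lnL0)` is referred to a chi-square distribution with `df`
#' degrees of freedom (the difference in free parameter counts).
#'
#' @param loglik0 log-likelihood of the null (nested) fit, or a
#'   `fit_result`.
#' @param loglik1 log-likelihood of the alternative fit, or a
#'   `fit_result`.
#' @param df degrees of freedom (>= 1); defaults to the difference of
#'   `n_params` when fit results are given.
#' @return an `lrt_result`: `two_delta`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(loglik0, loglik1, df = NULL) {
  n0 <- n1 <- NULL
  if (inherits(loglik0, "fit_result")) {
    n0 <- loglik0$n_params; loglik0 <- loglik0$loglik
  }
  if (inherits(loglik1, "fit_result")) {
    n1 <- loglik1$n_params; loglik1 <- loglik1$loglik
  }
  if (is.null(df)) {
    if (is.null(n0) || is.null(n1))
      stop("df must be given when raw log-likelihoods are supplied",
           call. = FALSE)
    df <- n1 - n0
  }
  if (df < 1L) stop("df must be >= 1 (models must be nested with the ",
                    "alternative richer)", call. = FALSE)
  two_delta <- 2 * (loglik1 - loglik0)
  tol <- 1e-6 * max(1, abs(loglik1))
  if (two_delta < -tol)
    stop("negative 2*deltaLnL (", format(two_delta),
         "): optimization failure in the richer model", call. = FALSE)
  two_delta <- max(two_delta, 0)
  structure(list(two_delta = two_delta, df = as.integer(df),
                 p_value = pchisq(two_delta, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Likelihood-ratio test: 2*deltaLnL =", format(x$two_delta),
      "df =", x$df, "p =", format.pval(x$p_value), "\n")
  invisible(x)
}
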