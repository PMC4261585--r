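## Phylogenetic likelihood of discrete characters: Felsenstein pruning with
## per-node rescaling, a discrete-Gamma mixture over site rate multipliers,
## branch-category rate multipliers, root-prior weighting, and the
## conditional-likelihood correction for unobservable (all-absent) patterns.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## One-time spectral factorization of a generator; returns f(nu) = exp(Q nu).
## Reversible generators take the symmetrized (numerically stable) route;
## general ones use eigen() with a Matrix::expm fallback when the
## eigenbasis is ill-conditioned or complex.
expm_factory <- function(q, pi = NULL) {
  a <- nrow(q)
  # exp(Q nu) rows sum to exactly 1; clip round-off and renormalize
  clean <- function(p) {
    p[p < 0] <- 0; p[p > 1] <- 1
    rs <- rowSums(p)
    rs[rs <= 0] <- 1
    p / rs
  }
  if (!is.null(pi) && all(pi > 0) &&
      max(abs(pi * q - t(pi * t(q)))) < 1e-10 * max(1, max(abs(q)))) {
    d <- sqrt(pi)
    s <- (d * q) %*% diag(1 / d, a)      # D Q D^-1, symmetric
    es <- eigen((s + t(s)) / 2, symmetric = TRUE)
    left <- (1 / d) * es$vectors         # D^-1 V
    right <- t(es$vectors) %*% diag(d, a)
    vals <- pmin(es$values, 0)           # generator spectrum is <= 0
    return(function(nu) clean(left %*% (exp(vals * nu) * right)))
  }
  ev <- tryCatch(eigen(q), error = function(e) NULL)
  ok <- !is.null(ev) && max(abs(Im(ev$values))) < 1e-8
  if (ok) {
    vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    ok <- !is.null(vinv) && max(Mod(vinv)) < 1e8
  }
  if (ok) {
    v <- Re(ev$vectors); vinv <- Re(vinv)
    vals <- pmin(Re(ev$values), 0)
    function(nu) clean(v %*% (exp(vals * nu) * vinv))
  } else {
    function(nu) clean(as.matrix(Matrix::expm(q * nu)))
  }
}

#' Transition probabilities over an evolutionary distance
#'
#' `P(nu) = exp(Q nu)` for a generator `Q` and nonnegative distance `nu`
#' (branch length x branch-category rate x Gamma rate multiplier).
#'
#' @param q generator matrix (ideally calibrated; see [calibrate_q()]).
#' @param nu nonnegative finite evolutionary distance.
#' @param pi optional stationary/root prior enabling the stable symmetric
#'   factorization for reversible `q`.
#' @return stochastic matrix of the same dimension as `q`.
#' @export
transition_probs <- function(q, nu, pi = NULL) {
  if (!is.finite(nu) || nu < 0)
    stop("nu must be nonnegative and finite", call. = FALSE)
  expm_factory(q, pi)(nu)
}

#' Bundle a likelihood configuration
#'
#' @param spec a `model_spec`.
#' @param mu positive rate per branch category (length = number of branch
#'   categories of the tree it is used with).
#' @param rel_rates relative rates for the template (default all 1).
#' @param pi root prior (default uniform); also the calibration weights.
#' @param gamma optional `gamma_rates` for among-site rate variation.
#' @param reversible force reversibility (destination-probability
#'   weighting).
#' @param zerocorrection condition the likelihood on patterns being
#'   observable (state 0 is the absence state).
#' @return a `lik_config`.
#' @export
lik_config <- function(spec, mu = 1, rel_rates = rep(1, spec$n_params),
                       pi = uniform_prior(spec$a), gamma = NULL,
                       reversible = FALSE, zerocorrection = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mu must be positive", call. = FALSE)
  pi <- check_prior(pi, spec$a)
  if (!is.null(gamma) && !inherits(gamma, "gamma_rates"))
    stop("gamma must be a gamma_rates object", call. = FALSE)
  structure(list(spec = spec, mu = mu, rel_rates = rel_rates, pi = pi,
                 gamma = gamma, reversible = reversible,
                 zerocorrection = zerocorrection),
            class = "lik_config")
}

config_q <- function(config) {
  q <- assemble_q(config$spec, config$rel_rates, config$pi,
                  config$reversible)
  calibrate_q(q, config$pi)
}

row_max <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx
}

## Postorder edge traversal of a tree, computed once per likelihood call:
## edge matrix in postorder plus the permutation back to the tree's own
## edge order (categories and transition matrices are indexed by it).
postorder_edges <- function(tree) {
  post <- reorder(tree, "postorder")
  key <- function(e) e[, 1] * (max(e) + 1L) + e[, 2]
  list(edge = post$edge,
       perm = match(key(post$edge), key(tree$edge)))
}

## Pruning over a taxa x npattern state matrix (entries 0..a-1) for one set
## of per-edge transition matrices (in the tree's edge order). Returns
## log-likelihood per pattern.
prune_loglik <- function(tree, pat, plist, pi, po = postorder_edges(tree)) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  a <- length(pi)
  npat <- ncol(pat)
  partial <- vector("list", nn)
  logscale <- numeric(npat)
  for (i in seq_len(ntip))
    partial[[i]] <- matrix(as.numeric(seq_len(a) - 1L ==
                                        rep(pat[i, ], each = a)),
                           npat, a, byrow = TRUE)
  edges <- po$edge
  for (k in seq_len(nrow(edges))) {
    w <- edges[k, 1]; v <- edges[k, 2]
    contrib <- partial[[v]] %*% t(plist[[po$perm[k]]])
    if (is.null(partial[[w]])) partial[[w]] <- contrib
    else partial[[w]] <- partial[[w]] * contrib
    # per-edge rescaling keeps partials in range on deep trees
    mx <- pmax(row_max(partial[[w]]), .Machine$double.xmin)
    partial[[w]] <- partial[[w]] / mx
    logscale <- logscale + log(mx)
  }
  lik <- as.vector(partial[[root_node(tree)]] %*% pi)
  ifelse(lik > 0, log(lik) + logscale, -Inf)
}

## Per-edge transition matrices for one Gamma-category rate multiplier.
edge_pmats <- function(tree, q, mu, rate, pi) {
  f <- expm_factory(q, pi)
  cats <- tree$edge.category
  if (is.null(cats)) cats <- rep(1L, nrow(tree$edge))
  if (max(cats) > length(mu))
    stop("tree has ", max(cats), " branch categories but only ",
         length(mu), " mu value(s) supplied", call. = FALSE)
  lapply(seq_len(nrow(tree$edge)), function(e)
    f(tree$edge.length[e] * mu[cats[e]] * rate))
}

align_patterns <- function(tree, pat, taxa) {
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx))
    stop("taxa mismatch between tree and matrix: missing ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  pat[idx, , drop = FALSE]
}

## Mixed (over Gamma categories) per-pattern log-likelihood plus the mixed
## log-likelihood of the unobservable all-zero pattern.
mixed_pattern_logliks <- function(tree, pat, config, with_unobs = TRUE) {
  q <- config_q(config)
  rates <- if (is.null(config$gamma)) 1 else config$gamma$rates
  K <- length(rates)
  npat <- ncol(pat)
  ntip <- nrow(pat)
  per_cat <- matrix(NA_real_, npat, K)
  unobs_cat <- numeric(K)
  zero_pat <- matrix(0L, ntip, 1)
  po <- postorder_edges(tree)
  for (k in seq_len(K)) {
    plist <- edge_pmats(tree, q, config$mu, rates[k], config$pi)
    per_cat[, k] <- prune_loglik(tree, pat, plist, config$pi, po)
    if (with_unobs)
      unobs_cat[k] <- prune_loglik(tree, zero_pat, plist, config$pi, po)
  }
  site_log <- apply(per_cat, 1, log_sum_exp) - log(K)
  log_unobs <- if (with_unobs) log_sum_exp(unobs_cat) - log(K) else NA_real_
  list(site_log = site_log, log_unobs = log_unobs)
}

#' Log-likelihood of a single site pattern at one Gamma rate
#'
#' Post-order pruning: leaf partials are state indicators, internal partials
#' combine children through the branch transition matrices, and the root is
#' weighted by the prior. No Gamma mixing or zero-correction is applied
#' here; see [total_loglik()].
#'
#' @param tree a rooted `rate_tree`.
#' @param pattern one state (0..a-1) per leaf, named by leaf label or given
#'   in the tree's tip order.
#' @param config a `lik_config`.
#' @param gamma_rate rate multiplier applied to every branch (default 1).
#' @return log-likelihood (`-Inf` for an impossible pattern).
#' @export
pattern_loglik <- function(tree, pattern, config, gamma_rate = 1) {
  if (!is.null(names(pattern)))
    pattern <- align_patterns(tree, matrix(pattern, ncol = 1),
                              names(pattern))
  pat <- matrix(as.integer(pattern), ncol = 1)
  if (nrow(pat) != length(tree$tip.label))
    stop("pattern length must equal the number of leaves", call. = FALSE)
  q <- config_q(config)
  plist <- edge_pmats(tree, q, config$mu, gamma_rate, config$pi)
  prune_loglik(tree, pat, plist, config$pi)
}

#' Log-likelihood of the unobservable (all-absent) pattern
#'
#' State 0 is the absence state; the unobservable pattern has every leaf in
#' state 0. This is the `L_-` of the zero-correction.
#'
#' @inheritParams pattern_loglik
#' @return log-likelihood of the all-zero pattern.
#' @export
unobservable_loglik <- function(tree, config, gamma_rate = 1) {
  pattern_loglik(tree, rep(0L, length(tree$tip.label)), config, gamma_rate)
}

#' Total log-likelihood of a character matrix on a tree
#'
#' Per site, the likelihood is averaged over the Gamma rate categories
#' (equal weights); with `zerocorrection` each site likelihood is divided
#' by `1 - L_-`, the probability of observability, where `L_-` is itself
#' the Gamma-mixed likelihood of the all-zero pattern. The total is the
#' pattern-weighted sum of log site likelihoods.
#'
#' @param tree a rooted `rate_tree`.
#' @param patterns a `pattern_set` (see [compress_patterns()]) or a
#'   `char_matrix`.
#' @param config a `lik_config`.
#' @return total log-likelihood (scalar; `-Inf`, with a warning naming the
#'   offending pattern, if some site has zero likelihood).
#' @export
total_loglik <- function(tree, patterns, config) {
  if (inherits(patterns, "char_matrix")) patterns <- compress_patterns(patterns)
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$nstates > config$spec$a)
    stop("matrix has ", patterns$nstates, " states but the model allows ",
         config$spec$a, call. = FALSE)
  pat <- align_patterns(tree, patterns$patterns, patterns$taxa)
  res <- mixed_pattern_logliks(tree, pat, config,
                               with_unobs = config$zerocorrection)
  site_log <- res$site_log
  if (config$zerocorrection) {
    p_unobs <- exp(res$log_unobs)
    if (p_unobs >= 1)
      stop("zero-correction failed: probability of the unobservable ",
           "pattern is ", format(p_unobs), " >= 1", call. = FALSE)
    site_log <- site_log - log1p(-p_unobs)
  }
  if (any(!is.finite(site_log))) {
    bad <- which(!is.finite(site_log))[1L]
    warning("site pattern (", paste(pat[, bad], collapse = ","),
            ") has zero likelihood; returning -Inf")
    return(-Inf)
  }
  sum(patterns$weights * site_log)
}
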