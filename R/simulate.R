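## Forward simulation of discrete characters on a tree: per site, draw a
## Gamma rate category, draw a root state from the prior, then walk the
## tree sampling each child state from the row of exp(Q * t * mu_cat * r)
## indexed by the parent state. Exact for this use; no event-level
## (Gillespie) simulation is needed because only tip states matter.

#' Simulate a character matrix on a tree
#'
#' @param tree a `rate_tree` (rooted or not; a basal polytomy is treated
#'   as the root).
#' @param spec a `model_spec`.
#' @param mu positive rate per branch category.
#' @param rel_rates relative rates for the template.
#' @param pi root prior (also the calibration weights).
#' @param gamma optional `gamma_rates` for among-site rate variation.
#' @param reversible force reversibility in the generator.
#' @param n_sites number of sites to simulate.
#' @param seed optional RNG seed; fixes the whole output stream.
#' @param condition_on_observable rejection-sample each site until the
#'   pattern is not all-zero (the distribution targeted by the
#'   zero-correction). Capped at 1e6 rejections per site.
#' @return a `char_matrix`, taxa in rows in the tree's tip order.
#' @export
simulate_matrix <- function(tree, spec, mu = 1,
                            rel_rates = rep(1, spec$n_params),
                            pi = uniform_prior(spec$a), gamma = NULL,
                            reversible = FALSE, n_sites = 100L,
                            seed = NULL, condition_on_observable = FALSE) {
  stopifnot(inherits(spec, "model_spec"), n_sites >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pi <- check_prior(pi, spec$a)
  q <- calibrate_q(assemble_q(spec, rel_rates, pi, reversible), pi)
  rates <- if (is.null(gamma)) 1 else gamma$rates
  f <- expm_factory(q, pi)
  cats <- tree$edge.category
  if (is.null(cats)) cats <- rep(1L, nrow(tree$edge))
  if (max(cats) > length(mu))
    stop("tree has ", max(cats), " branch categories but only ",
         length(mu), " mu value(s)", call. = FALSE)
  a <- spec$a
  ntip <- length(tree$tip.label)
  pre <- reorder(tree, "postorder")
  perm <- match(apply(pre$edge, 1, paste, collapse = "-"),
                apply(tree$edge, 1, paste, collapse = "-"))
  cats_pre <- cats[perm]
  edge_order <- rev(seq_len(nrow(pre$edge)))   # preorder: parents first
  # per (gamma category, edge) transition matrices, rows renormalized
  pmats <- lapply(seq_along(rates), function(k)
    lapply(seq_len(nrow(pre$edge)), function(e) {
      p <- f(pre$edge.length[e] * mu[cats_pre[e]] * rates[k])
      p / rowSums(p)
    }))
  draw_site <- function() {
    k <- if (length(rates) > 1L) sample.int(length(rates), 1L) else 1L
    state <- integer(ntip + tree$Nnode)
    state[root_node(tree)] <- sample.int(a, 1L, prob = pi)
    for (e in edge_order) {
      par <- pre$edge[e, 1]; child <- pre$edge[e, 2]
      state[child] <- sample.int(a, 1L, prob = pmats[[k]][[e]][state[par], ])
    }
    state[seq_len(ntip)] - 1L
  }
  out <- matrix(NA_integer_, ntip, n_sites)
  for (s in seq_len(n_sites)) {
    tries <- 0L
    repeat {
      col <- draw_site()
      tries <- tries + 1L
      if (!condition_on_observable || any(col != 0L)) break
      if (tries >= 1e6L)
        stop("rejection cap reached: observable patterns are vanishingly ",
             "rare under these parameters", call. = FALSE)
    }
    out[, s] <- col
  }
  rownames(out) <- tree$tip.label
  char_matrix(out, nstates = a)
}
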