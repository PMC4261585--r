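# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: brute-force enumeration over ancestral states with
# Matrix::expm for transition kernels, quadrature for the discrete-Gamma
# category means.

# deterministic random rooted binary tree with uniform branch lengths
random_tree <- function(n, seed, min_len = 0.05, max_len = 0.6) {
  set.seed(seed)
  phy <- ape::rtree(n, br = function(k) runif(k, min_len, max_len))
  parse_newick(write_newick(as_rate_tree(phy)))
}

# Brute-force likelihood of one pattern: sum over all ancestral-state
# assignments, transition kernels from Matrix::expm (independent of the
# package's spectral path). `nus` are the per-edge distances in the tree's
# own edge order.
enum_pattern_lik <- function(tree, pattern, q, nus, pi) {
  a <- length(pi)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  P <- lapply(nus, function(nu) as.matrix(Matrix::expm(q * nu)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(a)), nint)))
  total <- 0
  root <- ntip + 1L
  for (g in seq_len(nrow(grid))) {
    st <- c(pattern + 1L, grid[g, ])
    prob <- pi[st[root]]
    for (e in seq_len(nrow(tree$edge)))
      prob <- prob * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    total <- total + prob
  }
  total
}

# Enumeration oracle wired to a lik_config (single gamma rate).
enum_loglik <- function(tree, pattern, config, gamma_rate = 1) {
  q <- calibrate_q(
    assemble_q(config$spec, config$rel_rates, config$pi, config$reversible),
    config$pi)
  cats <- tree$edge.category
  if (is.null(cats)) cats <- rep(1L, nrow(tree$edge))
  nus <- tree$edge.length * config$mu[cats] * gamma_rate
  log(enum_pattern_lik(tree, pattern, q, nus, config$pi))
}

# all a^ntip leaf patterns as a matrix (one column per pattern)
all_patterns <- function(ntip, a) {
  g <- as.matrix(expand.grid(rep(list(0:(a - 1L)), ntip)))
  t(unname(g))
}

# quadrature oracle for discrete-Gamma conditional category means
gamma_rates_oracle <- function(alpha, K) {
  bounds <- qgamma(seq(0, 1, length.out = K + 1L),
                   shape = alpha, rate = alpha)
  vapply(seq_len(K), function(i) {
    K * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                  bounds[i], bounds[i + 1L],
                  rel.tol = 1e-12)$value
  }, numeric(1))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
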