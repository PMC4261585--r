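## Transition-rate model machinery.
##
## A model template is an a x a integer matrix over the off-diagonal cells:
## entry k > 0 ties the cell to relative-rate parameter k, 0 is a structural
## zero. Presets:
##   ER     all off-diagonal entries equal                (1 parameter)
##   SYM    q_ij = q_ji, each unordered pair free         (a(a-1)/2)
##   ARD    every off-diagonal entry free                 (a(a-1))
##   BDER   birth-death ladder, all neighbour rates equal (1)
##   BDSYM  ladder, q_{i,i+1} = q_{i+1,i} per rung        (a-1)
##   BDISYM ladder, the 0<->1 (innovation/loss) pair has its own rate,
##          all other rungs share one                     (2, needs a >= 3)
##   BDARD  ladder, every directed neighbour rate free    (2(a-1))
## GTR is not a template: it is SYM + reversible + estimated root prior.

model_names <- c("ER", "SYM", "ARD", "BDER", "BDSYM", "BDISYM", "BDARD",
                 "CUSTOM")

build_template <- function(name, a) {
  tpl <- matrix(0L, a, a)
  off <- which(row(tpl) != col(tpl))
  switch(name,
    ER = { tpl[off] <- 1L },
    SYM = {
      k <- 0L
      for (i in seq_len(a - 1L)) for (j in (i + 1L):a) {
        k <- k + 1L; tpl[i, j] <- k; tpl[j, i] <- k
      }
    },
    ARD = {
      k <- 0L
      for (i in seq_len(a)) for (j in seq_len(a)) if (i != j) {
        k <- k + 1L; tpl[i, j] <- k
      }
    },
    BDER = for (i in seq_len(a - 1L)) tpl[i, i + 1L] <- tpl[i + 1L, i] <- 1L,
    BDSYM = for (i in seq_len(a - 1L)) tpl[i, i + 1L] <- tpl[i + 1L, i] <- i,
    BDISYM = {
      tpl[1L, 2L] <- tpl[2L, 1L] <- 1L
      for (i in 2L:(a - 1L)) tpl[i, i + 1L] <- tpl[i + 1L, i] <- 2L
    },
    BDARD = for (i in seq_len(a - 1L)) {
      tpl[i, i + 1L] <- i                # births n -> n+1
      tpl[i + 1L, i] <- (a - 1L) + i     # deaths n+1 -> n
    })
  tpl
}

#' Create a transition-model specification
#'
#' @param name one of `"ER"`, `"SYM"`, `"ARD"`, `"BDER"`, `"BDSYM"`,
#'   `"BDISYM"`, `"BDARD"`, `"CUSTOM"`.
#' @param a number of character states (>= 2; BDISYM needs >= 3).
#' @param custom_template for `"CUSTOM"`: an `a x a` integer matrix tying
#'   off-diagonal cells to shared parameter indices, 0 for a structural
#'   zero. Indices need not be contiguous; they are relabelled.
#' @return a `model_spec`: list with `name`, `a`, `template`, `n_params`,
#'   `symmetric`, `neighbor_only`.
#' @export
#' @examples
#' make_model_spec("BDARD", a = 3)$n_params  # 4
make_model_spec <- function(name, a, custom_template = NULL) {
  name <- match.arg(toupper(name), model_names)
  a <- as.integer(a)
  if (a < 2L) stop("need at least 2 states (a >= 2)", call. = FALSE)
  if (name == "BDISYM" && a < 3L)
    stop("BDISYM is undefined for a = 2 (no entries besides the 0<->1 ",
         "pair); use BDSYM", call. = FALSE)
  if (name == "CUSTOM") {
    tpl <- custom_template
    if (is.null(tpl)) stop("CUSTOM needs a template", call. = FALSE)
    tpl <- as.matrix(tpl)
    if (!all(dim(tpl) == c(a, a)))
      stop("custom template must be ", a, " x ", a, call. = FALSE)
    if (any(tpl != round(tpl)) || any(tpl < 0))
      stop("custom template entries must be nonnegative integers",
           call. = FALSE)
    storage.mode(tpl) <- "integer"
    diag(tpl) <- 0L
    used <- sort(unique(tpl[tpl > 0L]))
    if (length(used) == 0L)
      stop("custom template has no free entries", call. = FALSE)
    tpl[tpl > 0L] <- match(tpl[tpl > 0L], used)
  } else {
    tpl <- build_template(name, a)
  }
  structure(list(name = name, a = a, template = tpl,
                 n_params = max(tpl),
                 symmetric = identical(tpl, t(tpl)),
                 neighbor_only = all(tpl[abs(row(tpl) - col(tpl)) > 1L] == 0L)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$name, "on", x$a, "states,", x$n_params,
      "relative-rate parameter(s)",
      if (x$symmetric) "(symmetric)" else "(irreversible)", "\n")
  invisible(x)
}

#' Uniform root prior
#' @param a number of states.
#' @return probability vector of length `a`.
#' @export
uniform_prior <- function(a) rep(1 / a, a)

check_prior <- function(pi, a) {
  if (length(pi) != a || any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("root prior must be ", a, " nonnegative probabilities summing ",
         "to 1", call. = FALSE)
  pi
}

#' Assemble an instantaneous rate matrix from a model specification
#'
#' Off-diagonal `q_ij` is the relative rate tied to that cell; with
#' `reversible = TRUE` each entry is additionally multiplied by the
#' destination-state root probability `pi_j` (the GTR construction), which
#' enforces detailed balance `pi_i q_ij = pi_j q_ji` for symmetric
#' templates. The result is a proper generator (rows sum to zero) but is
#' *not* yet calibrated; see [calibrate_q()].
#'
#' @param spec a `model_spec`.
#' @param rel_rates positive relative rates, length `spec$n_params`.
#' @param pi root prior (used only when `reversible = TRUE`).
#' @param reversible force reversibility by destination-probability
#'   weighting; requires a symmetric template.
#' @return an `a x a` generator matrix.
#' @export
assemble_q <- function(spec, rel_rates = rep(1, spec$n_params),
                       pi = uniform_prior(spec$a), reversible = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(rel_rates) != spec$n_params)
    stop("need ", spec$n_params, " relative rate(s), got ",
         length(rel_rates), call. = FALSE)
  if (any(!is.finite(rel_rates)) || any(rel_rates <= 0))
    stop("relative rates must be positive and finite", call. = FALSE)
  if (reversible && !spec$symmetric)
    stop("forced reversibility requires a symmetric template (ER, SYM, ",
         "BDER, BDSYM, BDISYM); for SYM it yields the GTR model",
         call. = FALSE)
  pi <- check_prior(pi, spec$a)
  q <- matrix(0, spec$a, spec$a)
  nz <- spec$template > 0L
  q[nz] <- rel_rates[spec$template[nz]]
  if (reversible) q <- sweep(q, 2L, pi, "*")
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  if (spec$name == "CUSTOM") {
    # structural zeros may make states unreachable from the root prior
    reach <- pi > 0
    repeat {
      new <- reach | (colSums(q[reach, , drop = FALSE] > 0) > 0)
      if (identical(new, reach)) break
      reach <- new
    }
    if (!all(reach))
      warning("custom template leaves state(s) ",
              paste(which(!reach) - 1L, collapse = ", "),
              " unreachable from states with positive root probability")
  }
  q
}

#' Calibrate a rate matrix
#'
#' Rescales the generator so that the expected number of transition events
#' per site per unit time under `pi` equals one: `-sum(pi_i * q_ii) = 1`.
#' After calibration the rate parameter `mu` multiplying branch lengths is
#' directly interpretable as the average number of transitions per site per
#' evolutionary time unit.
#'
#' @param q generator matrix.
#' @param pi probability vector weighting the states.
#' @return the calibrated generator.
#' @export
calibrate_q <- function(q, pi = uniform_prior(nrow(q))) {
  pi <- check_prior(pi, nrow(q))
  rate <- -sum(pi * diag(q))
  if (!is.finite(rate) || rate <= 1e-14)
    stop("calibration failed: expected transition rate under pi is zero ",
         "(pi mass only on absorbing states?)", call. = FALSE)
  q / rate
}

#' Discretize a mean-one Gamma distribution into equal-probability
#' rate categories
#'
#' The Gamma(shape = `alpha`, mean 1) distribution of among-site rate
#' multipliers is approximated by `K` categories of probability `1/K`, each
#' represented by its conditional mean, so the category rates average
#' exactly one and calibration is preserved.
#'
#' @param alpha shape parameter (> 0); small `alpha` = strong rate
#'   variation, large `alpha` approaches a single homogeneous rate.
#' @param K number of categories (>= 1).
#' @return a `gamma_rates`: list with `alpha`, `K`, and the nondecreasing
#'   `rates`.
#' @export
discrete_gamma <- function(alpha, K = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K == 1L) {
    rates <- 1
  } else {
    # conditional means via the identity x f(x; a, a) = f(x; a+1, a)
    bounds <- qgamma(seq(0, 1, length.out = K + 1L),
                     shape = alpha, rate = alpha)
    rates <- K * diff(pgamma(bounds, shape = alpha + 1, rate = alpha))
    rates <- rates / mean(rates)   # absorb quadrature round-off
  }
  structure(list(alpha = alpha, K = K, rates = rates),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat("gamma_rates: alpha =", format(x$alpha), "K =", x$K, "\n rates:",
      paste(format(x$rates, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Read a custom model template from a text file
#'
#' Accepts either a whitespace/comma-delimited integer grid or a JSON array
#' of rows. Entry 0 is a structural zero; equal positive entries share one
#' relative-rate parameter.
#'
#' @param path file path.
#' @return an integer matrix usable as `custom_template`.
#' @export
read_model_template <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\[", txt)) {
    m <- jsonlite::fromJSON(txt)
    m <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  } else {
    m <- as.matrix(read.table(path))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}
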