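#' Three-species interaction motifs
#'
#' The four classic three-species feeding structures: food chain,
#' apparent competition (two producers sharing one consumer), resource
#' competition (two consumers sharing one producer) and intraguild
#' predation (omnivory: the top consumer eats both the producer and the
#' intermediate consumer). Species are indexed with producers first,
#' then ascending trophic position, and links are stored as
#' (prey, predator) pairs.
#'
#' @param name One of `"food_chain"`, `"apparent_competition"`,
#'   `"resource_competition"`, `"intraguild_predation"`.
#' @return An object of class `motif_topology`: a list with elements
#'   `name`, `links` (matrix with columns `prey`, `predator`), `roles`
#'   (per-species role) and `n_species`.
#' @examples
#' build_motif("food_chain")$links
#' @export
build_motif <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !(name %in% motif_names())) {
    stop("unknown motif '", paste(name, collapse = ""),
         "'; valid motifs are: ", paste(motif_names(), collapse = ", "))
  }
  def <- switch(name,
    food_chain = list(
      links = rbind(c(1L, 2L), c(2L, 3L)),
      roles = c("producer", "intermediate_consumer", "top_consumer")),
    apparent_competition = list(
      links = rbind(c(1L, 3L), c(2L, 3L)),
      roles = c("producer", "producer", "top_consumer")),
    resource_competition = list(
      links = rbind(c(1L, 2L), c(1L, 3L)),
      roles = c("producer", "top_consumer", "top_consumer")),
    intraguild_predation = list(
      links = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
      roles = c("producer", "intermediate_consumer", "top_consumer")))
  colnames(def$links) <- c("prey", "predator")
  structure(list(name = name, links = def$links, roles = def$roles,
                 n_species = 3L),
            class = "motif_topology")
}

#' @rdname build_motif
#' @export
motif_names <- function() {
  c("food_chain", "apparent_competition", "resource_competition",
    "intraguild_predation")
}

as_motif <- function(x) {
  if (inherits(x, "motif_topology")) return(x)
  build_motif(x)
}

producer_idx <- function(motif) which(motif$roles == "producer")
consumer_idx <- function(motif) which(motif$roles != "producer")

#' Sampling ranges for local (trophic) parameters
#'
#' Uniform sampling bounds for each parameter class of the motif
#' dynamics: producer growth rate `r` (1/time) and carrying capacity `K`
#' (biomass density); per-link attack rate `A`, half-saturation constant
#' `B` (biomass density) and conversion efficiency `e`; per-consumer
#' density-dependent mortality coefficient `d`. Defaults span standard
#' Rosenzweig-MacArthur regimes in which both stable and oscillatory
#' local dynamics occur.
#'
#' @param r,K,A,B,e,d Length-2 numeric `c(lower, upper)` bounds.
#' @return An object of class `local_param_config`.
#' @export
local_param_config <- function(r = c(0.5, 2), K = c(1, 10), A = c(0.5, 5),
                               B = c(0.5, 5), e = c(0.1, 1),
                               d = c(0.05, 1)) {
  cfg <- list(r = r, K = K, A = A, B = B, e = e, d = d)
  for (nm in names(cfg)) {
    b <- cfg[[nm]]
    if (!is.numeric(b) || length(b) != 2L || !(b[1] < b[2]))
      stop("bounds for '", nm, "' must be c(lower, upper) with lower < upper")
  }
  structure(cfg, class = "local_param_config")
}

#' Sample local parameters for a motif
#'
#' Draws one independent parameterization of the motif dynamics from the
#' configured uniform ranges. Producers get `r` and `K` (and no
#' mortality term, `d = 0`); consumers get `d` (and no logistic term);
#' each feeding link gets `A`, `B`, `e`. Draws use the current R RNG
#' stream, so `set.seed()` before the call makes the draw reproducible.
#'
#' @param motif A `motif_topology` or motif name.
#' @param config A [local_param_config()].
#' @return An object of class `local_params` with elements `motif`, `r`,
#'   `K`, `d` (length-3 vectors, `NA` where a parameter is undefined for
#'   the species' role) and `A`, `B`, `e` (one entry per link).
#' @export
sample_local_parameters <- function(motif, config = local_param_config()) {
  motif <- as_motif(motif)
  if (!inherits(config, "local_param_config"))
    config <- do.call(local_param_config, config)
  np <- length(producer_idx(motif))
  nc <- length(consumer_idx(motif))
  nl <- nrow(motif$links)
  r <- K <- d <- rep(NA_real_, motif$n_species)
  # fixed draw order (r, K, d, A, B, e) so identical seeds give
  # identical parameter sets
  r[producer_idx(motif)] <- runif(np, config$r[1], config$r[2])
  K[producer_idx(motif)] <- runif(np, config$K[1], config$K[2])
  d[consumer_idx(motif)] <- runif(nc, config$d[1], config$d[2])
  A <- runif(nl, config$A[1], config$A[2])
  B <- runif(nl, config$B[1], config$B[2])
  e <- runif(nl, config$e[1], config$e[2])
  structure(list(motif = motif, r = r, K = K, d = d, A = A, B = B, e = e),
            class = "local_params")
}

#' Local motif dynamics
#'
#' Right-hand side of the within-patch dynamics: logistic primary
#' production for producers, type-II (saturating) functional responses
#' for feeding links and density-dependent consumer mortality, all
#' multiplied by the species' own density, i.e.
#' `f_i = x_i * [ r_i (1 - x_i/K_i) - sum_L A x_pred/(B + x_i)
#'   + sum_L e A x_prey/(B + x_prey) - d_i x_i ]`.
#'
#' @param params A `local_params` object.
#' @param x Non-negative per-species density vector.
#' @return Per-species rate vector `f(x)`.
#' @export
local_rhs <- function(params, x) {
  check_params(params)
  if (length(x) != params$motif$n_species)
    stop("x must have length ", params$motif$n_species)
  if (any(!is.finite(x)) || any(x < 0))
    stop("densities must be finite and non-negative; the model is ",
         "undefined at negative densities")
  x * percap_rates(params, x)
}

# per-capita rates g(x); f = x * g
percap_rates <- function(params, x) {
  m <- params$motif
  g <- numeric(m$n_species)
  pr <- producer_idx(m)
  cs <- consumer_idx(m)
  g[pr] <- params$r[pr] * (1 - x[pr] / params$K[pr])
  g[cs] <- -params$d[cs] * x[cs]
  for (l in seq_len(nrow(m$links))) {
    i <- m$links[l, 1L]  # prey
    j <- m$links[l, 2L]  # predator
    den <- params$B[l] + x[i]
    g[i] <- g[i] - params$A[l] * x[j] / den
    g[j] <- g[j] + params$e[l] * params$A[l] * x[i] / den
  }
  g
}

# Jacobian of the per-capita rates, dg_i/dx_j
percap_jacobian <- function(params, x) {
  m <- params$motif
  n <- m$n_species
  dg <- matrix(0, n, n)
  for (k in producer_idx(m)) dg[k, k] <- -params$r[k] / params$K[k]
  for (k in consumer_idx(m)) dg[k, k] <- -params$d[k]
  for (l in seq_len(nrow(m$links))) {
    i <- m$links[l, 1L]
    j <- m$links[l, 2L]
    den <- params$B[l] + x[i]
    dg[i, i] <- dg[i, i] + params$A[l] * x[j] / den^2
    dg[i, j] <- dg[i, j] - params$A[l] / den
    dg[j, i] <- dg[j, i] + params$e[l] * params$A[l] * params$B[l] / den^2
  }
  dg
}

#' Jacobian of the local dynamics at an arbitrary state
#'
#' Analytic partial derivatives of [local_rhs()]:
#' `J_ij = d f_i / d x_j = delta_ij g_i + x_i dg_i/dx_j` with `g` the
#' per-capita rates. At a coexistence equilibrium this is the local
#' Jacobian `P` (the `g` term vanishes).
#'
#' @inheritParams local_rhs
#' @return The Jacobian matrix of `local_rhs` at `x`.
#' @export
local_rhs_jacobian <- function(params, x) {
  check_params(params)
  if (any(!is.finite(x)) || any(x < 0)) stop("densities must be non-negative")
  g <- percap_rates(params, x)
  dg <- percap_jacobian(params, x)
  diag(g, length(g)) + x * dg
}

#' Local Jacobian at a feasible equilibrium
#'
#' @param params A `local_params` object.
#' @param eq An [find_equilibrium()] result with `feasible = TRUE`.
#' @return The matrix `P` of partial derivatives of the local dynamics
#'   at the coexistence equilibrium. For every feeding link (prey j,
#'   predator i), `P[i, j] > 0` and `P[j, i] < 0`.
#' @export
local_jacobian <- function(params, eq) {
  if (!inherits(eq, "equilibrium")) stop("eq must be an 'equilibrium' object")
  if (!isTRUE(eq$feasible))
    stop("cannot linearize at an infeasible equilibrium")
  local_rhs_jacobian(params, eq$x_star)
}

check_params <- function(params) {
  if (!inherits(params, "local_params"))
    stop("params must be a 'local_params' object")
  invisible(params)
}

#' @export
print.motif_topology <- function(x, ...) {
  cat("motif:", x$name, "\n")
  cat("roles:", paste(x$roles, collapse = ", "), "\n")
  cat("links (prey -> predator):",
      paste(sprintf("%d->%d", x$links[, 1], x$links[, 2]), collapse = ", "),
      "\n")
  invisible(x)
}
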