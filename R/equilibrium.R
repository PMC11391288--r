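#' Control settings for the equilibrium search
#'
#' @param residual_tol Maximum absolute value of the dynamics at an
#'   accepted equilibrium (1/time x biomass density).
#' @param feasible_min Smallest density accepted as "positive" for a
#'   coexistence state.
#' @param n_starts Number of random positive starting points for the
#'   multi-start Newton search.
#' @param distinct_tol Two roots closer than this (max-norm) count as
#'   the same root when recording multiplicity.
#' @param max_iter Newton iteration cap per start.
#' @param start_min Lower end of the log-uniform range for starting
#'   points; the upper end is the largest carrying capacity.
#' @return A list of control settings.
#' @export
equilibrium_control <- function(residual_tol = 1e-9, feasible_min = 1e-6,
                                n_starts = 8L, distinct_tol = 1e-4,
                                max_iter = 100L, start_min = 1e-3) {
  list(residual_tol = residual_tol, feasible_min = feasible_min,
       n_starts = as.integer(n_starts), distinct_tol = distinct_tol,
       max_iter = as.integer(max_iter), start_min = start_min)
}

#' Find a coexistence equilibrium of the motif dynamics
#'
#' Searches for a spatially homogeneous steady state with all densities
#' strictly positive by damped Newton iteration on the per-capita rates
#' `g(x) = 0` (which excludes boundary states) from multiple random
#' positive starting points. Non-convergence is not an error: if no
#' interior root is found the result has `feasible = FALSE` and reports
#' the smallest residual encountered. If several distinct interior roots
#' are found, the first is kept and the multiplicity recorded in
#' `n_roots`. Starting points are drawn from the current RNG stream.
#'
#' @param params A `local_params` object.
#' @param control See [equilibrium_control()].
#' @return An object of class `equilibrium`: list with `x_star`,
#'   `feasible`, `residual` (max |f(x_star)|) and `n_roots`.
#' @export
find_equilibrium <- function(params, control = equilibrium_control()) {
  check_params(params)
  max_K <- max(params$K, na.rm = TRUE)
  n <- params$motif$n_species
  roots <- list()
  best_res <- Inf
  best_x <- rep(NA_real_, n)
  for (s in seq_len(control$n_starts)) {
    x0 <- exp(runif(n, log(control$start_min), log(max_K)))
    x <- newton_interior(params, x0, control)
    if (is.null(x)) next
    res <- max(abs(x * percap_rates(params, x)))
    if (res < best_res) {
      best_res <- res
      best_x <- x
    }
    if (res < control$residual_tol && min(x) > control$feasible_min) {
      known <- any(vapply(roots, function(rt)
        max(abs(rt - x)) < control$distinct_tol, logical(1)))
      if (!known) roots[[length(roots) + 1L]] <- x
    }
  }
  if (length(roots) > 0L) {
    x <- roots[[1L]]
    structure(list(x_star = x, feasible = TRUE,
                   residual = max(abs(x * percap_rates(params, x))),
                   n_roots = length(roots)),
              class = "equilibrium")
  } else {
    structure(list(x_star = best_x, feasible = FALSE, residual = best_res,
                   n_roots = 0L),
              class = "equilibrium")
  }
}

# damped Newton on g(x) = 0 keeping all components strictly positive;
# returns the endpoint or NULL on failure
newton_interior <- function(params, x0, control) {
  x <- x0
  for (it in seq_len(control$max_iter)) {
    g <- percap_rates(params, x)
    if (max(abs(x * g)) < 0.5 * control$residual_tol) return(x)
    J <- percap_jacobian(params, x)
    step <- tryCatch(solve(J, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    xn <- NULL
    gn <- NULL
    for (h in 1:30) {
      cand <- x - lam * step
      if (all(cand > 0)) {
        gc_ <- percap_rates(params, cand)
        if (max(abs(gc_)) <= max(abs(g)) || lam < 1e-6) {
          xn <- cand
          gn <- gc_
          break
        }
      }
      lam <- lam / 2
    }
    if (is.null(xn)) return(NULL)
    if (max(abs(xn - x)) < 1e-14) {
      x <- xn
      break
    }
    x <- xn
  }
  if (max(abs(x * percap_rates(params, x))) < 0.5 * control$residual_tol)
    x else NULL
}

#' Sample feasible motif systems
#'
#' Repeatedly draws local parameterizations ([sample_local_parameters()])
#' and keeps those with a feasible coexistence equilibrium, until `n`
#' systems are collected. For each kept system the equilibrium, the
#' local Jacobian `P` and its spectral abscissa `lambda0`
#' (= max Re eig(P), the isolated-patch growth rate) are stored.
#' Rejected draws are counted: all robustness estimates downstream are
#' conditional on feasibility.
#'
#' @param motif A `motif_topology` or motif name.
#' @param n Number of feasible systems to return.
#' @param config A [local_param_config()].
#' @param control See [equilibrium_control()].
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param discard_cap Error out if more than this fraction of draws had
#'   to be discarded (flags a degenerate sampling configuration).
#' @return An object of class `feasible_systems`: list with `motif`,
#'   `systems` (each a list `params`, `eq`, `P`, `lambda0`),
#'   `n_discarded` and `attempts`.
#' @export
sample_feasible_systems <- function(motif, n, config = local_param_config(),
                                    control = equilibrium_control(),
                                    seed = NULL, discard_cap = 0.99) {
  motif <- as_motif(motif)
  if (!is.null(seed)) set.seed(seed)
  if (n < 1L) stop("n must be >= 1")
  max_attempts <- ceiling(n / (1 - discard_cap))
  systems <- vector("list", n)
  found <- 0L
  attempts <- 0L
  while (found < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    params <- sample_local_parameters(motif, config)
    eq <- find_equilibrium(params, control)
    if (!eq$feasible) next
    P <- local_jacobian(params, eq)
    lambda0 <- max(Re(eigen(P, only.values = TRUE)$values))
    found <- found + 1L
    systems[[found]] <- list(params = params, eq = eq, P = P,
                             lambda0 = lambda0)
  }
  if (found < n)
    stop("feasibility discard rate exceeded the cap (", discard_cap,
         "): only ", found, " feasible systems in ", attempts,
         " attempts; the parameter configuration looks degenerate")
  structure(list(motif = motif, systems = systems,
                 n_discarded = attempts - n, attempts = attempts),
            class = "feasible_systems")
}

#' Flatten sampled systems to a data frame
#'
#' One row per feasible draw: motif, parameters (link-indexed columns),
#' equilibrium densities, residual and isolated-patch growth rate.
#' Suitable for CSV export with [utils::write.csv()].
#'
#' @param x A `feasible_systems` object.
#' @param row.names,optional,... Passed on conventions of
#'   [base::as.data.frame()]; unused.
#' @export
as.data.frame.feasible_systems <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  rows <- lapply(seq_along(x$systems), function(i) {
    s <- x$systems[[i]]
    p <- s$params
    nl <- nrow(p$motif$links)
    out <- c(list(draw = i, motif = p$motif$name),
             as.list(setNames(p$r, paste0("r", 1:3))),
             as.list(setNames(p$K, paste0("K", 1:3))),
             as.list(setNames(p$d, paste0("d", 1:3))),
             as.list(setNames(p$A, paste0("A_link", seq_len(nl)))),
             as.list(setNames(p$B, paste0("B_link", seq_len(nl)))),
             as.list(setNames(p$e, paste0("e_link", seq_len(nl)))),
             as.list(setNames(s$eq$x_star, paste0("x_star", 1:3))),
             list(residual = s$eq$residual, n_roots = s$eq$n_roots,
                  lambda0 = s$lambda0))
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("equilibrium: feasible =", x$feasible,
      " residual =", format(x$residual, digits = 3),
      " n_roots =", x$n_roots, "\n")
  if (x$feasible) cat("x* =", paste(format(x$x_star, digits = 5),
                                    collapse = ", "), "\n")
  invisible(x)
}
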