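#' Monte-Carlo robustness grid for one motif and dispersal placement
#'
#' Draws `n_P` feasible local parameterizations and `n_C` connectivity
#' matrices, classifies every (P draw, C draw) pair, and stores the
#' label matrix. The same P draws are crossed with the same C draws
#' (nested design), which makes the local/spatial robustness
#' distributions and the shared-mean identity exact. Because the
#' unstable label depends only on `P`, unstable rows are classified
#' once and broadcast. For three-species systems the pairwise
#' classification uses an exact Routh-Hurwitz interval criterion over
#' the configured `kappa` range plus the asymptotic large-`kappa` test
#' (a continuous refinement of the grid-based [classify()]; the two
#' agree on all but marginal draws, which is itself tested).
#'
#' @param motif A `motif_topology` or motif name.
#' @param subset Matrix of active off-diagonal positions (columns `i`,
#'   `j`), e.g. one element of [enumerate_subsets()]. `NULL` means all
#'   allowed positions (maximum `n_cross`).
#' @param constrained Logical; apply the adaptive sign constraint to
#'   the connectivity draws?
#' @param n_P,n_C Numbers of local and connectivity draws.
#' @param seed Integer seed; local and connectivity sub-seeds are
#'   derived from it, so runs with equal seeds share their P draws and
#'   their C magnitudes across the constrained flag.
#' @param local_config,conn_config,stab_config See
#'   [local_param_config()], [connectivity_config()],
#'   [stability_config()].
#' @param eq_control See [equilibrium_control()].
#' @param systems Optional precomputed [sample_feasible_systems()]
#'   batch (must match `motif` and have at least `n_P` systems); used
#'   by [scan_motif()] to share local draws across subsets.
#' @return Object of class `robustness_grid`: list with `labels`
#'   (`n_P` x `n_C` character matrix with entries `"stable"`,
#'   `"unstable"`, `"pattern_forming"`), `lambda0`, and metadata
#'   (`motif`, `subset`, `constrained`, `seed`, `n_discarded`,
#'   `n_marginal`).
#' @export
build_grid <- function(motif, subset = NULL, constrained = FALSE,
                       n_P = 100, n_C = 100, seed = 1L,
                       local_config = local_param_config(),
                       conn_config = connectivity_config(),
                       stab_config = stability_config(),
                       eq_control = equilibrium_control(),
                       systems = NULL) {
  motif <- as_motif(motif)
  if (n_P < 1L || n_C < 1L) stop("n_P and n_C must be >= 1")
  if (is.null(subset)) subset <- cross_positions(motif)$positions
  if (is.null(systems)) {
    systems <- sample_feasible_systems(motif, n_P, config = local_config,
                                       control = eq_control,
                                       seed = derive_seed(seed, 1L))
  } else {
    if (!inherits(systems, "feasible_systems") ||
        systems$motif$name != motif$name)
      stop("systems must be a 'feasible_systems' batch for the same motif")
    if (length(systems$systems) < n_P)
      stop("precomputed systems batch has fewer than n_P draws")
  }
  sys <- systems$systems[seq_len(n_P)]
  S <- motif_sign_pattern(motif)
  set.seed(derive_seed(seed, 2L))
  C_list <- lapply(seq_len(n_C), function(i)
    sample_connectivity(S, subset, constrained, conn_config)$C)
  labels <- classify_pairs_3x3(sys, C_list, stab_config)
  lam0 <- vapply(sys, `[[`, numeric(1), "lambda0")
  structure(list(labels = labels, lambda0 = lam0, motif = motif,
                 subset = subset, constrained = constrained, seed = seed,
                 n_P = n_P, n_C = n_C,
                 n_discarded = systems$n_discarded,
                 n_marginal = sum(abs(lam0) <= stab_config$zero_tol)),
            class = "robustness_grid")
}

grid_levels <- c("stable", "unstable", "pattern_forming")

#' Total robustness of each dynamical class
#'
#' Fraction of the (P draw, C draw) grid carrying each label. The three
#' fractions partition the grid, so they sum to one exactly.
#'
#' @param grid A [build_grid()] result.
#' @return Named list with `omega_st`, `omega_us`, `omega_pf`.
#' @export
total_robustness <- function(grid) {
  lab <- grid$labels
  n <- length(lab)
  list(omega_st = sum(lab == "stable") / n,
       omega_us = sum(lab == "unstable") / n,
       omega_pf = sum(lab == "pattern_forming") / n)
}

class_key <- function(class) {
  class <- match.arg(class, grid_levels)
  class
}

#' Local robustness distribution
#'
#' One value of the local robustness `omega(P)` per connectivity draw:
#' the fraction of local parameterizations yielding the given class at
#' that fixed dispersal behaviour (column means of the indicator).
#'
#' @param grid A [build_grid()] result.
#' @param class `"stable"`, `"unstable"` or `"pattern_forming"`.
#' @return Numeric vector of length `n_C`.
#' @export
local_robustness_distribution <- function(grid, class = "pattern_forming") {
  class <- class_key(class)
  colMeans(grid$labels == class)
}

#' Spatial robustness distribution
#'
#' One value of the spatial robustness `omega(C)` per local draw: the
#' fraction of dispersal behaviours yielding the given class at that
#' fixed local parameterization (row means of the indicator).
#'
#' @inheritParams local_robustness_distribution
#' @return Numeric vector of length `n_P`.
#' @export
spatial_robustness_distribution <- function(grid,
                                            class = "pattern_forming") {
  class <- class_key(class)
  rowMeans(grid$labels == class)
}

#' Variance and skewness of the robustness distributions
#'
#' Second and third central moments of the local and spatial robustness
#' distributions about their shared mean (the total robustness;
#' identical for both distributions on a full grid). Skewness is the
#' third central moment standardized by variance^(3/2), reported as 0
#' when the variance is below 1e-12.
#'
#' @param local_dist,spatial_dist Vectors from
#'   [local_robustness_distribution()] and
#'   [spatial_robustness_distribution()] computed on the same grid.
#' @return Named list: `shared_mean`, `variance_local`,
#'   `variance_spatial`, `skew_local`, `skew_spatial`.
#' @export
robustness_moments <- function(local_dist, spatial_dist) {
  m1 <- mean(local_dist)
  m2 <- mean(spatial_dist)
  if (abs(m1 - m2) > 1e-8)
    stop("local and spatial distributions do not share a mean; ",
         "they must come from the same (full) grid")
  m <- (m1 + m2) / 2
  mom <- function(x) {
    v <- mean((x - m)^2)
    sk <- if (v < 1e-12) 0 else mean((x - m)^3) / v^1.5
    c(v, sk)
  }
  lo <- mom(local_dist)
  sp <- mom(spatial_dist)
  list(shared_mean = m, variance_local = lo[1], variance_spatial = sp[1],
       skew_local = lo[2], skew_spatial = sp[2])
}

#' Drop locally unstable parameterizations from a grid
#'
#' Removes every P row labelled unstable, so that on the filtered grid
#' `omega_pf + omega_st = 1` and the robustness of pattern formation
#' may reach 1. Used for the moment analyses and the large-web scans,
#' which condition on local stability.
#'
#' @param grid A [build_grid()] result.
#' @return A `robustness_grid` with the unstable rows removed.
#' @export
exclude_unstable <- function(grid) {
  us_row <- grid$labels[, 1L] == "unstable"
  if (all(us_row))
    stop("all local parameterizations are unstable; the filtered grid ",
         "is empty")
  out <- grid
  out$labels <- grid$labels[!us_row, , drop = FALSE]
  out$lambda0 <- grid$lambda0[!us_row]
  out$n_P <- sum(!us_row)
  out
}

#' Robustness scan of one motif across cross-diffusion prevalence
#'
#' For each number of interspecific dispersal responses `n_cross` (0 up
#' to the motif maximum), builds one robustness grid per placement of
#' the responses and averages the summaries across placements with
#' equal weight. The same feasible local draws are shared by every
#' grid (the local batch is drawn once per scan), so the unstable
#' fraction is constant across `n_cross` and matched-seed constrained
#' and unconstrained scans are paired draw by draw. Variance and
#' skewness of the pattern-forming robustness distributions are
#' computed on the locally-stable subset of each grid (unstable rows
#' excluded), averaged across placements.
#'
#' @inheritParams build_grid
#' @param n_cross_values Integer vector of `n_cross` values to scan;
#'   default 0 to the motif maximum.
#' @return A data frame with one row per `n_cross`: subset-averaged
#'   `omega_st`, `omega_us`, `omega_pf`, moment summaries, and run
#'   metadata.
#' @export
scan_motif <- function(motif, constrained = FALSE, n_P = 300, n_C = 300,
                       seed = 1L, local_config = local_param_config(),
                       conn_config = connectivity_config(),
                       stab_config = stability_config(),
                       eq_control = equilibrium_control(),
                       n_cross_values = NULL, systems = NULL) {
  motif <- as_motif(motif)
  pos <- cross_positions(motif)
  if (is.null(n_cross_values)) n_cross_values <- 0:pos$n_cross
  if (is.null(systems))
    systems <- sample_feasible_systems(motif, n_P, config = local_config,
                                       control = eq_control,
                                       seed = derive_seed(seed, 1L))
  rows <- lapply(n_cross_values, function(k) {
    subsets <- enumerate_subsets(pos, k)
    per <- lapply(seq_along(subsets), function(si) {
      g <- build_grid(motif, subset = subsets[[si]],
                      constrained = constrained, n_P = n_P, n_C = n_C,
                      seed = derive_seed(seed, 1000L + 101L * k + si),
                      local_config = local_config,
                      conn_config = conn_config,
                      stab_config = stab_config,
                      eq_control = eq_control, systems = systems)
      om <- total_robustness(g)
      gf <- exclude_unstable(g)
      mo <- robustness_moments(
        local_robustness_distribution(gf, "pattern_forming"),
        spatial_robustness_distribution(gf, "pattern_forming"))
      c(unlist(om), unlist(mo[c("variance_local", "variance_spatial",
                                "skew_local", "skew_spatial")]),
        n_marginal = g$n_marginal)
    })
    avg <- colMeans(do.call(rbind, per))
    data.frame(motif = motif$name, n_cross = k,
               n_subsets = length(subsets), constrained = constrained,
               omega_st = avg[["omega_st"]], omega_us = avg[["omega_us"]],
               omega_pf = avg[["omega_pf"]],
               variance_local = avg[["variance_local"]],
               variance_spatial = avg[["variance_spatial"]],
               skew_local = avg[["skew_local"]],
               skew_spatial = avg[["skew_spatial"]],
               n_P = n_P, n_C = n_C, seed = seed,
               n_discarded = systems$n_discarded,
               n_marginal = avg[["n_marginal"]])
  })
  do.call(rbind, rows)
}
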