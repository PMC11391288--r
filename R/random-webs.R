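#' Niche-model food-web topology
#'
#' Classic Williams-Martinez construction: each species gets a niche
#' value `n_i ~ U(0, 1)`; a feeding range `r_i = n_i * x_i` with
#' `x_i ~ Beta(1, beta)` and `beta = 1/(2 C) - 1` so the expected
#' connectance (links / N^2) matches the target `C`; and a range centre
#' `c_i ~ U(r_i / 2, n_i)`. Species `i` consumes every species whose
#' niche value falls inside `[c_i - r_i/2, c_i + r_i/2]`. The species
#' with the smallest niche value has its range set to 0 (a guaranteed
#' basal species). Cannibalistic self-links are ignored (the Jacobian
#' diagonal is reserved for self-regulation), and for mutually feeding
#' pairs only the orientation whose consumer has the higher niche value
#' is kept, so every link has a well-defined consumer and resource.
#' Whole webs are resampled until the undirected feeding graph is
#' connected.
#'
#' @param N Species count (>= 2).
#' @param target_connectance Desired links / N^2, in (0, 0.5).
#' @param max_attempts Resampling cap; exceeding it is an error
#'   (infeasible N / connectance combination).
#' @return Object of class `niche_web`: list with `N`, `niche`,
#'   `range`, `centre`, `links` (matrix with columns `consumer`,
#'   `resource`, sorted), `target_connectance`, `attempts`.
#' @export
niche_topology <- function(N, target_connectance, max_attempts = 1e4) {
  if (N < 2L) stop("N must be >= 2")
  if (target_connectance <= 0 || target_connectance >= 0.5)
    stop("target_connectance must be in (0, 0.5)")
  beta_par <- 1 / (2 * target_connectance) - 1
  for (attempt in seq_len(max_attempts)) {
    nv <- runif(N)
    rng <- nv * rbeta(N, 1, beta_par)
    rng[which.min(nv)] <- 0
    ctr <- runif(N, rng / 2, nv)
    cons <- integer(0)
    res <- integer(0)
    for (i in seq_len(N)) {
      if (rng[i] <= 0) next
      prey <- which(nv >= ctr[i] - rng[i] / 2 & nv <= ctr[i] + rng[i] / 2)
      prey <- prey[prey != i]
      cons <- c(cons, rep.int(i, length(prey)))
      res <- c(res, prey)
    }
    if (length(cons) > 0L) {
      # resolve mutual predation: keep the higher-niche consumer
      drop <- logical(length(cons))
      key <- paste(cons, res)
      rev_key <- paste(res, cons)
      mutual <- match(rev_key, key)
      for (l in seq_along(cons)) {
        m <- mutual[l]
        if (!is.na(m) && nv[cons[l]] < nv[res[l]]) drop[l] <- TRUE
      }
      cons <- cons[!drop]
      res <- res[!drop]
    }
    if (length(cons) == 0L) next
    if (!graph_connected(N, cons, res)) next
    links <- cbind(consumer = cons, resource = res)
    links <- links[order(links[, 1L], links[, 2L]), , drop = FALSE]
    return(structure(list(N = N, niche = nv, range = rng, centre = ctr,
                          links = links,
                          target_connectance = target_connectance,
                          attempts = attempt),
                     class = "niche_web"))
  }
  stop("no connected web found in ", max_attempts, " attempts; ",
       "N = ", N, " with connectance ", target_connectance,
       " looks infeasible")
}

# connectivity of the undirected feeding graph (simple BFS)
graph_connected <- function(N, from, to) {
  adj <- vector("list", N)
  for (l in seq_along(from)) {
    adj[[from[l]]] <- c(adj[[from[l]]], to[l])
    adj[[to[l]]] <- c(adj[[to[l]]], from[l])
  }
  seen <- logical(N)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Random Jacobian for a niche web
#'
#' Diagonal entries are fixed at -1 (self-regulation); for each link
#' (consumer i, resource j) the consumer-side entry `P[i, j]` is drawn
#' from a folded normal `|N(0, sigma)|` and the resource-side entry
#' `P[j, i]` from `-|N(0, sigma)|`. No other entries are touched.
#'
#' @param web A [niche_topology()] result.
#' @param sigma Scale of the folded-normal interaction strengths.
#' @return An `N` x `N` matrix.
#' @export
random_web_jacobian <- function(web, sigma = 0.5) {
  if (!inherits(web, "niche_web")) stop("web must be a 'niche_web'")
  P <- diag(-1, web$N)
  nl <- nrow(web$links)
  gain <- abs(rnorm(nl, 0, sigma))
  loss <- -abs(rnorm(nl, 0, sigma))
  for (l in seq_len(nl)) {
    i <- web$links[l, 1L]
    j <- web$links[l, 2L]
    P[i, j] <- gain[l]
    P[j, i] <- loss[l]
  }
  P
}

# canonical (sorted by i, j) off-diagonal positions where P is nonzero
web_cross_positions <- function(web) {
  pos <- rbind(web$links[, c(1L, 2L), drop = FALSE],
               web$links[, c(2L, 1L), drop = FALSE])
  colnames(pos) <- c("i", "j")
  pos <- unique(pos)
  pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
}

#' Random connectivity matrix for a niche web
#'
#' Diagonal entries are drawn uniform-positive; each off-diagonal
#' position with a trophic interaction receives a dispersal response
#' with probability `q`, with value uniform on (-1, 1) when
#' unconstrained or sign-forced by the adaptive rule
#' `sgn(C[i, j]) = -sgn(P[i, j])` when constrained. Bernoulli
#' outcomes, magnitudes and sign variates are always consumed from the
#' RNG stream in that order, so matched-seed constrained and
#' unconstrained draws share their active positions and magnitudes.
#'
#' @param web A [niche_topology()] result.
#' @param q Per-position probability of an interspecific response.
#' @param constrained Logical; apply the adaptive sign constraint?
#' @param diag_range Uniform range for the positive diagonal.
#' @return An `N` x `N` matrix.
#' @export
random_web_connectivity <- function(web, q, constrained = FALSE,
                                    diag_range = c(0, 1)) {
  if (!inherits(web, "niche_web")) stop("web must be a 'niche_web'")
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  pos <- web_cross_positions(web)
  m <- nrow(pos)
  C <- diag(runif(web$N, diag_range[1], diag_range[2]), web$N)
  active <- runif(m) < q
  mag <- runif(m)
  sign_u <- ifelse(runif(m) < 0.5, -1, 1)
  # consumer -> resource positions of P are positive
  cons_side <- logical(m)
  key <- paste(web$links[, 1L], web$links[, 2L])
  cons_side <- paste(pos[, 1L], pos[, 2L]) %in% key
  for (l in seq_len(m)) {
    if (!active[l]) next
    s <- if (constrained) {
      if (cons_side[l]) -1 else 1  # -sgn(P[i, j])
    } else sign_u[l]
    C[pos[l, 1L], pos[l, 2L]] <- s * mag[l]
  }
  C
}

# classify one (P, C) pair of arbitrary dimension: spectral abscissa at
# kappa = 0, asymptotic test, then the kappa grid with early exit.
classify_large <- function(P, C, lambda0, config) {
  zt <- config$zero_tol
  if (lambda0 > zt) return("unstable")
  evC <- eigen(C, only.values = TRUE)$values
  if (min(Re(evC)) < -config$asymptotic_tol) return("pattern_forming")
  for (kappa in config$kappa_grid[-1L]) {
    lam <- max(Re(eigen(P - kappa * C, only.values = TRUE)$values))
    if (lam > zt) return("pattern_forming")
  }
  "stable"
}

#' Pattern-formation robustness across web size and response prevalence
#'
#' For each (N, q) cell: draw `reps` niche webs with random Jacobian /
#' connectivity pairs, keep only locally stable Jacobians
#' (`lambda(0) < 0`; locally unstable draws are excluded so the
#' pattern-forming fraction may reach 1), classify the kept pairs and
#' report the pattern-forming fraction. Cell seeds are derived from
#' `seed` and the cell indices only, so constrained and unconstrained
#' scans with the same seed use identical webs, Jacobians, active
#' positions and magnitudes.
#'
#' @param N_values,q_values Vectors of web sizes and response
#'   probabilities.
#' @param reps Draws per cell.
#' @param constrained Logical; apply the adaptive sign constraint?
#' @param sigma Folded-normal interaction scale.
#' @param target_connectance Niche-model connectance target.
#' @param seed Integer seed.
#' @param stab_config See [stability_config()].
#' @param diag_range Uniform range for the connectivity diagonal.
#' @return Data frame with columns `N`, `q`, `constrained`,
#'   `reps_kept`, `reps_total`, `omega_pf` (`NA` when no draw was
#'   locally stable), `seed`.
#' @export
scan_Nq <- function(N_values, q_values, reps = 200, constrained = FALSE,
                    sigma = 0.5, target_connectance = 0.15, seed = 1L,
                    stab_config = stability_config(),
                    diag_range = c(0, 1)) {
  if (reps < 1L) stop("reps must be >= 1")
  rows <- list()
  for (ni in seq_along(N_values)) {
    for (qi in seq_along(q_values)) {
      cell_seed <- derive_seed(seed, 7919L * ni + qi)
      set.seed(cell_seed)
      kept <- 0L
      pf <- 0L
      for (rep in seq_len(reps)) {
        web <- niche_topology(N_values[ni], target_connectance)
        P <- random_web_jacobian(web, sigma)
        C <- random_web_connectivity(web, q_values[qi], constrained,
                                     diag_range)
        lambda0 <- max(Re(eigen(P, only.values = TRUE)$values))
        if (lambda0 > stab_config$zero_tol) next
        kept <- kept + 1L
        lab <- classify_large(P, C, lambda0, stab_config)
        if (lab == "pattern_forming") pf <- pf + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        N = N_values[ni], q = q_values[qi], constrained = constrained,
        reps_kept = kept, reps_total = reps,
        omega_pf = if (kept > 0L) pf / kept else NA_real_,
        seed = cell_seed)
    }
  }
  do.call(rbind, rows)
}

#' Export a niche web's links as an edge list
#'
#' @param web A `niche_web`.
#' @param path File path; two-column `consumer,resource` CSV.
#' @export
write_edge_list <- function(web, path) {
  utils::write.csv(as.data.frame(web$links), path, row.names = FALSE)
  invisible(path)
}
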