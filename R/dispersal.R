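#' Interspecific dispersal-response positions of a motif
#'
#' An off-diagonal entry `C[i, j]` of the connectivity matrix (the
#' dispersal response of species i to the local density of species j)
#' is permitted wherever the two species interact trophically, i.e.
#' wherever `P[i, j] != 0`. Both orientations of every feeding link are
#' allowed, so a two-link motif admits at most 4 interspecific
#' responses and the intraguild predation motif at most 6.
#'
#' @param motif A `motif_topology` or motif name.
#' @return Object of class `cross_position_set`: list with `positions`
#'   (matrix with columns `i`, `j`, sorted by (i, j)) and `n_cross`.
#' @export
cross_positions <- function(motif) {
  motif <- if (is.character(motif)) build_motif(motif) else motif
  links <- motif$links
  if (nrow(links) == 0L) {
    pos <- matrix(integer(0), ncol = 2L)
  } else {
    pos <- rbind(links[, c(1L, 2L), drop = FALSE],
                 links[, c(2L, 1L), drop = FALSE])
    pos <- unique(pos)
    pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
  }
  colnames(pos) <- c("i", "j")
  structure(list(positions = pos, n_cross = nrow(pos)),
            class = "cross_position_set")
}

#' Enumerate subsets of dispersal-response positions
#'
#' All combinations of `n_cross` positions out of the allowed set, in a
#' deterministic order. Robustness scans average over these placements
#' at each value of `n_cross`.
#'
#' @param positions A [cross_positions()] result.
#' @param n_cross Subset size, between 0 and `positions$n_cross`.
#' @return List of position matrices (possibly with zero rows).
#' @export
enumerate_subsets <- function(positions, n_cross) {
  if (!inherits(positions, "cross_position_set"))
    stop("positions must be a 'cross_position_set'")
  m <- positions$n_cross
  if (n_cross < 0L || n_cross > m)
    stop("n_cross must be between 0 and ", m)
  if (n_cross == 0L)
    return(list(positions$positions[integer(0), , drop = FALSE]))
  idx <- combn(m, n_cross, simplify = FALSE)
  lapply(idx, function(k) positions$positions[k, , drop = FALSE])
}

#' Sign pattern of a motif's local Jacobian
#'
#' For every feeding link (prey p, predator c) of a motif with all
#' species at positive equilibrium density, the type-II functional
#' response forces `P[c, p] > 0` and `P[p, c] < 0`. Diagonal entries
#' are sign-indefinite and reported as 0 (they never carry a
#' cross-diffusion constraint).
#'
#' @param motif A `motif_topology` or motif name.
#' @return 3x3 matrix with entries in -1, 0, 1.
#' @export
motif_sign_pattern <- function(motif) {
  motif <- as_motif(motif)
  n <- motif$n_species
  S <- matrix(0, n, n)
  for (l in seq_len(nrow(motif$links))) {
    p <- motif$links[l, 1L]
    cns <- motif$links[l, 2L]
    S[cns, p] <- 1
    S[p, cns] <- -1
  }
  S
}

#' Magnitude distributions for connectivity draws
#'
#' Uniform ranges for the strictly positive diagonal (mass-action
#' diffusion) and for off-diagonal magnitudes, shared between the motif
#' and random-web analyses (off-diagonals are uniform on (-1, 1), i.e.
#' magnitude uniform on (0, 1) with a sign).
#'
#' @param diag,offdiag Length-2 `c(lower, upper)` ranges.
#' @return An object of class `connectivity_config`.
#' @export
connectivity_config <- function(diag = c(0, 1), offdiag = c(0, 1)) {
  for (b in list(diag, offdiag))
    if (!is.numeric(b) || length(b) != 2L || !(b[1] < b[2]))
      stop("ranges must be c(lower, upper) with lower < upper")
  structure(list(diag = diag, offdiag = offdiag),
            class = "connectivity_config")
}

#' Sample a connectivity (linearized dispersal) matrix
#'
#' Diagonal entries are strictly positive; off-diagonal entries appear
#' only at the given subset of allowed positions. Magnitudes are drawn
#' first and signs applied last: unconstrained draws sign each entry
#' uniformly at random, constrained draws impose the adaptive rule
#' `sgn(C[i, j]) = -sgn(P[i, j])` (prey tracking / predator avoidance).
#' The sign variates are always consumed from the RNG stream, so
#' constrained and unconstrained draws from the same seed share their
#' magnitudes and differ only in the off-diagonal signs.
#'
#' @param P_signs Sign pattern of the local Jacobian (see
#'   [motif_sign_pattern()]).
#' @param subset Matrix of active off-diagonal positions (columns
#'   `i`, `j`); may have zero rows.
#' @param constrained Logical; apply the adaptive sign constraint?
#' @param config A [connectivity_config()].
#' @return Object of class `connectivity_matrix`: list with `C`,
#'   `constrained`, `active_positions`.
#' @export
sample_connectivity <- function(P_signs, subset, constrained = FALSE,
                                config = connectivity_config()) {
  n <- nrow(P_signs)
  if (is.null(dim(subset))) subset <- matrix(subset, ncol = 2L)
  k <- nrow(subset)
  dg <- runif(n, config$diag[1], config$diag[2])
  mag <- runif(k, config$offdiag[1], config$offdiag[2])
  sign_u <- ifelse(runif(k) < 0.5, -1, 1)  # drawn even when constrained
  C <- diag(dg, n)
  for (r in seq_len(k)) {
    i <- subset[r, 1L]
    j <- subset[r, 2L]
    if (i == j) stop("subset positions must be off-diagonal")
    ps <- P_signs[i, j]
    if (ps == 0)
      stop("subset position (", i, ",", j, ") has no trophic interaction ",
           "(P sign is zero); no dispersal response is permitted there")
    s <- if (constrained) -ps else sign_u[r]
    C[i, j] <- s * mag[r]
  }
  structure(list(C = C, constrained = constrained,
                 active_positions = subset),
            class = "connectivity_matrix")
}

# accept either a plain matrix or a connectivity_matrix
conn_mat <- function(C) {
  if (inherits(C, "connectivity_matrix")) C$C else C
}

#' Flatten connectivity draws to a data frame row
#'
#' @param x A `connectivity_matrix`.
#' @param row.names,optional,... Unused.
#' @export
as.data.frame.connectivity_matrix <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  n <- nrow(x$C)
  vals <- as.vector(x$C)
  nms <- as.vector(outer(seq_len(n), seq_len(n),
                         function(i, j) paste0("C", i, j)))
  out <- as.data.frame(as.list(setNames(vals, nms)))
  out$constrained <- x$constrained
  out$n_cross <- nrow(x$active_positions)
  out
}
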