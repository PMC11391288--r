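#' Configuration of the master-stability-function scan
#'
#' The Laplacian eigenvalue `kappa` plays the role of a wavenumber and
#' is scanned over `{0}` plus a log-spaced positive grid. Because any
#' undirected patch network can realize arbitrarily large `kappa`, the
#' finite grid is augmented by an asymptotic test: if `C` has an
#' eigenvalue with real part below `-asymptotic_tol`, then `P - kappa C`
#' is unstable for sufficiently large `kappa` regardless of the grid.
#'
#' @param n_kappa Number of positive grid points.
#' @param kappa_min,kappa_max Range of the positive log-spaced grid.
#' @param zero_tol Tolerance for calling a growth rate zero.
#' @param asymptotic_tol Tolerance on real parts of eigenvalues of `C`
#'   in the large-`kappa` test.
#' @return Object of class `stability_config` with the `kappa_grid`
#'   (starting at 0) and tolerances.
#' @export
stability_config <- function(n_kappa = 400L, kappa_min = 1e-3,
                             kappa_max = 1e3, zero_tol = 1e-9,
                             asymptotic_tol = 1e-9) {
  if (kappa_min <= 0 || kappa_max <= kappa_min)
    stop("need 0 < kappa_min < kappa_max")
  if (zero_tol <= 0) stop("zero_tol must be > 0")
  grid <- c(0, 10^seq(log10(kappa_min), log10(kappa_max),
                      length.out = n_kappa))
  structure(list(kappa_grid = grid, kappa_min = kappa_min,
                 kappa_max = kappa_max, zero_tol = zero_tol,
                 asymptotic_tol = asymptotic_tol),
            class = "stability_config")
}

#' Mode Jacobian of the linearized metacommunity
#'
#' The growth rate of a spatial eigenmode with Laplacian eigenvalue
#' `kappa` is governed by `J = P - kappa * C`.
#'
#' @param P Local Jacobian matrix.
#' @param C Connectivity matrix (or `connectivity_matrix` object).
#' @param kappa Non-negative scalar.
#' @return The matrix `P - kappa * C`.
#' @export
mode_jacobian <- function(P, C, kappa) {
  C <- conn_mat(C)
  if (!all(dim(P) == dim(C)))
    stop("P and C must have identical dimensions")
  if (length(kappa) != 1L || kappa < 0) stop("kappa must be a scalar >= 0")
  P - kappa * C
}

#' Master stability function (dispersion relation)
#'
#' `lambda(kappa) = max Re eig(P - kappa C)` evaluated on the configured
#' `kappa` grid, together with the asymptotic large-`kappa` instability
#' flag (an eigenvalue of `C` with negative real part implies
#' `lambda(kappa) -> +Inf`).
#'
#' @inheritParams mode_jacobian
#' @param config A [stability_config()].
#' @return Object of class `msf`: list with `kappa`, `lam`, `lead_im`
#'   (imaginary part of the leading eigenvalue, to distinguish static
#'   from oscillatory onsets) and `asymptotically_unstable`.
#' @export
msf <- function(P, C, config = stability_config()) {
  C <- conn_mat(C)
  if (!all(dim(P) == dim(C)))
    stop("P and C must have identical dimensions")
  grid <- config$kappa_grid
  lam <- numeric(length(grid))
  lead_im <- numeric(length(grid))
  for (k in seq_along(grid)) {
    ev <- tryCatch(
      eigen(P - grid[k] * C, only.values = TRUE)$values,
      error = function(e)
        stop("eigenvalue computation failed at kappa = ", grid[k]))
    top <- which.max(Re(ev))
    lam[k] <- Re(ev[top])
    lead_im[k] <- Im(ev[top])
  }
  evC <- eigen(C, only.values = TRUE)$values
  structure(list(kappa = grid, lam = lam, lead_im = lead_im,
                 asymptotically_unstable =
                   min(Re(evC)) < -config$asymptotic_tol),
            class = "msf")
}

#' Classify a metacommunity as stable, unstable or pattern-forming
#'
#' Three-way taxonomy from the master stability function:
#' \describe{
#'   \item{unstable}{`lambda(0) > 0`: coexistence fails already on an
#'     isolated patch, hence on every network. This label depends only
#'     on `P`.}
#'   \item{pattern_forming}{`lambda(0) < 0` but `lambda(kappa) > 0` for
#'     some `kappa > 0` (on the grid or asymptotically): dispersal
#'     destabilizes a locally stable state on suitable networks
#'     (Turing-type instability via cross-diffusion).}
#'   \item{stable}{`lambda(kappa) < 0` everywhere: the homogeneous
#'     state survives on any network.}
#' }
#' Marginal local stability (`|lambda(0)| <= zero_tol`) is classified
#' by sign but flagged. Whether the leading eigenvalue at the maximum
#' of `lambda` is complex (oscillatory onset) is recorded but does not
#' split the pattern-forming class.
#'
#' @inheritParams msf
#' @return Object of class `dynamical_class`: list with `label` (one of
#'   `"stable"`, `"unstable"`, `"pattern_forming"`), `marginal`,
#'   `oscillatory` and `lambda0`.
#' @export
classify <- function(P, C, config = stability_config()) {
  m <- msf(P, C, config)
  zt <- config$zero_tol
  lambda0 <- m$lam[1L]
  if (lambda0 > zt) {
    label <- "unstable"
  } else if (max(m$lam) > zt || m$asymptotically_unstable) {
    label <- "pattern_forming"
  } else {
    label <- "stable"
  }
  top <- which.max(m$lam)
  structure(list(label = label,
                 marginal = abs(lambda0) <= zt,
                 oscillatory = label == "pattern_forming" &&
                   abs(m$lead_im[top]) > zt,
                 lambda0 = lambda0),
            class = "dynamical_class")
}

#' @export
print.dynamical_class <- function(x, ...) {
  cat("dynamical class:", x$label,
      if (x$marginal) "(marginal lambda(0))" else "",
      if (isTRUE(x$oscillatory)) "(oscillatory onset)" else "", "\n")
  invisible(x)
}

#' Export an msf curve as a two-column data frame
#'
#' @param x An `msf` object.
#' @param row.names,optional,... Unused.
#' @export
as.data.frame.msf <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(kappa = x$kappa, lambda = x$lam)
}

#' Plot a master stability function
#'
#' Dispersion relation on a log `kappa` axis (the `kappa = 0` point is
#' drawn at the left edge).
#'
#' @param x An `msf` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.msf <- function(x, ...) {
  kp <- x$kappa[-1L]
  graphics::plot(kp, x$lam[-1L], log = "x", type = "l",
                 xlab = expression(kappa),
                 ylab = expression(lambda(kappa)), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::points(min(kp), x$lam[1L], pch = 16)
  invisible(x)
}
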