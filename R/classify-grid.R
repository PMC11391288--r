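# Fast pairwise classification for three-species systems.
#
# For N = 3 the characteristic polynomial of J(kappa) = P - kappa*C is a
# cubic whose coefficients are themselves polynomials in kappa (degrees
# 1, 2, 3). By the Routh-Hurwitz criterion, J(kappa) has an eigenvalue
# with positive real part iff one of
#   c2(kappa) = -tr(J), c0(kappa) = -det(J), h = c2*c1 - c0
# is negative (c1 = sum of principal 2x2 minors). A dispersal-driven
# instability at some kappa in [kappa_min, kappa_max] therefore reduces
# to checking whether the minimum of each of these low-degree
# polynomials over the interval is negative; the minima are found
# analytically from the critical points. This is a continuous-interval
# refinement of evaluating lambda(kappa) on the log grid and is paired
# with the same asymptotic large-kappa test as `classify()`.

# vectorized minimum of k0 + k1 x + k2 x^2 + k3 x^3 over [a, b]
cubic_min_on <- function(k0, k1, k2, k3, a, b) {
  peval <- function(x) ((k3 * x + k2) * x + k1) * x + k0
  A <- 3 * k3
  Bq <- 2 * k2
  disc <- Bq * Bq - 4 * A * k1
  sq <- sqrt(pmax(disc, 0))
  r1 <- (-Bq - sq) / (2 * A)
  r2 <- (-Bq + sq) / (2 * A)
  # degenerate leading coefficient: derivative is linear
  rl <- -k1 / Bq
  deg <- A == 0
  if (any(deg)) {
    r1[deg] <- rl[deg]
    r2[deg] <- rl[deg]
  }
  r1[!is.finite(r1)] <- a
  r2[!is.finite(r2)] <- a
  r1 <- pmin(pmax(r1, a), b)
  r2 <- pmin(pmax(r2, a), b)
  pmin(peval(a), peval(b), peval(r1), peval(r2))
}

# does P - kappa*C have an eigenvalue with positive real part for some
# kappa in [a, b]?  P: 3x3 matrix; Ce: 9 x s matrix of C entries
# (column-major, one column per C draw). Returns logical vector.
pf_any_interval_3x3 <- function(P, Ce, a, b) {
  s <- ncol(Ce)
  if (s == 0L) return(logical(0))
  p11 <- P[1, 1]; p21 <- P[2, 1]; p31 <- P[3, 1]
  p12 <- P[1, 2]; p22 <- P[2, 2]; p32 <- P[3, 2]
  p13 <- P[1, 3]; p23 <- P[2, 3]; p33 <- P[3, 3]
  c11 <- Ce[1, ]; c21 <- Ce[2, ]; c31 <- Ce[3, ]
  c12 <- Ce[4, ]; c22 <- Ce[5, ]; c32 <- Ce[6, ]
  c13 <- Ce[7, ]; c23 <- Ce[8, ]; c33 <- Ce[9, ]

  # entries of J as linear polynomials m = (p, -c) in kappa;
  # (a0,a1)*(b0,b1) = (a0 b0, a0 b1 + a1 b0, a1 b1)
  # 2x2 minors needed for det and for c1 (quadratics q0,q1,q2):
  q1_0 <- p22 * p33 - p23 * p32
  q1_1 <- -p22 * c33 - c22 * p33 + p23 * c32 + c23 * p32
  q1_2 <- c22 * c33 - c23 * c32

  q2_0 <- p21 * p33 - p23 * p31
  q2_1 <- -p21 * c33 - c21 * p33 + p23 * c31 + c23 * p31
  q2_2 <- c21 * c33 - c23 * c31

  q3_0 <- p21 * p32 - p22 * p31
  q3_1 <- -p21 * c32 - c21 * p32 + p22 * c31 + c22 * p31
  q3_2 <- c21 * c32 - c22 * c31

  qa_0 <- p11 * p22 - p12 * p21
  qa_1 <- -p11 * c22 - c11 * p22 + p12 * c21 + c12 * p21
  qa_2 <- c11 * c22 - c12 * c21

  qb_0 <- p11 * p33 - p13 * p31
  qb_1 <- -p11 * c33 - c11 * p33 + p13 * c31 + c13 * p31
  qb_2 <- c11 * c33 - c13 * c31

  # det(J) = m11*Q1 - m12*Q2 + m13*Q3 (cubic d0..d3)
  d0 <- p11 * q1_0 - p12 * q2_0 + p13 * q3_0
  d1 <- p11 * q1_1 - c11 * q1_0 - (p12 * q2_1 - c12 * q2_0) +
    p13 * q3_1 - c13 * q3_0
  d2 <- p11 * q1_2 - c11 * q1_1 - (p12 * q2_2 - c12 * q2_1) +
    p13 * q3_2 - c13 * q3_1
  d3 <- -c11 * q1_2 + c12 * q2_2 - c13 * q3_2

  # c1 = sum of principal minors (quadratic), c2 = -tr(J) (linear)
  a0 <- qa_0 + qb_0 + q1_0
  a1 <- qa_1 + qb_1 + q1_1
  a2 <- qa_2 + qb_2 + q1_2
  t0 <- -(p11 + p22 + p33)
  t1 <- c11 + c22 + c33

  # h = c2 * c1 - c0 = c2 * c1 + det (cubic)
  h0 <- t0 * a0 + d0
  h1 <- t0 * a1 + t1 * a0 + d1
  h2 <- t0 * a2 + t1 * a1 + d2
  h3 <- t1 * a2 + d3

  min_c2 <- pmin(t0 + t1 * a, t0 + t1 * b)
  min_c0 <- cubic_min_on(-d0, -d1, -d2, -d3, a, b)
  min_h <- cubic_min_on(h0, h1, h2, h3, a, b)
  (min_c2 < 0) | (min_c0 < 0) | (min_h < 0)
}

# classify all (P draw, C draw) pairs of a 3-species grid.
# systems: list with elements $P, $lambda0; C_list: list of 3x3 matrices.
classify_pairs_3x3 <- function(systems, C_list, config) {
  n_P <- length(systems)
  n_C <- length(C_list)
  zt <- config$zero_tol
  at <- config$asymptotic_tol
  lam0 <- vapply(systems, `[[`, numeric(1), "lambda0")
  min_re_C <- vapply(C_list, function(C)
    min(Re(eigen(C, only.values = TRUE)$values)), numeric(1))
  labels <- matrix("stable", n_P, n_C)
  us <- lam0 > zt
  labels[us, ] <- "unstable"
  asy <- min_re_C < -at
  if (any(!us)) {
    labels[!us, asy] <- "pattern_forming"
    cand <- which(!asy)
    if (length(cand) > 0L) {
      Ce <- vapply(C_list[cand], as.vector, numeric(9))
      Ce <- matrix(Ce, nrow = 9L)
      for (i in which(!us)) {
        pf <- pf_any_interval_3x3(systems[[i]]$P, Ce,
                                  config$kappa_min, config$kappa_max)
        labels[i, cand[pf]] <- "pattern_forming"
      }
    }
  }
  labels
}
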