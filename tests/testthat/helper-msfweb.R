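# shared fixtures and independent oracles for the test suite

# hand-assembled food-chain parameters where only species 1 and 2 are
# effectively present (the third species is held at zero density)
two_species_chain_params <- function(r = 1, K = 1, A = 1, B = 1,
                                     e = 0.5, d = 0.1, d3 = 0.5) {
  m <- build_motif("food_chain")
  structure(list(motif = m,
                 r = c(r, NA, NA), K = c(K, NA, NA),
                 d = c(NA, d, d3),
                 A = c(A, 1), B = c(B, 1), e = c(e, 0.5)),
            class = "local_params")
}

# independent classification oracle: dense log grid of direct
# eigenvalue evaluations, wider than the package default
brute_classify <- function(P, C, n_grid = 2000, k_max = 1e4) {
  lambda0 <- max(Re(eigen(P, only.values = TRUE)$values))
  if (lambda0 > 1e-9) return("unstable")
  for (k in 10^seq(-4, log10(k_max), length.out = n_grid)) {
    if (max(Re(eigen(P - k * C, only.values = TRUE)$values)) > 1e-9)
      return("pattern_forming")
  }
  if (min(Re(eigen(C, only.values = TRUE)$values)) < -1e-9)
    return("pattern_forming")
  "stable"
}

# small cached batch of feasible systems per motif (shared across
# test files to avoid re-running the equilibrium search)
.sys_cache <- new.env(parent = emptyenv())
cached_systems <- function(motif, n = 40, seed = 77) {
  key <- paste(motif, n, seed)
  if (is.null(.sys_cache[[key]]))
    .sys_cache[[key]] <- sample_feasible_systems(motif, n, seed = seed)
  .sys_cache[[key]]
}
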