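test_that("mode Jacobian is P - kappa C", {
  P <- matrix(c(-1, 0, 0, -1), 2)
  C <- matrix(c(1, 2, 2, 1), 2)
  expect_equal(mode_jacobian(P, C, 0), P)
  expect_equal(mode_jacobian(P, C, 1), matrix(-2, 2, 2))
  expect_error(mode_jacobian(P, diag(3), 1), "dimensions")
  expect_error(mode_jacobian(P, C, -1), ">= 0")
})

test_that("msf matches closed forms for diagonal and symmetric cases", {
  cfg <- stability_config(n_kappa = 50)
  # diagonal P and C: lambda(kappa) = max(-1 - kappa, -2 - 3 kappa)
  m <- msf(diag(c(-1, -2)), diag(c(1, 3)), cfg)
  expect_equal(m$lam, pmax(-1 - m$kappa, -2 - 3 * m$kappa),
               tolerance = 1e-12)
  expect_true(all(diff(m$lam) < 0))
  expect_false(m$asymptotically_unstable)

  # C shares eigenvectors with I: lambda(kappa) = -1 + kappa
  m2 <- msf(-diag(2), matrix(c(1, 2, 2, 1), 2), cfg)
  expect_equal(m2$lam, -1 + m2$kappa, tolerance = 1e-12)
  expect_equal(m2$lam[1], -1)  # lambda(0) = spectral abscissa of P
  expect_true(m2$asymptotically_unstable)  # eig(C) = {3, -1}
})

test_that("msf values equal direct eigenvalue recomputation", {
  cfg <- stability_config(n_kappa = 60)
  fs <- cached_systems("food_chain", 5, seed = 13)
  S <- motif_sign_pattern("food_chain")
  pos <- cross_positions("food_chain")$positions
  set.seed(2)
  for (s in fs$systems[1:3]) {
    C <- sample_connectivity(S, pos)$C
    m <- msf(s$P, C, cfg)
    direct <- vapply(m$kappa, function(k)
      max(Re(eigen(s$P - k * C, only.values = TRUE)$values)), numeric(1))
    expect_equal(m$lam, direct, tolerance = 1e-12)
  }
})

test_that("classification follows the three-way taxonomy", {
  cfg <- stability_config(n_kappa = 100)
  # locally unstable: unstable regardless of C
  Pu <- matrix(c(0.5, 0, 0, -1), 2)
  expect_equal(classify(Pu, diag(2), cfg)$label, "unstable")
  expect_equal(classify(Pu, matrix(c(1, 5, 5, 1), 2), cfg)$label,
               "unstable")
  # pure shift: stable for all kappa
  expect_equal(classify(-diag(2), diag(2), cfg)$label, "stable")
  # crossing at kappa = 1
  cl <- classify(-diag(2), matrix(c(1, 2, 2, 1), 2), cfg)
  expect_equal(cl$label, "pattern_forming")
  expect_false(cl$marginal)
})

test_that("classification is invariant under species permutation", {
  fs <- cached_systems("intraguild_predation", 10, seed = 41)
  S <- motif_sign_pattern("intraguild_predation")
  pos <- cross_positions("intraguild_predation")$positions
  cfg <- stability_config(n_kappa = 100)
  set.seed(6)
  for (s in fs$systems[1:6]) {
    C <- sample_connectivity(S, pos)$C
    perm <- sample(3)
    l1 <- classify(s$P, C, cfg)$label
    l2 <- classify(s$P[perm, perm], C[perm, perm], cfg)$label
    expect_equal(l1, l2)
  }
})

test_that("uniform intraspecific diffusion never creates patterns", {
  # C = c*I is a pure spectral shift: lambda(kappa) = lambda(0) - c*kappa
  fs <- cached_systems("food_chain", 40, seed = 19)
  cfg <- stability_config(n_kappa = 100)
  stable <- Filter(function(s) s$lambda0 < -1e-9, fs$systems)
  set.seed(14)
  for (s in stable[seq_len(min(8, length(stable)))]) {
    cl <- classify(s$P, runif(1, 0.1, 2) * diag(3), cfg)
    expect_equal(cl$label, "stable")
  }
})

test_that("grid refinement leaves classifications essentially unchanged", {
  fs <- cached_systems("intraguild_predation", 40, seed = 77)
  S <- motif_sign_pattern("intraguild_predation")
  pos <- cross_positions("intraguild_predation")$positions
  coarse <- stability_config(n_kappa = 400)
  fine <- stability_config(n_kappa = 800)
  set.seed(21)
  Cs <- replicate(5, sample_connectivity(S, pos)$C, simplify = FALSE)
  changed <- 0L
  n <- 0L
  for (s in fs$systems) {
    for (C in Cs) {
      n <- n + 1L
      if (classify(s$P, C, coarse)$label != classify(s$P, C, fine)$label)
        changed <- changed + 1L
    }
  }
  expect_lte(changed / n, 0.005)
})

test_that("pairwise interval classifier agrees with the grid classifier", {
  cfg <- stability_config()
  for (nm in c("food_chain", "intraguild_predation")) {
    fs <- cached_systems(nm, 20, seed = 91)
    S <- motif_sign_pattern(nm)
    pos <- cross_positions(nm)$positions
    set.seed(33)
    Cs <- replicate(20, sample_connectivity(S, pos)$C, simplify = FALSE)
    fast <- msfweb:::classify_pairs_3x3(fs$systems, Cs, cfg)
    slow <- matrix("", 20, 20)
    for (i in 1:20) for (j in 1:20)
      slow[i, j] <- classify(fs$systems[[i]]$P, Cs[[j]], cfg)$label
    expect_gte(mean(fast == slow), 0.995)
  }
})

test_that("pairwise classifier agrees with an independent dense-grid oracle", {
  cfg <- stability_config()
  fs <- cached_systems("food_chain", 12, seed = 47)
  S <- motif_sign_pattern("food_chain")
  pos <- cross_positions("food_chain")$positions
  set.seed(52)
  Cs <- replicate(12, sample_connectivity(S, pos)$C, simplify = FALSE)
  fast <- msfweb:::classify_pairs_3x3(fs$systems, Cs, cfg)
  mismatch <- 0L
  for (i in 1:12) for (j in 1:12) {
    if (brute_classify(fs$systems[[i]]$P, Cs[[j]]) != fast[i, j])
      mismatch <- mismatch + 1L
  }
  expect_lte(mismatch / 144, 0.005)
})

test_that("the unstable label depends only on P", {
  fs <- cached_systems("apparent_competition", 60, seed = 64)
  us <- Filter(function(s) s$lambda0 > 1e-9, fs$systems)
  expect_gt(length(us), 0)
  S <- motif_sign_pattern("apparent_competition")
  pos <- cross_positions("apparent_competition")$positions
  cfg <- stability_config(n_kappa = 50)
  set.seed(3)
  for (C in replicate(5, sample_connectivity(S, pos)$C,
                      simplify = FALSE))
    expect_equal(classify(us[[1]]$P, C, cfg)$label, "unstable")
})

test_that("msf exports as a two-column curve", {
  m <- msf(-diag(2), diag(2), stability_config(n_kappa = 10))
  df <- as.data.frame(m)
  expect_named(df, c("kappa", "lambda"))
  expect_equal(nrow(df), 11L)
})
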