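test_that("canonical motif topologies match the four feeding structures", {
  fc <- build_motif("food_chain")
  expect_equal(unname(fc$links), rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(fc$roles,
               c("producer", "intermediate_consumer", "top_consumer"))

  igp <- build_motif("intraguild_predation")
  expect_equal(nrow(igp$links), 3L)
  expect_equal(unname(igp$links), rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))

  for (nm in motif_names()) {
    m <- build_motif(nm)
    expect_equal(nrow(m$links),
                 if (nm == "intraguild_predation") 3L else 2L)
    # every species appears in at least one link
    expect_setequal(unique(as.vector(m$links)), 1:3)
    # producers are never predators
    expect_false(any(m$roles[m$links[, "predator"]] == "producer"))
    # species 1 is always a producer
    expect_equal(m$roles[1], "producer")
  }
})

test_that("unknown motif names raise an error listing valid options", {
  expect_error(build_motif("foodchain "), "food_chain.*intraguild_predation")
  expect_error(build_motif(42), "valid motifs")
})

test_that("local dynamics vanish at boundary fixed points", {
  p <- two_species_chain_params()
  # producer alone at carrying capacity, consumers absent
  expect_equal(local_rhs(p, c(1, 0, 0)), rep(0, 3))
  # extinction state
  expect_equal(local_rhs(p, c(0, 0, 0)), rep(0, 3))
})

test_that("local dynamics reproduce a hand-evaluated rate", {
  p <- two_species_chain_params(r = 1, K = 1, A = 1, B = 1, e = 0.5,
                                d = 0.1)
  f <- local_rhs(p, c(0.5, 0.5, 0))
  # producer: 0.5 * (1*(1 - 0.5) - 1*0.5/(1 + 0.5)) = 1/12
  expect_equal(f[1], 0.5 * (0.5 - 0.5 / 1.5), tolerance = 1e-12)
  expect_equal(f[1], 1 / 12, tolerance = 1e-12)
  # consumer: 0.5 * (0.5*1*0.5/1.5 - 0.1*0.5)
  expect_equal(f[2], 0.5 * (0.5 * 0.5 / 1.5 - 0.05), tolerance = 1e-12)
})

test_that("negative densities are rejected", {
  p <- two_species_chain_params()
  expect_error(local_rhs(p, c(-0.1, 0.5, 0)), "negative")
  expect_error(local_rhs_jacobian(p, c(-0.1, 0.5, 0)), "non-negative")
})

test_that("feasible equilibria satisfy the residual oracle", {
  for (nm in c("food_chain", "intraguild_predation")) {
    fs <- cached_systems(nm, 20, seed = 31)
    for (s in fs$systems) {
      expect_true(s$eq$feasible)
      expect_gt(min(s$eq$x_star), 1e-6)
      expect_lt(max(abs(local_rhs(s$params, s$eq$x_star))), 1e-9)
    }
  }
})

test_that("quadratic mortality lets a weakly fed consumer persist at low density", {
  # per-capita mortality d*x vanishes as x -> 0, so any positive gain
  # supports a (small) positive consumer density: exclusion by
  # starvation cannot happen under this closure
  p <- two_species_chain_params(A = 1, B = 1, e = 0.05, d = 1)
  set.seed(4)
  eq <- find_equilibrium(p)
  expect_true(eq$feasible)
  expect_lt(eq$x_star[2], 0.05)

  skip_if_not_installed("deSolve")
  # independent oracle: time-stepping settles on the same state
  out <- deSolve::ode(
    y = c(0.5, 0.5, 0.1), times = seq(0, 2000, by = 100),
    func = function(t, x, parms) list(local_rhs(p, pmax(x, 0))),
    parms = NULL)
  expect_equal(unname(out[nrow(out), -1]), eq$x_star, tolerance = 1e-4)
})

test_that("overexploitation collapse yields an infeasible equilibrium", {
  m <- build_motif("apparent_competition")
  p <- structure(list(motif = m, r = c(1, 0.05, NA), K = c(5, 1, NA),
                      d = c(NA, NA, 0.05), A = c(2, 5), B = c(1, 0.5),
                      e = c(0.8, 0.9)), class = "local_params")
  set.seed(4)
  eq <- find_equilibrium(p)
  expect_false(eq$feasible)

  skip_if_not_installed("deSolve")
  # independent oracle: the flow runs into the boundary (producers
  # crash), so no interior steady state is reachable
  out <- deSolve::ode(
    y = c(1, 0.5, 0.2), times = seq(0, 5000, by = 250),
    func = function(t, x, parms) list(local_rhs(p, pmax(x, 0))),
    parms = NULL)
  expect_lt(min(abs(out[nrow(out), 2:3])), 1e-6)
})

test_that("analytic Jacobian agrees with central finite differences", {
  fs <- cached_systems("intraguild_predation", 10, seed = 55)
  for (s in fs$systems[1:5]) {
    x <- s$eq$x_star
    J <- local_rhs_jacobian(s$params, x)
    h <- 1e-6
    Jfd <- sapply(1:3, function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h
      xm[j] <- xm[j] - h
      (local_rhs(s$params, xp) - local_rhs(s$params, xm)) / (2 * h)
    })
    expect_lt(max(abs(J - Jfd) / (abs(J) + 1)), 1e-6)
  }
})

test_that("producer-only reduction has Jacobian entry -r at x = K", {
  p <- two_species_chain_params(r = 1.7, K = 2.5)
  J <- local_rhs_jacobian(p, c(2.5, 0, 0))
  expect_equal(J[1, 1], -1.7, tolerance = 1e-12)
})

test_that("Jacobian sign pattern matches the motif at feasible equilibria", {
  for (nm in motif_names()) {
    fs <- cached_systems(nm, 40, seed = 19)
    for (s in fs$systems) {
      for (l in seq_len(nrow(s$params$motif$links))) {
        prey <- s$params$motif$links[l, 1L]
        pred <- s$params$motif$links[l, 2L]
        expect_gt(s$P[pred, prey], 0)
        expect_lt(s$P[prey, pred], 0)
      }
    }
  }
})

test_that("relabelling species permutes the Jacobian identically", {
  fs <- cached_systems("intraguild_predation", 10, seed = 23)
  perm <- c(2L, 3L, 1L)  # new index of each old species
  for (s in fs$systems[1:5]) {
    m <- s$params$motif
    m2 <- structure(list(
      name = m$name,
      links = matrix(perm[m$links], ncol = 2L,
                     dimnames = list(NULL, c("prey", "predator"))),
      roles = m$roles[order(perm)], n_species = 3L),
      class = "motif_topology")
    p2 <- s$params
    p2$motif <- m2
    p2$r <- s$params$r[order(perm)]
    p2$K <- s$params$K[order(perm)]
    p2$d <- s$params$d[order(perm)]
    x2 <- s$eq$x_star[order(perm)]
    J1 <- local_rhs_jacobian(s$params, s$eq$x_star)
    J2 <- local_rhs_jacobian(p2, x2)
    expect_equal(J2[perm, perm], unname(J1), tolerance = 1e-12)
  }
})

test_that("parameter sampling respects bounds and is seed-deterministic", {
  cfg <- local_param_config()
  set.seed(9)
  for (i in 1:50) {
    p <- sample_local_parameters("intraguild_predation", cfg)
    prod <- which(p$motif$roles == "producer")
    cons <- which(p$motif$roles != "producer")
    expect_true(all(p$r[prod] >= cfg$r[1] & p$r[prod] <= cfg$r[2]))
    expect_true(all(p$K[prod] >= cfg$K[1] & p$K[prod] <= cfg$K[2]))
    expect_true(all(p$d[cons] >= cfg$d[1] & p$d[cons] <= cfg$d[2]))
    expect_true(all(p$e >= cfg$e[1] & p$e <= cfg$e[2]))
    expect_true(all(is.na(p$r[cons])) && all(is.na(p$d[prod])))
  }
  set.seed(123)
  a <- sample_local_parameters("food_chain")
  set.seed(123)
  b <- sample_local_parameters("food_chain")
  expect_identical(a, b)
})

test_that("sampled conversion efficiencies have the uniform mean", {
  set.seed(61)
  e <- replicate(5000,
    sample_local_parameters("food_chain")$e)  # 2 links per draw
  e <- as.vector(e)
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - 0.55), 3 * se)
})

test_that("degenerate sampling bounds are rejected", {
  expect_error(local_param_config(e = c(1, 0.1)), "lower < upper")
  expect_error(local_param_config(K = c(2, 2)), "lower < upper")
})

test_that("feasible systems export as flat rows", {
  fs <- cached_systems("food_chain", 20, seed = 31)
  df <- as.data.frame(fs)
  expect_equal(nrow(df), 20L)
  expect_true(all(c("motif", "x_star1", "residual", "lambda0") %in%
                  names(df)))
  expect_true(all(df$residual < 1e-9))
})
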