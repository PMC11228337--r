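test_that("genetic covariance is D R D with h2 on the diagonal", {
  p2 <- sim_params(c("A", "B"), h2 = c(1, 1), genetic_cor = diag(2),
                   accuracy = c(0.5, 0.5))
  expect_equal(unname(genetic_covariance(p2)), diag(2))
  pw <- sim_params(c("YLD", "TKW"), h2 = c(0.21, 0.50),
                   genetic_cor = matrix(c(1, -0.21, -0.21, 1), 2, 2),
                   accuracy = c(0.29, 0.39))
  S <- genetic_covariance(pw)
  expect_equal(S["YLD", "TKW"], -0.21 * sqrt(0.21 * 0.50), tolerance = 1e-12)
  expect_equal(round(S["YLD", "TKW"], 4), -0.0680)
  expect_equal(diag(S), c(YLD = 0.21, TKW = 0.50))
})

test_that("the packaged wheat parameter set is valid and matches its sources", {
  p <- wheat_params()
  expect_equal(p$traits, c("YLD", "TKW", "Prot", "Screen", "Sr", "Yr", "Lr"))
  expect_equal(unname(p$h2["Yr"]), 0.59)
  expect_equal(unname(p$h2["YLD"]), 0.21)
  expect_equal(unname(p$accuracy["YLD"]), 0.29)
  expect_equal(unname(p$accuracy["Yr"]), 0.47)
  expect_equal(p$genetic_cor["TKW", "Screen"], -0.61)
  expect_equal(p$m_ref, 3331L)
  expect_equal(p$m_cand, 3005L)
  S <- genetic_covariance(p)
  expect_true(isSymmetric(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("parameter validation rejects degenerate inputs", {
  R <- diag(2)
  expect_error(sim_params(c("A", "A"), c(0.5, 0.5), R, c(0.5, 0.5)),
               "unique")
  expect_error(sim_params(c("A", "B"), c(0.5, 1.2), R, c(0.5, 0.5)),
               "h2")
  expect_error(sim_params(c("A", "B"), c(0.5, 0.5), R, c(0.5, 0)),
               "accuracy")
  bad <- matrix(c(1, 0.9, 0.2, 1), 2, 2)
  expect_error(sim_params(c("A", "B"), c(0.5, 0.5), bad, c(0.5, 0.5)),
               "symmetric")
  nonpsd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sim_params(c("A", "B"), c(0.5, 0.5), nonpsd, c(0.5, 0.5)),
               "eigenvalue")
})

test_that("perfect accuracy makes GEBVs equal true breeding values", {
  p <- sim_params(c("A", "B"), h2 = c(0.4, 0.6),
                  genetic_cor = matrix(c(1, 0.3, 0.3, 1), 2, 2),
                  accuracy = c(1, 1))
  pop <- simulate_gebv(p, m = 50, seed = 30)
  expect_equal(pop$gebv, pop$tbv, tolerance = 1e-12)
})

test_that("simulated GEBVs reproduce the accuracy and variance they promise", {
  p1 <- sim_params("A", h2 = 1, genetic_cor = matrix(1), accuracy = 0.5)
  pop <- simulate_gebv(p1, m = 200000, seed = 31)
  expect_equal(cor(pop$gebv[, 1], pop$tbv[, 1]), 0.5, tolerance = 0.005)
  expect_equal(var(pop$gebv[, 1]), 0.25 * 1, tolerance = 0.01)
})

test_that("breeding-value correlations reproduce the generating structure", {
  p <- wheat_params()
  pop <- simulate_gebv(p, m = 100000, seed = 32)
  emp <- cor(pop$tbv)
  # 3 SE of a correlation at m = 1e5 is about 0.01
  expect_lt(max(abs(emp - p$genetic_cor)), 0.015)
  # GEBV cross-correlations are the genetic ones shrunk by r_j * r_k
  shrunk <- p$genetic_cor * outer(p$accuracy, p$accuracy)
  diag(shrunk) <- 1
  expect_lt(max(abs(cor(pop$gebv) - shrunk)), 0.015)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  p <- wheat_params()
  a <- simulate_gebv(p, m = 100, seed = 33)
  b <- simulate_gebv(p, m = 100, seed = 33)
  expect_identical(a$gebv, b$gebv)
  expect_identical(a$tbv, b$tbv)
})

test_that("simulator agrees with an independent multivariate-normal oracle", {
  skip_if_not_installed("MASS")
  p <- wheat_params()
  S <- genetic_covariance(p)
  set.seed(34)
  oracle <- MASS::mvrnorm(50000, mu = rep(0, 7), Sigma = S)
  pop <- simulate_gebv(p, m = 50000, seed = 35)
  expect_equal(cov(pop$tbv), cov(oracle), tolerance = 0.05)
})

test_that("empirical P is the GEBV correlation matrix with guards", {
  set.seed(36)
  x <- rnorm(100)
  m <- cbind(a = x, b = x, c = -x + 0, d = rnorm(100))
  P <- empirical_P(m)
  expect_equal(P["a", "b"], 1)
  expect_equal(P["a", "c"], -1)
  expect_equal(diag(P), c(a = 1, b = 1, c = 1, d = 1))
  expect_error(empirical_P(cbind(a = rep(1, 50), b = rnorm(50))),
               "zero-variance.*a")
  expect_error(empirical_P(matrix(rnorm(6), 2, 3)), "more individuals")
  # simulated fixture: empirical P tracks the shrunk generating structure
  p <- wheat_params()
  pop <- simulate_gebv(p, m = 50000, seed = 37)
  shrunk <- p$genetic_cor * outer(p$accuracy, p$accuracy)
  diag(shrunk) <- 1
  expect_lt(max(abs(empirical_P(pop$gebv) - shrunk)), 0.02)
})
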