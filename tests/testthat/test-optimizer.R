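test_that("zero iterations reproduce the classical no-iteration index", {
  st <- small_study(m_ref = 300, m_cand = 0, seed = 5)
  dg <- wheat_targets()$equal
  f0 <- dgi(st$ref, dg, st$G, n_select = 30, iterations = 0)
  fb <- dgi_baseline(st$ref, dg, st$G, n_select = 30)
  expect_equal(f0$d, fb$d)
  expect_equal(f0$b, fb$b)
  expect_equal(f0$response, fb$response)
  expect_equal(f0$theta, fb$theta)
  # the fit *is* its own baseline
  expect_equal(fb$response, fb$baseline$response)
  expect_equal(unname(fb$d), unname(dg))
  # and the baseline b solves the index equation at d = dg
  expect_equal(unname(expected_gains(st$G, fb$b)), unname(dg),
               tolerance = 1e-8)
})

test_that("accepted penalties never increase and end at or below the baseline", {
  st <- small_study(m_ref = 500, m_cand = 0, seed = 6)
  fit <- dgi(st$ref, wheat_targets()$equal, st$G, n_select = 50,
             iterations = 300, seed = 8)
  tr <- fit$trajectory
  acc <- tr$theta[tr$accepted]
  expect_true(all(diff(acc) < 0))            # strict acceptance
  expect_equal(fit$theta, min(acc))
  expect_lte(fit$theta, fit$baseline$theta)
  expect_equal(fit$theta, theta_penalty(fit$response, fit$target))
  # invariant: returned b matches the returned d through the index equation
  expect_equal(fit$b, dg_weights(st$G, fit$P, fit$d), tolerance = 1e-10)
})

test_that("a fixed seed makes the whole fit bit-reproducible", {
  st <- small_study(m_ref = 300, m_cand = 0, seed = 9)
  f1 <- dgi(st$ref, wheat_targets()$equal, st$G, n_select = 30,
            iterations = 100, seed = 123)
  f2 <- dgi(st$ref, wheat_targets()$equal, st$G, n_select = 30,
            iterations = 100, seed = 123)
  f2$call <- f1$call
  expect_identical(f1, f2)
})

test_that("single-trait fits are ranking-invariant: flat trajectory at the
           truncation-selection intensity", {
  set.seed(13)
  m <- 3000
  gebv <- matrix(rnorm(m), m, 1, dimnames = list(NULL, "T1"))
  fit <- dgi(gebv, target = 0.5, G = matrix(1), P = matrix(1),
             n_select = 100, iterations = 100, seed = 14)
  # any d > 0 yields the same ranking, hence the same theta; strict
  # acceptance therefore never fires after the start
  expect_false(any(fit$trajectory$accepted[-1]))
  expect_equal(unname(fit$d), 0.5)
  # the 0.5-SD target is unreachable: the top 100/3000 sit at the
  # truncated-normal mean regardless of d
  p <- 100 / m
  expect_equal(unname(fit$response), dnorm(qnorm(1 - p)) / p,
               tolerance = 0.1)
})

test_that("a vanishing proposal SD pins the search at the target d", {
  st <- small_study(m_ref = 300, m_cand = 0, seed = 15)
  fit <- dgi(st$ref, wheat_targets()$equal, st$G, n_select = 30,
             iterations = 50, proposal_sd = 1e-12, seed = 16)
  expect_equal(unname(fit$d), unname(wheat_targets()$equal),
               tolerance = 1e-9)
  expect_equal(max(abs(fit$trajectory$theta - fit$baseline$theta)), 0,
               tolerance = 1e-6)
})

test_that("input violations are caught before any iteration", {
  st <- small_study(m_ref = 100, m_cand = 0, seed = 17)
  dg <- wheat_targets()$equal
  expect_error(dgi(st$ref, c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5, 0), st$G),
               "zero")
  expect_error(dgi(st$ref, c(dg[-7], bad = -0.5), st$G), "labels disagree")
  expect_error(dgi(st$ref, unname(dg)[-1], st$G), "length")
  expect_error(dgi(st$ref[, -1], dg, st$G), "trait")
  ref_na <- st$ref; ref_na[1, 1] <- NA
  expect_error(dgi(ref_na, dg, st$G), "missing")
})

test_that("candidate and reference responses agree for exchangeable populations", {
  st <- small_study(m_ref = 2500, m_cand = 2500, seed = 18)
  dg <- wheat_targets()$yield_dominant
  fit <- dgi(st$ref, dg, st$G, n_select = 80, iterations = 300, seed = 19)
  cand <- predict(fit, st$cand)
  # same generating distribution: responses differ only by sampling error
  expect_lt(mean(abs(cand$response - fit$response)), 0.25)
  expect_equal(sign(cand$response), sign(fit$response))
})

test_that("replicate runs are deterministic, consistent and symmetric", {
  st <- small_study(m_ref = 400, m_cand = 300, seed = 20)
  dg <- wheat_targets()$yield_dominant
  r1 <- dgi_replicates(st$ref, st$cand, dg, st$G, replicates = 3,
                       seed = 100, n_select = 40, iterations = 100)
  r2 <- dgi_replicates(st$ref, st$cand, dg, st$G, replicates = 3,
                       seed = 100, n_select = 40, iterations = 100)
  expect_equal(r1$scores, r2$scores)
  expect_equal(r1$mean_cor, r2$mean_cor)
  expect_true(isSymmetric(r1$cor))
  expect_true(all(diag(r1$cor) == 1))
  expect_gte(r1$mean_cor, -1); expect_lte(r1$mean_cor, 1)
  # rank-based consistency is available too
  rs <- dgi_replicates(st$ref, st$cand, dg, st$G, replicates = 2,
                       seed = 100, n_select = 40, iterations = 100,
                       cor_method = "spearman")
  expect_true(is.finite(rs$mean_cor))
  expect_error(dgi_replicates(st$ref, st$cand, dg, st$G, replicates = 1),
               "at least 2")
})

test_that("summary, coef, residuals and plot expose the fit coherently", {
  st <- small_study(m_ref = 300, m_cand = 200, seed = 21)
  fit <- dgi(st$ref, wheat_targets()$equal, st$G, n_select = 30,
             iterations = 50, seed = 22)
  s <- summary(fit, candidates = st$cand)
  expect_named(s$table, c("Trait", "Sampled_d", "Index_b", "Target_dg",
                          "Response_NoIteration", "Response_Ref",
                          "Response_Cand"))
  expect_equal(nrow(s$table), 7)
  expect_equal(s$table$Target_dg, unname(wheat_targets()$equal))
  expect_equal(coef(fit), fit$b)
  expect_equal(residuals(fit), fit$response - fit$target)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
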