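# Model assembly, deviance, Gibbs sampler contracts.

test_that("Model 1 assembly yields the five variance sources", {
  sim <- simulate_study(small_sim_config(seed = 21))
  asm <- assemble_mmmc(model1_spec(), sim$children, weights = sim$weights)
  expect_equal(asm$variance_sources,
               c("neighbourhood", "school", "triad", "dyad", "individual"))
  expect_equal(length(asm$classes), 4L)
  expect_false(asm$classes$school$multiple)
  expect_true(asm$classes$dyad$multiple)
  # cross-classified by construction: some schools span several neighbourhoods
  tab <- table(sim$children$school_id, sim$children$neighbourhood_id)
  expect_true(all(rowSums(tab > 0) >= 2))
})

test_that("a spec with no classifications reduces to intercept-only regression", {
  d <- data.frame(child_id = c("a", "b", "c"), y = c(1, 2, 3))
  asm <- assemble_mmmc(mmmc_spec(), d)
  expect_equal(length(asm$classes), 0L)
  expect_equal(asm$variance_sources, "individual")
  expect_equal(unname(asm$X[, 1]), rep(1, 3))
})

test_that("dyad incidence matches a hand-built matrix and the weighted-sum contract", {
  toy <- toy_assembled()
  Z <- as.matrix(toy$assembled$classes$dyad$Z)
  # A and B share dyad 1 with weight 1: identical incidence rows
  expect_equal(Z[1, ], Z[2, ])
  expect_equal(unname(Z[1, ]), c(1, 0, 0))
  # C: weights (1/2, 1/2) on dyads 2 and 3
  expect_equal(unname(Z[3, ]), c(0, 0.5, 0.5))
  # D friendless: exactly zero contribution at this level
  expect_equal(unname(Z[4, ]), c(0, 0, 0))
  # linear predictor contribution is the weighted sum of clique effects
  u <- c(10, -4, 6)
  expect_equal(as.numeric(Z %*% u), c(10, 10, (-4 + 6) / 2, 0))
})

test_that("missing covariates are rejected at assembly", {
  d <- data.frame(child_id = c("a", "b"), y = c(1, 2),
                  gender = c("boy", "girl"), x = c(1, NA))
  sp <- mmmc_spec(fixed = c("gender", "x"))
  expect_error(assemble_mmmc(sp, d), "complete_case_filter")
  expect_error(assemble_mmmc(mmmc_spec(classifications = list(g = "nope")),
                             data.frame(child_id = "a", y = 1)), "not found")
})

test_that("deviance matches closed forms and a direct density oracle", {
  d1 <- data.frame(child_id = "a", y = 0)
  asm1 <- assemble_mmmc(mmmc_spec(), d1)
  expect_equal(mmmc_deviance(asm1, beta = 0, sigma2_e = 1), log(2 * pi),
               tolerance = 1e-12)

  # doubling the residual variance: D(2s2) - D(s2) = n log 2 - SSR / (2 s2)
  set.seed(421)
  n <- 20
  d <- data.frame(child_id = sprintf("c%d", 1:n), y = rnorm(n, 5, 2))
  asm <- assemble_mmmc(mmmc_spec(), d)
  s2 <- 3.7
  ssr <- sum((d$y - 4)^2)
  expect_equal(mmmc_deviance(asm, 4, sigma2_e = 2 * s2) -
                 mmmc_deviance(asm, 4, sigma2_e = s2),
               n * log(2) - ssr / (2 * s2), tolerance = 1e-9)

  # random small model vs independent log-density summation
  toy <- toy_assembled()
  u <- list(dyad = c(1.5, -2, 0.7))
  beta <- 2.2
  mu <- beta + as.numeric(toy$assembled$classes$dyad$Z %*% u$dyad)
  s2g <- c(boy = 4, girl = 9)
  sd_i <- sqrt(s2g[c(1, 2, 1, 2)])
  expect_equal(mmmc_deviance(toy$assembled, beta, u, s2g),
               -2 * sum(dnorm(toy$data$y, mu, sd_i, log = TRUE)),
               tolerance = 1e-9)
})

test_that("chains are bit-identical for a fixed seed", {
  sim <- simulate_study(small_sim_config(seed = 22))
  asm <- assemble_mmmc(model1_spec(), sim$children, weights = sim$weights)
  f1 <- fit_mmmc(asm, mcmc_options(seed = 9, burn_in = 20, iterations = 40))
  f2 <- fit_mmmc(asm, mcmc_options(seed = 9, burn_in = 20, iterations = 40))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$deviance, f2$deviance)
  expect_identical(f1$classes$dyad$draws, f2$classes$dyad$draws)
  f3 <- fit_mmmc(asm, mcmc_options(seed = 10, burn_in = 20, iterations = 40))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("posterior summaries are invariant to consistent row permutation", {
  sim <- simulate_study(small_sim_config(seed = 23))
  ch <- sim$children
  asm <- assemble_mmmc(model1_spec(), ch, weights = sim$weights)
  f1 <- fit_mmmc(asm, mcmc_options(seed = 4, burn_in = 100, iterations = 300))
  set.seed(424)
  perm <- sample(nrow(ch))
  asm2 <- assemble_mmmc(model1_spec(), ch[perm, ], weights = sim$weights)
  f2 <- fit_mmmc(asm2, mcmc_options(seed = 4, burn_in = 100, iterations = 300))
  # same model, so posterior means agree within Monte-Carlo error
  expect_equal(mean(f1$classes$school$draws), mean(f2$classes$school$draws),
               tolerance = 0.25)
  expect_equal(mean(f1$residual), mean(f2$residual), tolerance = 0.1)
})

test_that("intercept-only posterior matches the analytic conjugate posterior", {
  set.seed(425)
  n <- 50
  y <- rnorm(n, 10, 3)
  d <- data.frame(child_id = sprintf("c%d", 1:n), y = y)
  asm <- assemble_mmmc(mmmc_spec(), d)
  # thinned so the KS test's iid assumption holds for the draws compared
  fit <- fit_mmmc(asm, mcmc_options(seed = 6, burn_in = 500, iterations = 15000,
                                    thin = 5,
                                    priors = mmmc_priors(variance_shape = 0.001,
                                                         variance_rate = 0.001)))
  a <- 0.001; b <- 0.001
  ss <- sum((y - mean(y))^2)
  # sigma2 | y ~ Inv-Gamma(a + (n-1)/2, b + ss/2)
  ks_s2 <- ks.test(fit$residual[, 1],
                   function(q) 1 - pgamma(1 / q, a + (n - 1) / 2, rate = b + ss / 2))
  expect_gt(ks_s2$p.value, 0.001)
  # beta | y ~ t_{2a+n-1}(ybar, scale)
  df <- 2 * a + n - 1
  scale <- sqrt((2 * b + ss) / (n * df))
  ks_b <- ks.test((fit$beta[, 1] - mean(y)) / scale, "pt", df = df)
  expect_gt(ks_b$p.value, 0.001)
})

test_that("variance components are recovered in a balanced nested design", {
  set.seed(426)
  n_s <- 50; per <- 25
  d <- data.frame(child_id = sprintf("c%d", 1:(n_s * per)),
                  school_id = rep(sprintf("s%d", 1:n_s), each = per))
  u <- rnorm(n_s, 0, sqrt(66))
  d$y <- 60 + u[rep(1:n_s, each = per)] + rnorm(nrow(d), 0, sqrt(415))
  asm <- assemble_mmmc(mmmc_spec(classifications = list(school = "school_id")), d)
  fit <- fit_mmmc(asm, mcmc_options(seed = 7, burn_in = 300, iterations = 1200))
  s2s <- fit$classes$school$draws[, 1]
  # truth within 2 posterior SDs
  expect_lt(abs(mean(s2s) - 66), 2 * sd(s2s) + 1e-9)
  s2e <- fit$residual[, 1]
  expect_lt(abs(mean(s2e) - 415), 2 * sd(s2e) + 1e-9)
})

test_that("MM posterior matches deterministic grid integration of the marginal", {
  # y ~ N(b0, s2d * Z Z' + s2e I): integrate b0 analytically, put the exact
  # posterior of (s2d, s2e) on a log grid, and compare the Gibbs sampler
  set.seed(427)
  n <- 200
  ids <- sprintf("c%d", 1:n)
  noms <- do.call(rbind, lapply(1:n, function(i)
    data.frame(nominator_id = ids[i], nominee_id = sample(ids[-i], 2))))
  net <- build_adjacency(noms, ids)
  w2 <- build_weight_matrix(net, enumerate_cliques(net, 2), "dyad")
  ud <- rnorm(length(w2$groups), 0, 10)
  sw <- w2$weights
  contrib <- tapply(sw$weight * ud[sw$group], sw$child_id, sum)
  cv <- numeric(n); names(cv) <- ids; cv[names(contrib)] <- contrib
  y <- 50 + cv + rnorm(n, 0, 5)
  d <- data.frame(child_id = ids, y = y)
  asm <- assemble_mmmc(mmmc_spec(classifications = list(dyad = "weights")), d,
                       weights = list(dyad = w2))

  Z <- as.matrix(asm$classes$dyad$Z)
  ZZt <- Z %*% t(Z)
  one <- rep(1, n)
  loglik <- function(s2d, s2e) {
    ch <- chol(s2d * ZZt + diag(s2e, n))
    Vi_y <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    Vi_1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
    A <- sum(one * Vi_1)
    r <- y - (sum(one * Vi_y) / A) * one
    Vi_r <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
    -sum(log(diag(ch))) - 0.5 * sum(r * Vi_r) - 0.5 * log(A)
  }
  a <- 0.001; b <- 0.001
  lp <- function(s2) (-a - 1) * log(s2) - b / s2
  # wide enough that the joint posterior (including mass near zero for the
  # weakly identified dyad variance) is covered
  g_d <- exp(seq(log(0.2), log(2000), length = 110))
  g_e <- exp(seq(log(1), log(300), length = 110))
  L <- outer(seq_along(g_d), seq_along(g_e), Vectorize(function(i, j)
    loglik(g_d[i], g_e[j]) + lp(g_d[i]) + lp(g_e[j])))
  L <- exp(L - max(L))
  post <- L * outer(g_d, g_e)                 # log-grid Jacobian
  post <- post / sum(post)
  gmedian <- function(marg, grid) grid[which.min(abs(cumsum(marg) - 0.5))]
  oracle_d <- gmedian(rowSums(post), g_d)
  oracle_e <- gmedian(colSums(post), g_e)

  fit <- fit_mmmc(asm, mcmc_options(seed = 11, burn_in = 3000, iterations = 25000,
                                    priors = mmmc_priors(a, b)))
  # medians: robust for this heavy-tailed, weakly identified posterior
  expect_lt(abs(median(fit$classes$dyad$draws) - oracle_d) / oracle_d, 0.15)
  expect_lt(abs(median(fit$residual) - oracle_e) / oracle_e, 0.15)
})
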