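test_that("kernel construction matches a brute-force elementwise oracle", {
  G <- random_grel(6, seed = 2)
  recs <- data.frame(individual = c("i1", "i3", "i5", "i1", "i3", "i6"),
                     environment = rep(c("PAL", "SRO"), each = 3))
  for (model in c("MM", "MDs", "MDe")) {
    ks <- build_kernels(G, recs, model)
    n <- nrow(recs)
    for (role in ks$kernel_roles) {
      K <- ks$kernels[[role]]
      for (r in seq_len(n))
        for (s in seq_len(n)) {
          g <- G$G[recs$individual[r], recs$individual[s]]
          expected <- switch(
            sub(":.*", "", role),
            main = g,
            gxe_common = g * (recs$environment[r] == recs$environment[s]),
            gxe_env = g * (recs$environment[r] == sub(".*:", "", role)) *
              (recs$environment[s] == sub(".*:", "", role)))
          expect_equal(K[r, s], expected, tolerance = 1e-12)
        }
    }
  }
  # MDe kernels sum to the MDs G-by-E kernel exactly
  mds <- build_kernels(G, recs, "MDs")
  mde <- build_kernels(G, recs, "MDe")
  expect_equal(mde$kernels[["gxe_env:PAL"]] + mde$kernels[["gxe_env:SRO"]],
               mds$kernels$gxe_common, tolerance = 1e-12)
  # structural constraints
  expect_error(build_kernels(G, recs, "SM"), "single environment")
  expect_error(build_kernels(G, recs[1:3, ], "MDe"), "2 environments")
  bad <- recs; bad$individual[1] <- "zz"
  expect_error(build_kernels(G, bad, "MM"), "absent")
})

test_that("closed-form GBLUP equals the Henderson MME solution and its limits", {
  set.seed(42)
  n <- 5
  G <- random_grel(n, seed = 5)$G
  y <- rnorm(n)
  lam <- 2
  u <- gblup_closed_form(G, y, lam)
  Kinv <- solve(G)
  C <- rbind(cbind(n, t(rep(1, n))),
             cbind(rep(1, n), diag(n) + lam * Kinv))
  sol <- solve(C, c(sum(y), y))
  expect_equal(unname(u), unname(sol[-1]), tolerance = 1e-10)
  # lambda -> infinity shrinks to zero
  expect_lt(max(abs(gblup_closed_form(G, y, 1e8))), 1e-5)
  # lambda -> 0 with full-rank K interpolates the centered data
  u0 <- gblup_closed_form(G, y, 1e-10, intercept = "mean")
  expect_equal(unname(u0), y - mean(y), tolerance = 1e-4)
})

test_that("Gibbs posterior means agree with closed-form GBLUP at fixed variances", {
  set.seed(42)
  n <- 60
  G <- random_grel(n, seed = 11)
  y <- drop(t(chol(G$G)) %*% rnorm(n)) + rnorm(n, 0, 0.7)
  lam <- 1.2
  recs <- data.frame(individual = G$ids, environment = "SRO")
  ks <- build_kernels(G, recs, "SM")
  uhat <- gblup_closed_form(G$G, y, lam)
  fit <- fit_gibbs(ks, y,
                   mcmc_settings(burn_in = 1000, n_iter = 11000, thin = 1,
                                 seed = 3),
                   fix_variances = list(residual = lam, kernel = 1))
  expect_lt(max(abs(fit$gebv - uhat)) / sd(y), 0.03)
  # deviation shrinks as the chain grows
  fit_s <- fit_gibbs(ks, y,
                     mcmc_settings(burn_in = 100, n_iter = 400, thin = 1,
                                   seed = 3),
                     fix_variances = list(residual = lam, kernel = 1))
  expect_lt(max(abs(fit$gebv - uhat)), max(abs(fit_s$gebv - uhat)))
  # held-out records are predicted through the kernel covariance
  tr <- 1:40
  yna <- y; yna[-tr] <- NA
  uh <- gblup_closed_form(G$G, y[tr], lam, train = tr)
  fit_p <- fit_gibbs(ks, yna,
                     mcmc_settings(burn_in = 1000, n_iter = 11000, thin = 1,
                                   seed = 4),
                     fix_variances = list(residual = lam, kernel = 1))
  expect_lt(max(abs(fit_p$gebv - uh)) / sd(y[tr]), 0.05)
})

test_that("the sampler is reproducible and near-degenerate cases behave", {
  G <- random_grel(20, seed = 6)
  recs <- data.frame(individual = G$ids, environment = "SRO")
  ks <- build_kernels(G, recs, "SM")
  set.seed(1); y <- rnorm(20)
  st <- mcmc_settings(burn_in = 100, n_iter = 600, thin = 2, seed = 9)
  f1 <- fit_gibbs(ks, y, st)
  f2 <- fit_gibbs(ks, y, st)
  expect_identical(f1$gebv, f2$gebv)
  expect_identical(f1$variance_posterior_means, f2$variance_posterior_means)
  # constant response: genetic values collapse toward zero
  fc <- fit_gibbs(ks, rep(5, 20), st)
  expect_lt(max(abs(fc$gebv)), 0.05)
  expect_lt(fc$variance_posterior_means["main"], 1e-6)
  expect_error(fit_gibbs(ks, c(1, rep(NA, 19)), st), "at least 2")
})

test_that("MM restricted to one environment reproduces SM exactly", {
  G <- random_grel(15, seed = 8)
  recs1 <- data.frame(individual = G$ids, environment = "SRO")
  set.seed(2); y <- rnorm(15)
  st <- mcmc_settings(burn_in = 200, n_iter = 1200, thin = 2, seed = 5)
  sm <- fit_gibbs(build_kernels(G, recs1, "SM"), y, st)
  mm <- fit_gibbs(build_kernels(G, recs1, "MM"), y, st)
  expect_identical(sm$gebv, mm$gebv)
})

test_that("MDs recovers a simulated common G-by-E variance", {
  rel_errs <- numeric(0)
  for (seed in 1:6) {
    set.seed(seed)
    n <- 100
    G <- random_grel(n, n_mark = 250, seed = 40 + seed)
    L <- t(chol(G$G))
    g <- drop(L %*% rnorm(n))
    d1 <- drop(L %*% rnorm(n)) * sqrt(0.8)
    d2 <- drop(L %*% rnorm(n)) * sqrt(0.8)
    y <- c(g + d1, g + d2) + rnorm(2 * n, 0, sqrt(0.5)) +
      rep(c(0, 0.5), each = n)
    recs <- data.frame(individual = rep(G$ids, 2),
                       environment = rep(c("PAL", "SRO"), each = n))
    ks <- build_kernels(G, recs, "MDs")
    fit <- fit_gibbs(ks, y, mcmc_settings(burn_in = 400, n_iter = 2800,
                                          thin = 3, seed = seed))
    rel_errs <- c(rel_errs,
                  (fit$variance_posterior_means["gxe_common"] - 0.8) / 0.8)
  }
  expect_lt(abs(mean(rel_errs)), 0.25)
})

test_that("MDe with equal environment variances matches MDs predictions", {
  n <- 60
  G <- random_grel(n, seed = 13)
  set.seed(3)
  y <- c(rnorm(n), rnorm(n, 0.4))
  recs <- data.frame(individual = rep(G$ids, 2),
                     environment = rep(c("PAL", "SRO"), each = n))
  st <- mcmc_settings(burn_in = 1000, n_iter = 9000, thin = 2, seed = 21)
  fv <- list(residual = 0.8, kernel = 0.6)
  mds <- fit_gibbs(build_kernels(G, recs, "MDs"), y, st, fix_variances = fv)
  mde <- fit_gibbs(build_kernels(G, recs, "MDe"), y, st, fix_variances = fv)
  # same model once the environment variances coincide; Monte-Carlo error only
  expect_gt(cor(mds$gebv, mde$gebv), 0.99)
  expect_lt(mean(abs(mds$gebv - mde$gebv)) / sd(y), 0.02)
})

test_that("predictive ability and Fisher Z follow their definitions", {
  x <- c(0.1, 0.5, 0.7, 0.9)
  expect_equal(predictive_ability(x, x), 1)
  expect_equal(predictive_ability(x, -x), -1)
  # hand-computed Pearson on a 4-point example
  a <- c(1, 2, 3, 5); b <- c(2, 1, 4, 6)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(predictive_ability(a, b), hand)
  expect_true(is.na(predictive_ability(rep(1, 4), b)))
  expect_error(predictive_ability(1:2, 2:1), "at least 3")
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "< 1")
})
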