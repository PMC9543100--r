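test_that("VIF matches its closed form", {
  # exactly uncorrelated (centred, orthogonal) columns
  X <- withr::with_seed(55, qr.Q(qr(scale(matrix(rnorm(60), 20, 3),
                                          scale = FALSE))))
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(suppressWarnings(vif_check(X))), rep(1, 3),
               tolerance = 1e-8)
  X2 <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  expect_true(is.infinite(suppressWarnings(vif_check(X2))["a"]))
  # two predictors with sample correlation exactly 0.8 -> VIF = 2.7778
  z1 <- scale(rnorm(100))[, 1]
  e <- scale(residuals(lm(rnorm(100) ~ z1)))[, 1]
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * e
  expect_equal(unname(suppressWarnings(vif_check(cbind(z1, x2)))),
               rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_error(vif_check(cbind(z1)), "at least two")
})

test_that("basis sets match textbook cases", {
  chain <- sem_dag(data.frame(from = c("X", "M"), to = c("M", "Y")),
                   binary = character(), random = NULL)
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$x, "X")
  expect_equal(bs[[1]]$y, "Y")
  expect_equal(bs[[1]]$cond, "M")
  full <- sem_dag(data.frame(from = c("A", "A", "B"),
                             to = c("B", "C", "C")),
                  binary = character(), random = NULL)
  expect_length(basis_set(full), 0)
  expect_error(sem_dag(data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
})

test_that("every basis claim is d-separated in every DAG up to 5 nodes", {
  # all DAGs whose edges respect a fixed topological order; every DAG is
  # isomorphic to one of these and d-separation ignores labels
  for (n in 2:5) {
    for (edges in ordered_dags(n)) {
      dag <- sem_dag_or_null(edges, n)
      if (is.null(dag)) next
      for (cl in basis_set(dag))
        expect_true(oracle_dsep(dag$edges, cl$x, cl$y, cl$cond))
    }
  }
})

test_that("Fisher's C arithmetic is exact", {
  f0 <- fisher_c(c(1, 1, 1))
  expect_equal(f0$C, 0)
  expect_equal(f0$pvalue, 1)
  f2 <- fisher_c(c(0.5, 0.5))
  expect_equal(f2$C, -2 * (log(0.5) + log(0.5)))
  expect_equal(f2$C, 2.772589, tolerance = 1e-6)
  expect_equal(f2$df, 4)
  expect_equal(f2$pvalue, 1 - pchisq(f2$C, 4))
})

test_that("the d-sep global test has nominal type-I error", {
  dag <- sem_dag(data.frame(from = c("X", "X", "M1"),
                            to = c("M1", "M2", "Y")),
                 binary = character(), random = NULL)
  rej <- 0L; n_rep <- 500
  for (s in seq_len(n_rep)) {
    dat <- withr::with_seed(3000 + s, {
      X <- rnorm(100)
      M1 <- 0.6 * X + rnorm(100)
      M2 <- -0.5 * X + rnorm(100)
      Y <- 0.7 * M1 + rnorm(100)
      data.frame(X = X, M1 = M1, M2 = M2, Y = Y)
    })
    ds <- dsep_test(dag, dat)
    rej <- rej + (ds$pvalue <= 0.05)
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("standardized coefficients follow the variance arithmetic", {
  # linear component, both variables pre-standardized: beta* = beta
  dat <- withr::with_seed(61, {
    x <- scale(rnorm(300))[, 1]
    y <- scale(0.5 * x + rnorm(300, sd = 0.8))[, 1]
    data.frame(x = x, y = y)
  })
  dag <- sem_dag(data.frame(from = "x", to = "y"),
                 binary = character(), random = NULL)
  fit <- sem_fit(dag, dat)
  std <- standardize_paths(fit)
  expect_equal(std$std_estimate, std$estimate, tolerance = 1e-10)
  expect_lte(abs(std$std_estimate), 1 + 1e-8)
  # Bernoulli component with null fixed effect: latent denominator is
  # essentially sqrt(pi^2 / 3)
  datb <- withr::with_seed(62, data.frame(x = rnorm(400),
                                          outcome = rbinom(400, 1, 0.5)))
  dagb <- sem_dag(data.frame(from = "x", to = "outcome"),
                  random = NULL)
  fitb <- sem_fit(dagb, datb)
  stdb <- standardize_paths(fitb)
  comp <- fitb$components$outcome
  denom <- sqrt(comp$variances$var_fixed + pi^2 / 3)
  expect_equal(stdb$std_estimate,
               stdb$estimate * sd(datb$x) / denom, tolerance = 1e-12)
  expect_equal(denom, sqrt(pi^2 / 3), tolerance = 0.02)
  expect_equal(sqrt(pi^2 / 3), 1.813799, tolerance = 1e-6)
})

test_that("effect decomposition sums products over directed paths", {
  # A -> B -> Y plus direct A -> Y: total = c + a * b
  dat <- withr::with_seed(63, {
    A <- rnorm(500)
    B <- 0.6 * A + rnorm(500, sd = 0.6)
    Y <- 0.5 * A + 0.4 * B + rnorm(500, sd = 0.5)
    data.frame(A = A, B = B, Y = Y)
  })
  dag <- sem_dag(data.frame(from = c("A", "B", "A"),
                            to = c("B", "Y", "Y")),
                 binary = character(), random = NULL)
  fit <- sem_fit(dag, dat)
  std <- standardize_paths(fit)
  eff <- effects_decomposition(fit, std, response = "Y")
  cf <- function(f, t) std$std_estimate[std$from == f & std$to == t]
  a_row <- eff[eff$node == "A", ]
  expect_equal(a_row$direct, cf("A", "Y"))
  expect_equal(a_row$indirect, cf("A", "B") * cf("B", "Y"))
  expect_equal(a_row$total, a_row$direct + a_row$indirect)
  b_row <- eff[eff$node == "B", ]
  expect_equal(b_row$direct, cf("B", "Y"))
  expect_equal(b_row$indirect, 0)
  expect_equal(sum(eff$relative_total), 100)
})

test_that("conditional R2 follows the Nakagawa variance partition", {
  # perfect fixed-effect fit without random effects: R2c -> 1
  dat <- data.frame(x = 1:50, y = 2 * (1:50) + 3)
  dag <- sem_dag(data.frame(from = "x", to = "y"),
                 binary = character(), random = NULL)
  fit <- suppressWarnings(sem_fit(dag, dat))
  expect_gt(suppressWarnings(conditional_r2(fit))[["y"]], 0.999999)
  # mixed null model: R2c = var_re / (var_re + var_resid)
  datg <- withr::with_seed(64, {
    g <- rep(sprintf("g%02d", 1:20), each = 15)
    u <- rnorm(20, 0, 1); names(u) <- unique(g)
    data.frame(g = g, x = rnorm(300),
               y = u[g] + rnorm(300, sd = 0.5))
  })
  m <- suppressWarnings(lme4::lmer(y ~ 1 + (1 | g), data = datg))
  vc <- lme4::VarCorr(m)
  r2c <- conditional_r2(m)
  expect_equal(r2c, vc$g[1, 1] / (vc$g[1, 1] + attr(vc, "sc")^2),
               tolerance = 1e-8)
  # R2c never falls below the marginal (fixed-effects-only) R2
  m2 <- lme4::lmer(y ~ x + (1 | g), data = datg)
  vf <- var(as.numeric(model.matrix(m2) %*% lme4::fixef(m2)))
  vc2 <- lme4::VarCorr(m2)
  marginal <- vf / (vf + vc2$g[1, 1] + attr(vc2, "sc")^2)
  expect_gte(conditional_r2(m2), marginal)
})

test_that("stepwise selection keeps true graphs and finds missing edges", {
  gen <- function(s, extra_edge) {
    withr::with_seed(s, {
      X <- rnorm(200)
      M <- 0.6 * X + rnorm(200)
      Y <- 0.7 * M + (if (extra_edge) 0.8 * X else 0) + rnorm(200)
      data.frame(X = X, M = M, Y = Y)
    })
  }
  dag0 <- sem_dag(data.frame(from = c("X", "M"), to = c("M", "Y")),
                  binary = character(), random = NULL)
  keep_true <- 0L; found <- 0L; n_rep <- 100
  for (s in seq_len(n_rep)) {
    sel0 <- sem_selection(dag0, gen(s, FALSE))
    keep_true <- keep_true + (nrow(sel0$fit$dag$edges) == 2)
    sel1 <- sem_selection(dag0, gen(s, TRUE))
    found <- found +
      any(sel1$fit$dag$edges$from == "X" & sel1$fit$dag$edges$to == "Y")
    expect_lte(sel1$dsep$aic, sel1$ledger$aic[1])
  }
  expect_gte(keep_true, 90)
  expect_gte(found, 90)
})

test_that("both SEM variants fit the synthetic covariates", {
  lakes <- impute_water_temperature(fix$lakes)
  cov <- assemble_covariates(fix$records, lakes, fix$communities,
                             fix$Dphy, fix$Dfun,
                             extra_lake_cols = c("accum_temp",
                                                 "max_temp"))
  main <- suppressWarnings(sem_fit(default_sem_dag(), cov))
  ds_main <- suppressWarnings(dsep_test(main))
  expect_true(is.finite(ds_main$C))
  expect_gte(ds_main$C, 0)
  expect_equal(ds_main$df %% 2, 0)
  tv <- suppressWarnings(sem_fit(default_sem_dag(temperature = TRUE),
                                 cov))
  ds_tv <- suppressWarnings(dsep_test(tv))
  expect_true(is.finite(ds_tv$C))
  expect_s3_class(standardize_paths(tv), "data.frame")
  r2 <- conditional_r2(main)
  expect_true(all(r2 >= 0 & r2 <= 1))
})
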