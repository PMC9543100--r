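test_that("phylogenetic covariance equals shared path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr, scale = FALSE)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["A", "A"], 2)
  Vs <- phylo_covariance(tr)
  expect_equal(max(diag(Vs)), 1)
  # star tree: no shared history off the diagonal
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  Vst <- phylo_covariance(star, scale = FALSE)
  expect_equal(unname(Vst[upper.tri(Vst)]), rep(0, 6))
  # sub-matrix extraction after full-tree computation
  Vsub <- phylo_covariance(tr, species = c("A", "C"), scale = FALSE)
  expect_equal(dim(Vsub), c(2, 2))
  expect_equal(Vsub["A", "A"], 2)
  expect_error(phylo_covariance(tr, species = "Z"), "Z")
})

test_that("phylogenetic covariances are positive semi-definite", {
  for (s in 1:100) {
    tr <- simulate_tree(10, seed = 4000 + s)
    V <- phylo_covariance(tr)
    expect_silent(chol(V + diag(1e-8, nrow(V))))
  }
})

test_that("WAIC reduces to -2 log-likelihood for a degenerate posterior", {
  ll <- matrix(log(c(0.7, 0.4, 0.9)), nrow = 1)
  expect_warning(w <- waic(ll), "fewer than 100")
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll))
})

test_that("WAIC prefers the generating model", {
  # posterior draws via the Gaussian (Laplace) approximation of a GLM;
  # model A: intercept only, model B: intercept + slope
  wins_large <- 0L; small_gap <- 0L
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    dat <- withr::with_seed(s, {
      x <- rnorm(150)
      list(x = x, y0 = rbinom(150, 1, 0.5),
           y1 = rbinom(150, 1, plogis(1.5 * x)))
    })
    draw_ll <- function(y, with_x) {
      X <- if (with_x) cbind(1, dat$x) else cbind(rep(1, 150))
      f <- suppressWarnings(glm.fit(X, y, family = binomial()))
      cf <- f$coefficients
      Vc <- chol2inv(chol(crossprod(X * sqrt(f$weights))))
      dr <- withr::with_seed(s + 7,
        matrix(rnorm(400 * length(cf)), 400) %*% chol(Vc))
      dr <- sweep(dr, 2, cf, "+")
      eta <- dr %*% t(X)
      ll <- log(ifelse(rep(y, each = 400) == 1, plogis(eta),
                       1 - plogis(eta)))
      dim(ll) <- dim(eta); ll
    }
    # data from the larger model: larger model should win
    wA <- waic(draw_ll(dat$y1, FALSE))$waic
    wB <- waic(draw_ll(dat$y1, TRUE))$waic
    wins_large <- wins_large + (wB < wA)
    # data from the smaller model: difference stays small
    d0 <- waic(draw_ll(dat$y0, TRUE))$waic -
      waic(draw_ll(dat$y0, FALSE))$waic
    small_gap <- small_gap + (abs(d0) < 10)
  }
  expect_gte(wins_large, 90)
  expect_gte(small_gap, 90)
})

test_that("relative importance is the normalized absolute coefficient", {
  eq <- relative_importance(setNames(rep(0.3, 8), paste0("p", 1:8)))
  expect_equal(unname(eq), rep(12.5, 8))
  ri <- relative_importance(setNames(c(2, -1, 1, 0, 0, 0, 0, 0),
                                     paste0("p", 1:8)))
  expect_equal(unname(ri[1:3]), c(50, 25, 25))
  expect_equal(sum(ri), 100)
  grouped <- relative_importance(
    setNames(c(2, -1, 1, 0.5), c("a", "b", "c", "d")),
    groups = list(g1 = c("a", "b"), g2 = c("c", "d")))
  expect_equal(sum(attr(grouped, "groups")), 100)
  expect_error(relative_importance(c(a = 0, b = 0)), "zero")
})

test_that("likelihood identities hold", {
  y <- rep(c(0L, 1L), 25)
  expect_equal(bernoulli_loglik(rep(0, 50), y), 50 * log(0.5))
  # scale confounding: doubling Sigma while halving sigma2 leaves the
  # phylogenetic effect density unchanged
  V <- phylo_covariance(simulate_tree(8, seed = 3), scale = FALSE)
  w <- withr::with_seed(4, rnorm(8, sd = 0.5))
  expect_equal(phylo_effect_logdensity(w, 0.6, V),
               phylo_effect_logdensity(w, 0.3, 2 * V))
  # with Sigma = I the phylogenetic effect is exchangeable with the iid
  # species intercept: only v + w enters the linear predictor
  v <- withr::with_seed(5, rnorm(8, sd = 0.3))
  idx <- rep(1:8, 5)
  x <- withr::with_seed(6, rnorm(40))
  yy <- rep(c(0L, 1L), 20)
  expect_equal(bernoulli_loglik(x + v[idx] + w[idx], yy),
               bernoulli_loglik(x + w[idx] + v[idx], yy))
  expect_equal(phylo_effect_logdensity(w, 0.25, diag(8)),
               sum(dnorm(w, 0, 0.5, log = TRUE)))
})

test_that("the hierarchical fit is calibrated under the null", {
  # all betas zero, no random effects: nominal coverage of the 95% CIs
  tr <- simulate_tree(12, seed = 21)
  Sig <- phylo_covariance(tr)
  covered <- 0L; total <- 0L
  for (s in 1:12) {
    dat <- withr::with_seed(800 + s, data.frame(
      outcome = rbinom(200, 1, 0.5),
      x1_z = rnorm(200), x2_z = rnorm(200),
      lake_id = sample(sprintf("l%02d", 1:15), 200, TRUE),
      species_id = sample(tr$tip.label, 200, TRUE)))
    f <- suppressWarnings(fit_hier(dat, Sig,
                                   predictors = c("x1_z", "x2_z"),
                                   n_chains = 2, n_iter = 400,
                                   n_adapt = 200, seed = s))
    ci <- f$summary[c("x1_z", "x2_z"), ]
    covered <- covered + sum(ci$q2.5 < 0 & ci$q97.5 > 0)
    total <- total + 2L
  }
  expect_gte(covered, round(0.85 * total))
})

test_that("an intercept-only-style fit on balanced outcomes centres at zero", {
  tr <- simulate_tree(10, seed = 31)
  dat <- withr::with_seed(32, data.frame(
    outcome = sample(rep(c(0L, 1L), 150)),
    noise_z = rnorm(300),
    lake_id = sample(sprintf("l%02d", 1:20), 300, TRUE),
    species_id = sample(tr$tip.label, 300, TRUE)))
  f <- suppressWarnings(fit_hier(dat, phylo_covariance(tr),
                                 predictors = "noise_z",
                                 n_chains = 2, n_iter = 600,
                                 n_adapt = 300, seed = 2))
  expect_lt(abs(f$summary["(Intercept)", "mean"]), 0.3)
  expect_true(all(f$summary$q2.5 <= f$summary$q15))
  expect_true(all(f$summary$q85 <= f$summary$q97.5))
  expect_true(all(f$sigma2 >= 0))
  expect_true(is.finite(f$waic$waic))
})

test_that("prediction curves follow the sign of the coefficient", {
  cov <- fix$covariates
  Sig <- phylo_covariance(fix$tree, unique(cov$species_id))
  f <- suppressWarnings(fit_hier(cov, Sig, n_chains = 2, n_iter = 600,
                                 n_adapt = 300, seed = 9))
  pc <- prediction_curve(f, "in_mpd")
  expect_true(all(diff(pc$prob) < 0))   # beta_in_mpd < 0
  pc2 <- prediction_curve(f, "in_mfd")
  expect_true(all(diff(pc2$prob) > 0))  # beta_in_mfd > 0
  # at the predictor mean all predictors sit at 0: P = mean plogis(b0)
  at_mean <- prediction_curve(f, "in_mpd",
                              grid = mean(cov$in_mpd))
  expect_equal(at_mean$prob,
               mean(plogis(f$draws[, "(Intercept)"])),
               tolerance = 1e-12)
  expect_true(all(pc$lower <= pc$prob & pc$prob <= pc$upper))
  expect_error(prediction_curve(f, "nonexistent"), "not in model")
})
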