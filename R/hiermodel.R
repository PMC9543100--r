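#' Phylogenetic covariance matrix for a species subset
#'
#' Brownian-motion covariance: the shared root-to-MRCA path length of
#' each pair of tips, computed on the full tree first and then restricted
#' to the requested subset, finally rescaled so the largest diagonal
#' entry is 1 (keeping the random-effect variance parameter
#' interpretable).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param species tip labels to keep (default: all tips).
#' @param scale rescale so `max(diag(Sigma)) == 1` (default TRUE).
#' @return symmetric positive semi-definite matrix with species dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL, scale = TRUE) {
  V <- ape::vcv(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(V))
    if (length(miss))
      stop("species not in tree: ", paste(miss, collapse = ", "))
    V <- V[species, species, drop = FALSE]
  }
  V <- V[order(rownames(V)), order(colnames(V)), drop = FALSE]
  if (scale) V <- V / max(diag(V))
  V
}

.hier_jags_model <- "model {
  for (i in 1:N) {
    logit(p[i]) <- b0 + inprod(X[i, ], beta) + u[lake[i]] + v[sp[i]] + w[sp[i]]
    y[i] ~ dbern(p[i])
  }
  for (j in 1:L) { u[j] ~ dnorm(0, tau_L) }
  for (k in 1:S) { v[k] ~ dnorm(0, tau_S) }
  w[1:S] ~ dmnorm(zeroS, Omega[, ] * tau_P)
  b0 ~ dnorm(0, beta_prec)
  for (m in 1:P) { beta[m] ~ dnorm(0, beta_prec) }
  tau_L ~ dgamma(hyper_shape, hyper_rate)
  tau_S ~ dgamma(hyper_shape, hyper_rate)
  tau_P ~ dgamma(hyper_shape, hyper_rate)
}"

#' Fit the Bayesian phylogenetic hierarchical establishment model
#'
#' Bernoulli outcomes on the logit scale with standardized fixed effects,
#' iid lake and species random intercepts, and a phylogenetically
#' correlated species effect `w ~ N(0, sigma2_P * Sigma)`. Posterior via
#' MCMC (JAGS): Gaussian `N(0, 10^2)` priors on fixed effects and
#' Gamma(0.01, 0.01) priors on the three random-effect precisions.
#'
#' @param covariates covariate table from [assemble_covariates()] (must
#'   contain the requested predictor columns, `outcome`, `lake_id`,
#'   `species_id`).
#' @param Sigma phylogenetic covariance over the introduced species (from
#'   [phylo_covariance()]); its dimnames must cover every
#'   `species_id` present.
#' @param predictors standardized predictor columns; default is the
#'   mean-distance family.
#' @param n_chains,n_iter,n_adapt MCMC settings (defaults 4 chains, 2000
#'   kept iterations each, 500 adaptation/burn-in).
#' @param seed integer seed; per-chain RNGs derive from it.
#' @param priors list with `beta_sd` (default 10), `hyper_shape`,
#'   `hyper_rate` (default 0.01 each).
#' @param rhat_limit convergence gate on the fixed effects (default
#'   1.01); exceeding it triggers `on_nonconvergence`.
#' @param on_nonconvergence `"warn"` (default) or `"error"`.
#' @return object of class `hier_fit`: `summary` (per-parameter posterior
#'   mean/median/sd, 95% and 70% equal-tailed intervals), `sigma2`
#'   (posterior means of the three variance components), `waic`,
#'   `rhat`, `ess`, `draws` (parameter draws, all chains stacked),
#'   `loglik` (draws x events pointwise log-likelihood) and the model
#'   frame bookkeeping needed by [prediction_curve()].
#' @export
fit_hier <- function(covariates, Sigma,
                     predictors = c("in_mpd_z", "in_mfd_z", "native_mpd_z",
                                    "native_mfd_z", "richness_z", "area_z",
                                    "elevation_z", "latitude_z"),
                     n_chains = 4, n_iter = 2000, n_adapt = 500,
                     seed = 1L, priors = list(),
                     rhat_limit = 1.01,
                     on_nonconvergence = c("warn", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  pr <- utils::modifyList(list(beta_sd = 10, hyper_shape = 0.01,
                               hyper_rate = 0.01), priors)
  stopifnot(all(predictors %in% names(covariates)),
            all(c("outcome", "lake_id", "species_id") %in%
                  names(covariates)))
  X <- as.matrix(covariates[, predictors, drop = FALSE])
  if (anyNA(X)) stop("missing values in the design")
  y <- as.integer(covariates$outcome)
  lake_f <- factor(covariates$lake_id)
  sp_levels <- sort(unique(as.character(covariates$species_id)))
  miss <- setdiff(sp_levels, rownames(Sigma))
  if (length(miss))
    stop("species missing from Sigma: ", paste(miss, collapse = ", "))
  Sigma <- Sigma[sp_levels, sp_levels]
  sp_f <- factor(covariates$species_id, levels = sp_levels)
  S <- length(sp_levels)
  Omega <- solve(Sigma + diag(1e-8, S))
  Omega <- (Omega + t(Omega)) / 2
  data <- list(N = length(y), L = nlevels(lake_f), S = S,
               P = ncol(X), X = X, y = y,
               lake = as.integer(lake_f), sp = as.integer(sp_f),
               Omega = Omega, zeroS = rep(0, S),
               beta_prec = 1 / pr$beta_sd^2,
               hyper_shape = pr$hyper_shape, hyper_rate = pr$hyper_rate)
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch))
  jm <- rjags::jags.model(textConnection(.hier_jags_model), data = data,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  smp <- rjags::coda.samples(jm, c("b0", "beta", "u", "v", "w",
                                   "tau_L", "tau_S", "tau_P"),
                             n.iter = n_iter)

  # JAGS drops the index on length-1 vectors
  vec_names <- function(base, n)
    if (n == 1) base else paste0(base, "[", seq_len(n), "]")
  fixed_names <- c("b0", vec_names("beta", ncol(X)))
  rhat <- tryCatch({
    g <- coda::gelman.diag(smp[, fixed_names, drop = FALSE],
                           multivariate = FALSE, autoburnin = FALSE)
    stats::setNames(g$psrf[, 1], c("(Intercept)", predictors))
  }, error = function(e) stats::setNames(rep(NA_real_, ncol(X) + 1),
                                         c("(Intercept)", predictors)))
  if (n_chains > 1 && any(is.finite(rhat) & rhat > rhat_limit)) {
    msg <- paste0("convergence gate failed: max Rhat = ",
                  round(max(rhat, na.rm = TRUE), 4))
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  ess <- tryCatch(coda::effectiveSize(smp[, fixed_names, drop = FALSE]),
                  error = function(e) NULL)

  draws <- do.call(rbind, lapply(smp, as.matrix))
  # pointwise log-likelihood for WAIC
  bcols <- vec_names("beta", ncol(X))
  ucols <- vec_names("u", nlevels(lake_f))[as.integer(lake_f)]
  vcols <- vec_names("v", S)[as.integer(sp_f)]
  wcols <- vec_names("w", S)[as.integer(sp_f)]
  eta <- sweep(draws[, bcols, drop = FALSE] %*% t(X), 1,
               draws[, "b0"], "+") +
    draws[, ucols, drop = FALSE] + draws[, vcols, drop = FALSE] +
    draws[, wcols, drop = FALSE]
  pm <- stats::plogis(eta)
  loglik <- log(ifelse(rep(y, each = nrow(pm)) == 1, pm, 1 - pm))
  dim(loglik) <- dim(pm)

  qs <- function(x) c(mean = mean(x), median = stats::median(x),
                      sd = stats::sd(x),
                      q2.5 = unname(stats::quantile(x, 0.025)),
                      q97.5 = unname(stats::quantile(x, 0.975)),
                      q15 = unname(stats::quantile(x, 0.15)),
                      q85 = unname(stats::quantile(x, 0.85)))
  coef_draws <- draws[, c("b0", bcols), drop = FALSE]
  colnames(coef_draws) <- c("(Intercept)", predictors)
  summ <- as.data.frame(t(apply(coef_draws, 2, qs)))
  sigma2 <- c(lake = mean(1 / draws[, "tau_L"]),
              species = mean(1 / draws[, "tau_S"]),
              phylo = mean(1 / draws[, "tau_P"]))

  scaling <- NULL
  raw <- sub("_z$", "", predictors)
  if (all(raw %in% names(covariates)))
    scaling <- data.frame(predictor = predictors, raw = raw,
                          mean = vapply(raw, function(cc)
                            mean(covariates[[cc]]), numeric(1)),
                          sd = vapply(raw, function(cc)
                            stats::sd(covariates[[cc]]), numeric(1)))

  structure(list(summary = summ, sigma2 = sigma2,
                 waic = waic(loglik), rhat = rhat, ess = ess,
                 draws = coef_draws, predictors = predictors,
                 n_events = length(y), scaling = scaling,
                 loglik = loglik),
            class = "hier_fit")
}

#' @exportS3Method base::print
print.hier_fit <- function(x, ...) {
  cat("Bayesian phylogenetic hierarchical establishment model\n")
  cat("events:", x$n_events, "  WAIC:", round(x$waic$waic, 1), "\n\n")
  print(round(x$summary, 3))
  cat("\nrandom-effect variances:\n")
  print(round(x$sigma2, 3))
  invisible(x)
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 (lppd - p_WAIC)` with `p_WAIC` the sum over observations of
#' the posterior variance of the pointwise log-likelihood.
#'
#' @param x a draws x observations matrix of pointwise log-likelihood
#'   values, or a `hier_fit`.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(x) UseMethod("waic")

#' @export
waic.hier_fit <- function(x) x$waic

#' @export
waic.matrix <- function(x) {
  if (nrow(x) < 100)
    warning("fewer than 100 posterior draws; WAIC will be noisy")
  # log mean exp, column-wise, guarded against underflow
  m <- apply(x, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(x, 2, m)))))
  p_waic <- if (nrow(x) == 1) 0 else sum(apply(x, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Relative importance of the standardized predictors
#'
#' The share of each predictor is the absolute value of its posterior
#' mean coefficient divided by the sum of absolute values over all
#' non-intercept predictors, expressed as a percentage (interpretable as
#' a variance partition because the predictors are standardized).
#'
#' @param fit a `hier_fit`, or a named numeric vector of standardized
#'   coefficients (no intercept).
#' @param groups optional named list of predictor groups; grouped shares
#'   are returned as attribute `groups`.
#' @return named percentage vector summing to 100.
#' @export
relative_importance <- function(fit, groups = NULL) {
  beta <- if (inherits(fit, "hier_fit"))
    stats::setNames(fit$summary$mean[-1], rownames(fit$summary)[-1])
  else fit
  tot <- sum(abs(beta))
  if (tot == 0) stop("all coefficients are zero: importance undefined")
  shares <- 100 * abs(beta) / tot
  if (!is.null(groups))
    attr(shares, "groups") <- vapply(groups, function(g)
      sum(shares[g]), numeric(1))
  shares
}

#' Posterior predicted establishment probability along one predictor
#'
#' Probability of establishment over a raw-scale grid of one predictor,
#' all other predictors held at their means (0 on the standardized
#' scale) and random effects at their population mean of zero, with an
#' equal-tailed 95% credible band.
#'
#' @param fit a `hier_fit` fitted on a covariate table carrying raw
#'   columns next to the `_z` ones.
#' @param predictor raw predictor name (e.g. `"in_mpd"`).
#' @param grid raw-scale grid; default 50 points over mean +/- 2.5 SD.
#' @return data.frame `grid`, `prob`, `lower`, `upper`.
#' @export
prediction_curve <- function(fit, predictor, grid = NULL) {
  if (is.null(fit$scaling)) stop("fit carries no raw-scale information")
  row <- fit$scaling[fit$scaling$raw == predictor, ]
  if (nrow(row) != 1) stop("predictor '", predictor, "' not in model")
  if (is.null(grid))
    grid <- seq(row$mean - 2.5 * row$sd, row$mean + 2.5 * row$sd,
                length.out = 50)
  z <- (grid - row$mean) / row$sd
  eta <- outer(fit$draws[, "(Intercept)"], rep(1, length(z))) +
    outer(fit$draws[, row$predictor], z)
  p <- stats::plogis(eta)
  data.frame(grid = grid, prob = colMeans(p),
             lower = apply(p, 2, stats::quantile, 0.025),
             upper = apply(p, 2, stats::quantile, 0.975))
}

#' Bernoulli log-likelihood of a linear predictor
#'
#' @param eta logit-scale linear predictor.
#' @param y 0/1 outcomes.
#' @return total log-likelihood.
#' @export
bernoulli_loglik <- function(eta, y)
  sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE))

#' Log-density of the phylogenetically correlated effect
#'
#' `w ~ N(0, sigma2 * Sigma)`; used for scale-confounding diagnostics
#' (only the product `sigma2 * Sigma` is identified).
#'
#' @param w effect vector.
#' @param sigma2 scale variance.
#' @param Sigma covariance structure matrix.
#' @return log-density.
#' @export
phylo_effect_logdensity <- function(w, sigma2, Sigma) {
  V <- sigma2 * Sigma
  L <- chol(V)
  z <- backsolve(L, w, transpose = TRUE)
  -0.5 * (length(w) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}
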