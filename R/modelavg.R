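#' Fit one candidate GLMM (logit link, lake and species intercepts)
#'
#' The frequentist counterpart of the hierarchical model, without the
#' phylogenetic covariance term: `outcome ~ subset + (1 | lake_id) +
#' (1 | species_id)` with a Bernoulli response, marginal likelihood by
#' the Laplace approximation (lme4). The random-effect structure is
#' never subset; only fixed effects vary across candidates.
#'
#' @param subset character vector of predictor columns (may be empty for
#'   the intercept-only model).
#' @param covariates covariate table with `outcome`, `lake_id`,
#'   `species_id` and the predictor columns.
#' @param nAGQ passed to [lme4::glmer()] (default 1 = Laplace; 0 is a
#'   faster approximation for large candidate sweeps).
#' @return list `loglik`, `k` (fixed effects incl. intercept + 2 variance
#'   parameters), `coef`, `se`, `fit` (the `glmerMod`), `converged`,
#'   `singular` (TRUE when a variance estimate hit the zero bound).
#' @export
fit_glmm <- function(subset, covariates, nAGQ = 1) {
  rhs <- c(if (length(subset)) subset else "1",
           "(1 | lake_id)", "(1 | species_id)")
  form <- stats::reformulate(rhs, response = "outcome")
  fit <- suppressMessages(lme4::glmer(
    form, data = covariates, family = stats::binomial(), nAGQ = nAGQ,
    control = lme4::glmerControl(calc.derivs = FALSE,
                                 check.conv.singular = "ignore")))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  conv <- length(fit@optinfo$conv$lme4) == 0
  list(loglik = as.numeric(stats::logLik(fit)),
       k = length(cf) + 2L, coef = cf, se = se, fit = fit,
       converged = conv, singular = lme4::isSingular(fit))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1) / (n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (must exceed `k + 1`).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets GLMM comparison ranked by AICc
#'
#' Fits every subset of the candidate predictors (2^p models, p <= 12),
#' always retaining the lake and species random intercepts, and ranks
#' the candidates by AICc. Ties break deterministically: fewer
#' parameters first, then lexicographic subset. Per-model failures are
#' recorded and skipped without aborting the sweep.
#'
#' @param covariates covariate table.
#' @param predictors candidate predictor columns.
#' @param nAGQ passed to [fit_glmm()].
#' @return data.frame of class `dredge_table`, one row per fitted model:
#'   `subset` ("+"-joined), `df` (= k), `loglik`, `aicc`, `delta`,
#'   `weight`; attribute `fits` holds the per-model coefficient/SE lists,
#'   attribute `failures` any skipped subsets, attribute `n` the sample
#'   size.
#' @export
dredge_glmm <- function(covariates, predictors, nAGQ = 1) {
  p <- length(predictors)
  if (p > 12) stop("more than 12 candidate predictors")
  n <- nrow(covariates)
  subsets <- lapply(seq_len(2^p) - 1L, function(mask)
    predictors[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0])
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  failures <- character(0)
  for (i in seq_along(subsets)) {
    sb <- subsets[[i]]
    f <- tryCatch(fit_glmm(sb, covariates, nAGQ = nAGQ),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, paste(sb, collapse = "+"))
      next
    }
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      subset = paste(sort(sb), collapse = "+"),
      df = f$k, loglik = f$loglik, aicc = aicc(f$loglik, f$k, n))
  }
  keep <- !vapply(rows, is.null, logical(1))
  tab <- do.call(rbind, rows[keep])
  fits <- fits[keep]
  ord <- order(tab$aicc, tab$df, tab$subset)
  tab <- tab[ord, ]; fits <- fits[ord]
  tab$delta <- tab$aicc - min(tab$aicc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  rownames(tab) <- NULL
  structure(tab, fits = fits, failures = failures, n = n,
            predictors = predictors,
            class = c("dredge_table", "data.frame"))
}

#' Akaike model averaging over the top candidate set
#'
#' Retains candidates with `delta AICc < cutoff` (the best model always
#' qualifies), renormalizes their Akaike weights, and averages the
#' coefficients with the full-average (zero-substitution) convention: a
#' model lacking a predictor contributes a coefficient of 0.
#' Unconditional standard errors follow Burnham & Anderson:
#' `sqrt( sum_i w_i (se_i^2 + (b_i - b_bar)^2) )`.
#'
#' @param dredge a `dredge_table` from [dredge_glmm()].
#' @param cutoff delta-AICc retention threshold (default 2).
#' @return data.frame per predictor: `estimate`, `se`, `z`, plus
#'   attribute `retained` (the retained candidate subtable with
#'   renormalized weights).
#' @export
model_average <- function(dredge, cutoff = 2) {
  keep <- dredge$delta < cutoff
  tab <- dredge[keep, , drop = FALSE]
  fits <- attr(dredge, "fits")[keep]
  w <- exp(-tab$delta / 2); w <- w / sum(w)
  tab$weight <- w
  terms <- unique(unlist(lapply(fits, function(f) names(f$coef))))
  est <- se <- stats::setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    b <- vapply(fits, function(f)
      if (tm %in% names(f$coef)) unname(f$coef[tm]) else 0, numeric(1))
    s <- vapply(fits, function(f)
      if (tm %in% names(f$coef)) unname(f$se[tm]) else 0, numeric(1))
    est[tm] <- sum(w * b)
    se[tm] <- sqrt(sum(w * (s^2 + (b - est[tm])^2)))
  }
  out <- data.frame(estimate = est, se = se, z = est / se)
  attr(out, "retained") <- tab
  out
}
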