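#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on the other
#' predictors. Values above 3 flag problematic multicollinearity in this
#' pipeline's screening convention.
#'
#' @param X numeric matrix or data.frame of at least two predictors.
#' @return named vector of VIFs (`Inf` under perfect collinearity).
#' @export
vif_check <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two predictors")
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Directed acyclic path model
#'
#' @param edges two-column data.frame or matrix (`from`, `to`) of
#'   directed edges over measured variables.
#' @param binary nodes modeled with a Bernoulli (logit) component
#'   (default `"outcome"` when present).
#' @param random random-intercept grouping columns used in every
#'   component model (default `c("lake_id", "species_id")`; `NULL` for
#'   fixed-effect-only components).
#' @return a `sem_dag` list: `edges`, `nodes` (topological order),
#'   `binary`, `random`.
#' @export
sem_dag <- function(edges, binary = "outcome",
                    random = c("lake_id", "species_id")) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  nodes <- unique(c(edges$from, edges$to))
  order <- .topo_sort(nodes, edges)  # errors on a cycle
  for (b in intersect(binary, nodes))
    if (b %in% edges$from)
      stop("binary response '", b, "' must have no outgoing edges")
  structure(list(edges = edges, nodes = order,
                 binary = intersect(binary, nodes), random = random),
            class = "sem_dag")
}

.topo_sort <- function(nodes, edges) {
  order <- character(0); remaining <- nodes
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(nd)
      !any(edges$to == nd & edges$from %in% remaining), logical(1))]
    if (!length(free)) stop("graph contains a cycle")
    order <- c(order, sort(free))
    remaining <- setdiff(remaining, free)
  }
  order
}

.parents <- function(dag, node) sort(dag$edges$from[dag$edges$to == node])

.adjacent <- function(dag, a, b)
  any((dag$edges$from == a & dag$edges$to == b) |
        (dag$edges$from == b & dag$edges$to == a))

#' Shipley's union basis set of independence claims
#'
#' One claim per non-adjacent ordered pair `(X, Y)` with `Y` later in
#' topological order: `X` independent of `Y` given the union of the
#' parents of both. Ordering of claims is deterministic (topological,
#' lexicographic within ties).
#'
#' @param dag a `sem_dag`.
#' @return list of claims, each `list(x, y, cond)`.
#' @export
basis_set <- function(dag) {
  claims <- list()
  nd <- dag$nodes
  for (j in seq_along(nd)) for (i in seq_len(j - 1)) {
    x <- nd[i]; y <- nd[j]
    if (.adjacent(dag, x, y)) next
    claims[[length(claims) + 1L]] <-
      list(x = x, y = y,
           cond = sort(setdiff(union(.parents(dag, x), .parents(dag, y)),
                               c(x, y))))
  }
  claims
}

# fit one component regression: response ~ predictors (+ random intercepts).
# Mixed fits that are degenerate (e.g. a lake-level response with a lake
# random intercept, where the intercept would absorb the residual) fall
# back to the fixed-effects-only fit; the fallback is marked with
# attr(fit, "re_dropped").
.fit_node <- function(response, predictors, data, family, random) {
  if (length(random)) {
    fit <- tryCatch(.fit_node_raw(response, predictors, data, family,
                                  random),
                    error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    fit <- .fit_node_raw(response, predictors, data, family, NULL)
    attr(fit, "re_dropped") <- TRUE
    return(fit)
  }
  .fit_node_raw(response, predictors, data, family, random)
}

.fit_node_raw <- function(response, predictors, data, family, random) {
  rhs <- c(if (length(predictors)) predictors else "1",
           if (length(random)) paste0("(1 | ", random, ")"))
  form <- stats::reformulate(rhs, response = response)
  if (!length(random)) {
    if (family == "binomial")
      stats::glm(form, data = data, family = stats::binomial())
    else stats::lm(form, data = data)
  } else if (family == "binomial") {
    suppressMessages(lme4::glmer(
      form, data = data, family = stats::binomial(),
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
  } else {
    suppressMessages(lme4::lmer(
      form, data = data,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
  }
}

# coefficient table with Wald p-values, uniform across engines
.coef_table <- function(fit) {
  if (inherits(fit, "merMod")) {
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    z <- cf / se
    data.frame(term = names(cf), estimate = unname(cf), se = unname(se),
               p = 2 * stats::pnorm(-abs(z)))
  } else {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               p = s[, 4])
  }
}

# (random-effect variances, residual variance, fixed-effect fitted values)
.variance_parts <- function(fit, family) {
  if (inherits(fit, "merMod")) {
    vc <- lme4::VarCorr(fit)
    re <- vapply(vc, function(m) m[1, 1], numeric(1))
    resid <- if (family == "binomial") pi^2 / 3
             else attr(vc, "sc")^2
    eta <- as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit))
  } else {
    re <- numeric(0)
    resid <- if (family == "binomial") pi^2 / 3
             else summary(fit)$sigma^2
    eta <- as.numeric(stats::model.matrix(fit) %*% stats::coef(fit))
  }
  list(re = re, resid = resid, var_fixed = stats::var(eta))
}

# count of estimated parameters of one component model
.n_params <- function(fit, family) {
  if (inherits(fit, "merMod"))
    length(lme4::fixef(fit)) + length(lme4::VarCorr(fit)) +
      (family != "binomial")
  else length(stats::coef(fit)) + (family != "binomial")
}

.node_family <- function(dag, node)
  if (node %in% dag$binary) "binomial" else "gaussian"

#' Fit the component models of a piecewise SEM
#'
#' One regression per endogenous node: the node on its parents, with the
#' DAG's random intercepts, Gaussian for continuous nodes and Bernoulli
#' (logit) for binary ones.
#'
#' @param dag a `sem_dag`.
#' @param data data.frame holding every node column (and the grouping
#'   columns).
#' @return list of class `sem_fit`: `dag`, `components` (per endogenous
#'   node: fit, family, coefficients), `K` (total estimated parameters),
#'   `data`.
#' @export
sem_fit <- function(dag, data) {
  endo <- dag$nodes[vapply(dag$nodes, function(nd)
    length(.parents(dag, nd)) > 0, logical(1))]
  components <- lapply(endo, function(nd) {
    fam <- .node_family(dag, nd)
    fit <- .fit_node(nd, .parents(dag, nd), data, fam, dag$random)
    list(node = nd, family = fam, fit = fit, coef = .coef_table(fit),
         variances = .variance_parts(fit, fam),
         k = .n_params(fit, fam))
  })
  names(components) <- endo
  structure(list(dag = dag, components = components,
                 K = sum(vapply(components, `[[`, numeric(1), "k")),
                 data = data),
            class = "sem_fit")
}

#' d-separation test of a piecewise SEM
#'
#' Each basis-set claim `(X, Y | Z)` is tested by regressing `Y` (the
#' later node in topological order) on `Z` plus `X` — with the family
#' and random intercepts of the DAG — and taking the two-sided Wald
#' p-value of `X`. Fisher's `C = -2 sum log p` is chi-squared with
#' `2 * (number of claims)` degrees of freedom under the model, and the
#' d-sep information criterion is `AIC = C + 2 K` with `K` the total
#' parameter count across component models.
#'
#' @param fit a `sem_fit` (or a `sem_dag`, in which case component
#'   models are fitted on `data` first).
#' @param data data.frame (defaults to the fit's data).
#' @return list of class `dsep_result`: `claims` (data.frame `x`, `y`,
#'   `cond`, `estimate`, `p`), `C`, `df`, `pvalue`, `K`, `aic`.
#' @export
dsep_test <- function(fit, data = NULL) {
  if (inherits(fit, "sem_dag")) fit <- sem_fit(fit, data)
  dag <- fit$dag
  if (is.null(data)) data <- fit$data
  claims <- basis_set(dag)
  rows <- lapply(claims, function(cl) {
    fam <- .node_family(dag, cl$y)
    m <- .fit_node(cl$y, c(cl$cond, cl$x), data, fam, dag$random)
    ct <- .coef_table(m)
    r <- ct[ct$term == cl$x, ]
    data.frame(x = cl$x, y = cl$y,
               cond = paste(cl$cond, collapse = "+"),
               estimate = r$estimate, p = r$p)
  })
  claims_df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(x = character(), y = character(), cond = character(),
                    estimate = numeric(), p = numeric())
  fc <- fisher_c(claims_df$p)
  structure(list(claims = claims_df, C = fc$C, df = fc$df,
                 pvalue = fc$pvalue, K = fit$K, aic = fc$C + 2 * fit$K),
            class = "dsep_result")
}

#' Fisher's C statistic over independence-claim p-values
#'
#' `C = -2 sum log p`, chi-squared with `2 * length(p)` degrees of
#' freedom when the claims hold.
#'
#' @param p vector of claim p-values.
#' @return list `C`, `df`, `pvalue`.
#' @export
fisher_c <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p <- pmax(p, .Machine$double.xmin)
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df,
       pvalue = if (df > 0) 1 - stats::pchisq(C, df) else 1)
}

#' @exportS3Method base::print
print.dsep_result <- function(x, ...) {
  cat(sprintf("Fisher's C = %.2f, d.f. = %d, p = %.3f; K = %d, AIC = %.2f\n",
              x$C, x$df, x$pvalue, x$K, x$aic))
  if (nrow(x$claims)) print(x$claims, digits = 3)
  invisible(x)
}

#' Standardized path coefficients
#'
#' Linear components: `beta * sd(x) / sd(y)`. Bernoulli components use
#' the latent-theoretic scale: `beta * sd(x) / sqrt(var_fixed +
#' sum(var_random) + pi^2 / 3)`, extending the observation-variance
#' standardization to mixed models by including the random-effect
#' variances in the denominator.
#'
#' @param fit a `sem_fit`.
#' @return data.frame `from`, `to`, `estimate` (raw), `std_estimate`,
#'   `p`.
#' @export
standardize_paths <- function(fit) {
  data <- fit$data
  rows <- lapply(seq_len(nrow(fit$dag$edges)), function(i) {
    from <- fit$dag$edges$from[i]; to <- fit$dag$edges$to[i]
    comp <- fit$components[[to]]
    r <- comp$coef[comp$coef$term == from, ]
    sdx <- stats::sd(data[[from]])
    if (sdx == 0) stop("zero-variance predictor: ", from)
    denom <- if (comp$family == "binomial")
      sqrt(comp$variances$var_fixed + sum(comp$variances$re) + pi^2 / 3)
    else stats::sd(data[[to]])
    data.frame(from = from, to = to, estimate = r$estimate,
               std_estimate = r$estimate * sdx / denom, p = r$p)
  })
  do.call(rbind, rows)
}

#' Direct, indirect, total and relative total effects on the response
#'
#' Direct effect: the standardized coefficient of the edge into the
#' response (0 when absent). Indirect effect: the sum over all directed
#' paths of length two or more of the product of standardized edge
#' coefficients. Relative total: `|total| / sum |total| * 100`.
#'
#' @param fit a `sem_fit`.
#' @param std standardized edge table from [standardize_paths()]
#'   (computed if missing).
#' @param response terminal node (default the DAG's binary node).
#' @param significant_only drop edges with `p >= alpha` before the
#'   decomposition (default FALSE).
#' @param alpha significance cutoff used when `significant_only`.
#' @return data.frame per non-response node: `direct`, `indirect`,
#'   `total`, `relative_total`.
#' @export
effects_decomposition <- function(fit, std = NULL, response = NULL,
                                  significant_only = FALSE, alpha = 0.05) {
  if (is.null(std)) std <- standardize_paths(fit)
  if (is.null(response))
    response <- if (length(fit$dag$binary)) fit$dag$binary[1]
                else fit$dag$nodes[length(fit$dag$nodes)]
  if (significant_only) std <- std[std$p < alpha, , drop = FALSE]
  nodes <- setdiff(fit$dag$nodes, response)
  # sum of products of coefficients over all directed paths from `v`
  # to the response, split by path length 1 vs >= 2
  paths_total <- function(v) {
    direct <- 0; indirect <- 0
    walk <- function(node, prod, len) {
      out <- std[std$from == node, , drop = FALSE]
      for (i in seq_len(nrow(out))) {
        val <- prod * out$std_estimate[i]
        if (out$to[i] == response) {
          if (len == 0) direct <<- direct + val
          else indirect <<- indirect + val
        } else walk(out$to[i], val, len + 1)
      }
    }
    walk(v, 1, 0)
    c(direct = direct, indirect = indirect)
  }
  eff <- t(vapply(nodes, paths_total, numeric(2)))
  out <- data.frame(node = nodes, direct = eff[, "direct"],
                    indirect = eff[, "indirect"],
                    total = eff[, "direct"] + eff[, "indirect"])
  tot <- sum(abs(out$total))
  out$relative_total <- if (tot > 0) 100 * abs(out$total) / tot else NA_real_
  rownames(out) <- NULL
  out
}

#' Conditional R-squared of one component model
#'
#' `R2c = (var_fixed + var_random) / (var_fixed + var_random +
#' var_resid)`; for Bernoulli components the residual variance is the
#' latent-scale logistic variance `pi^2 / 3`.
#'
#' @param fit a fitted component model (`lm`, `glm`, `lmerMod`,
#'   `glmerMod`) or a `sem_fit` (returns one value per endogenous node).
#' @param family `"gaussian"` or `"binomial"` (ignored for `sem_fit`).
#' @export
conditional_r2 <- function(fit, family = "gaussian") {
  if (inherits(fit, "sem_fit"))
    return(vapply(fit$components, function(cp)
      conditional_r2(cp$fit, cp$family), numeric(1)))
  vp <- .variance_parts(fit, family)
  (vp$var_fixed + sum(vp$re)) /
    (vp$var_fixed + sum(vp$re) + vp$resid)
}

#' Default initial path model over the measured variables
#'
#' Geography drives native diversity, diversity drives the
#' introduced-native similarity metrics, and the two similarity metrics
#' plus lake area act directly on establishment. The temperature variant
#' replaces the three geographic drivers with accumulated and maximum
#' water temperature.
#'
#' @param temperature use `accum_temp`/`max_temp` instead of
#'   `latitude`/`elevation`/`area` as exogenous drivers.
#' @param random random-intercept grouping columns (default lake and
#'   species).
#' @return a `sem_dag` whose binary terminal node is `outcome`.
#' @export
default_sem_dag <- function(temperature = FALSE,
                            random = c("lake_id", "species_id")) {
  geo <- if (temperature) c("accum_temp", "max_temp")
         else c("latitude", "elevation", "area")
  edges <- rbind(
    data.frame(from = geo, to = "richness"),
    data.frame(from = "richness", to = c("native_mpd", "native_mfd")),
    data.frame(from = c("richness", "native_mpd"), to = "in_mpd"),
    data.frame(from = c("richness", "native_mfd"), to = "in_mfd"),
    data.frame(from = c("in_mpd", "in_mfd"), to = "outcome"),
    if (!temperature) data.frame(from = "area", to = "outcome"))
  sem_dag(edges, binary = "outcome", random = random)
}

#' Stepwise d-sep model selection
#'
#' Starting from an initial DAG, repeatedly adds one directed edge for a
#' violated independence claim (from the earlier node into the later
#' one, preserving acyclicity). At each step the violated claims are
#' tried in order of significance and the first candidate that lowers
#' the d-sep AIC (`C + 2K`) is kept; selection stops when no candidate
#' improves the AIC or no claim is violated.
#'
#' @param dag initial `sem_dag`.
#' @param data data.frame.
#' @param alpha violation threshold for candidate edges (default 0.05).
#' @param max_steps safety bound on added edges.
#' @param max_tries candidates examined per step (default 5).
#' @return list: `fit` (best `sem_fit`), `dsep` (its `dsep_result`),
#'   `ledger` (data.frame of candidate steps, accepted or not).
#' @export
sem_selection <- function(dag, data, alpha = 0.05, max_steps = 30,
                          max_tries = 5) {
  fit <- sem_fit(dag, data)
  ds <- dsep_test(fit)
  ledger <- data.frame(step = 0L, edge = "", accepted = TRUE,
                       C = ds$C, K = ds$K, aic = ds$aic)
  for (step in seq_len(max_steps)) {
    viol <- ds$claims[ds$claims$p < alpha, , drop = FALSE]
    if (!nrow(viol)) break
    viol <- viol[order(viol$p), , drop = FALSE]
    improved <- FALSE
    for (i in seq_len(min(nrow(viol), max_tries))) {
      cand_edge <- viol[i, ]
      cand <- sem_dag(rbind(dag$edges,
                            data.frame(from = cand_edge$x,
                                       to = cand_edge$y)),
                      binary = dag$binary, random = dag$random)
      cand_fit <- sem_fit(cand, data)
      cand_ds <- dsep_test(cand_fit)
      accept <- cand_ds$aic < ds$aic
      ledger <- rbind(ledger, data.frame(
        step = step, edge = paste(cand_edge$x, "->", cand_edge$y),
        accepted = accept, C = cand_ds$C, K = cand_ds$K,
        aic = cand_ds$aic))
      if (accept) {
        dag <- cand; fit <- cand_fit; ds <- cand_ds
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(fit = fit, dsep = ds, ledger = ledger)
}
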