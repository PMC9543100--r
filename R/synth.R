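#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the scale of the Swedish lakes introduction survey the
#' pipeline is designed for: 38 species total, an introduced pool of 23,
#' 965 introduction events, native richness between 2 and 27 with median
#' around 6 and declining toward high latitude and elevation, and a
#' latent logistic establishment model with a negative coefficient on
#' introduced-native phylogenetic distance and a positive one on
#' introduced-native functional distance.
#'
#' @param n_species number of species on the tree (default 38).
#' @param n_lakes number of lakes (default 100).
#' @param n_events number of introduction events (default 965).
#' @param birth_rate Yule birth rate (default 1).
#' @param lambda phylogenetic signal of the traits in `[0, 1]`:
#'   1 = pure Brownian motion, 0 = fully independent noise (default 0.7).
#' @param n_traits number of continuous traits (default 10).
#' @param richness_range attainable native richness (default `c(2, 27)`).
#' @param richness_mean expected richness at mean latitude/elevation.
#' @param slope_lat,slope_elev log-scale decline of expected richness per
#'   SD of latitude / elevation (defaults 0.35, 0.20).
#' @param beta0 intercept of the establishment model (logit scale).
#' @param beta_in_mpd,beta_in_mfd true standardized coefficients of the
#'   two focal predictors (defaults -0.6, +0.5).
#' @param beta_other_sd SD of the small true coefficients drawn for the
#'   six remaining predictors (default 0.15).
#' @param sigma_lake,sigma_species,sigma_phylo random-effect SDs
#'   (defaults 0.5 each).
#' @param n_introduced size of the introduced-species pool (default 23).
#' @param obs_frac_temp fraction of lakes with observed water
#'   temperatures (default 0.3).
#' @param phylo_cluster strength of phylogenetic clustering of native
#'   assemblages; 0 = none (default 1).
#' @param lat_range,elev_range lake latitude (deg N) and elevation (m)
#'   ranges.
#' @param seed root seed; all stage seeds derive from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_species = 38, n_lakes = 100, n_events = 965,
                         birth_rate = 1, lambda = 0.7, n_traits = 10,
                         richness_range = c(2, 27), richness_mean = 6.5,
                         slope_lat = 0.35, slope_elev = 0.20,
                         beta0 = 0, beta_in_mpd = -0.6, beta_in_mfd = 0.5,
                         beta_other_sd = 0.15,
                         sigma_lake = 0.5, sigma_species = 0.5,
                         sigma_phylo = 0.5, n_introduced = 23,
                         obs_frac_temp = 0.3, phylo_cluster = 1,
                         lat_range = c(55, 69), elev_range = c(0, 800),
                         seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, n_events >= 1,
            sigma_lake >= 0, sigma_species >= 0, sigma_phylo >= 0,
            n_introduced <= n_species)
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a Yule (pure-birth) ultrametric phylogeny
#'
#' @param n_species number of tips (at least 3).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return a `phylo` with tips relabelled `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  stopifnot(n_species >= 3)
  tree <- withr::with_seed(seed,
    ape::rphylo(n_species, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Simulate continuous traits with tunable phylogenetic signal
#'
#' Each trait is a blend `sqrt(lambda) * BM + sqrt(1 - lambda) * e` of a
#' Brownian-motion realization along the tree (unit rate) and iid normal
#' noise with variance equal to the Brownian tip variance, so the
#' marginal trait variance is unaffected by `lambda`.
#'
#' @param tree a `phylo`.
#' @param lambda signal in `[0, 1]`.
#' @param n_traits number of traits.
#' @param seed integer seed.
#' @return species x traits numeric matrix (rownames = tip labels).
#' @export
simulate_traits <- function(tree, lambda = 0.7, n_traits = 10, seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1)
  V <- ape::vcv(tree)
  n <- nrow(V)
  Lt <- chol(V + diag(1e-10, n))
  tipvar <- mean(diag(V))
  X <- withr::with_seed(seed, {
    bm <- crossprod(Lt, matrix(stats::rnorm(n * n_traits), n, n_traits))
    noise <- matrix(stats::rnorm(n * n_traits, sd = sqrt(tipvar)),
                    n, n_traits)
    sqrt(lambda) * bm + sqrt(1 - lambda) * noise
  })
  rownames(X) <- rownames(V)
  colnames(X) <- sprintf("trait%02d", seq_len(n_traits))
  X[order(rownames(X)), , drop = FALSE]
}

#' Simulate lakes and native communities along geographic gradients
#'
#' Latitude, elevation, area and depth are drawn from the configured
#' ranges; expected native richness declines log-linearly with
#' standardized latitude and elevation (Poisson, clipped to the
#' configured richness range); natives are sampled with mild phylogenetic
#' clustering (probability decaying with cophenetic distance to a random
#' anchor species). Accumulated/maximum water temperature are generated
#' from air temperature (a linear function of latitude and elevation plus
#' noise), depth and area, and observed only for a configured fraction of
#' lakes, leaving the rest for imputation.
#'
#' @param config a `synth_config`.
#' @param tree the species phylogeny.
#' @param seed integer seed.
#' @return list with `lakes` (data.frame) and `communities` (lake x
#'   species 0/1 matrix).
#' @export
simulate_lakes_and_communities <- function(config, tree, seed = 1L) {
  n <- config$n_lakes
  Dphy <- cophenetic_distances(tree)
  sp <- rownames(Dphy)
  withr::with_seed(seed, {
    lat <- stats::runif(n, config$lat_range[1], config$lat_range[2])
    elev <- stats::runif(n, config$elev_range[1], config$elev_range[2])
    area <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
    depth <- stats::rlnorm(n, meanlog = 2, sdlog = 0.5)
    air <- 1500 - 80 * (lat - mean(config$lat_range)) - 0.8 * elev +
      stats::rnorm(n, sd = 40)
    accum <- 50 + 0.85 * air - 6 * depth + 0.05 * area +
      stats::rnorm(n, sd = 30)
    maxt <- 8 + 0.008 * air - 0.08 * depth + 0.002 * area +
      stats::rnorm(n, sd = 0.8)
    obs <- stats::runif(n) < config$obs_frac_temp
    latz <- as.numeric(scale(lat)); elevz <- as.numeric(scale(elev))
    mu <- config$richness_mean *
      exp(-config$slope_lat * latz - config$slope_elev * elevz)
    rich <- pmin(pmax(stats::rpois(n, mu), config$richness_range[1]),
                 config$richness_range[2])
    communities <- matrix(0, n, length(sp),
                          dimnames = list(sprintf("lake%03d", seq_len(n)),
                                          sp))
    scale_d <- mean(Dphy[upper.tri(Dphy)])
    for (i in seq_len(n)) {
      anchor <- sample(sp, 1)
      w <- exp(-config$phylo_cluster * Dphy[anchor, ] / scale_d)
      natives <- sample(sp, rich[i], prob = w)
      communities[i, natives] <- 1
    }
    lakes <- data.frame(
      lake_id = rownames(communities), area = area, elevation = elev,
      latitude = lat, longitude = stats::runif(n, 11, 24), depth = depth,
      air_temp = air,
      accum_temp = ifelse(obs, accum, NA_real_),
      max_temp = ifelse(obs, maxt, NA_real_),
      accum_temp_true = accum, max_temp_true = maxt)
    list(lakes = lakes, communities = communities)
  })
}

#' Forward-simulate introduction events and establishment outcomes
#'
#' Events pair a lake with an exotic species drawn from the introduced
#' pool (unequal geometric frequencies, mimicking repeated introductions
#' of popular species), excluding species native to the target lake.
#' Covariates are computed through the metrics module and standardized;
#' the outcome is Bernoulli with
#' `logit p = beta0 + X beta + u_lake + v_species + w_species`, where `w`
#' is drawn from a multivariate normal with the (unit-diagonal-scaled)
#' phylogenetic covariance of the introduced pool.
#'
#' @param config a `synth_config`.
#' @param lakes,communities output of
#'   [simulate_lakes_and_communities()].
#' @param Dphy,Dfun species distance matrices.
#' @param tree the phylogeny (for the phylogenetic covariance of `w`).
#' @param seed integer seed.
#' @return records data.frame (`lake_id`, `species_id`, `outcome`,
#'   `year`); attribute `truth` holds the generating parameters and
#'   attribute `covariates` the standardized covariate table the outcomes
#'   were generated from.
#' @export
simulate_introductions <- function(config, lakes, communities, Dphy, Dfun,
                                   tree, seed = 1L) {
  sp <- colnames(communities)
  withr::with_seed(seed, {
    pool <- sort(sample(sp, config$n_introduced))
    pw <- 0.85^seq_along(pool); pw <- pw / sum(pw)
    n <- config$n_events
    lake_id <- character(n); species_id <- character(n)
    for (i in seq_len(n)) {
      repeat {
        lk <- sample(rownames(communities), 1)
        s <- sample(pool, 1, prob = pw)
        natives <- sp[communities[lk, ] == 1]
        if (!(s %in% natives) && length(natives) >= 2) break
      }
      lake_id[i] <- lk; species_id[i] <- s
    }
    records <- data.frame(lake_id = lake_id, species_id = species_id,
                          outcome = 0L,
                          year = sample(1900:2000, n, replace = TRUE))
    cov <- assemble_covariates(records, lakes, communities, Dphy, Dfun,
                               standardize = TRUE)
    stopifnot(nrow(cov) == n)
    preds <- c("in_mpd_z", "in_mfd_z", "native_mpd_z", "native_mfd_z",
               "richness_z", "area_z", "elevation_z", "latitude_z")
    beta <- c(config$beta_in_mpd, config$beta_in_mfd,
              stats::rnorm(6, 0, config$beta_other_sd))
    names(beta) <- preds
    X <- as.matrix(cov[, preds])
    u <- stats::rnorm(nrow(communities), 0, config$sigma_lake)
    names(u) <- rownames(communities)
    v <- stats::rnorm(length(pool), 0, config$sigma_species)
    names(v) <- pool
    Sig <- phylo_covariance(tree, pool)
    Lw <- chol(Sig + diag(1e-8, nrow(Sig)))
    w <- as.numeric(crossprod(Lw, stats::rnorm(length(pool)))) *
      config$sigma_phylo
    names(w) <- rownames(Sig)
    eta <- config$beta0 + as.numeric(X %*% beta) +
      u[cov$lake_id] + v[cov$species_id] + w[cov$species_id]
    records$outcome <- stats::rbinom(n, 1, stats::plogis(eta))
    cov$outcome <- records$outcome
    attr(records, "truth") <- list(beta0 = config$beta0, beta = beta,
                                   u = u, v = v, w = w, pool = pool,
                                   sigma = c(lake = config$sigma_lake,
                                             species = config$sigma_species,
                                             phylo = config$sigma_phylo))
    attr(records, "covariates") <- cov
    records
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs tree, trait, lake/community and introduction simulation with
#' stage seeds derived from the root seed, returning an object with the
#' same shape as [read_intro_data()] output plus the generating truth.
#'
#' @param config a `synth_config`.
#' @return list of class `intro_data` with elements `records`, `lakes`,
#'   `communities`, `traits`, `tree`, plus `Dphy`, `Dfun`, `covariates`
#'   and `truth`.
#' @export
synth_dataset <- function(config = synth_config()) {
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L, 4))
  tree <- simulate_tree(config$n_species, config$birth_rate, seeds[1])
  traits <- simulate_traits(tree, config$lambda, config$n_traits, seeds[2])
  lc <- simulate_lakes_and_communities(config, tree, seeds[3])
  Dphy <- cophenetic_distances(tree)
  Dfun <- functional_distances(trait_pca(traits))
  records <- simulate_introductions(config, lc$lakes, lc$communities,
                                    Dphy, Dfun, tree, seeds[4])
  structure(list(records = records, lakes = lc$lakes,
                 communities = lc$communities, traits = traits,
                 tree = tree, Dphy = Dphy, Dfun = Dfun,
                 covariates = attr(records, "covariates"),
                 truth = attr(records, "truth")),
            class = "intro_data")
}
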