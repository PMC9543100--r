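#' Read and cross-reference the four pipeline inputs
#'
#' Loads the introduction-events table, lake attributes, the lake x
#' species native presence matrix, the trait table (CSV, comma separated,
#' header row) and the rooted Newick phylogeny, and cross-references their
#' species and lake identifier sets.
#'
#' @param records_path,lakes_path,community_path,traits_path,tree_path
#'   file paths.
#' @param drop_unmatched drop introduction records whose species is absent
#'   from tree or traits instead of failing (default FALSE).
#' @return list of class `intro_data`: `records`, `lakes`, `communities`
#'   (numeric matrix, lakes x species), `traits` (numeric matrix),
#'   `tree` (`phylo`), and `report` (identifier cross-reference).
#' @export
read_intro_data <- function(records_path, lakes_path, community_path,
                            traits_path, tree_path,
                            drop_unmatched = FALSE) {
  for (p in c(records_path, lakes_path, community_path, traits_path,
              tree_path))
    if (!file.exists(p)) stop("missing input file: ", p)
  records <- utils::read.csv(records_path, stringsAsFactors = FALSE)
  stopifnot(all(c("lake_id", "species_id", "outcome") %in% names(records)))
  lakes <- utils::read.csv(lakes_path, stringsAsFactors = FALSE)
  stopifnot(all(c("lake_id", "area", "elevation", "latitude",
                  "longitude") %in% names(lakes)))
  comm_df <- utils::read.csv(community_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  communities <- as.matrix(comm_df[, -1, drop = FALSE])
  rownames(communities) <- as.character(comm_df[[1]])
  traits_df <- utils::read.csv(traits_path, stringsAsFactors = FALSE,
                               check.names = FALSE)
  traits <- as.matrix(traits_df[, -1, drop = FALSE])
  rownames(traits) <- as.character(traits_df[[1]])
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse Newick tree: ", tree_path)

  rec_sp <- unique(records$species_id[!is.na(records$species_id) &
                                        records$species_id != ""])
  comm_sp <- colnames(communities)
  report <- list(
    species_missing_from_tree = setdiff(union(rec_sp, comm_sp),
                                        tree$tip.label),
    species_missing_from_traits = setdiff(union(rec_sp, comm_sp),
                                          rownames(traits)),
    lakes_missing_from_attributes = setdiff(unique(records$lake_id),
                                            lakes$lake_id),
    lakes_missing_from_community = setdiff(unique(records$lake_id),
                                           rownames(communities))
  )
  bad <- intersect(rec_sp, union(report$species_missing_from_tree,
                                 report$species_missing_from_traits))
  if (length(bad)) {
    if (!drop_unmatched)
      stop("recorded species missing from tree or traits: ",
           paste(bad, collapse = ", "))
    records <- records[!records$species_id %in% bad, , drop = FALSE]
  }
  structure(list(records = records, lakes = lakes,
                 communities = communities, traits = traits, tree = tree,
                 report = report),
            class = "intro_data")
}

#' Apply the five data-cleaning filter rules
#'
#' The rules, numbered as in the source protocol: (1) drop introductions
#' into lakes whose native richness is zero; (2) drop introductions of
#' hybrid taxa; (3) drop records with a missing species name; (4) drop
#' native taxa recorded only at family rank from the communities; (5)
#' coerce uncertain presence codes (default 0.5) in the community matrix
#' to absence. Rules 4 and 5 redefine native richness and are therefore
#' applied before the richness screen of rule 1; every removal is logged
#' under its rule number. Filtering is idempotent.
#'
#' @param data an `intro_data` list (or any list with `records`, `lakes`,
#'   `communities` elements).
#' @param hybrid_taxa explicit species ids to treat as hybrids; ids
#'   containing the multiplication sign or `" x "` are always treated as
#'   hybrids.
#' @param family_level_taxa native column names resolved only to family
#'   rank, to be removed from the community matrix.
#' @param uncertain_code presence code meaning "unsure" (default 0.5);
#'   set to `NA` to coerce missing presences to 0 instead.
#' @return the filtered `intro_data`; attribute `filter_log` is a
#'   data.frame with one row per removal (rule, item, detail) and
#'   attribute `filter_counts` the per-rule removal counts.
#' @export
apply_filters <- function(data, hybrid_taxa = character(),
                          family_level_taxa = character(),
                          uncertain_code = 0.5) {
  records <- data$records
  communities <- data$communities
  log <- list()
  push <- function(rule, item, detail)
    log[[length(log) + 1L]] <<- data.frame(rule = rule, item = item,
                                           detail = detail)

  # rule 5: uncertain presence codes -> absent
  if (is.na(uncertain_code)) {
    n5 <- sum(is.na(communities))
    communities[is.na(communities)] <- 0
  } else {
    unc <- !is.na(communities) & communities == uncertain_code
    n5 <- sum(unc)
    communities[unc] <- 0
  }
  if (n5 > 0) push(5L, "presence cells", paste(n5, "uncertain codes set to 0"))

  # rule 4: family-rank native taxa removed from communities
  fam <- intersect(family_level_taxa, colnames(communities))
  for (f in fam) push(4L, f, "native taxon at family rank removed")
  if (length(fam))
    communities <- communities[, setdiff(colnames(communities), fam),
                               drop = FALSE]

  # rule 1: lakes with zero native richness
  richness <- rowSums(communities == 1)
  empty_lakes <- rownames(communities)[richness == 0]
  drop1 <- records$lake_id %in% empty_lakes
  for (lk in unique(records$lake_id[drop1]))
    push(1L, lk, "lake with native richness 0")

  # rule 2: hybrid introductions
  is_hybrid <- records$species_id %in% hybrid_taxa |
    grepl("×| x ", records$species_id)
  for (sp in unique(records$species_id[is_hybrid & !drop1]))
    push(2L, sp, "hybrid taxon")

  # rule 3: missing species name
  blank <- is.na(records$species_id) | trimws(records$species_id) == ""
  if (any(blank & !drop1 & !is_hybrid))
    push(3L, "records", paste(sum(blank & !drop1 & !is_hybrid),
                              "records with missing species name"))

  keep <- !(drop1 | is_hybrid | blank)
  out <- data
  out$records <- records[keep, , drop = FALSE]
  out$communities <- communities
  log_df <- if (length(log)) do.call(rbind, log)
            else data.frame(rule = integer(), item = character(),
                            detail = character())
  counts <- c(rule1 = sum(drop1), rule2 = sum(is_hybrid & !drop1),
              rule3 = sum(blank & !drop1 & !is_hybrid),
              rule4 = length(fam), rule5 = n5)
  attr(out, "filter_log") <- log_df
  attr(out, "filter_counts") <- counts
  out
}

#' Impute accumulated and maximum water temperature
#'
#' Two-stage ordinary least squares. Stage 1 regresses observed
#' accumulated air temperature on latitude and elevation and predicts air
#' temperature for every lake; stage 2 regresses each observed water
#' temperature (accumulated, then maximum) on depth, area and the
#' stage-1 prediction, and fills only the missing values. When the lakes
#' table has no `air_temp` column the reduced form is used: water
#' temperature regressed directly on depth, area, latitude and elevation.
#' Observed water temperatures are never altered.
#'
#' @param lakes data.frame with `latitude`, `elevation`, `depth`, `area`,
#'   optionally `air_temp`, and the partially observed targets
#'   `accum_temp` and/or `max_temp`.
#' @param targets water-temperature columns to impute.
#' @return `lakes` with targets filled; attribute `imputation` holds the
#'   fitted coefficients and R-squared per stage.
#' @export
impute_water_temperature <- function(lakes,
                                     targets = c("accum_temp", "max_temp")) {
  stopifnot(all(c("latitude", "elevation", "depth", "area") %in%
                  names(lakes)))
  info <- list()
  has_air <- "air_temp" %in% names(lakes)
  if (has_air) {
    obs_air <- !is.na(lakes$air_temp)
    if (sum(obs_air) < 4)
      stop("fewer observed air temperatures than regression parameters")
    m1 <- stats::lm(air_temp ~ latitude + elevation, data = lakes,
                    subset = obs_air)
    lakes$.air_hat <- as.numeric(stats::predict(m1, newdata = lakes))
    info$stage1 <- list(coef = stats::coef(m1),
                        r2 = summary(m1)$r.squared)
  }
  for (tg in intersect(targets, names(lakes))) {
    obs <- !is.na(lakes[[tg]])
    form <- if (has_air) stats::reformulate(c("depth", "area", ".air_hat"),
                                            response = tg)
            else stats::reformulate(c("depth", "area", "latitude",
                                      "elevation"), response = tg)
    p <- length(attr(stats::terms(form), "term.labels")) + 1L
    if (sum(obs) < p + 1L)
      stop("fewer observed lakes than parameters for ", tg)
    X <- stats::model.matrix(form[-2], data = lakes[obs, ])
    vifs <- tryCatch(vif_check(X[, -1, drop = FALSE]), error = identity)
    if (inherits(vifs, "error") || any(!is.finite(vifs)) ||
        any(vifs > 1e6))
      stop("collinear stage-2 design for ", tg, "; VIFs: ",
           paste(round(unlist(vifs), 1), collapse = ", "))
    m2 <- stats::lm(form, data = lakes, subset = obs)
    pred <- as.numeric(stats::predict(m2, newdata = lakes))
    lakes[[tg]][!obs] <- pred[!obs]
    info[[tg]] <- list(coef = stats::coef(m2), se = summary(m2)$coef[, 2],
                       r2 = summary(m2)$r.squared, n_obs = sum(obs),
                       vif = vifs)
  }
  lakes$.air_hat <- NULL
  attr(lakes, "imputation") <- info
  lakes
}

#' Write the intermediate tables of an `intro_data` object
#'
#' CSV writers that round-trip cell-for-cell with [read_intro_data()].
#'
#' @param data an `intro_data` list.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_intro_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.csv"),
             lakes = file.path(dir, "lakes.csv"),
             community = file.path(dir, "community.csv"),
             traits = file.path(dir, "traits.csv"),
             tree = file.path(dir, "tree.nwk"))
  utils::write.csv(data$records, paths["records"], row.names = FALSE)
  utils::write.csv(data$lakes, paths["lakes"], row.names = FALSE)
  comm <- data.frame(lake_id = rownames(data$communities),
                     data$communities, check.names = FALSE)
  utils::write.csv(comm, paths["community"], row.names = FALSE)
  tr <- data.frame(species_id = rownames(data$traits), data$traits,
                   check.names = FALSE)
  utils::write.csv(tr, paths["traits"], row.names = FALSE)
  ape::write.tree(data$tree, paths["tree"])
  invisible(paths)
}
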