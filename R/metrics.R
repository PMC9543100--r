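#' @title Community and introduced-native similarity metrics
#' @description Diversity metrics of a lake's native assemblage (MPD-type
#'   mean pairwise and MNTD-type mean nearest-neighbour distances) and
#'   similarity metrics between an introduced species and that assemblage
#'   (I-N mean and I-N nearest distances), evaluated on either the
#'   phylogenetic or the functional distance matrix.
#' @name similarity-metrics
NULL

.check_species <- function(sp, D, what) {
  miss <- setdiff(sp, rownames(D))
  if (length(miss))
    stop(what, " not in distance matrix: ", paste(miss, collapse = ", "))
}

#' Mean pairwise distance among a native assemblage
#'
#' @param native_set character vector of at least two species ids.
#' @param D distance matrix with species dimnames.
#' @return mean of d(i, j) over all unordered pairs.
#' @export
native_mean_pairwise <- function(native_set, D) {
  native_set <- unique(native_set)
  if (length(native_set) < 2)
    stop("undefined metric: native set has fewer than 2 species",
         call. = FALSE)
  .check_species(native_set, D, "native species")
  sub <- D[native_set, native_set]
  mean(sub[upper.tri(sub)])
}

#' Mean nearest-neighbour distance within a native assemblage
#'
#' @inheritParams native_mean_pairwise
#' @return mean over species i of min over j != i of d(i, j).
#' @export
native_mean_nearest <- function(native_set, D) {
  native_set <- unique(native_set)
  if (length(native_set) < 2)
    stop("undefined metric: native set has fewer than 2 species",
         call. = FALSE)
  .check_species(native_set, D, "native species")
  sub <- D[native_set, native_set]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

#' Mean distance from an introduced species to all natives
#'
#' The introduced species is excluded from the native set before averaging
#' (it may appear there through a data error).
#'
#' @param introduced single species id.
#' @param native_set character vector of native species ids (at least one
#'   after excluding `introduced`).
#' @param D distance matrix with species dimnames.
#' @export
introduced_native_mean <- function(introduced, native_set, D) {
  native_set <- setdiff(unique(native_set), introduced)
  if (length(native_set) < 1)
    stop("undefined metric: empty native set", call. = FALSE)
  .check_species(c(introduced, native_set), D, "species")
  mean(D[introduced, native_set])
}

#' Distance from an introduced species to its nearest native
#'
#' @inheritParams introduced_native_mean
#' @export
introduced_native_nearest <- function(introduced, native_set, D) {
  native_set <- setdiff(unique(native_set), introduced)
  if (length(native_set) < 1)
    stop("undefined metric: empty native set", call. = FALSE)
  .check_species(c(introduced, native_set), D, "species")
  min(D[introduced, native_set])
}

#' Assemble the per-introduction covariate table
#'
#' One row per introduction event, carrying the eight similarity/diversity
#' covariates (I-N MPD, I-N MFD, I-N MNTD, I-N MNFD; native MPD, MFD,
#' MNTD, MNFD), native richness and lake geography, plus z-score
#' standardized copies (suffix `_z`) computed over the retained event set.
#' Events whose lake has fewer than two native species (after excluding
#' the introduced species itself) are dropped and logged: the native
#' pairwise metrics are undefined there.
#'
#' @param records data.frame with columns `lake_id`, `species_id`,
#'   `outcome` (and optionally `year`).
#' @param lakes data.frame with columns `lake_id`, `area`, `elevation`,
#'   `latitude` (extra columns are carried through by name on request via
#'   `extra_lake_cols`).
#' @param communities lake x species 0/1 matrix (rownames = lake ids).
#' @param Dphy,Dfun phylogenetic and functional `dist_matrix` objects.
#' @param standardize append `_z` columns (default TRUE).
#' @param extra_lake_cols further lake columns to carry (e.g.
#'   `c("accum_temp", "max_temp")` for the temperature SEM variant).
#' @return data.frame of metrics; attribute `log` is a data.frame of
#'   dropped events with reasons, attribute `flagged` lists events whose
#'   introduced species was coded native in the target lake.
#' @export
assemble_covariates <- function(records, lakes, communities, Dphy, Dfun,
                                standardize = TRUE,
                                extra_lake_cols = character()) {
  stopifnot(all(c("lake_id", "species_id", "outcome") %in% names(records)))
  lakes <- as.data.frame(lakes)
  rownames(lakes) <- as.character(lakes$lake_id)
  miss_lake <- setdiff(unique(records$lake_id), rownames(communities))
  if (length(miss_lake))
    stop("lakes in records absent from community matrix: ",
         paste(miss_lake, collapse = ", "))
  n <- nrow(records)
  keep <- logical(n); flagged <- character(0)
  drops <- list()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lk <- as.character(records$lake_id[i])
    sp <- as.character(records$species_id[i])
    natives <- colnames(communities)[communities[lk, ] == 1]
    if (sp %in% natives) {
      flagged <- c(flagged, paste0(lk, ":", sp))
      natives <- setdiff(natives, sp)
    }
    if (length(natives) < 2) {
      drops[[length(drops) + 1L]] <-
        data.frame(lake_id = lk, species_id = sp,
                   reason = "fewer than 2 native species")
      next
    }
    keep[i] <- TRUE
    out[[i]] <- data.frame(
      lake_id = lk, species_id = sp,
      outcome = records$outcome[i],
      in_mpd = introduced_native_mean(sp, natives, Dphy),
      in_mfd = introduced_native_mean(sp, natives, Dfun),
      in_mntd = introduced_native_nearest(sp, natives, Dphy),
      in_mnfd = introduced_native_nearest(sp, natives, Dfun),
      native_mpd = native_mean_pairwise(natives, Dphy),
      native_mfd = native_mean_pairwise(natives, Dfun),
      native_mntd = native_mean_nearest(natives, Dphy),
      native_mnfd = native_mean_nearest(natives, Dfun),
      richness = length(natives),
      area = lakes[lk, "area"],
      elevation = lakes[lk, "elevation"],
      latitude = lakes[lk, "latitude"]
    )
  }
  tab <- do.call(rbind, out[keep])
  for (cc in extra_lake_cols)
    tab[[cc]] <- lakes[tab$lake_id, cc]
  if (standardize) {
    zcols <- c("in_mpd", "in_mfd", "in_mntd", "in_mnfd", "native_mpd",
               "native_mfd", "native_mntd", "native_mnfd", "richness",
               "area", "elevation", "latitude", extra_lake_cols)
    for (cc in zcols)
      tab[[paste0(cc, "_z")]] <- as.numeric(scale(tab[[cc]]))
  }
  rownames(tab) <- NULL
  attr(tab, "log") <- if (length(drops)) do.call(rbind, drops)
                      else data.frame(lake_id = character(),
                                      species_id = character(),
                                      reason = character())
  attr(tab, "flagged") <- flagged
  tab
}
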