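#' Pairwise phylogenetic (cophenetic) distances from a tree
#'
#' Sums branch lengths along the tip-to-tip path for every pair of tips,
#' optionally pruning an outgroup first. The result is the raw-scale
#' phylogenetic distance matrix used by all downstream similarity and
#' diversity metrics.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param outgroup optional tip label to drop before computing distances
#'   (e.g. a non-teleost rooting taxon).
#' @return a symmetric numeric matrix with species as dimnames and zero
#'   diagonal; attribute `kind` is `"phylogenetic"`.
#' @export
cophenetic_distances <- function(tree, outgroup = NULL) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label)
      stop("outgroup '", outgroup, "' is not a tip of the tree")
    tree <- ape::drop.tip(tree, outgroup)
  }
  D <- ape::cophenetic.phylo(tree)
  D <- D[order(rownames(D)), order(colnames(D))]
  new_dist_matrix(D, kind = "phylogenetic")
}

#' Construct a validated species-by-species distance matrix
#'
#' @param D square symmetric numeric matrix with species dimnames.
#' @param kind `"phylogenetic"` or `"functional"`.
#' @return `D` with class `dist_matrix` and a `kind` attribute.
#' @export
new_dist_matrix <- function(D, kind = c("phylogenetic", "functional")) {
  kind <- match.arg(kind)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D)))
    stop("D must carry identical species row and column names")
  if (any(!is.finite(D))) stop("non-finite distances")
  if (any(D < 0)) stop("negative distances")
  if (any(abs(D - t(D)) > 1e-8)) stop("D is not symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("D has a nonzero diagonal")
  diag(D) <- 0
  structure(D, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' Principal-component trait space from a morphological trait table
#'
#' Column-standardizes the traits (correlation-matrix PCA by default, since
#' morphological traits arrive on incommensurate scales) and retains the
#' first `npc` component scores. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param traits numeric matrix or data frame, species in rows (rownames =
#'   species ids), continuous traits in columns.
#' @param npc number of components to retain (default 5).
#' @param scale. standardize columns before decomposition (default TRUE).
#' @return a `trait_space` list: `scores` (species x npc), `loadings`,
#'   `var_explained` (fractions, all components).
#' @export
trait_pca <- function(traits, npc = 5, scale. = TRUE) {
  X <- as.matrix(traits)
  if (!is.numeric(X)) stop("traits must be numeric")
  if (is.null(rownames(X))) stop("traits must carry species rownames")
  if (any(!is.finite(X))) stop("non-finite trait values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (nrow(X) < npc + 1) stop("need more species than retained components")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  # deterministic sign: flip so the largest-|loading| entry is positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  npc <- min(npc, ncol(pc$x))
  structure(list(
    scores = pc$x[, seq_len(npc), drop = FALSE],
    loadings = pc$rotation,
    var_explained = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "trait_space")
}

#' Euclidean functional distances over retained principal components
#'
#' @param trait_space a `trait_space` from [trait_pca()], or a bare numeric
#'   score matrix with species rownames.
#' @return a `dist_matrix` of kind `"functional"`.
#' @export
functional_distances <- function(trait_space) {
  S <- if (inherits(trait_space, "trait_space")) trait_space$scores
       else as.matrix(trait_space)
  D <- as.matrix(stats::dist(S, method = "euclidean"))
  D <- D[order(rownames(D)), order(colnames(D))]
  new_dist_matrix(D, kind = "functional")
}

#' Functional dendrogram by agglomerative hierarchical clustering
#'
#' Species are ordered lexicographically before clustering so that ties in
#' merge heights resolve deterministically.
#'
#' @param D a `dist_matrix` (or plain symmetric matrix with dimnames).
#' @param method linkage: `"complete"` (default), `"average"` or
#'   `"ward.D2"`.
#' @return an `hclust` object; convert with [ape::as.phylo()] for Newick
#'   export.
#' @export
build_dendrogram <- function(D, method = c("complete", "average", "ward.D2")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  ord <- order(rownames(D))
  D <- D[ord, ord]
  stats::hclust(stats::as.dist(D), method = method)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles with a one-sided upper-tail
#' permutation p-value: rows and columns of `D2` are permuted jointly and
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`. With `exact = TRUE`
#' (n of at most 7 species) all `n!` permutations are enumerated and the
#' p-value is the exact proportion of permutations with `r >= r_obs`
#' (the identity permutation counts in the numerator).
#'
#' @param D1,D2 square symmetric matrices over the same species, in the
#'   same order (checked via dimnames when present).
#' @param n_perm number of random permutations (default 9999, minimum 99).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations instead of sampling.
#' @return list with elements `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999, seed = 1L, exact = FALSE) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("dimension mismatch")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("species orderings of D1 and D2 differ")
  n <- nrow(D1)
  ut <- upper.tri(D1)
  x <- D1[ut]
  if (stats::sd(x) == 0 || stats::sd(D2[ut]) == 0)
    stop("zero variance in a distance triangle")
  r_obs <- stats::cor(x, D2[ut])
  if (exact) {
    if (n > 7) stop("exact enumeration supported for n <= 7 species")
    perms <- .all_permutations(n)
    r_all <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stats::cor(x, D2[p, p][ut])
    }, numeric(1))
    return(list(r = r_obs, p = mean(r_all >= r_obs - 1e-12),
                n_perm = nrow(perms)))
  }
  if (n_perm < 99) stop("n_perm must be at least 99")
  r_perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(x, D2[p, p][ut])
  }, numeric(1)))
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1),
       n_perm = n_perm)
}

# all permutations of 1:n as a matrix (n! rows), recursive construction
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
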