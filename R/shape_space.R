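# PCA shape space over descriptor matrices: eigendecomposition of the
# sample variance-covariance matrix, contour reconstruction at the PC
# extremes, accession averaging, and the trait correlation/cluster analysis.

#' Fit a PCA shape space to a descriptor matrix
#'
#' PCA on the sample variance-covariance matrix (denominator n - 1; no
#' column standardization), computed through the SVD of the centered data.
#' Eigenvector signs follow a fixed convention: the largest-magnitude
#' loading of each component is positive, so scores are reproducible across
#' refits (e.g. cross-validation folds).
#'
#' @param m a [descriptor_matrix()] (seeds x features), or any numeric
#'   matrix.
#' @return An object of class `shape_space`: `mean`, orthonormal
#'   `eigenvectors` (features x components), `eigenvalues` (non-increasing),
#'   seed `scores`, `explained` variance fractions (summing to 1), plus the
#'   descriptor metadata needed for reconstruction.
#' @export
fit_pca <- function(m) {
  x <- unclass(m)
  n <- nrow(x)
  if (n < 2L) stop("PCA needs at least 2 rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  k <- min(n - 1L, ncol(x))
  d <- sv$d[seq_len(k)]
  v <- sv$v[, seq_len(k), drop = FALSE]
  ev <- d^2 / (n - 1L)
  # sign convention: largest-magnitude loading positive (first index on ties)
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) -1 else 1
  }, 0)
  v <- sweep(v, 2L, flip, `*`)
  scores <- xc %*% v
  tot <- sum(ev)
  expl <- if (tot > 0) ev / tot else rep(0, k)
  if (tot == 0) warning("constant descriptor matrix: all eigenvalues are 0")
  colnames(v) <- colnames(scores) <- paste0("PC", seq_len(k))
  dc <- attr(m, "dc")
  structure(list(mean = mu, eigenvectors = v, eigenvalues = ev,
                 scores = scores, explained = expl,
                 feature_kind = attr(m, "feature_kind"),
                 config = attr(m, "config"), P = attr(m, "P"),
                 dc_mean = if (is.null(dc)) c(0, 0) else colMeans(dc)),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d seeds, %d components (%s)\n",
              nrow(x$scores), length(x$eigenvalues),
              if (is.null(x$feature_kind)) "generic" else x$feature_kind))
  cat(sprintf("  first 4 PCs explain %.1f%% of variance\n",
              100 * sum(x$explained[seq_len(min(4, length(x$explained)))])))
  invisible(x)
}

# Turn a descriptor vector back into a contour, following the shape space's
# feature kind: SPP reshapes directly, EFD inverts the Fourier series.
descriptor_to_contour <- function(space, desc, P = NULL) {
  if (is.null(P)) P <- if (is.null(space$P)) 500L else space$P
  if (!is.null(space$feature_kind) && space$feature_kind == "SPP") {
    m <- matrix(desc, ncol = 2L)
    structure(list(points = cbind(x = m[, 1L], y = m[, 2L]),
                   base_index = 1L, view = "front", P = nrow(m)),
              class = c("resampled_contour", "contour"))
  } else {
    contour_from_efd(efd_from_vector(desc, dc = space$dc_mean), P = P)
  }
}

#' Reconstruct contours at the extremes of a principal component
#'
#' Builds the descriptor vectors `mean + k_sd * sqrt(eigenvalue) *
#' eigenvector` for k in (-k_sd, 0, +k_sd) and renders each as a contour
#' (SPP descriptors are reshaped to coordinates, EFD descriptors inverted
#' through the Fourier series). Used to visualize the morphological meaning
#' of each PC.
#'
#' @param s a `shape_space`.
#' @param pc component index.
#' @param k_sd score offset in standard deviations (default 2).
#' @return Named list of contours `minus`, `mean`, `plus`.
#' @export
reconstruct_pc_extremes <- function(s, pc, k_sd = 2) {
  pc <- as.integer(pc)
  if (pc < 1L || pc > length(s$eigenvalues)) stop("`pc` out of range")
  sd_pc <- sqrt(s$eigenvalues[pc])
  v <- s$eigenvectors[, pc]
  lapply(stats::setNames(c(-k_sd, 0, k_sd), c("minus", "mean", "plus")),
         function(k) descriptor_to_contour(s, s$mean + k * sd_pc * v))
}

#' Average descriptors by accession
#'
#' Arithmetic mean of the seed-level descriptor rows of each accession
#' (10 seeds per accession in the standard design). Accessions present in
#' the mapping but without any seed rows are dropped with a warning.
#'
#' @param m descriptor (or score) matrix with one row per seed.
#' @param mapping factor/character vector of accession ids, one per row.
#' @return Matrix of accession means (accessions x features), with an
#'   `n_seeds` attribute.
#' @export
average_by_accession <- function(m, mapping) {
  if (length(mapping) != nrow(m)) stop("every seed row must be mapped")
  f <- if (is.factor(mapping)) mapping else factor(mapping)
  empty <- setdiff(levels(f), unique(as.character(f)))
  if (length(empty))
    warning("accessions without seeds dropped: ", paste(empty, collapse = ", "))
  f <- droplevels(f)
  cnt <- as.integer(table(f))
  out <- rowsum(unclass(m), f) / cnt
  attr(out, "n_seeds") <- stats::setNames(cnt, levels(f))
  out
}

#' Correlation-based clustering of morphometric traits
#'
#' Pairwise Pearson correlation r across accessions, trait distance
#' d = 1 - r^2, centroid-linkage agglomeration. Traits with zero variance
#' are an error (their correlation is undefined).
#'
#' @param panel numeric matrix/data frame, accessions x traits (at least 3
#'   accessions and 2 traits).
#' @return The `hclust` dendrogram, with the distance matrix attached as
#'   attribute `distance`.
#' @export
trait_cluster <- function(panel) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 2L || nrow(panel) < 3L)
    stop("need at least 2 traits and 3 accessions")
  sds <- apply(panel, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trait(s): ",
         paste(colnames(panel)[sds == 0], collapse = ", "))
  r <- stats::cor(panel)
  d <- stats::as.dist(1 - r^2)
  hc <- stats::hclust(d, method = "centroid")
  attr(hc, "distance") <- d
  hc
}

#' Write a trait dendrogram as Newick text
#'
#' @param hc an `hclust` from [trait_cluster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
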