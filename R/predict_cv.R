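# Repeated 10-fold cross-validated genomic prediction of shape: per-PC
# mixed models, descriptor back-transform, contour rendering, and the
# contour-level Q2 accuracy statistic.

#' Cross-validation fold assignments shared across methods
#'
#' Accessions are shuffled with a fixed seed and split into `folds`
#' near-equal folds, independently per replicate. Passing the same fold
#' matrix to every method x procedure combination gives the paired design
#' needed for the ANOVA comparison.
#'
#' @param n number of accessions.
#' @param folds folds per replicate (default 10).
#' @param reps replicates (default 10).
#' @param seed RNG seed.
#' @return Integer matrix `n x reps` of fold labels in 1..folds.
#' @export
make_cv_folds <- function(n, folds = 10L, reps = 10L, seed = 1L) {
  set.seed(seed)
  sapply(seq_len(reps), function(r) sample(rep_len(seq_len(folds), n)))
}

#' Contour-level prediction accuracy Q2
#'
#' \deqn{Q^2 = 1 - \frac{\sum_l \sum_t (\bar x_{lt} - \hat x_{lt})^2 +
#'   (\bar y_{lt} - \hat y_{lt})^2}{\sum_l \sum_t (\bar x_{lt} - \bar{\bar
#'   x}_t)^2 + (\bar y_{lt} - \bar{\bar y}_t)^2}}
#' where \eqn{\bar x_{lt}} are the observed accession-mean coordinates,
#' \eqn{\hat x_{lt}} the predictions, and \eqn{\bar{\bar x}_t} the grand
#' mean over accessions at contour point t. 1 is perfect; 0 means no better
#' than predicting the grand-mean shape; worse than that is negative.
#'
#' @param obs,pred arrays `L x T x 2` (accessions x contour points x (x, y))
#'   or lists of contours in matching accession order.
#' @return The Q2 value.
#' @export
q2 <- function(obs, pred) {
  obs <- as_coord_array(obs)
  pred <- as_coord_array(pred)
  if (!all(dim(obs) == dim(pred))) stop("obs/pred dimensions differ")
  grand <- apply(obs, c(2L, 3L), mean)           # T x 2 grand-mean contour
  num <- sum((obs - pred)^2)
  den <- sum(sweep(obs, c(2L, 3L), grand)^2)
  if (den == 0) stop("all accession mean contours identical: Q2 undefined")
  1 - num / den
}

as_coord_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    pts <- lapply(x, function(ci) if (inherits(ci, "contour")) ci$points else ci)
    P <- nrow(pts[[1L]])
    arr <- array(0, c(length(pts), P, 2L))
    for (i in seq_along(pts)) arr[i, , ] <- pts[[i]]
    return(arr)
  }
  stop("cannot interpret contour collection")
}

#' Genomic prediction of seed shape under repeated k-fold cross-validation
#'
#' Each of the first `n_pcs` principal components is modeled separately
#' (GBLUP on the additive kinship, or multi-kernel Gaussian RKHS on the
#' genotypes). Predicted accession descriptors are assembled as
#' `mean + sum_k score_hat_k * eigenvector_k` (components beyond `n_pcs`
#' set to their mean, i.e. 0), rendered as contours, and scored against the
#' observed accession-mean contours with [q2()] once per replicate.
#'
#' @param space a `shape_space` fitted to the seed-level descriptors.
#' @param desc the seed-level [descriptor_matrix()] the space was fitted to.
#' @param mapping accession id per seed row of `desc`.
#' @param K additive kinship (for `model = "GBLUP"`); rows/cols named by
#'   accession.
#' @param g `genotype_matrix` (for `model = "RKHS"`).
#' @param model `"GBLUP"` or `"RKHS"`.
#' @param n_pcs PCs to predict (default 30; capped with a warning if fewer
#'   components exist).
#' @param folds,reps cross-validation design (default 10 x 10).
#' @param seed seed for the fold assignments (ignored when `fold_matrix`
#'   is given).
#' @param fold_matrix optional precomputed [make_cv_folds()] matrix, shared
#'   across method combinations.
#' @return An object of class `prediction_evaluation`: per-replicate `q2`,
#'   predicted scores (`pred_scores`, accessions x PCs x reps), observed
#'   accession scores, and the accession ids.
#' @export
predict_shape_cv <- function(space, desc, mapping, K = NULL, g = NULL,
                             model = c("GBLUP", "RKHS"), n_pcs = 30L,
                             folds = 10L, reps = 10L, seed = 1L,
                             fold_matrix = NULL) {
  model <- match.arg(model)
  if (model == "GBLUP" && is.null(K)) stop("GBLUP needs a kinship matrix K")
  if (model == "RKHS" && is.null(g)) stop("RKHS needs a genotype_matrix g")
  obs_desc <- average_by_accession(unclass(desc), mapping)
  acc <- rownames(obs_desc)
  L <- length(acc)
  navail <- ncol(space$scores)
  if (navail < n_pcs) {
    warning("only ", navail, " components available; predicting all of them")
    n_pcs <- navail
  }
  obs_scores <- average_by_accession(space$scores, mapping)[acc, , drop = FALSE]
  if (model == "GBLUP") {
    if (!is.null(rownames(K))) K <- K[acc, acc]
  } else {
    if (!is.null(rownames(g$geno))) g <- genotype_matrix(g$geno[acc, ], g$map)
    gk <- gaussian_kernels(g)
  }
  if (is.null(fold_matrix)) fold_matrix <- make_cv_folds(L, folds, reps, seed)
  reps <- ncol(fold_matrix)
  pred_scores <- array(0, c(L, n_pcs, reps),
                       dimnames = list(acc, paste0("PC", seq_len(n_pcs)), NULL))
  obs_contours <- descriptors_to_contours(space, obs_desc)
  q2s <- numeric(reps)
  for (r in seq_len(reps)) {
    fold <- fold_matrix[, r]
    for (fd in sort(unique(fold))) {
      test <- which(fold == fd); train <- which(fold != fd)
      if (model == "GBLUP") {
        eig <- eigen(K[train, train, drop = FALSE], symmetric = TRUE)
        for (k in seq_len(n_pcs)) {
          fit <- reml_kernel(obs_scores[train, k], K[train, train, drop = FALSE],
                             eig = eig)
          u <- fit$sigma_u2 * (K[test, train, drop = FALSE] %*% fit$Vinv_resid)
          pred_scores[test, k, r] <- fit$beta[1L] + as.numeric(u)
        }
      } else {
        ktr <- lapply(gk$kernels, function(Km) Km[train, train, drop = FALSE])
        for (k in seq_len(n_pcs)) {
          fit <- reml_multikernel(obs_scores[train, k], ktr)
          u <- numeric(length(test))
          for (j in seq_along(gk$kernels)) {
            u <- u + fit$sigma2[j] *
              as.numeric(gk$kernels[[j]][test, train, drop = FALSE] %*% fit$Vinv_resid)
          }
          pred_scores[test, k, r] <- fit$beta[1L] + u
        }
      }
    }
    pd <- matrix(space$mean, L, length(space$mean), byrow = TRUE) +
      pred_scores[, , r, drop = FALSE][, , 1L] %*%
        t(space$eigenvectors[, seq_len(n_pcs), drop = FALSE])
    pred_contours <- descriptors_to_contours(space, pd)
    q2s[r] <- q2(obs_contours, pred_contours)
  }
  structure(list(q2 = q2s, pred_scores = pred_scores, obs_scores = obs_scores,
                 accessions = acc, model = model, n_pcs = n_pcs,
                 fold_matrix = fold_matrix),
            class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat(sprintf("<prediction_evaluation> %s on %d accessions, %d PCs, %d reps\n",
              x$model, length(x$accessions), x$n_pcs, length(x$q2)))
  cat(sprintf("  Q2: mean %.3f (range %.3f .. %.3f)\n",
              mean(x$q2), min(x$q2), max(x$q2)))
  invisible(x)
}

# Render every row of a descriptor matrix as a contour coordinate array.
descriptors_to_contours <- function(space, desc_rows) {
  n <- nrow(desc_rows)
  first <- descriptor_to_contour(space, desc_rows[1L, ])
  arr <- array(0, c(n, nrow(first$points), 2L))
  arr[1L, , ] <- first$points
  if (n > 1L) for (i in 2:n)
    arr[i, , ] <- descriptor_to_contour(space, desc_rows[i, ])$points
  arr
}

#' ANOVA comparison of Q2 across methods and procedures
#'
#' Tests the main effects of the scale-standardization and
#' direction-standardization factors (and the descriptor method, when it
#' varies) on the replicate-level Q2 values from a balanced design with
#' shared CV splits.
#'
#' @param q2_table data frame with columns `q2`, `replicate`, and any of
#'   `method`, `procedure`, `scale`.
#' @return The `aov` summary table (data frame of F statistics and
#'   p-values).
#' @export
compare_methods_anova <- function(q2_table) {
  stopifnot(is.data.frame(q2_table), "q2" %in% names(q2_table))
  factors <- intersect(c("method", "procedure", "scale"), names(q2_table))
  factors <- factors[vapply(factors, function(f) length(unique(q2_table[[f]])) > 1L, TRUE)]
  if (length(factors) == 0L) stop("no varying factor to test")
  for (f in factors) q2_table[[f]] <- factor(q2_table[[f]])
  counts <- table(q2_table[factors])
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced Q2 table: shared CV splits are required")
  fml <- stats::as.formula(paste("q2 ~", paste(factors, collapse = " + ")))
  fit <- stats::aov(fml, data = q2_table)
  tab <- as.data.frame(summary(fit)[[1L]])
  names(tab) <- c("df", "sum_sq", "mean_sq", "F", "p")
  tab$term <- trimws(rownames(tab))
  rownames(tab) <- NULL
  tab[, c("term", "df", "sum_sq", "mean_sq", "F", "p")]
}
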