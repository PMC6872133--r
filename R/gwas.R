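# Q+K mixed-model association scan.  Population structure enters as fixed
# genotype-PC covariates (Q), family relatedness as a kinship random effect
# (K).  Variance components are estimated once on the marker-free null
# model (the P3D/EMMAX approximation) and each marker is then tested by a
# generalized-least-squares Wald/t test in the rotated model.

#' Benjamini-Hochberg step-up threshold
#'
#' Largest k with \eqn{p_{(k)} \le k \cdot fdr / m}; all p-values at or
#' below \eqn{p_{(k)}} are declared significant. The set is empty when no k
#' qualifies.
#'
#' @param pvals p-values in (0, 1].
#' @param fdr target false discovery rate (default 0.05).
#' @return List with `threshold` (NA when nothing passes) and logical
#'   `significant`.
#' @export
bh_threshold <- function(pvals, fdr = 0.05) {
  m <- length(pvals)
  s <- sort(pvals)
  ok <- which(s <= seq_len(m) * fdr / m)
  if (length(ok) == 0L)
    return(list(threshold = NA_real_, significant = rep(FALSE, m)))
  thr <- s[max(ok)]
  list(threshold = thr, significant = pvals <= thr)
}

#' Structure covariates: leading PCs of the genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param n_pcs number of PCs (default 6).
#' @return Lines x `n_pcs` score matrix.
#' @export
structure_pcs <- function(g, n_pcs = 6L) {
  W <- sweep(g$geno, 2L, colMeans(g$geno))
  sv <- svd(W, nu = n_pcs, nv = 0L)
  sc <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  colnames(sc) <- paste0("PC", seq_len(n_pcs))
  rownames(sc) <- rownames(g$geno)
  sc
}

#' Q+K mixed-model genome-wide association scan
#'
#' Per-marker model \eqn{y = m\beta + Qv + u + e} with
#' \eqn{u \sim (0, \sigma_g^2 K)}. Q holds the first `n_structure_pcs`
#' genotype PCs. Variance components are estimated by REML once on the null
#' model (no marker) and held fixed for every marker test
#' (population-parameters-previously-determined); each marker's effect is
#' then tested with a GLS t statistic after projecting out the fixed
#' covariates. Markers collinear with the covariates get p = 1 and a flag.
#' Significance is controlled at `fdr` by Benjamini-Hochberg.
#'
#' @param y named phenotype vector (accession means of a PC score, or any
#'   per-line trait).
#' @param g a MAF-filtered `genotype_matrix`.
#' @param K kinship matrix (default: [additive_relationship()] of `g`).
#' @param n_structure_pcs number of structure PCs (default 6).
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.05).
#' @return A data frame of class `gwas_result`: `marker`, `chr`, `pos`,
#'   `beta`, `se`, `stat`, `p`, `neglog10p`, `significant`, `flagged`, with
#'   the BH threshold and variance components as attributes.
#' @export
gwas_qk <- function(y, g, K = NULL, n_structure_pcs = 6L, fdr = 0.05) {
  if (anyNA(y)) stop("phenotype must be complete")
  if (!is.null(names(y)) && !is.null(rownames(g$geno)))
    y <- y[rownames(g$geno)]
  n <- length(y)
  if (n != nrow(g$geno)) stop("phenotype/genotype dimension mismatch")
  if (is.null(K)) K <- additive_relationship(g)
  Q <- structure_pcs(g, n_structure_pcs)
  X0 <- cbind(intercept = 1, Q)
  null_fit <- reml_kernel(y, K, X = X0)
  eig <- null_fit$eig
  w <- 1 / (null_fit$lambda * pmax(eig$values, 0) + 1)
  z <- sqrt(w)
  U <- eig$vectors
  yt <- z * as.numeric(crossprod(U, y))
  X0t <- z * crossprod(U, X0)
  Mt <- z * crossprod(U, g$geno)          # rotated, whitened marker columns
  qr0 <- qr(X0t)
  ry <- qr.resid(qr0, yt)
  RM <- qr.resid(qr0, Mt)
  mm <- colSums(RM^2)
  my <- as.numeric(crossprod(RM, ry))
  p0 <- ncol(X0t)
  df <- n - p0 - 1L
  flagged <- mm < 1e-8 * n
  beta <- ifelse(flagged, NA_real_, my / mm)
  rss <- sum(ry^2) - ifelse(flagged, 0, beta^2 * mm)
  se <- sqrt(pmax(rss, 0) / df / mm)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  p[flagged] <- 1
  stat[flagged] <- 0
  bh <- bh_threshold(p, fdr)
  out <- data.frame(marker = g$map$marker, chr = g$map$chr, pos = g$map$pos,
                    beta = beta, se = se, stat = stat, p = p,
                    neglog10p = -log10(p), significant = bh$significant,
                    flagged = flagged)
  attr(out, "bh_threshold") <- bh$threshold
  attr(out, "sigma_g2") <- null_fit$sigma_u2
  attr(out, "sigma_e2") <- null_fit$sigma_e2
  attr(out, "n_structure_pcs") <- n_structure_pcs
  class(out) <- c("gwas_result", "data.frame")
  out
}
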