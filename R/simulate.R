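# Synthetic genotype-to-shape data with known ground truth.
#
# Genotypes follow a Balding-Nichols structured panel of inbred lines.
# Seed contours are built from a superellipse template deformed by four
# heritable latent modes -- overall (log) size, front-view log aspect
# ratio, side-view log aspect ratio, and the depth of the indentation at
# the base landmark -- plus two environmental layers: a smooth random
# radial deformation field (low harmonics with a decaying spectrum, the
# realistic seed-to-seed component) and small per-point digitisation
# jitter.

#' Configuration of the synthetic genotype-to-shape simulator
#'
#' Defaults describe the standard desk-scale population: 300 accessions x
#' 10 seeds, a 2,000-marker / 10-chromosome inbred panel with 3
#' subpopulations, four latent shape modes with variance ratios 10:5:2:1
#' (variances 0.130, 0.065, 0.026, 0.013 for size, front aspect, side
#' aspect, indentation), heritabilities 0.8/0.7/0.6/0.5 (size most
#' heritable), per-point jitter of 0.5% of the mean radius and a smooth
#' environmental deformation field (harmonics 2..8, sd 0.02/k^1.5 per
#' component).
#'
#' @param n_accessions,seeds_per_accession population design.
#' @param n_markers,n_chromosomes,n_subpopulations,fst genotype panel.
#' @param n_qtl_per_mode QTL underlying each latent mode.
#' @param mode_variances named variances of the four latent modes.
#' @param h2_per_mode heritability of each mode, in `[0, 1]`.
#' @param noise_sd per-point jitter, as a fraction of the mean radius.
#' @param smooth_sd scale of the smooth environmental deformation field.
#' @param base_radius template radius in pixels.
#' @param residual_het probability of a heterozygous call in the inbred
#'   panel.
#' @param n_vertices vertices of each generated contour polygon.
#' @param master_seed seed controlling every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 300L, seeds_per_accession = 10L,
                       n_markers = 2000L, n_chromosomes = 10L,
                       n_subpopulations = 3L, fst = 0.15,
                       n_qtl_per_mode = 20L,
                       mode_variances = c(size = 0.130, front_aspect = 0.065,
                                          side_aspect = 0.026, indent = 0.013),
                       h2_per_mode = c(0.8, 0.7, 0.6, 0.5),
                       noise_sd = 0.005, smooth_sd = 0.02,
                       base_radius = 100, residual_het = 0.01,
                       n_vertices = 720L, master_seed = 1L) {
  stopifnot(all(h2_per_mode >= 0 & h2_per_mode <= 1),
            all(mode_variances >= 0), seeds_per_accession >= 1L,
            master_seed < 2^31 - 10)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a structured inbred genotype panel
#'
#' Balding-Nichols model: ancestral allele frequencies are uniform on
#' (0.1, 0.9); each subpopulation draws its frequency from the
#' corresponding Beta distribution with divergence `fst`; lines are inbred
#' (codes 0/2) apart from `residual_het` heterozygous calls. The marker map
#' places markers evenly along `n_chromosomes` chromosomes.
#'
#' @param cfg a [sim_config()].
#' @return A `genotype_matrix` with accessions `acc001 ...` and a
#'   `subpop` attribute.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$master_seed)
  m <- cfg$n_markers; n <- cfg$n_accessions; S <- cfg$n_subpopulations
  p0 <- stats::runif(m, 0.1, 0.9)
  shp <- (1 - cfg$fst) / cfg$fst
  psub <- matrix(0, S, m)
  for (s in seq_len(S)) psub[s, ] <- stats::rbeta(m, p0 * shp, (1 - p0) * shp)
  subpop <- rep_len(seq_len(S), n)
  geno <- matrix(0L, n, m)
  for (s in seq_len(S)) {
    rows <- which(subpop == s)
    draw <- matrix(stats::rbinom(length(rows) * m, 1L,
                                 rep(psub[s, ], each = length(rows))),
                   length(rows), m)
    geno[rows, ] <- 2L * draw
  }
  het <- matrix(stats::runif(n * m) < cfg$residual_het, n, m)
  geno[het] <- 1L
  rownames(geno) <- sprintf("acc%03d", seq_len(n))
  colnames(geno) <- sprintf("m%05d", seq_len(m))
  per_chr <- ceiling(m / cfg$n_chromosomes)
  map <- data.frame(marker = colnames(geno),
                    chr = rep(seq_len(cfg$n_chromosomes), each = per_chr)[seq_len(m)],
                    pos = ((seq_len(m) - 1L) %% per_chr + 1L) * 1e5)
  g <- genotype_matrix(geno, map)
  attr(g, "subpop") <- subpop
  g
}

# superellipse radius with exponent k and relative semi-axes (a, b)
superellipse_r <- function(theta, a, b, k = 2.5) {
  (abs(cos(theta) / a)^k + abs(sin(theta) / b)^k)^(-1 / k)
}

# render one seed polygon from its latent mode values; theta = 0 is the
# base landmark, which sits in the indentation
render_seed <- function(theta, size, aspect, indent, smooth_coefs, jitter_sd,
                        base_radius, dent_depth0 = 0.15, dent_width = 0.35) {
  a <- exp(aspect / 2); b <- exp(-aspect / 2)
  r <- base_radius * superellipse_r(theta, a, b)
  dd <- dent_depth0 + indent
  ang <- atan2(sin(theta), cos(theta))           # wrapped distance to 0
  r <- r * (1 - dd * exp(-0.5 * (ang / dent_width)^2))
  if (!is.null(smooth_coefs)) {
    dev <- rep(0, length(theta))
    for (k in seq_len(nrow(smooth_coefs)))
      dev <- dev + smooth_coefs[k, 1L] * cos((k + 1L) * theta) +
                   smooth_coefs[k, 2L] * sin((k + 1L) * theta)
    r <- r * (1 + dev)
  }
  pts <- cbind(x = r * cos(theta), y = r * sin(theta))
  if (jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sd * base_radius),
                        ncol = 2L)
  pts * exp(size)
}

#' Simulate seed contours from a genotype panel
#'
#' Per accession, the genetic value of each latent mode is the sum of its
#' planted QTL effects, rescaled so the between-accession variance is
#' `h2 * mode_variance`; each seed adds environmental mode noise with the
#' complementary variance, the smooth radial deformation field, and
#' per-point jitter. The contour template is a superellipse (front and side
#' views differ in their aspect mode) with a Gaussian indentation at the
#' base landmark, which is the first vertex of every contour.
#'
#' @param g a `genotype_matrix` from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @param views which views to render (default both).
#' @return A list of class `sim_shapes`: per-view named contour lists,
#'   `mapping` (data frame seed_id / accession_id), and `truth` (QTL
#'   indices/effects per mode, accession-level genetic mode values,
#'   seed-level realized mode values).
#' @export
simulate_shapes <- function(g, cfg, views = c("front", "side")) {
  set.seed(cfg$master_seed + 1L)
  n <- nrow(g$geno); S <- cfg$seeds_per_accession
  acc <- rownames(g$geno)
  modes <- names(cfg$mode_variances)
  W <- sweep(g$geno, 2L, colMeans(g$geno))
  qtl <- list(); gvals <- matrix(0, n, length(modes), dimnames = list(acc, modes))
  for (j in seq_along(modes)) {
    idx <- sample.int(ncol(W), cfg$n_qtl_per_mode)
    eff <- stats::rnorm(cfg$n_qtl_per_mode)
    gv <- as.numeric(W[, idx, drop = FALSE] %*% eff)
    target <- cfg$h2_per_mode[j] * cfg$mode_variances[j]
    sdg <- stats::sd(gv)
    gv <- if (target > 0 && sdg > 0) gv * sqrt(target) / sdg else rep(0, n)
    eff_scaled <- if (target > 0 && sdg > 0) eff * sqrt(target) / sdg else rep(0, length(eff))
    qtl[[modes[j]]] <- list(idx = idx, effects = eff_scaled)
    gvals[, j] <- gv
  }
  env_sd <- sqrt((1 - cfg$h2_per_mode) * cfg$mode_variances)
  seed_modes <- matrix(0, n * S, length(modes))
  for (j in seq_along(modes))
    seed_modes[, j] <- rep(gvals[, j], each = S) +
      stats::rnorm(n * S, 0, env_sd[j])
  seed_ids <- paste0(rep(acc, each = S), "_s", sprintf("%02d", rep(seq_len(S), n)))
  dimnames(seed_modes) <- list(seed_ids, modes)
  theta <- 2 * pi * (0:(cfg$n_vertices - 1L)) / cfg$n_vertices
  sm_k <- 2:8
  sm_sd <- cfg$smooth_sd / (sm_k^1.5)
  out <- list()
  for (v in views) {
    aspect_col <- if (v == "front") "front_aspect" else "side_aspect"
    cl <- vector("list", n * S)
    for (i in seq_len(n * S)) {
      smc <- cbind(stats::rnorm(length(sm_k), 0, sm_sd),
                   stats::rnorm(length(sm_k), 0, sm_sd))
      pts <- NULL
      for (try in 1:10) {
        pts <- render_seed(theta, seed_modes[i, "size"],
                           seed_modes[i, aspect_col], seed_modes[i, "indent"],
                           smc, cfg$noise_sd, cfg$base_radius)
        rad <- sqrt(rowSums(pts^2))
        if (all(rad > 0.05 * cfg$base_radius)) break
        pts <- NULL
      }
      if (is.null(pts)) stop("could not render a non-self-intersecting contour")
      cl[[i]] <- contour(pts, 1L, v)
    }
    names(cl) <- seed_ids
    out[[v]] <- cl
  }
  out$mapping <- data.frame(seed_id = seed_ids,
                            accession_id = rep(acc, each = S))
  out$truth <- list(qtl = qtl, accession_modes = gvals,
                    seed_modes = seed_modes, config = cfg)
  class(out) <- "sim_shapes"
  out
}

#' @export
print.sim_shapes <- function(x, ...) {
  v <- intersect(c("front", "side"), names(x))
  cat(sprintf("<sim_shapes> %d seeds, views: %s\n",
              nrow(x$mapping), paste(v, collapse = ", ")))
  invisible(x)
}

#' Rasterize contours into binary masks
#'
#' Even-odd scanline polygon fill onto a square canvas; contours are
#' translated to the canvas center. The base landmark of each contour is
#' reported in the landmark table in image coordinates, ready for
#' re-ingestion through [trace_contour()].
#'
#' @param contours named list of `contour`s.
#' @param image_size canvas side length in pixels.
#' @return List of class `mask_set`: `masks` (named list of
#'   [binary_image]s) and `landmarks` (data frame image_id, view, x, y).
#' @export
render_masks <- function(contours, image_size = 256L) {
  image_size <- as.integer(image_size)
  masks <- list(); lms <- NULL
  ctr <- (image_size - 1) / 2
  for (id in names(contours)) {
    cn <- contours[[id]]
    pts <- sweep(cn$points, 2L, colMeans(cn$points))
    pts <- sweep(pts, 2L, c(ctr, ctr), `+`)
    if (any(pts < 1 | pts > image_size - 2))
      stop("contour outside canvas: ", id)
    mask <- matrix(FALSE, image_size, image_size)
    px <- pts[, 1L]; py <- pts[, 2L]
    n <- length(px)
    j <- c(n, seq_len(n - 1L))
    for (row in seq_len(image_size)) {
      yy <- image_size - row                    # pixel-center y of this row
      crosses <- (py > yy) != (py[j] > yy)
      if (!any(crosses)) next
      xs <- px[crosses] + (yy - py[crosses]) *
        (px[j][crosses] - px[crosses]) / (py[j][crosses] - py[crosses])
      xs <- sort(xs)
      for (q in seq(1L, length(xs) - 1L, by = 2L)) {
        c1 <- ceiling(xs[q]); c2 <- floor(xs[q + 1L])
        if (c2 >= c1) mask[row, (c1:c2) + 1L] <- TRUE
      }
    }
    masks[[id]] <- binary_image(mask)
    base <- pts[cn$base_index, ]
    lms <- rbind(lms, data.frame(image_id = id, view = cn$view,
                                 x = base[1L], y = base[2L]))
  }
  structure(list(masks = masks, landmarks = lms), class = "mask_set")
}
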