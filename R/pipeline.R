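# Orchestration of the full comparison grid: descriptor method x
# standardization procedure x scale setting x view, with shared CV splits,
# per-combination shape spaces, trait panels, Q2 tables and GWAS scans.

#' Pipeline run configuration
#'
#' @param descriptors,procedures,scales,views the comparison grid
#'   (defaults: SPP/EFD20/EFD250 x SL/GPA/FESA/FESL x scaled/unscaled x
#'   front/side when data for both views exist).
#' @param n_pcs_gp PCs carried into genomic prediction (default 30).
#' @param n_pcs_gwas PCs scanned by GWAS (default 4; must not exceed
#'   `n_pcs_gp`).
#' @param cv_folds,cv_reps cross-validation design.
#' @param maf_threshold marker filter applied before genetics.
#' @param do_gp,do_gwas toggle the genetics stages.
#' @param gp_model `"GBLUP"` or `"RKHS"`.
#' @param P resampling density.
#' @param seed seed for the shared CV splits.
#' @return A list of class `run_config`.
#' @export
run_config <- function(descriptors = c("SPP", "EFD20", "EFD250"),
                       procedures = c("SL", "GPA", "FESA", "FESL"),
                       scales = c(TRUE, FALSE), views = c("front", "side"),
                       n_pcs_gp = 30L, n_pcs_gwas = 4L,
                       cv_folds = 10L, cv_reps = 10L, maf_threshold = 0.03,
                       do_gp = TRUE, do_gwas = FALSE, gp_model = "GBLUP",
                       P = 500L, seed = 1L) {
  if (n_pcs_gwas > n_pcs_gp) stop("n_pcs_gwas must not exceed n_pcs_gp")
  if (length(descriptors) == 0L || length(procedures) == 0L ||
      length(scales) == 0L || length(views) == 0L) stop("empty grid")
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the yaml package")
  vals <- yaml::yaml.load_file(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Run the full comparison grid
#'
#' For every combination in the grid: resample the contours of the view,
#' standardize, build the descriptor matrix, fit the PCA shape space, and
#' (optionally) run cross-validated genomic prediction scored by Q2 and a
#' Q+K GWAS of the leading accession-mean PC scores. One fold matrix per
#' replicate is shared across all combinations so Q2 values are paired.
#' Failures are isolated per combination: the run continues and the
#' failing cell records its error message.
#'
#' @param cfg a [run_config()].
#' @param contours list with entries `front` and/or `side`: named lists of
#'   `contour`s (e.g. from [simulate_shapes()] or [read_contours_csv()]).
#' @param mapping data frame `seed_id`, `accession_id`.
#' @param genotypes a `genotype_matrix` (required for GP/GWAS stages).
#' @param outdir optional directory for CSV outputs.
#' @return A list of class `grid_result`: per-combination results
#'   (`space`, `q2`, `gwas`, `trait_scores` or `error`), the combined
#'   `trait_panel`, the replicate-level `q2_table`, the ANOVA table (when
#'   at least two grid cells succeeded with GP on), and `status`
#'   (`"ok"`/`"partial"`/`"failed"`).
#' @export
run_grid <- function(cfg, contours, mapping, genotypes = NULL, outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  views <- intersect(cfg$views, names(contours))
  if (length(views) == 0L) stop("no contour data for the requested views")
  acc <- unique(mapping$accession_id)
  K <- NULL; gflt <- NULL
  if (!is.null(genotypes) && (cfg$do_gp || cfg$do_gwas)) {
    gflt <- maf_filter(genotypes, cfg$maf_threshold)
    gflt <- genotype_matrix(gflt$geno[acc, , drop = FALSE], gflt$map)
    K <- additive_relationship(gflt)
  }
  fold_matrix <- make_cv_folds(length(acc), cfg$cv_folds, cfg$cv_reps, cfg$seed)
  # resample and standardize once per view x procedure x scale
  resampled <- lapply(contours[views], function(cl) lapply(cl, resample, P = cfg$P))
  cells <- expand.grid(view = views, procedure = cfg$procedures,
                       scale = cfg$scales, descriptor = cfg$descriptors,
                       stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  q2_table <- NULL; panel <- NULL
  sets <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    label <- cell_label(cell)
    results[[i]] <- tryCatch({
      skey <- paste(cell$view, cell$procedure, cell$scale)
      if (is.null(sets[[skey]]))
        sets[[skey]] <- standardize_set(resampled[[cell$view]],
                                        procedure = cell$procedure,
                                        scale = cell$scale)
      desc <- descriptor_matrix(sets[[skey]], cell$descriptor)
      space <- fit_pca(desc)
      seed_map <- mapping$accession_id[match(rownames(desc), mapping$seed_id)]
      acc_scores <- average_by_accession(space$scores, seed_map)
      npc <- min(cfg$n_pcs_gwas, ncol(acc_scores))
      trait_scores <- acc_scores[, seq_len(npc), drop = FALSE]
      colnames(trait_scores) <- paste0(label, "_PC", seq_len(npc))
      res <- list(label = label, cell = cell, space = space,
                  trait_scores = trait_scores)
      if (cfg$do_gp && !is.null(K)) {
        pe <- predict_shape_cv(space, desc, seed_map, K = K, g = gflt,
                               model = cfg$gp_model, n_pcs = cfg$n_pcs_gp,
                               fold_matrix = fold_matrix)
        res$q2 <- pe$q2
      }
      if (cfg$do_gwas && !is.null(gflt)) {
        res$gwas <- lapply(seq_len(npc), function(k) {
          y <- stats::setNames(acc_scores[, k], rownames(acc_scores))
          gwas_qk(y, gflt, K = K)
        })
        names(res$gwas) <- colnames(trait_scores)
      }
      res
    }, error = function(e) list(label = label, cell = cell,
                                error = conditionMessage(e)))
  }
  ok <- !vapply(results, function(r) !is.null(r$error), TRUE)
  for (i in which(ok)) {
    r <- results[[i]]
    panel <- if (is.null(panel)) r$trait_scores else cbind(panel, r$trait_scores)
    if (!is.null(r$q2))
      q2_table <- rbind(q2_table,
                        data.frame(q2 = r$q2, replicate = seq_along(r$q2),
                                   method = r$cell$descriptor,
                                   procedure = r$cell$procedure,
                                   scale = ifelse(r$cell$scale, "scaleT", "scaleF"),
                                   view = r$cell$view))
  }
  anova_tab <- NULL
  if (!is.null(q2_table) && nrow(unique(q2_table[, c("method", "procedure",
                                                     "scale", "view")])) > 1L)
    anova_tab <- tryCatch(compare_methods_anova(q2_table), error = function(e) NULL)
  status <- if (all(ok)) "ok" else if (any(ok)) "partial" else "failed"
  out <- structure(list(results = results, trait_panel = panel,
                        q2_table = q2_table, anova = anova_tab,
                        cells = cells, status = status,
                        fold_matrix = fold_matrix),
                   class = "grid_result")
  if (!is.null(outdir)) write_grid_outputs(out, outdir)
  out
}

cell_label <- function(cell) {
  paste0(toupper(substr(cell$view, 1L, 1L)), "_", cell$procedure, "_",
         ifelse(cell$scale, "scaleT", "scaleF"), "_", cell$descriptor)
}

#' @export
print.grid_result <- function(x, ...) {
  nok <- sum(!vapply(x$results, function(r) !is.null(r$error), TRUE))
  cat(sprintf("<grid_result> %d/%d cells succeeded (%s)\n",
              nok, length(x$results), x$status))
  invisible(x)
}

write_grid_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$trait_panel))
    utils::write.csv(data.frame(accession_id = rownames(res$trait_panel),
                                res$trait_panel, check.names = FALSE),
                     file.path(outdir, "trait_panel.csv"), row.names = FALSE)
  if (!is.null(res$q2_table))
    utils::write.csv(res$q2_table, file.path(outdir, "q2_table.csv"),
                     row.names = FALSE)
  if (!is.null(res$anova))
    utils::write.csv(res$anova, file.path(outdir, "q2_anova.csv"),
                     row.names = FALSE)
  for (r in res$results) {
    if (!is.null(r$gwas)) {
      for (nm in names(r$gwas))
        utils::write.csv(r$gwas[[nm]],
                         file.path(outdir, paste0("gwas_", nm, ".csv")),
                         row.names = FALSE)
    }
  }
  invisible(outdir)
}

#' Trait panel labels
#'
#' Builds the `[view]_[procedure]_[scale]_[PC]` label grammar used for the
#' trait correlation/cluster analysis (e.g. `S_GPA_scaleF_PC2`).
#'
#' @param view `"front"` or `"side"`.
#' @param procedure standardization procedure name.
#' @param scale logical scale flag.
#' @param pc PC number.
#' @return Character label.
#' @export
trait_label <- function(view, procedure, scale, pc) {
  paste0(toupper(substr(view, 1L, 1L)), "_", procedure, "_",
         ifelse(scale, "scaleT", "scaleF"), "_PC", pc)
}
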