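# Plain-text serialization: contours, descriptor matrices with metadata
# headers, genotypes (CSV matrix + map, or VCF via vcfR), landmark tables.

#' Write contours to CSV
#'
#' Long format: `seed_id, view, point_index, x, y`; the base landmark is
#' `point_index` 0.
#'
#' @param contours named list of `contour`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(names(contours), function(id) {
    cn <- contours[[id]]
    n <- nrow(cn$points)
    ord <- c(cn$base_index:n, seq_len(cn$base_index - 1L))
    data.frame(seed_id = id, view = cn$view, point_index = seq_len(n) - 1L,
               x = cn$points[ord, 1L], y = cn$points[ord, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read contours from CSV
#'
#' @param path CSV written by [write_contours_csv()] (or matching its
#'   column contract).
#' @return Named list of `contour`s, base landmark first.
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$seed_id), function(d) {
    d <- d[order(d$point_index), ]
    contour(cbind(d$x, d$y), 1L, d$view[1L])
  })
  out[unique(df$seed_id)]
}

#' Write a descriptor matrix with a metadata header
#'
#' The header is a block of `# key=value` lines (feature kind, procedure,
#' scale flag, reference distance, P) followed by the CSV body.
#'
#' @param m a [descriptor_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptors_csv <- function(m, path) {
  cfg <- attr(m, "config")
  hdr <- c(paste0("# feature_kind=", attr(m, "feature_kind")),
           paste0("# procedure=", cfg$procedure),
           paste0("# scale=", cfg$scale),
           paste0("# c=", cfg$c),
           paste0("# P=", attr(m, "P")))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    data.frame(seed_id = rownames(m) %||% seq_len(nrow(m)), unclass(m)),
    path, sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
  invisible(path)
}

#' Read genotypes from a CSV matrix plus map
#'
#' @param geno_path CSV with lines in rows (first column line id), markers
#'   in columns, codes 0/1/2.
#' @param map_path CSV with columns `marker`, `chr`, `pos`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_csv <- function(geno_path, map_path = NULL) {
  df <- utils::read.csv(geno_path, check.names = FALSE)
  geno <- as.matrix(df[, -1L, drop = FALSE])
  rownames(geno) <- df[[1L]]
  map <- if (!is.null(map_path)) utils::read.csv(map_path) else NULL
  genotype_matrix(geno, map)
}

#' Write genotypes as CSV matrix plus map
#'
#' @param g a `genotype_matrix`.
#' @param geno_path,map_path output paths.
#' @return `geno_path`, invisibly.
#' @export
write_genotypes_csv <- function(g, geno_path, map_path = NULL) {
  utils::write.csv(data.frame(line = rownames(g$geno), g$geno,
                              check.names = FALSE),
                   geno_path, row.names = FALSE)
  if (!is.null(map_path)) utils::write.csv(g$map, map_path, row.names = FALSE)
  invisible(geno_path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Uses the GT field; genotypes are coded as counts of the alternate
#' allele. Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  code <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) sum(as.integer(al)), 0L)
  }
  geno <- t(apply(gt, 2L, code))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  colnames(geno) <- rownames(gt)
  map <- data.frame(marker = rownames(gt),
                    chr = vcfR::getCHROM(v), pos = vcfR::getPOS(v))
  genotype_matrix(geno, map)
}

#' Read a landmark table
#'
#' @param path CSV with columns `image_id`, `view`, `x`, `y`.
#' @return Data frame of landmarks.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "view", "x", "y")
  if (!all(need %in% names(df))) stop("landmark CSV needs columns ",
                                      paste(need, collapse = ", "))
  df
}
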