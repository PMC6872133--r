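# MAF filtering, the additive relationship matrix, GBLUP/RKHS prediction
# and the Q2 statistic.

test_that("MAF filter keeps markers strictly above the threshold", {
  geno <- cbind(rep(0, 10), c(1, rep(0, 9)), c(2, 2, rep(0, 8)))
  g <- genotype_matrix(geno)
  expect_equal(maf(g), c(0, 0.05, 0.2), ignore_attr = TRUE)
  gf <- maf_filter(g, 0.03)
  expect_equal(ncol(gf$geno), 2L)        # the 1/20 heterozygote marker stays
  g0 <- maf_filter(g, 0)
  expect_equal(ncol(g0$geno), 2L)        # only the monomorphic marker drops
  expect_error(maf_filter(genotype_matrix(matrix(0, 5, 2)), 0.03), "all markers")
})

test_that("additive relationship matches a direct evaluation of the formula", {
  set.seed(4)
  geno <- matrix(sample(0:2, 40, replace = TRUE), 5, 8)
  g <- genotype_matrix(geno)
  A <- additive_relationship(g)
  p <- colMeans(geno) / 2
  W <- sweep(geno, 2, 2 * p)
  A_oracle <- (W %*% t(W)) / (2 * sum(p * (1 - p)))
  expect_equal(unclass(A), A_oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(A - t(A))), 1e-10)
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  dup <- genotype_matrix(rbind(geno, geno[1, ]))
  Ad <- additive_relationship(dup)
  expect_equal(Ad[1, 6], Ad[1, 1], tolerance = 1e-12)  # identical lines

  big <- simulate_genotypes(sim_config(n_accessions = 200, n_markers = 1500,
                                       master_seed = 8))
  Ab <- additive_relationship(maf_filter(big))
  expect_lt(max(abs(rowMeans(Ab))), 0.15)              # centering property
})

test_that("GBLUP finds no heritability in pure noise and predicts the mean", {
  set.seed(11)
  g <- simulate_genotypes(sim_config(n_accessions = 200, n_markers = 1000,
                                     master_seed = 11))
  K <- additive_relationship(maf_filter(g))
  y <- stats::rnorm(200)
  fit <- gblup_fit_predict(y, K, 1:150, 151:200)
  expect_lt(fit$h2_hat, 0.1)
  expect_lt(stats::sd(fit$pred), 0.2 * stats::sd(y))
  expect_lt(abs(mean(fit$pred) - mean(y[1:150])), 0.2 * stats::sd(y))
})

test_that("GBLUP predicts a strongly structured trait well", {
  g <- simulate_genotypes(sim_config(n_accessions = 200, n_markers = 1000,
                                     n_subpopulations = 4, fst = 0.3,
                                     master_seed = 12))
  K <- additive_relationship(maf_filter(g))
  set.seed(12)
  cluster_mean <- c(-1.5, -0.5, 0.5, 1.5)[attr(g, "subpop")]
  y <- cluster_mean + stats::rnorm(200, 0, sqrt(0.01))
  folds <- make_cv_folds(200, 5, 1, seed = 2)[, 1]
  pred <- numeric(200)
  for (fd in 1:5) {
    te <- which(folds == fd)
    pred[te] <- gblup_fit_predict(y, K, which(folds != fd), te)$pred
  }
  expect_gt(stats::cor(pred, y), 0.9)
})

test_that("a duplicated line is predicted close to its twin's BLUP", {
  g <- simulate_genotypes(sim_config(n_accessions = 100, n_markers = 800,
                                     master_seed = 13))
  geno2 <- rbind(g$geno, dup = g$geno[1, ])
  rownames(geno2)[101] <- "dup"
  K <- additive_relationship(genotype_matrix(geno2, g$map))
  set.seed(13)
  W <- sweep(geno2, 2, colMeans(geno2))
  gv <- as.numeric(scale(W %*% stats::rnorm(800))) * sqrt(0.7)
  y <- gv + stats::rnorm(101, 0, sqrt(0.3))
  fit <- gblup_fit_predict(y, K, 1:100, 101)
  blup_twin <- fit$fit$beta[1] + fit$fit$u[1]
  expect_lt(abs(fit$pred - blup_twin), 0.05 * stats::sd(y))
})

test_that("GBLUP predictions are shift- and scale-equivariant in y", {
  g <- simulate_genotypes(sim_config(n_accessions = 80, n_markers = 400,
                                     master_seed = 14))
  K <- additive_relationship(maf_filter(g))
  set.seed(14)
  y <- as.numeric(scale(K %*% stats::rnorm(80))) + stats::rnorm(80, 0, 0.5)
  p1 <- gblup_fit_predict(y, K, 1:60, 61:80)$pred
  p2 <- gblup_fit_predict(y + 7, K, 1:60, 61:80)$pred
  p3 <- gblup_fit_predict(3 * y, K, 1:60, 61:80)$pred
  expect_equal(p2, p1 + 7, tolerance = 1e-6)
  expect_equal(p3, 3 * p1, tolerance = 1e-6)
})

test_that("Gaussian kernel bandwidths use the median squared distance", {
  geno <- rbind(L1 = rep(0, 10),
                L2 = c(2, rep(0, 9)),
                L3 = c(0, 2, 2, 2, 2, rep(0, 5)))
  gk <- gaussian_kernels(list(geno = geno))
  expect_equal(gk$M, 16)                 # median of {4, 16, 20}
  expect_equal(gk$h, c(1 / 5, 1, 5) / 16)
  expect_equal(unname(gk$kernels[[2]][1, 2]), exp(-4 / 16))
})

test_that("RKHS matches GBLUP on a linear trait and wins under epistasis", {
  g <- simulate_genotypes(sim_config(n_accessions = 150, n_markers = 500,
                                     master_seed = 15))
  gf <- maf_filter(g)
  K <- additive_relationship(gf)
  set.seed(15)
  W <- sweep(gf$geno, 2, colMeans(gf$geno))
  gv <- as.numeric(scale(W %*% stats::rnorm(ncol(W)))) * sqrt(0.7)
  y <- gv + stats::rnorm(150, 0, sqrt(0.3))
  acc <- function(pred, idx) stats::cor(pred, y[idx])
  a_g <- acc(gblup_fit_predict(y, K, 1:100, 101:150)$pred, 101:150)
  a_r <- acc(rkhs_fit_predict(y, gf, 1:100, 101:150)$pred, 101:150)
  expect_lt(abs(a_g - a_r), 0.05)

  # epistatic trait: pairwise products of 10 QTL
  wins <- 0L
  for (r in 1:10) {
    gi <- simulate_genotypes(sim_config(n_accessions = 120, n_markers = 300,
                                        master_seed = 300 + r))
    gfi <- maf_filter(gi)
    Ki <- additive_relationship(gfi)
    set.seed(400 + r)
    q <- sample(ncol(gfi$geno), 10)
    Wq <- sweep(gfi$geno[, q], 2, colMeans(gfi$geno[, q]))
    pairs <- utils::combn(10, 2)
    epi <- rowSums(sapply(seq_len(ncol(pairs)), function(j)
      Wq[, pairs[1, j]] * Wq[, pairs[2, j]] * stats::rnorm(1)))
    yi <- as.numeric(scale(epi)) + stats::rnorm(120, 0, 0.4)
    folds <- make_cv_folds(120, 3, 1, seed = r)[, 1]
    pg <- pr <- numeric(120)
    for (fd in 1:3) {
      te <- which(folds == fd); tr <- which(folds != fd)
      pg[te] <- gblup_fit_predict(yi, Ki, tr, te)$pred
      pr[te] <- rkhs_fit_predict(yi, gfi, tr, te)$pred
    }
    if (stats::cor(pr, yi) >= stats::cor(pg, yi)) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("Q2 identities and the hand-computed toy value", {
  set.seed(6)
  obs <- array(stats::rnorm(4 * 10 * 2), c(4, 10, 2))
  expect_equal(q2(obs, obs), 1)
  grand <- apply(obs, c(2, 3), mean)
  pred_mean <- aperm(array(grand, c(10, 2, 4)), c(3, 1, 2))
  expect_equal(q2(obs, pred_mean), 0)
  flipped <- 2 * pred_mean - obs         # reflect through the grand mean
  expect_lt(q2(obs, flipped), 0)

  obs_toy <- array(c(0, 1, 2, 4,  1, 3, 5, 7,
                     2, 2, 2, 2,  0, 1, 0, 1), c(4, 2, 2))
  pred_toy <- obs_toy + array(c(0.1, -0.2, 0.3, 0, rep(0.25, 4),
                                rep(-0.1, 4), rep(0, 4)), c(4, 2, 2))
  num <- den <- 0
  gm <- apply(obs_toy, c(2, 3), mean)
  for (l in 1:4) for (t in 1:2) {
    num <- num + (obs_toy[l, t, 1] - pred_toy[l, t, 1])^2 +
      (obs_toy[l, t, 2] - pred_toy[l, t, 2])^2
    den <- den + (obs_toy[l, t, 1] - gm[t, 1])^2 +
      (obs_toy[l, t, 2] - gm[t, 2])^2
  }
  expect_equal(q2(obs_toy, pred_toy), 1 - num / den, tolerance = 1e-12)
  same <- array(1, c(3, 5, 2))
  expect_error(q2(same, same * 0), "undefined")
})

test_that("the Q2 ANOVA detects planted factor effects and nothing else", {
  grid <- expand.grid(replicate = 1:10, procedure = c("SL", "GPA"),
                      scale = c("scaleT", "scaleF"))
  set.seed(7)
  resid <- stats::rnorm(nrow(grid), 0, 0.01)
  grid$q2 <- 0.5 + resid
  flat <- grid
  flat$q2 <- 0.5 + rep(resid[1:10], 4)   # identical cells
  tab0 <- compare_methods_anova(flat)
  expect_equal(tab0$F[tab0$term %in% c("procedure", "scale")], c(0, 0),
               tolerance = 1e-9)
  expect_equal(tab0$p[tab0$term %in% c("procedure", "scale")], c(1, 1),
               tolerance = 1e-9)

  grid$q2 <- grid$q2 + ifelse(grid$scale == "scaleF", 10 * stats::sd(resid), 0)
  tab <- compare_methods_anova(grid)
  expect_lt(tab$p[tab$term == "scale"], 0.01)

  perm <- grid
  perm$q2[perm$procedure == "SL" & perm$scale == "scaleT"] <-
    sample(perm$q2[perm$procedure == "SL" & perm$scale == "scaleT"])
  expect_equal(compare_methods_anova(perm)$F, tab$F, tolerance = 1e-12)

  expect_error(compare_methods_anova(grid[-1, ]), "unbalanced")
})

test_that("shape prediction under CV is deterministic and uses shared folds", {
  pop <- standard_population()
  sub <- pop$shapes$front[1:200]         # 20 accessions x 10 seeds
  rs <- lapply(sub, resample, 200)
  set <- standardize_set(rs, "GPA", scale = FALSE)
  desc <- descriptor_matrix(set, "SPP")
  space <- fit_pca(desc)
  mapping <- pop$shapes$mapping$accession_id[1:200]
  gf <- maf_filter(pop$genotypes)
  acc <- unique(mapping)
  gsub <- genotype_matrix(gf$geno[acc, ], gf$map)
  K <- additive_relationship(gsub)
  fm <- make_cv_folds(20, 4, 2, seed = 5)
  p1 <- predict_shape_cv(space, desc, mapping, K = K, model = "GBLUP",
                         n_pcs = 5, fold_matrix = fm)
  p2 <- predict_shape_cv(space, desc, mapping, K = K, model = "GBLUP",
                         n_pcs = 5, fold_matrix = fm)
  expect_identical(p1$q2, p2$q2)
  expect_length(p1$q2, 2L)
  expect_true(all(p1$q2 <= 1))
  expect_warning(
    predict_shape_cv(space, desc, mapping, K = K, model = "GBLUP",
                     n_pcs = 10000, fold_matrix = fm),
    "components available")
})
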