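# The standard synthetic population (300 accessions x 10 seeds, front
# view), standardized with GPA + scaling, with SPP and full-resolution EFD
# shape spaces.  Built once and cached for the tests that share it.

.pop_cache <- new.env(parent = emptyenv())

standard_population <- function() {
  if (is.null(.pop_cache$pop)) {
    cfg <- sim_config(master_seed = 1L)
    g <- simulate_genotypes(cfg)
    sh <- simulate_shapes(g, cfg, views = "front")
    rs <- lapply(sh$front, resample, 500L)
    set <- standardize_set(rs, "GPA", scale = TRUE)
    spp <- descriptor_matrix(set, "SPP")
    efd <- descriptor_matrix(set, "EFD250")
    .pop_cache$pop <- list(cfg = cfg, genotypes = g, shapes = sh, set = set,
                           pca_spp = fit_pca(spp), pca_efd = fit_pca(efd))
  }
  .pop_cache$pop
}
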