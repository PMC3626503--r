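# shared fixtures for the suite; everything is generated in code

default_rates <- function() error_rates(ado_het = 0.41, fdr = 6.7e-5)

# small population: full clonal structure, light backgrounds, fast to observe
small_config <- function(seed = 1, ...) {
  sim_config(n_germline_het_sites = 500, n_background_hom_sites = 2000,
             seed = seed, ...)
}

# one default-config pipeline run shared by tests in a session
.pipeline_cache <- new.env(parent = emptyenv())
pipeline_fixture <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.pipeline_cache[[key]]))
    .pipeline_cache[[key]] <- run_pipeline(sim_config(seed = seed))
  .pipeline_cache[[key]]
}

# stages up to calling on a default config (cheaper than the full pipeline)
called_fixture <- function(seed = 1) {
  key <- paste0("c", seed)
  if (is.null(.pipeline_cache[[key]])) {
    cfg <- sim_config(seed = seed)
    truth <- simulate_population(cfg)
    obs <- simulate_observations(truth, cfg)
    tissue <- simulate_tissue(truth)
    normal <- truth$cells$cell_id[!truth$cells$is_tumor]
    tumor <- truth$cells$cell_id[truth$cells$is_tumor]
    ann <- truth$sites[, c("site_id", "gene", "class")]
    calls <- call_somatic(obs, tissue, normal, tumor, 6, 3, ann)
    .pipeline_cache[[key]] <- list(cfg = cfg, truth = truth, obs = obs,
                                   tissue = tissue, normal = normal,
                                   tumor = tumor, ann = ann, calls = calls)
  }
  .pipeline_cache[[key]]
}
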