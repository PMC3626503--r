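#' Run the full synthetic single-cell somatic analysis pipeline
#'
#' End-to-end orchestration on simulated data: population and observation
#' simulation, per-cell QC, error-model estimation from normal cells,
#' binomial threshold derivation, somatic calling, bulk support, SMAFS
#' population genetics, and clonal reconstruction. Every stage consumes only
#' the outputs of earlier stages (never the simulation truth), except the
#' final recovery diagnostics which compare against the planted structure.
#' All randomness is seeded from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param exome_size exome size used in threshold derivation (default from
#'   config).
#' @param bulk_depth mean bulk-tissue depth (default 137).
#' @param bn_filter suspicious-gene filter threshold (default 0.5).
#' @param bulk_min_reads mutant reads required for bulk support (default 1).
#' @param estimator per-site frequency estimator feeding the SMAFS stages:
#'   "ml" (default; the ADO/FDR-aware maximum-likelihood estimator) or
#'   "count" (raw genotype counting).
#' @return object of class `pipeline_report`: a list with elements `truth`,
#'   `obs` (dimensions only), `qc`, `rates`, `thresholds`, `calls`,
#'   `call_summary`, `smafs` (spectrum, hyperbolic fit, NS-shift test, bulk
#'   R-squared), `clones` (H matrix, assignment, recovery diagnostics),
#'   `divergence`, `seed`.
#' @export
run_pipeline <- function(config = sim_config(), exome_size = config$exome_size_bp,
                         bulk_depth = 137, bn_filter = 0.5,
                         bulk_min_reads = 1, estimator = c("ml", "count")) {
  estimator <- match.arg(estimator)
  truth <- simulate_population(config)
  obs <- simulate_observations(truth, config)
  tissue <- simulate_tissue(truth)
  bulk <- simulate_bulk(truth, mean_depth = bulk_depth)
  targets <- sim_targets(truth)

  germline_sites <- truth$sites$site_id[truth$sites$group == "germline"]
  hom_sites <- truth$sites$site_id[truth$sites$group == "background"]

  qc <- qc_cells(obs, targets, sex = "male", germline_sites = germline_sites)
  qualified <- qc$cell_id[qc$qualified]
  normal_cells <- intersect(qualified,
                            truth$cells$cell_id[!truth$cells$is_tumor])
  tumor_cells <- intersect(qualified,
                           truth$cells$cell_id[truth$cells$is_tumor])
  if (length(normal_cells) == 0)
    stop("error-estimation stage: no qualified normal cells")
  if (length(tumor_cells) == 0)
    stop("calling stage: no qualified tumor cells")

  obs_q <- obs[obs$cell_id %in% qualified, , drop = FALSE]
  rates <- estimate_error_rates(
    obs_q[obs_q$cell_id %in% normal_cells, , drop = FALSE],
    tissue, germline_sites, hom_sites)

  thr_cancer <- min_mutant_cancer_cells(max(rates$fdr, 1e-12),
                                        length(tumor_cells), exome_size)
  thr_normal <- min_normal_cells_covered(rates$ado_het,
                                         length(normal_cells), exome_size)

  annotation <- truth$sites[, c("site_id", "gene", "class")]
  calls <- call_somatic(obs_q, tissue, normal_cells, tumor_cells,
                        min_normal_covered = thr_normal,
                        min_mutant_cancer = thr_cancer,
                        annotation = annotation)
  calls <- bulk_support(calls, bulk, min_reads = bulk_min_reads)
  call_summary <- summarize_calls(calls)

  freqs <- if (estimator == "ml") {
    tum_obs <- obs_q[obs_q$cell_id %in% tumor_cells &
                       obs_q$site_id %in% calls$site_id, , drop = FALSE]
    vapply(split(tum_obs, tum_obs$site_id)[calls$site_id], ml_frequency,
           numeric(1), rates = rates)
  } else calls$cell_freq
  spectrum <- build_spectrum(freqs, calls$class)
  hyp <- fit_hyperbolic(spectrum, exclude_bins = c(5, 6))
  ns <- freqs[calls$class == "NS" & !is.na(calls$class)]
  s <- freqs[calls$class == "S" & !is.na(calls$class)]
  shift <- if (length(ns) && length(s)) test_ns_shift(ns, s) else NULL
  bulk_at_calls <- bulk[match(calls$site_id, bulk$site_id), ]
  r2 <- correlate_with_bulk(freqs,
                            bulk_at_calls$mut_reads / bulk_at_calls$depth)

  ns_sites <- calls$site_id[calls$class == "NS" & !is.na(calls$class)]
  ann_ns <- annotation[annotation$site_id %in% ns_sites, , drop = FALSE]
  hm <- build_h_matrix(obs_q[obs_q$site_id %in% ns_sites, , drop = FALSE],
                       tissue, rates, ann_ns,
                       cells = c(tumor_cells, normal_cells),
                       normal_cells = normal_cells,
                       bn_filter_threshold = bn_filter)
  assign <- cluster_cells_genes(hm)

  tumor_clusters <- assign$cell_clusters[tumor_cells]
  recovery <- list(
    n_tumor_clusters = length(unique(tumor_clusters)),
    normal_separated = length(intersect(
      unique(assign$cell_clusters[normal_cells]),
      unique(tumor_clusters))) == 0)
  if (requireNamespace("mclust", quietly = TRUE)) {
    planted <- truth$cells$clone[match(names(assign$cell_clusters),
                                       truth$cells$cell_id)]
    recovery$ari <- mclust::adjustedRandIndex(assign$cell_clusters, planted)
  }

  structure(list(
    seed = config$seed, config = config, truth = truth,
    n_obs = nrow(obs), qc = qc, rates = rates,
    thresholds = c(min_mutant_cancer = as.integer(thr_cancer),
                   min_normal_covered = as.integer(thr_normal)),
    calls = calls, call_summary = call_summary,
    smafs = list(estimator = estimator, frequencies = freqs,
                 spectrum = spectrum, hyperbolic = hyp, ns_shift = shift,
                 bulk_r2 = r2),
    clones = list(h_matrix = hm, assignment = assign, recovery = recovery),
    divergence = divergence_generations(
      count = max(config$n_cloneB_muts, config$n_cloneC_muts),
      S = 6e7)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Single-cell somatic analysis pipeline report\n")
  cat(sprintf("  seed %d; %d observations; %d/%d cells qualified\n",
              x$seed, x$n_obs, sum(x$qc$qualified), nrow(x$qc)))
  cat(sprintf("  error model: ADO = %.3f, FDR = %.2e\n",
              x$rates$ado_het, x$rates$fdr))
  cat(sprintf("  thresholds: >=%d mutant cancer cells, >=%d covered normal cells\n",
              x$thresholds["min_mutant_cancer"],
              x$thresholds["min_normal_covered"]))
  cat(sprintf("  calls: %d somatic sites, NS/S = %s, bulk support %.2f%%\n",
              nrow(x$calls),
              format(x$call_summary$ns_s_ratio),
              x$call_summary$bulk_support_pct))
  cat(sprintf("  SMAFS: peak excess %s (goodness-of-fit p = %.2e), bulk R2 = %.3f\n",
              if (x$smafs$hyperbolic$peak_excess) "yes" else "no",
              x$smafs$hyperbolic$p_value, x$smafs$bulk_r2))
  cat(sprintf("  clones: %d tumor clusters, normal cells separated: %s\n",
              x$clones$recovery$n_tumor_clusters,
              x$clones$recovery$normal_separated))
  if (!is.null(x$clones$recovery$ari))
    cat(sprintf("  adjusted Rand index vs planted clones: %.3f\n",
                x$clones$recovery$ari))
  invisible(x)
}
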