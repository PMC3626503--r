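test_that("relative FNR arithmetic matches its definition", {
  prof <- data.frame(depth = c(10, 20, 30),
                     HR_T = c(0.5, 0.4, 0.5), CR_T = c(1, 1, 1),
                     HR_S = c(0.3, 0.4, 0.6), CR_S = c(1, 1, 1))
  expect_equal(relative_fnr(prof, 10), 0.4)
  expect_equal(relative_fnr(prof, 20), 0)
  expect_equal(relative_fnr(prof, 30), -0.2)  # tissue below cell: outlier
  prof$HR_T[1] <- 0
  expect_error(relative_fnr(prof, 10), "undefined")
})

test_that("allele dropout is recovered from a single normal cell", {
  cfg <- sim_config(seed = 21, n_tumor_cells = 3, n_normal_cells = 2,
                    n_ancestral_muts = 0, n_cloneB_muts = 0,
                    n_cloneC_muts = 0, n_neutral_tail_muts = 0,
                    n_germline_het_sites = 20000, n_background_hom_sites = 0)
  truth <- simulate_population(cfg)
  obs <- simulate_observations(truth, cfg, cells = "BN01")
  tissue <- simulate_tissue(truth)
  est <- estimate_ado(obs, tissue, truth$sites$site_id)
  expect_lt(abs(as.numeric(est) - 0.41), 0.03)
})

test_that("a noise-free cell has zero estimated dropout", {
  cfg <- sim_config(seed = 22, n_tumor_cells = 3, n_normal_cells = 2,
                    n_ancestral_muts = 0, n_cloneB_muts = 0,
                    n_cloneC_muts = 0, n_neutral_tail_muts = 0,
                    n_germline_het_sites = 10000, n_background_hom_sites = 0,
                    ado_het = 0, fdr_per_site = 0)
  truth <- simulate_population(cfg)
  obs <- simulate_observations(truth, cfg, cells = "BN01")
  tissue <- simulate_tissue(truth)
  est <- estimate_ado(obs, tissue, truth$sites$site_id)
  expect_lt(as.numeric(est), 0.01)
})

test_that("population ADO averages per-cell recoveries and increases monotonically", {
  grid <- c(0.2, 0.4, 0.6)
  est <- vapply(seq_along(grid), function(i) {
    cfg <- sim_config(seed = 30 + i, n_tumor_cells = 3, n_normal_cells = 2,
                      n_ancestral_muts = 0, n_cloneB_muts = 0,
                      n_cloneC_muts = 0, n_neutral_tail_muts = 0,
                      n_germline_het_sites = 15000,
                      n_background_hom_sites = 0, ado_het = grid[i])
    truth <- simulate_population(cfg)
    obs <- simulate_observations(truth, cfg, cells = "BN01")
    as.numeric(estimate_ado(obs, simulate_tissue(truth),
                            truth$sites$site_id))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(max(abs(est - grid)), 0.03)
  # two cells with distinct injected rates average to the midpoint
  expect_equal(mean(c(est[1], est[3])), 0.4, tolerance = 0.05)
})

test_that("FDR estimator reproduces hand arithmetic and recovers a grid", {
  tbl <- data.frame(cell_id = "BN01", site_id = sprintf("h%05d", 1:30000),
                    depth = 30, qual = 30, ranksum_p = 0.5,
                    genotype = c(rep("NC", 2), rep("NN", 29998)))
  est <- estimate_fdr(tbl, tbl$site_id)
  expect_equal(est$fdr, 2 / 30000)
  tbl$genotype <- "NN"
  expect_equal(estimate_fdr(tbl, tbl$site_id)$fdr, 0)
  expect_error(estimate_fdr(tbl[0, ], character(0)), "empty")

  for (f in c(1e-5, 6.7e-5, 1e-4)) {
    cfg <- sim_config(seed = round(1e5 * f), n_tumor_cells = 2,
                      n_normal_cells = 6, n_ancestral_muts = 0,
                      n_cloneB_muts = 0, n_cloneC_muts = 0,
                      n_neutral_tail_muts = 0, n_germline_het_sites = 0,
                      n_background_hom_sites = 100000, fdr_per_site = f)
    truth <- simulate_population(cfg)
    obs <- simulate_observations(truth, cfg,
                                 cells = sprintf("BN%02d", 1:6))
    est <- estimate_fdr(obs, truth$sites$site_id)
    se <- sqrt(f / est$n_pairs)
    expect_lt(abs(est$fdr - f), 3 * se + 1e-6)
  }
})

test_that("mitochondrial cross-check counts retained singleton variants", {
  v <- data.frame(cell_id = sprintf("BN%02d", 1:7), pos = 1:7 * 100,
                  mut_reads = 10)
  expect_equal(as.numeric(mito_fdr_crosscheck(v, 11)), 7 / (11 * 16561))
  expect_equal(as.numeric(mito_fdr_crosscheck(v[0, ], 11)), 0)
  expect_equal(as.numeric(mito_fdr_crosscheck(v[1, ], 1)), 1 / 16561)
  # shared variant excluded from the all-false-positive numerator
  v2 <- rbind(v, data.frame(cell_id = "BN08", pos = 100, mut_reads = 8))
  expect_equal(as.numeric(mito_fdr_crosscheck(v2, 11)), 6 / (11 * 16561))
  # low-support variants discarded before counting
  v$mut_reads[1:3] <- 4
  expect_equal(as.numeric(mito_fdr_crosscheck(v, 11)), 4 / (11 * 16561))
  expect_error(mito_fdr_crosscheck(v, 11, genome_len = 0), "positive")
})

test_that("SNP site filter applies all five criteria and names failures", {
  rec <- data.frame(qual = c(30, 30, 30, 30, 30, 15),
                    depth = c(10, 4, 10, 10, 10, 10),
                    allele_qual_p = c(0.5, 0.5, 0.005, 0.5, 0.5, 0.5),
                    dist_nearest = c(100, 100, 100, 3, 100, 100),
                    het_qual_ratio = c(1, 1, 1, 1, 0.25, 1))
  out <- snp_site_filter(rec)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reasons[2], "min_reads")
  expect_equal(out$reasons[3], "allele_quality_p")
  expect_equal(out$reasons[4], "snp_distance")
  expect_equal(out$reasons[5], "allele_quality_ratio")
  expect_equal(out$reasons[6], "quality")
  expect_error(snp_site_filter(rec[, -2]), "depth")
})

test_that("cell QC enforces coverage and the male X false-het check", {
  targets <- data.frame(chrom = rep(c("chr1", "chrX"), each = 500),
                        start = 0:999 * 10, end = 0:999 * 10 + 1)
  mk_cell <- function(id, n_auto, n_x, x_het) {
    data.frame(cell_id = id,
               chrom = c(rep("chr1", n_auto), rep("chrX", n_x)),
               pos = c(targets$start[seq_len(n_auto)],
                       targets$start[500 + seq_len(n_x)]) + 1L,
               ref = "A", alt = "T", depth = 30, mut_reads = 0, qual = 30,
               ranksum_p = 0.5,
               genotype = c(rep("NN", n_auto),
                            rep(c("NC", "NN"), c(x_het, n_x - x_het))))
  }
  obs <- rbind(mk_cell("good", 450, 450, 0),    # 90% coverage, clean X
               mk_cell("lowcov", 350, 349, 0),  # 69.9% coverage
               mk_cell("badx", 450, 450, 45))   # 10% X het rate
  qc <- qc_cells(obs, targets, sex = "male", baseline_rate = 6.7e-5)
  qc <- qc[match(c("good", "lowcov", "badx"), qc$cell_id), ]
  expect_equal(qc$qualified, c(TRUE, FALSE, FALSE))
  expect_match(qc$reason[2], "low coverage")
  expect_match(qc$reason[3], "X false-het")
  # permutation invariance in cell order
  qc2 <- qc_cells(obs[sample.int(nrow(obs)), ], targets, sex = "male",
                  baseline_rate = 6.7e-5)
  expect_equal(qc2[order(qc2$cell_id), ], qc[order(qc$cell_id), ],
               ignore_attr = TRUE)
  # unknown chromosomes are a hard error
  obs$chrom[1] <- "chr99"
  expect_error(qc_cells(obs, targets), "chr99")
})

test_that("full error model is estimated from simulated normal cells", {
  cfg <- sim_config(seed = 77, n_tumor_cells = 3, n_normal_cells = 5,
                    n_ancestral_muts = 0, n_cloneB_muts = 0,
                    n_cloneC_muts = 0, n_neutral_tail_muts = 0,
                    n_germline_het_sites = 10000,
                    n_background_hom_sites = 50000)
  truth <- simulate_population(cfg)
  obs <- simulate_observations(truth, cfg, cells = sprintf("BN%02d", 1:5))
  tissue <- simulate_tissue(truth)
  gl <- truth$sites$site_id[truth$sites$group == "germline"]
  hs <- truth$sites$site_id[truth$sites$group == "background"]
  rates <- estimate_error_rates(obs, tissue, gl, hs)
  expect_s3_class(rates, "error_rates")
  expect_equal(rates$ado_het, mean(rates$per_cell_ado))
  expect_lt(abs(rates$ado_het - 0.41), 0.03)
  expect_lt(abs(rates$fdr - 6.7e-5), 5e-5)
})
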