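test_that("tissue-derived genotype priors follow the quality tiers", {
  expect_equal(genotype_prior("NN", 30, 0.5),
               c(NN = 0.99, NC = 0.005, CC = 0.005))
  expect_equal(genotype_prior("NN", 5, 0.5),
               c(NN = 1 / 3, NC = 1 / 3, CC = 1 / 3))
  expect_equal(genotype_prior("NC", 15, 0.5),
               c(NN = 0.05, NC = 0.9, CC = 0.05))
  # a poor rank-sum p-value collapses the prior regardless of quality
  expect_equal(genotype_prior("NN", 30, 0.01),
               c(NN = 1 / 3, NC = 1 / 3, CC = 1 / 3))
  expect_error(genotype_prior("CC", 30, 0.5), "germline")
})

test_that("genotype likelihoods follow the calibrated binomial branches", {
  rates <- error_rates(ado_het = 0.41, ado_hom = 0.41, fdr = 6.7e-5)
  lk <- genotype_likelihood(0, 30, "NN", rates)
  expect_equal(lk[["NN"]], 0.59 * (1 - 6.7e-5)^30, tolerance = 1e-10)
  expect_equal(lk[["NC"]], 0.5 * 0.41 * (1 - 6.7e-5)^30, tolerance = 1e-10)
  lk2 <- genotype_likelihood(15, 30, "NC", rates)
  expect_equal(lk2[["NC"]], 1 - 0.41)
  # the mirrored homozygous-mutant branch
  lk3 <- genotype_likelihood(30, 30, "CC", rates)
  expect_equal(lk3[["CC"]], 0.59 * (1 - 6.7e-5)^30, tolerance = 1e-10)
  expect_equal(lk3[["NC"]], 0.5 * 0.41 * (1 - 6.7e-5)^30, tolerance = 1e-10)
  # noise-free degenerate case
  lk0 <- genotype_likelihood(0, 30, "NN", error_rates(0, 0))
  expect_equal(unname(lk0), c(1, 0, 0))
  # corrected variant drops the homozygous dropout factor
  lkc <- genotype_likelihood(0, 30, "NN", rates, corrected = TRUE)
  expect_equal(lkc[["NN"]], (1 - 6.7e-5)^30, tolerance = 1e-10)
  expect_error(genotype_likelihood(5, 0, "NN", rates), ">= 1")
})

test_that("posteriors are normalized everywhere", {
  set.seed(17)
  rates <- default_rates()
  for (r in 1:200) {
    n <- sample(1:80, 1)
    m <- sample(0:n, 1)
    gt <- sample(c("NN", "NC", "CC"), 1)
    pr <- genotype_prior(sample(c("NN", "NC"), 1),
                         sample(c(5, 15, 30), 1), stats::runif(1))
    pp <- genotype_posterior(pr, genotype_likelihood(m, n, gt, rates))
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    expect_true(all(pp >= 0))
  }
})

test_that("H score measures posterior mutant odds in log10", {
  expect_equal(h_score(c(NN = 1 / 3, NC = 1 / 3, CC = 1 / 3)), log10(2))
  expect_equal(h_score(c(NN = 0.5, NC = 0.5, CC = 0)), 0)
  expect_equal(h_score(c(NN = 0.005, NC = 0.9, CC = 0.095)), log10(199))
  # flooring keeps degenerate posteriors finite
  expect_true(is.finite(h_score(c(NN = 0, NC = 1, CC = 0))))
})

test_that("H matrix separates mutant from reference cells on clean data", {
  cfg <- small_config(31, ado_het = 0, ado_hom = 0, fdr_per_site = 0,
                      per_read_error = 0, coverage_fraction = 1)
  truth <- simulate_population(cfg)
  obs <- simulate_observations(truth, cfg)
  # reads fully consistent with the genotype (very low depth can otherwise
  # draw zero mutant reads for a true heterozygote, which the model rightly
  # scores as reference-like)
  obs$mut_reads <- ifelse(obs$genotype == "NC", pmax(1, obs$depth %/% 2),
                          ifelse(obs$genotype == "CC", obs$depth, 0L))
  tissue <- simulate_tissue(truth)
  rates <- error_rates(1e-6, 1e-9)  # vanishing but nonzero rates
  ann <- truth$sites[truth$sites$group %in%
                       c("ancestral", "cloneB", "cloneC"),
                     c("site_id", "gene", "class")]
  normal <- truth$cells$cell_id[!truth$cells$is_tumor]
  hm <- build_h_matrix(obs[obs$site_id %in% ann$site_id, ], tissue, rates,
                       ann, normal_cells = normal,
                       bn_filter_threshold = NA)
  g <- true_genotypes(truth, match(colnames(hm$site_H),
                                   truth$sites$site_id))
  g <- g[rownames(hm$site_H), ]
  seen <- !hm$imputed  # imputed entries average over cells of both signs
  expect_true(all((hm$site_H > 0)[seen] == (g != "NN")[seen]))
})

test_that("imputed H entries equal the observed column means exactly", {
  fx <- called_fixture(1)
  rates <- default_rates()
  ns_sites <- fx$calls$site_id[fx$calls$class == "NS"]
  hm <- build_h_matrix(fx$obs[fx$obs$site_id %in% ns_sites, ], fx$tissue,
                       rates, fx$ann[fx$ann$site_id %in% ns_sites, ],
                       cells = c(fx$tumor, fx$normal),
                       normal_cells = fx$normal)
  for (j in which(colSums(hm$imputed) > 0)) {
    observed <- hm$site_H[!hm$imputed[, j], j]
    imputed <- hm$site_H[hm$imputed[, j], j]
    expect_equal(unique(imputed), mean(observed), tolerance = 1e-12)
  }
})

test_that("suspicious genes red in normal cells are filtered", {
  cells <- c(sprintf("BC%02d", 1:6), sprintf("BN%02d", 1:3))
  mk <- function(site, gts) {
    data.frame(cell_id = cells, chrom = "chr1", pos = 1, ref = "A",
               alt = "T", depth = 30,
               mut_reads = ifelse(gts == "NC", 15, 0), qual = 30,
               ranksum_p = 0.5, genotype = gts, site_id = site)
  }
  obs <- rbind(mk("s1", c(rep("NC", 6), rep("NN", 3))),   # clean gene
               mk("s2", c(rep("NC", 6), "NC", "NN", "NN")))  # red BN cell
  tissue <- data.frame(site_id = c("s1", "s2"), genotype = "NN",
                       qual = 30, ranksum_p = 0.5)
  ann <- data.frame(site_id = c("s1", "s2"), gene = c("G1", "G2"))
  hm <- build_h_matrix(obs, tissue, default_rates(), ann,
                       normal_cells = sprintf("BN%02d", 1:3))
  expect_equal(hm$filtered_genes, "G2")
  expect_equal(colnames(hm$H), "G1")
})

test_that("clustering recovers the planted clones and ignores cell order", {
  rep1 <- pipeline_fixture(1)
  rec <- rep1$clones$recovery
  expect_equal(rec$n_tumor_clusters, 3L)
  expect_true(rec$normal_separated)
  expect_gte(rec$ari, 0.9)
  # permuting the cells leaves the partition unchanged
  hm <- rep1$clones$h_matrix
  set.seed(2)
  perm <- sample.int(nrow(hm$H))
  a1 <- cluster_cells_genes(hm$H)
  a2 <- cluster_cells_genes(hm$H[perm, ])
  expect_equal(a2$cell_clusters[rownames(hm$H)],
               a1$cell_clusters[rownames(hm$H)])
  expect_error(cluster_cells_genes(hm$H[1:2, ]), "3 cells")
})

test_that("a single planted clone clusters into tumor versus normal only", {
  cfg <- small_config(41, n_cloneB_muts = 0, n_cloneC_muts = 0,
                      n_neutral_tail_muts = 0)
  truth <- simulate_population(cfg)
  obs <- simulate_observations(truth, cfg)
  tissue <- simulate_tissue(truth)
  normal <- truth$cells$cell_id[!truth$cells$is_tumor]
  tumor <- truth$cells$cell_id[truth$cells$is_tumor]
  ann <- truth$sites[truth$sites$group == "ancestral",
                     c("site_id", "gene", "class")]
  hm <- build_h_matrix(obs[obs$site_id %in% ann$site_id, ], tissue,
                       default_rates(), ann,
                       cells = c(tumor, normal), normal_cells = normal)
  asg <- cluster_cells_genes(hm)
  expect_equal(asg$k_cells, 2L)
  expect_equal(length(unique(asg$cell_clusters[tumor])), 1L)
  expect_equal(length(unique(asg$cell_clusters[normal])), 1L)
})

test_that("exclusivity test matches the hypergeometric closed form", {
  M <- matrix(FALSE, 44, 2, dimnames = list(NULL, c("ga", "gb")))
  M[1:15, "ga"] <- TRUE
  M[16:30, "gb"] <- TRUE
  res <- exclusivity_test(M, "ga", "gb")
  expect_equal(res$exclusivity_p, choose(29, 15) / choose(44, 15),
               tolerance = 1e-12)
  # identical mutation vectors: maximal concurrence, no exclusivity
  M2 <- cbind(ga = c(rep(TRUE, 10), rep(FALSE, 10)),
              gb = c(rep(TRUE, 10), rep(FALSE, 10)))
  res2 <- exclusivity_test(M2, "ga", "gb")
  expect_equal(res2$exclusivity_p, 1)
  expect_lt(res2$concurrence_p, 1e-4)
  # all-mutant gene is uninformative
  M3 <- cbind(ga = rep(TRUE, 10), gb = rep(c(TRUE, FALSE), 5))
  res3 <- exclusivity_test(M3, "ga", "gb")
  expect_equal(res3$concurrence_p, 1)
  expect_equal(res3$exclusivity_p, 1)
})

test_that("exclusivity test agrees with enumeration on small tables", {
  set.seed(61)
  for (r in 1:50) {
    n <- sample(6:20, 1)
    ka <- sample(1:(n - 1), 1)
    kb <- sample(1:(n - 1), 1)
    a <- seq_len(n) %in% sample.int(n, ka)
    b <- seq_len(n) %in% sample.int(n, kb)
    if (!any(a) || !any(b)) next
    M <- cbind(ga = a, gb = b)
    res <- exclusivity_test(M, "ga", "gb")
    x <- sum(a & b)
    expect_equal(res$exclusivity_p, stats::phyper(x, ka, n - ka, kb),
                 tolerance = 1e-12)
    expect_equal(res$concurrence_p,
                 stats::phyper(x - 1, ka, n - ka, kb, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("divergence generations scale with count, rate and size", {
  est <- divergence_generations(12, 5e-9, 6e7)
  expect_equal(est$generations, 40L)
  expect_equal(divergence_generations(0)$generations, 0L)
  expect_equal(divergence_generations(12, 5e-9, 1.2e8)$generations, 20L)
  expect_error(divergence_generations(12, 0, 6e7), "positive")
})

test_that("cohort recurrence counts distinct patients per gene", {
  cohort <- data.frame(
    patient = c(sprintf("P%02d", 1:7), "P01", "P08", "P09", "P10", "P08"),
    gene = c(rep("CFTR", 7), "CFTR", "NIPBL", "NIPBL", "NIPBL", "ATM"))
  res <- survey_recurrence(c("CFTR", "NIPBL", "ATM", "ABSENT"), cohort)
  expect_equal(res$n_patients, c(7L, 3L, 1L, 0L))
  expect_equal(res$recurrent, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("PCA separates tumor from normal cells on its first component", {
  fx <- called_fixture(1)
  cells <- c(fx$tumor, fx$normal)
  o <- fx$obs[fx$obs$site_id %in% fx$calls$site_id &
                fx$obs$cell_id %in% cells, ]
  G <- matrix(NA_real_, length(cells), nrow(fx$calls),
              dimnames = list(cells, fx$calls$site_id))
  G[cbind(match(o$cell_id, cells), match(o$site_id, fx$calls$site_id))] <-
    c(NN = 0, NC = 1, CC = 2)[o$genotype]
  p <- pca_cells(G)
  pc1 <- p$x[, 1]
  rng_t <- range(pc1[fx$tumor]); rng_n <- range(pc1[fx$normal])
  expect_true(rng_t[2] < rng_n[1] || rng_n[2] < rng_t[1])
  # eigenvalue ordering
  expect_true(all(diff(p$sdev) <= 1e-12))
  # identical cells land on identical coordinates
  G2 <- matrix(rep(c(0, 1, 0, 2), 5), nrow = 5, ncol = 4, byrow = TRUE)
  p2 <- stats::prcomp(G2)
  expect_equal(max(abs(sweep(pca_cells(G2)$x, 2,
                             pca_cells(G2)$x[1, ]))), 0, tolerance = 1e-9)
  expect_error(pca_cells(matrix(1, 4, 3)), "constant")
})
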