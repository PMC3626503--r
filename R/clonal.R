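#' Genotype prior from the matched-tissue call at a site
#'
#' The prior over the three genotypes (NN homozygous reference, NC
#' heterozygous mutant, CC homozygous mutant) puts weight Pn on the genotype
#' called in normal tissue, where Pn is tiered by the tissue call quality:
#' 1/3 when quality < 10 or the allele rank-sum p-value < 0.05, 0.9 for
#' quality in [10, 20), 0.99 for quality >= 20. The homozygous-mutant
#' genotype, never expected in normal tissue, always receives (1 - Pn) / 2;
#' the remaining mass goes to the other diploid genotype.
#'
#' @param tissue_gt tissue genotype, "NN" or "NC" ("CC" is rejected: a
#'   homozygous-mutant germline call is unexpected).
#' @param qual tissue call quality score (phred-like).
#' @param ranksum_p allele-quality rank-sum test p-value of the tissue call.
#' @return named numeric prior c(NN, NC, CC) summing to 1.
#' @examples
#' genotype_prior("NN", 30, 0.5)  # c(0.99, 0.005, 0.005)
#' @export
genotype_prior <- function(tissue_gt, qual, ranksum_p) {
  if (tissue_gt == "CC") stop("unexpected homozygous-mutant germline")
  if (!tissue_gt %in% c("NN", "NC")) stop("tissue genotype must be NN or NC")
  pn <- prior_weight(qual, ranksum_p)
  other <- (1 - pn) / 2
  if (tissue_gt == "NN") c(NN = pn, NC = other, CC = other)
  else c(NN = other, NC = pn, CC = other)
}

# Pn tier from quality score and rank-sum p-value (vectorized)
prior_weight <- function(qual, ranksum_p) {
  ifelse(qual < 10 | ranksum_p < 0.05, 1 / 3,
         ifelse(qual < 20, 0.9, 0.99))
}

#' Genotype likelihoods calibrated by allele dropout and false discovery
#'
#' P(observed | genotype) for the three genotypes given the observed
#' genotype call and the read counts:
#' \itemize{
#'   \item P(O|NN) = (1 - f_homo) C(n,m) f_p^m (1 - f_p)^(n-m);
#'   \item P(O|NC): if observed NN, (1/2) f_heter C(n,m) f_p^m (1-f_p)^(n-m)
#'     (the mutant allele dropped out and the m mutant reads are errors); if
#'     observed NC, 1 - f_heter; if observed CC, the mirror of the NN branch
#'     with n - m error reads;
#'   \item P(O|CC) = (1 - f_homo) C(n,n-m) f_p^(n-m) (1 - f_p)^m.
#' }
#' The (1 - f_homo) factor on the homozygous branches is kept as stated in
#' the source model even though dropout cannot change a homozygote's
#' genotype; `corrected = TRUE` drops it.
#'
#' @param m mutant read count.
#' @param n total read count (>= 1).
#' @param obs_gt observed genotype call, NN/NC/CC.
#' @param rates an [error_rates()] object (f_heter = ado_het, f_homo =
#'   ado_hom, f_p = fdr).
#' @param corrected drop the (1 - f_homo) factor on homozygous branches.
#' @return named numeric c(NN, NC, CC) of likelihoods (not normalized).
#' @export
genotype_likelihood <- function(m, n, obs_gt, rates, corrected = FALSE) {
  if (n < 1) stop("total read count must be >= 1")
  if (m < 0 || m > n) stop("mutant reads must lie in [0, n]")
  fh <- rates$ado_het; fo <- rates$ado_hom; fp <- rates$fdr
  hom_factor <- if (corrected) 1 else 1 - fo
  err_m <- stats::dbinom(m, n, fp)        # m mutant reads all errors
  err_rev <- stats::dbinom(n - m, n, fp)  # n - m reference reads all errors
  p_nn <- hom_factor * err_m
  p_cc <- hom_factor * err_rev
  p_nc <- switch(obs_gt,
                 NN = 0.5 * fh * err_m,
                 NC = 1 - fh,
                 CC = 0.5 * fh * err_rev,
                 stop("observed genotype must be NN, NC or CC"))
  c(NN = p_nn, NC = p_nc, CC = p_cc)
}

#' Posterior genotype probabilities at one (cell, site)
#'
#' @param prior prior from [genotype_prior()].
#' @param likelihood likelihoods from [genotype_likelihood()].
#' @return named numeric posterior c(NN, NC, CC) summing to 1.
#' @export
genotype_posterior <- function(prior, likelihood) {
  w <- prior * likelihood
  s <- sum(w)
  if (s <= 0) return(c(NN = 1 / 3, NC = 1 / 3, CC = 1 / 3))
  w / s
}

#' Mutant-evidence H score from a genotype posterior
#'
#' log10 of the posterior odds of mutant (NC or CC) versus homozygous
#' reference. Probabilities are floored at `eps` to keep the score finite.
#'
#' @param posterior named numeric c(NN, NC, CC).
#' @param eps floor (default 1e-12).
#' @return the H score.
#' @examples
#' h_score(c(NN = 1 / 3, NC = 1 / 3, CC = 1 / 3))  # log10(2)
#' @export
h_score <- function(posterior, eps = 1e-12) {
  mut <- max(posterior[["NC"]] + posterior[["CC"]], eps)
  ref <- max(posterior[["NN"]], eps)
  log10(mut / ref)
}

#' Build the cells x genes mutant-evidence matrix
#'
#' For every covered (cell, site) the H score is computed from the
#' ADO/FDR-calibrated likelihood and the tissue-derived prior. Sites not
#' covered in a cell are imputed with the mean H of the covered cells at
#' that site. Site scores are then aggregated per gene (maximum by default:
#' a gene is mutant in a cell if any of its sites is). Genes that look
#' mutant in any normal cell (gene-level H at or above
#' `bn_filter_threshold` in one or more normal cells) are suspicious --
#' paralogous alignment or residual model false positives -- and are removed.
#'
#' @param obs observation table restricted to the sites of interest (must
#'   carry site_id).
#' @param tissue_gt data.frame site_id, genotype, qual, ranksum_p for the
#'   matched normal tissue.
#' @param rates an [error_rates()] object.
#' @param annotation data.frame site_id, gene mapping sites to genes.
#' @param cells character vector of cell ids to include (rows); default all
#'   cells present in `obs`.
#' @param normal_cells character vector of normal cell ids (for the
#'   suspicious-gene filter).
#' @param bn_filter_threshold gene-level H threshold in normal cells
#'   (default 0.5); NA disables the filter.
#' @param aggregate "max" (default) or "sum" aggregation of site H scores
#'   within a gene.
#' @param corrected passed to [genotype_likelihood()].
#' @return object of class `h_matrix`: list with `H` (cells x genes), `site_H`
#'   (cells x sites, imputed), `imputed` (logical mask of imputed entries),
#'   `filtered_genes`, `normal_cells`.
#' @export
build_h_matrix <- function(obs, tissue_gt, rates, annotation,
                           cells = NULL, normal_cells = character(0),
                           bn_filter_threshold = 0.5,
                           aggregate = c("max", "sum"), corrected = FALSE) {
  aggregate <- match.arg(aggregate)
  if (is.null(cells)) cells <- sort(unique(obs$cell_id))
  site_ids <- intersect(annotation$site_id, unique(obs$site_id))
  if (length(site_ids) == 0) stop("no annotated sites present in obs")
  genes <- annotation$gene[match(site_ids, annotation$site_id)]
  if (anyNA(genes)) stop("gene with zero sites / unannotated site")

  o <- obs[obs$site_id %in% site_ids & obs$cell_id %in% cells, , drop = FALSE]
  ti <- match(o$site_id, tissue_gt$site_id)
  if (anyNA(ti)) stop("tissue genotype missing for some call sites")
  pn <- prior_weight(tissue_gt$qual[ti], tissue_gt$ranksum_p[ti])
  tgt <- tissue_gt$genotype[ti]
  if (any(tgt == "CC")) stop("unexpected homozygous-mutant germline")
  other <- (1 - pn) / 2
  pr_nn <- ifelse(tgt == "NN", pn, other)
  pr_nc <- ifelse(tgt == "NC", pn, other)
  pr_cc <- other

  fh <- rates$ado_het; fo <- rates$ado_hom; fp <- rates$fdr
  hom_factor <- if (corrected) 1 else 1 - fo
  err_m <- stats::dbinom(o$mut_reads, o$depth, fp)
  err_rev <- stats::dbinom(o$depth - o$mut_reads, o$depth, fp)
  l_nn <- hom_factor * err_m
  l_cc <- hom_factor * err_rev
  l_nc <- ifelse(o$genotype == "NC", 1 - fh,
                 ifelse(o$genotype == "NN", 0.5 * fh * err_m,
                        0.5 * fh * err_rev))
  w_nn <- pr_nn * l_nn; w_nc <- pr_nc * l_nc; w_cc <- pr_cc * l_cc
  tot <- w_nn + w_nc + w_cc
  h <- log10(pmax((w_nc + w_cc) / tot, 1e-12) / pmax(w_nn / tot, 1e-12))

  site_H <- matrix(NA_real_, length(cells), length(site_ids),
                   dimnames = list(cells, site_ids))
  site_H[cbind(match(o$cell_id, cells), match(o$site_id, site_ids))] <- h
  imputed <- is.na(site_H)
  col_means <- colMeans(site_H, na.rm = TRUE)
  col_means[is.nan(col_means)] <- 0
  for (j in which(colSums(imputed) > 0))
    site_H[imputed[, j], j] <- col_means[j]

  agg_fun <- if (aggregate == "max") max else sum
  gene_levels <- unique(genes)
  H <- vapply(gene_levels, function(g) {
    cols <- which(genes == g)
    apply(site_H[, cols, drop = FALSE], 1, agg_fun)
  }, numeric(length(cells)))
  if (length(cells) == 1) H <- matrix(H, nrow = 1)
  dimnames(H) <- list(cells, gene_levels)

  # suspicious-gene filter on raw (observed, non-imputed) normal-cell values:
  # imputed entries average over mostly-tumor cells and would wrongly flag
  # clean genes
  filtered <- character(0)
  if (!is.na(bn_filter_threshold) && length(normal_cells)) {
    bn <- intersect(normal_cells, cells)
    if (length(bn)) {
      raw <- site_H
      raw[imputed] <- NA_real_
      raw_bn <- raw[bn, , drop = FALSE]
      gene_bad <- vapply(gene_levels, function(g) {
        v <- raw_bn[, genes == g, drop = FALSE]
        any(apply(v, 1, function(r) if (all(is.na(r))) -Inf
                  else agg_fun(r[!is.na(r)])) >= bn_filter_threshold)
      }, logical(1))
      filtered <- gene_levels[gene_bad]
      H <- H[, !gene_bad, drop = FALSE]
    }
  }
  structure(list(H = H, site_H = site_H, imputed = imputed,
                 filtered_genes = filtered, normal_cells = normal_cells),
            class = "h_matrix")
}

#' @export
print.h_matrix <- function(x, ...) {
  cat(sprintf("H matrix: %d cells x %d genes (%d suspicious genes filtered)\n",
              nrow(x$H), ncol(x$H), length(x$filtered_genes)))
  invisible(x)
}

#' Two-dimensional hierarchical clustering of the H matrix
#'
#' Cells and genes are clustered by hierarchical agglomeration (Euclidean
#' distance, Ward linkage). H scores are first saturated at `cap` -- the
#' log-odds magnitude grows with read depth long after the mutant call is
#' certain, so uncapped values measure depth, not evidence class (a heatmap
#' saturates its color scale the same way). The tree is cut by recursive
#' refinement: successive splits (k = 2, 3, ...) are accepted while the
#' split's local silhouette -- the mean silhouette of the two newborn
#' clusters over the cells of the cluster being split -- stays at or above
#' `tau`. Clonal structure is hierarchical (the tumor/normal divide dwarfs
#' subclone divides), so a locally strong subclone split is kept even when
#' it barely moves the global silhouette. Cluster labels are ordered by
#' decreasing size.
#'
#' @param hm an `h_matrix` (or a plain numeric matrix cells x genes).
#' @param k_range candidate cluster counts (default 2:6).
#' @param cap symmetric saturation bound on H before clustering (default 3;
#'   Inf disables).
#' @param method linkage method (default "ward.D2").
#' @param tau minimum local silhouette for accepting a split (default 0.10).
#' @return object of class `clone_assignment`: list with `cell_clusters`
#'   (named integer), `gene_clusters`, `k_cells`, `k_genes`,
#'   `cell_silhouette`, `gene_silhouette` (global mean silhouettes per k),
#'   `cell_hclust`, `gene_hclust`.
#' @export
cluster_cells_genes <- function(hm, k_range = 2:6, cap = 3,
                                method = "ward.D2", tau = 0.10) {
  H <- if (inherits(hm, "h_matrix")) hm$H else hm
  if (nrow(H) < 3) stop("need at least 3 cells to cluster")
  H <- pmin(pmax(H, -cap), cap)
  cut_axis <- function(M) {
    d <- stats::dist(M)
    dm <- as.matrix(d)
    hc <- stats::hclust(d, method = method)
    ks <- k_range[k_range < nrow(M)]
    sil <- vapply(ks, function(k) {
      cl <- stats::cutree(hc, k)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- 1L
    for (kk in seq(2L, max(ks))) {
      prev <- stats::cutree(hc, kk - 1L)
      cur <- stats::cutree(hc, kk)
      n_children <- rowSums(table(prev, cur) > 0)
      par <- as.integer(names(n_children)[n_children > 1])
      inside <- which(prev %in% par)
      if (length(inside) < 3) break
      child <- as.integer(factor(cur[inside]))
      if (length(unique(child)) < 2) break
      ls <- mean(cluster::silhouette(
        child, as.dist(dm[inside, inside]))[, "sil_width"])
      if (!is.finite(ls) || ls < tau) break
      k <- kk
    }
    if (k == 1L) k <- min(ks)  # no strong split: fall back to coarsest cut
    cl <- stats::cutree(hc, k)
    # relabel by decreasing cluster size (ties by first appearance)
    sizes <- sort(table(cl), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes), names(sizes))
    cl <- relab[as.character(cl)]
    names(cl) <- rownames(M)
    list(clusters = cl, k = k, sil = stats::setNames(sil, ks), hclust = hc)
  }
  cells <- cut_axis(H)
  genes <- cut_axis(t(H))
  structure(list(cell_clusters = cells$clusters, gene_clusters = genes$clusters,
                 k_cells = cells$k, k_genes = genes$k,
                 cell_silhouette = cells$sil, gene_silhouette = genes$sil,
                 cell_hclust = cells$hclust, gene_hclust = genes$hclust),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat(sprintf("Clone assignment: %d cell clusters, %d gene groups\n",
              x$k_cells, x$k_genes))
  print(table(x$cell_clusters))
  invisible(x)
}

#' Export a clustering dendrogram as a newick string
#'
#' @param hc an `hclust` object (e.g. `cell_hclust` of a clone assignment).
#' @return single newick string.
#' @export
dendrogram_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("package 'ape' required for newick export")
  ape::write.tree(ape::as.phylo(hc))
}

#' Binary cells x genes mutation matrix from genotype calls
#'
#' A cell is mutant in a gene when it carries a mutant call (NC or CC) at
#' any of the gene's sites.
#'
#' @param obs observation table with site_id.
#' @param annotation data.frame site_id, gene.
#' @param cells cell ids forming the rows (default all in obs).
#' @return logical matrix cells x genes.
#' @export
binary_mutation_matrix <- function(obs, annotation, cells = NULL) {
  if (is.null(cells)) cells <- sort(unique(obs$cell_id))
  o <- obs[obs$cell_id %in% cells & obs$site_id %in% annotation$site_id, ,
           drop = FALSE]
  gene <- annotation$gene[match(o$site_id, annotation$site_id)]
  mut <- o$genotype %in% c("NC", "CC")
  genes <- unique(annotation$gene)
  M <- matrix(FALSE, length(cells), length(genes),
              dimnames = list(cells, genes))
  idx <- cbind(match(o$cell_id[mut], cells), match(gene[mut], genes))
  M[idx] <- TRUE
  M
}

#' Concurrence and exclusivity test for a gene pair
#'
#' Fisher exact test on the 2x2 table of cells mutant/not-mutant in each
#' gene. The concurrence p-value is the one-sided enrichment of co-mutant
#' cells; the exclusivity p-value the one-sided depletion. Mirroring how
#' such maps are usually displayed, p-values of 0.3 or more are flagged
#' `shown = FALSE`.
#'
#' @param M logical cells x genes matrix from [binary_mutation_matrix()].
#' @param gene_a,gene_b column names.
#' @param n_perm if > 0, additionally compute permutation p-values by
#'   shuffling one gene's cell labels `n_perm` times.
#' @return list with `concurrence_p`, `exclusivity_p`, `table`, `shown`,
#'   and optionally `concurrence_p_perm`, `exclusivity_p_perm`.
#' @export
exclusivity_test <- function(M, gene_a, gene_b, n_perm = 0) {
  a <- M[, gene_a]; b <- M[, gene_b]
  if (!any(a) || !any(b)) stop("both genes must be mutant in >= 1 cell")
  tab <- table(factor(a, levels = c(TRUE, FALSE)),
               factor(b, levels = c(TRUE, FALSE)))
  conc <- stats::fisher.test(tab, alternative = "greater")$p.value
  excl <- stats::fisher.test(tab, alternative = "less")$p.value
  out <- list(concurrence_p = conc, exclusivity_p = excl, table = tab,
              shown = c(concurrence = conc < 0.3, exclusivity = excl < 0.3))
  if (n_perm > 0) {
    co_obs <- sum(a & b)
    co_perm <- vapply(seq_len(n_perm), function(i) sum(sample(a) & b),
                      integer(1))
    out$concurrence_p_perm <- (sum(co_perm >= co_obs) + 1) / (n_perm + 1)
    out$exclusivity_p_perm <- (sum(co_perm <= co_obs) + 1) / (n_perm + 1)
  }
  out
}

#' Generations separating subclones under a fixed mutation rate
#'
#' With mu mutations per bp per cell generation over a callable size S, a
#' clone that accumulated `count` private mutations diverged roughly
#' count / (mu * S) generations ago (rounded up). The default inputs -- the
#' larger clone-private nonsynonymous gene count (12) and a 60 Mb callable
#' size with mu = 5e-9 -- bound the clone divergence at 40 generations.
#'
#' @param count clone-private mutation count.
#' @param mu mutation rate per bp per cell generation (default 5e-9).
#' @param S callable genome size in bp (default 6e7).
#' @return list with `generations` and the echoed assumptions.
#' @export
divergence_generations <- function(count = 12, mu = 5e-9, S = 6e7) {
  if (mu <= 0 || S <= 0) stop("mu and S must be positive")
  list(generations = as.integer(ceiling(count / (mu * S))),
       count = count, mu = mu, S = S)
}

#' Survey recurrence of mutant genes in a patient cohort
#'
#' @param genes character vector of genes to query.
#' @param cohort data.frame patient, gene listing non-silent mutant genes
#'   per patient.
#' @param min_patients recurrence threshold (default 3 patients).
#' @return data.frame gene, n_patients, recurrent.
#' @export
survey_recurrence <- function(genes, cohort, min_patients = 3) {
  counts <- vapply(genes, function(g)
    length(unique(cohort$patient[cohort$gene == g])), integer(1))
  data.frame(gene = genes, n_patients = counts,
             recurrent = counts >= min_patients,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Principal component analysis of cells at somatic sites
#'
#' Standard principal decomposition of the cells x sites genotype matrix
#' (coded 0/1/2 mutant alleles) after low-rank completion of missing
#' entries: starting from column-mean imputation, missing values are
#' refined by iterated truncated SVD reconstruction until convergence.
#'
#' @param G numeric matrix cells x sites with NAs at uncovered entries.
#' @param rank rank of the completion SVD (default 5, capped by dimension).
#' @param max_iter,tol iteration controls.
#' @return a `prcomp` object (scores in `$x`, one row per cell).
#' @export
pca_cells <- function(G, rank = 5, max_iter = 50, tol = 1e-6) {
  if (nrow(G) < 2) stop("need >= 2 cells")
  vals <- G[is.finite(G)]
  if (length(vals) && all(vals == vals[1]) && !anyNA(G))
    stop("constant genotype matrix carries no structure")
  miss <- is.na(G)
  if (any(miss)) {
    cm <- colMeans(G, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    X <- G
    X[miss] <- cm[col(G)[miss]]
    r <- min(rank, dim(G) - 1)
    for (it in seq_len(max_iter)) {
      s <- svd(X, nu = r, nv = r)
      Xhat <- s$u %*% diag(s$d[seq_len(r)], r, r) %*% t(s$v)
      delta <- sqrt(mean((X[miss] - Xhat[miss])^2))
      X[miss] <- Xhat[miss]
      if (delta < tol) break
    }
    G <- X
  }
  stats::prcomp(G, center = TRUE, scale. = FALSE)
}
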