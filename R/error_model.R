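#' Container for single-cell error-model estimates
#'
#' @param ado_het allele dropout probability for heterozygous genotypes
#'   (f_heter, the population mean over qualified normal cells).
#' @param fdr per-site false heterozygous probability (f_p).
#' @param ado_hom allele dropout probability for homozygous genotypes
#'   (f_homo). Dropout does not change a homozygote's genotype, so this rate
#'   is never estimable separately; it defaults to `ado_het` and only enters
#'   the genotype likelihoods.
#' @param per_cell_ado optional named numeric of per-cell ADO estimates.
#' @return object of class `error_rates`.
#' @export
error_rates <- function(ado_het, fdr, ado_hom = ado_het, per_cell_ado = NULL) {
  vals <- c(ado_het = ado_het, ado_hom = ado_hom, fdr = fdr)
  if (any(vals < 0 | vals > 1)) stop("error rates must lie in [0, 1]")
  structure(list(ado_het = ado_het, ado_hom = ado_hom, fdr = fdr,
                 per_cell_ado = per_cell_ado),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("Single-cell error model: ADO(het) = %.4f, ADO(hom) = %.4f, FDR = %.3g\n",
              x$ado_het, x$ado_hom, x$fdr))
  if (!is.null(x$per_cell_ado))
    cat(sprintf("  per-cell ADO over %d normal cells (range %.3f-%.3f)\n",
                length(x$per_cell_ado), min(x$per_cell_ado),
                max(x$per_cell_ado)))
  invisible(x)
}

# positions of `chrom`/`pos` covered by 0-based half-open target intervals
.in_targets <- function(chrom, pos, targets) {
  ok <- logical(length(chrom))
  for (ch in unique(chrom)) {
    ti <- targets[targets$chrom == ch, , drop = FALSE]
    oi <- which(chrom == ch)
    if (nrow(ti) == 0) next
    ord <- order(ti$start)
    starts <- ti$start[ord]; ends <- ti$end[ord]
    j <- findInterval(pos[oi] - 1L, starts)
    ok[oi] <- j >= 1L & (pos[oi] - 1L) < ends[pmax(j, 1L)]
  }
  ok
}

#' Per-cell quality control: exome coverage and X-chromosome false-het check
#'
#' A cell is retained when it covers at least `coverage_min` of the target
#' bases and, for a male sample, its X-chromosome heterozygous call rate is
#' not significantly above the autosomal false-heterozygous expectation
#' (one-sided binomial test at level `alpha`). Male X sites are hemizygous,
#' so heterozygous calls there are whole-genome-amplification artifacts; an
#' excess marks a cell with anomalously high error.
#'
#' @param obs observation table (see [read_observations()] for columns).
#' @param targets data.frame chrom/start/end, 0-based half-open target
#'   regions.
#' @param sex "male" or "female"; the X test only applies to males.
#' @param coverage_min minimum fraction of target bases covered (default
#'   0.70).
#' @param alpha significance level of the X false-het test (default 0.01).
#' @param baseline_rate expected false-heterozygous rate per site. When NULL
#'   it is estimated per cell as the autosomal heterozygous call rate outside
#'   `germline_sites` (or over all autosomal sites when no catalog is given,
#'   which inflates the baseline and makes the test conservative).
#' @param germline_sites optional character vector of germline site ids to
#'   exclude from the baseline estimate (requires a `site_id` column).
#' @return data.frame with one row per cell: cell_id, exome_coverage_fraction,
#'   x_het_rate, x_het_pvalue, qualified, reason.
#' @export
qc_cells <- function(obs, targets, sex = c("male", "female"),
                     coverage_min = 0.70, alpha = 0.01,
                     baseline_rate = NULL, germline_sites = NULL) {
  sex <- match.arg(sex)
  if (nrow(targets) == 0) stop("target region set is empty")
  unknown <- setdiff(unique(obs$chrom), unique(targets$chrom))
  if (length(unknown))
    stop("observation chromosomes absent from targets: ",
         paste(unknown, collapse = ", "))
  total_bp <- sum(targets$end - targets$start)
  is_x <- obs$chrom %in% c("chrX", "X")
  in_t <- .in_targets(obs$chrom, obs$pos, targets)
  het <- obs$genotype == "NC"
  is_gl <- if (!is.null(germline_sites) && "site_id" %in% names(obs))
    obs$site_id %in% germline_sites else rep(FALSE, nrow(obs))

  out <- lapply(split(seq_len(nrow(obs)), obs$cell_id), function(i) {
    cov_bp <- length(unique(paste0(obs$chrom[i], ":", obs$pos[i])[in_t[i]]))
    coverage <- cov_bp / total_bp
    xi <- i[is_x[i]]
    n_x <- length(xi); x_het <- sum(het[xi])
    auto <- i[!is_x[i] & !is_gl[i]]
    base <- if (is.null(baseline_rate)) {
      if (length(auto)) sum(het[auto]) / length(auto) else 0
    } else baseline_rate
    if (sex == "male" && n_x > 0) {
      pval <- if (base <= 0) as.numeric(x_het == 0) else if (base >= 1) 1 else
        stats::binom.test(x_het, n_x, base, alternative = "greater")$p.value
    } else pval <- NA_real_
    reason <- character(0)
    if (coverage < coverage_min) reason <- c(reason, "low coverage")
    if (!is.na(pval) && pval < alpha) reason <- c(reason, "X false-het excess")
    data.frame(exome_coverage_fraction = coverage,
               x_het_rate = if (n_x > 0) x_het / n_x else NA_real_,
               x_het_pvalue = pval,
               qualified = length(reason) == 0,
               reason = if (length(reason)) paste(reason, collapse = "; ")
                        else "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(cell_id = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res[order(res$cell_id), , drop = FALSE]
}

#' Relative false-negative rate at one sequencing depth
#'
#' The allele-dropout estimator compares the heterozygous call rate of a
#' single cell with that of tissue sequencing, each conditional on coverage
#' at depth n over a germline background subset:
#' (HR_T/CR_T - HR_S/CR_S) / (HR_T/CR_T). Negative values (tissue below the
#' cell) mark outlier depths excluded from the median.
#'
#' @param profile data.frame with columns depth, HR_T, CR_T, HR_S, CR_S
#'   (proportions of the background subset).
#' @param n depth at which to evaluate; must be present in `profile`.
#' @return the relative FNR at depth n (may be negative).
#' @export
relative_fnr <- function(profile, n) {
  row <- profile[profile$depth == n, , drop = FALSE]
  if (nrow(row) != 1) stop("depth ", n, " not present exactly once in profile")
  if (row$CR_T <= 0 || row$HR_T <= 0)
    stop("tissue heterozygous rate undefined at depth ", n)
  rt <- row$HR_T / row$CR_T
  rs <- if (row$CR_S > 0) row$HR_S / row$CR_S else 0
  (rt - rs) / rt
}

#' Depth profile of heterozygous and covered rates over a germline subset
#'
#' @param cell_obs observations of one single cell (must carry `site_id`).
#' @param tissue_obs tissue genotype table (site_id, depth, genotype).
#' @param germline_sites character vector of background germline site ids
#'   covered in both tissue sequencings.
#' @param bin_width width of the depth strata in reads (default 5; single
#'   depths are too sparse at exome-scale subset sizes). The reported depth
#'   is the stratum's lower edge.
#' @return data.frame depth, HR_T, CR_T, HR_S, CR_S, n_sites_T, n_sites_S.
#' @export
depth_profile <- function(cell_obs, tissue_obs, germline_sites,
                          bin_width = 5) {
  nsub <- length(germline_sites)
  if (nsub == 0) stop("empty germline subset")
  ts <- tissue_obs[tissue_obs$site_id %in% germline_sites, , drop = FALSE]
  cs <- cell_obs[cell_obs$site_id %in% germline_sites, , drop = FALSE]
  tb <- (ts$depth %/% bin_width) * bin_width
  sb <- (cs$depth %/% bin_width) * bin_width
  depths <- sort(unique(c(tb, sb)))
  t_cov <- table(factor(tb, levels = depths))
  t_het <- table(factor(tb[ts$genotype == "NC"], levels = depths))
  s_cov <- table(factor(sb, levels = depths))
  s_het <- table(factor(sb[cs$genotype == "NC"], levels = depths))
  data.frame(depth = depths,
             HR_T = as.numeric(t_het) / nsub, CR_T = as.numeric(t_cov) / nsub,
             HR_S = as.numeric(s_het) / nsub, CR_S = as.numeric(s_cov) / nsub,
             n_sites_T = as.numeric(t_cov), n_sites_S = as.numeric(s_cov))
}

#' Estimate allele dropout for one normal cell
#'
#' Computes the per-depth relative FNR over a germline background subset,
#' restricts to informative depth strata (within the 1st-99th percentile of
#' the cell's observed depths and with at least `min_sites` subset sites in
#' both the cell and the tissue stratum), discards outlier depths where the
#' relative FNR is negative, and returns the median over the remaining
#' depths.
#'
#' @inheritParams depth_profile
#' @param min_sites minimum subset sites per depth stratum (default 50).
#' @param depth_quantiles percentile window of cell depths retained.
#' @return the cell's ADO estimate, with attributes `n_depths_used` and
#'   `outlier_depths`.
#' @export
estimate_ado <- function(cell_obs, tissue_obs, germline_sites,
                         min_sites = 50, depth_quantiles = c(0.01, 0.99),
                         bin_width = 5) {
  prof <- depth_profile(cell_obs, tissue_obs, germline_sites, bin_width)
  qs <- stats::quantile(
    cell_obs$depth[cell_obs$site_id %in% germline_sites],
    depth_quantiles, names = FALSE)
  keep <- prof$depth >= qs[1] & prof$depth <= qs[2] &
    prof$n_sites_T >= min_sites & prof$n_sites_S >= min_sites &
    prof$HR_T > 0 & prof$CR_T > 0
  prof <- prof[keep, , drop = FALSE]
  if (nrow(prof) == 0) stop("insufficient depth strata")
  fnr <- vapply(prof$depth, function(d) relative_fnr(prof, d), numeric(1))
  outliers <- prof$depth[fnr < 0]
  usable <- fnr[fnr >= 0]
  if (length(usable) < 3) stop("insufficient depth strata")
  structure(stats::median(usable),
            n_depths_used = length(usable), outlier_depths = outliers)
}

#' Estimate the per-site false discovery rate from normal cells
#'
#' Over a high-confidence homozygous background subset, restricted per cell
#' to top-tier genotype quality and to depths inside the central 95% interval
#' of a Poisson distribution with mean equal to the cell's mean depth, the
#' per-cell FDR is the fraction of subset sites called heterozygous; the
#' population FDR is the mean over cells.
#'
#' @param obs observations of one or more normal cells (with `site_id`).
#' @param hom_sites character vector of high-confidence homozygous site ids.
#' @param top_qual minimum quality for the top tier (default 20).
#' @return list with `fdr` (population mean), `per_cell` (named numeric) and
#'   `n_pairs` (total subset site-cell observations used).
#' @export
estimate_fdr <- function(obs, hom_sites, top_qual = 20) {
  sub <- obs[obs$site_id %in% hom_sites & obs$qual >= top_qual, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty high-confidence homozygous subset")
  per_cell <- vapply(split(seq_len(nrow(sub)), sub$cell_id), function(i) {
    lam <- mean(sub$depth[i])
    lo <- stats::qpois(0.025, lam); hi <- stats::qpois(0.975, lam)
    j <- i[sub$depth[i] >= lo & sub$depth[i] <= hi]
    if (length(j) == 0) return(NA_real_)
    sum(sub$genotype[j] == "NC") / length(j)
  }, numeric(1))
  per_cell <- per_cell[!is.na(per_cell)]
  if (length(per_cell) == 0) stop("empty high-confidence homozygous subset")
  list(fdr = mean(per_cell), per_cell = per_cell, n_pairs = nrow(sub))
}

#' Estimate the full error model from normal-cell observations
#'
#' Convenience wrapper: per-cell ADO by [estimate_ado()] averaged over
#' normal cells, FDR by [estimate_fdr()].
#'
#' @param obs observations of the normal cells.
#' @param tissue_obs tissue genotype table.
#' @param germline_sites,hom_sites background site-id sets.
#' @param ... passed to [estimate_ado()].
#' @return an [error_rates()] object.
#' @export
estimate_error_rates <- function(obs, tissue_obs, germline_sites, hom_sites,
                                 ...) {
  per_cell <- vapply(split(seq_len(nrow(obs)), obs$cell_id), function(i)
    as.numeric(estimate_ado(obs[i, , drop = FALSE], tissue_obs,
                            germline_sites, ...)),
    numeric(1))
  fdr <- estimate_fdr(obs, hom_sites)
  error_rates(ado_het = mean(per_cell), fdr = fdr$fdr,
              per_cell_ado = per_cell)
}

#' Mitochondrial cross-check of the false discovery rate
#'
#' Mitochondrial DNA is captured deeply as a by-product of exome capture.
#' Treating every retained single-cell mitochondrial variant as a false
#' positive (the premise holds when no two cells share a variant), the FDR is
#' the number of retained singleton variants divided by (cells x genome
#' length). Variants supported by fewer than `min_mut_reads` mutant reads are
#' discarded first; a variant seen in two or more cells is excluded from the
#' numerator, since recurrence across cells is evidence it is real.
#'
#' @param variants data.frame with columns cell_id, pos, mut_reads.
#' @param n_cells number of cells surveyed.
#' @param genome_len mitochondrial genome length in bp (default 16561).
#' @param min_mut_reads minimum mutant reads to retain a variant (default 5).
#' @return the cross-check FDR estimate, with attribute `n_variants`.
#' @export
mito_fdr_crosscheck <- function(variants, n_cells, genome_len = 16561,
                                min_mut_reads = 5) {
  if (genome_len <= 0) stop("genome_len must be positive")
  v <- variants[variants$mut_reads >= min_mut_reads, , drop = FALSE]
  if (nrow(v) == 0) return(structure(0, n_variants = 0L))
  shared <- names(which(table(v$pos[!duplicated(paste(v$cell_id, v$pos))]) >= 2))
  v <- v[!(v$pos %in% as.numeric(shared)), , drop = FALSE]
  structure(nrow(v) / (n_cells * genome_len), n_variants = nrow(v))
}

#' Per-site SNP quality filter
#'
#' Applies the five site-level filters used upstream of all analyses:
#' consensus quality at least Q20, at least five reads, allele-quality
#' rank-sum p-value above 0.01, at least 5 bp from the nearest other SNP,
#' and a heterozygous allele quality ratio within [1/3, 3].
#'
#' @param records data.frame with columns qual, depth, allele_qual_p,
#'   dist_nearest, het_qual_ratio.
#' @param min_qual,min_depth,min_p,min_dist,ratio_range filter thresholds.
#' @return `records` with logical `pass` and character `reasons` columns
#'   appended.
#' @export
snp_site_filter <- function(records, min_qual = 20, min_depth = 5,
                            min_p = 0.01, min_dist = 5,
                            ratio_range = c(1 / 3, 3)) {
  needed <- c("qual", "depth", "allele_qual_p", "dist_nearest",
              "het_qual_ratio")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("missing field(s): ", paste(missing, collapse = ", "))
  fails <- cbind(
    quality = records$qual < min_qual,
    min_reads = records$depth < min_depth,
    allele_quality_p = records$allele_qual_p <= min_p,
    snp_distance = records$dist_nearest < min_dist,
    allele_quality_ratio = records$het_qual_ratio < ratio_range[1] |
      records$het_qual_ratio > ratio_range[2])
  records$pass <- rowSums(fails) == 0
  records$reasons <- apply(fails, 1, function(f)
    paste(colnames(fails)[f], collapse = ","))
  records
}
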