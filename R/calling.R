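#' Minimum mutant cancer cells required to call a somatic mutation
#'
#' A false heterozygote arises independently in each cell with per-site
#' probability p_f. Requiring the mutation in at least i cancer cells makes
#' the genome-wide expected count of coincidental false calls
#' C(n,i) p_f^i (1-p_f)^(n-i) * S; the threshold is the smallest i >= 1 that
#' drives this expectation below one. With p_f = 6.7e-5, n = 44 qualified
#' cancer cells and a 50 Mb exome this gives 3.
#'
#' @param p_f per-site false heterozygous probability (0 < p_f < 1 unless 0,
#'   which trivially gives 1).
#' @param n number of qualified cancer cells.
#' @param S exome size in bp.
#' @return integer threshold, with attribute `pmf_at_i` (the binomial term at
#'   the chosen i).
#' @examples
#' min_mutant_cancer_cells(6.7e-5, 44, 5e7)  # 3
#' @export
min_mutant_cancer_cells <- function(p_f, n, S) {
  if (p_f < 0 || p_f >= 1) stop("p_f must lie in [0, 1)")
  if (n < 1 || S < 1) stop("n and S must be >= 1")
  for (i in seq_len(n)) {
    pmf <- stats::dbinom(i, n, p_f)
    if (pmf * S < 1) return(structure(as.integer(i), pmf_at_i = pmf))
  }
  stop("no cell count i <= n drives the expected false-call count below 1")
}

#' Minimum read-covered normal cells required at a candidate site
#'
#' Guards against allele dropout hiding a germline heterozygote: the more
#' normal cells confirm a homozygous-reference genotype, the less likely a
#' germline variant dropped out in all of them. The printed binomial form of
#' this criterion does not reproduce the published operating point of six
#' covered normal cells under any single-term reading, so the probability
#' model is pluggable:
#' \describe{
#'   \item{fixed}{return `fixed` (default 6), the published operating point;
#'     with p_a = 0 no redundancy is needed and 1 is returned.}
#'   \item{power}{smallest i with (p_a/2)^i * S < 1 -- the chance that the
#'     mutant allele dropped out in all i covered normal cells, genome-wide.}
#'   \item{binomial}{smallest i with C(n,i) p_a^i (1-p_a)^(n-i) * S < 1,
#'     the same form as [min_mutant_cancer_cells()].}
#' }
#'
#' @param p_a allele dropout probability.
#' @param n number of qualified normal cells.
#' @param S exome size in bp.
#' @param model probability model (see Details).
#' @param fixed operating point returned by the "fixed" model.
#' @return integer threshold.
#' @examples
#' min_normal_cells_covered(0.41, 11, 5e7)                   # 6 (operating point)
#' min_normal_cells_covered(0.41, 11, 3e7, model = "power")  # 11
#' @export
min_normal_cells_covered <- function(p_a, n, S,
                                     model = c("fixed", "power", "binomial"),
                                     fixed = 6L) {
  model <- match.arg(model)
  if (p_a < 0 || p_a >= 1) stop("p_a must lie in [0, 1)")
  if (n < 1 || S < 1) stop("n and S must be >= 1")
  if (p_a == 0) return(1L)
  if (model == "fixed") return(as.integer(fixed))
  if (model == "power") {
    i <- ceiling(log(1 / S) / log(p_a / 2))
    if ((p_a / 2)^i * S >= 1) i <- i + 1
    return(as.integer(max(1, i)))
  }
  for (i in seq_len(n)) {
    if (stats::dbinom(i, n, p_a) * S < 1) return(as.integer(i))
  }
  stop("no cell count i <= n satisfies the inequality")
}

#' Call somatic mutations across the cell population
#'
#' A site is called somatic when (1) every read-covered normal cell is
#' homozygous reference there, with at least `min_normal_covered` normal
#' cells covered; (2) the matched normal tissue is homozygous reference at
#' the site; and (3) at least `min_mutant_cancer` cancer cells carry a mutant
#' genotype (NC or CC). Sites with zero covered normal cells cannot be
#' evaluated and are tallied separately.
#'
#' @param obs observation table (must carry `site_id`) for all qualified
#'   cells, pre-filtered by [snp_site_filter()] conventions.
#' @param tissue_gt data.frame site_id, genotype for the matched normal
#'   tissue.
#' @param normal_cells,tumor_cells character vectors of qualified cell ids.
#' @param min_normal_covered,min_mutant_cancer thresholds, typically from
#'   [min_normal_cells_covered()] and [min_mutant_cancer_cells()].
#' @param annotation optional data.frame site_id, gene, class giving the
#'   consequence class (NS, S, UTR3, UTR5, intron, intergenic) and gene of
#'   each site; annotation is consumed, not computed.
#' @return object of class `somatic_calls`: a data.frame with one row per
#'   called site (site_id, chrom, pos, ref, alt, n_normal_covered,
#'   n_cancer_mutant, n_cancer_covered, cell_freq, gene, class) and
#'   attributes `not_evaluable` (sites with no covered normal cell) and
#'   `thresholds`.
#' @export
call_somatic <- function(obs, tissue_gt, normal_cells, tumor_cells,
                         min_normal_covered = 6L, min_mutant_cancer = 3L,
                         annotation = NULL) {
  if (!"site_id" %in% names(obs)) stop("obs must carry a site_id column")
  is_norm <- obs$cell_id %in% normal_cells
  is_tum <- obs$cell_id %in% tumor_cells
  mutant <- obs$genotype %in% c("NC", "CC")

  f <- factor(obs$site_id)
  lev <- levels(f)
  n_norm_cov <- tabulate(f[is_norm], nbins = length(lev))
  n_norm_mut <- tabulate(f[is_norm & mutant], nbins = length(lev))
  n_tum_cov <- tabulate(f[is_tum], nbins = length(lev))
  n_tum_mut <- tabulate(f[is_tum & mutant], nbins = length(lev))
  n_tum_hom <- tabulate(f[is_tum & obs$genotype == "CC"], nbins = length(lev))
  n_tum_het <- n_tum_mut - n_tum_hom

  tiss <- tissue_gt$genotype[match(lev, tissue_gt$site_id)]
  not_evaluable <- n_norm_cov == 0
  pass <- !not_evaluable &
    n_norm_cov >= min_normal_covered &
    n_norm_mut == 0 &
    !is.na(tiss) & tiss == "NN" &
    n_tum_mut >= min_mutant_cancer

  idx <- match(lev[pass], obs$site_id)
  calls <- data.frame(
    site_id = lev[pass],
    chrom = obs$chrom[idx], pos = obs$pos[idx],
    ref = obs$ref[idx], alt = obs$alt[idx],
    n_normal_covered = n_norm_cov[pass],
    n_cancer_mutant = n_tum_mut[pass],
    n_cancer_covered = n_tum_cov[pass],
    cell_freq = (n_tum_het[pass] + 2 * n_tum_hom[pass]) /
      pmax(2 * n_tum_cov[pass], 1),
    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    j <- match(calls$site_id, annotation$site_id)
    calls$gene <- annotation$gene[j]
    calls$class <- annotation$class[j]
  } else {
    calls$gene <- rep(NA_character_, nrow(calls))
    calls$class <- rep(NA_character_, nrow(calls))
  }
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("somatic_calls", "data.frame"),
            not_evaluable = sum(not_evaluable),
            thresholds = c(min_normal_covered = min_normal_covered,
                           min_mutant_cancer = min_mutant_cancer))
}

#' @export
print.somatic_calls <- function(x, ...) {
  cat(sprintf("Somatic call set: %d sites (%d not evaluable)\n", nrow(x),
              attr(x, "not_evaluable")))
  th <- attr(x, "thresholds")
  cat(sprintf("  thresholds: >=%d covered normal cells, >=%d mutant cancer cells\n",
              th["min_normal_covered"], th["min_mutant_cancer"]))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Rounded percentage of a count
#'
#' @param x count of interest.
#' @param n total.
#' @param digits decimals (default 2).
#' @return 100 * x / n rounded to `digits`.
#' @examples
#' fraction_pct(374, 443)  # 84.42
#' @export
fraction_pct <- function(x, n, digits = 2) {
  if (n <= 0) return(NA_real_)
  round(100 * x / n, digits)
}

#' Nonsynonymous-to-synonymous ratio
#'
#' @param n_ns,n_s nonsynonymous and synonymous call counts.
#' @return n_ns / n_s rounded to 2 decimals (NA when n_s is 0).
#' @examples
#' ns_s_ratio(146, 59)  # 2.47
#' @export
ns_s_ratio <- function(n_ns, n_s) {
  if (n_s == 0) return(NA_real_)
  round(n_ns / n_s, 2)
}

#' Summarize a somatic call set by consequence class and bulk support
#'
#' Produces the class-count summary used to report a call set: counts and
#' percentages per consequence class, the NS/S ratio to two decimals, and
#' (when bulk support flags are present) the same stratified by whether the
#' mutant allele was observed in bulk tissue sequencing.
#'
#' @param calls a `somatic_calls` data.frame with a `class` column and
#'   optionally a `bulk_support` logical column.
#' @return list with `by_class` (data.frame class, n, pct), `ns_s_ratio`,
#'   `total`, and when bulk flags exist `by_support` (the same stratified)
#'   and `bulk_support_pct`.
#' @export
summarize_calls <- function(calls) {
  classes <- c("NS", "S", "UTR3", "UTR5", "intron", "intergenic")
  tab <- function(x) {
    n <- table(factor(x$class, levels = classes))
    data.frame(class = classes, n = as.integer(n),
               pct = fraction_pct(as.integer(n), max(nrow(x), 1)),
               stringsAsFactors = FALSE)
  }
  out <- list(total = nrow(calls), by_class = tab(calls),
              ns_s_ratio = ns_s_ratio(sum(calls$class == "NS", na.rm = TRUE),
                                      sum(calls$class == "S", na.rm = TRUE)))
  if ("bulk_support" %in% names(calls)) {
    # column percentages: within each consequence class, the share of calls
    # that are / are not supported by bulk reads
    class_tot <- table(factor(calls$class, levels = classes))
    strat <- function(flag) {
      n <- table(factor(calls$class[calls$bulk_support == flag],
                        levels = classes))
      data.frame(class = classes, n = as.integer(n),
                 pct = round(100 * as.integer(n) /
                               pmax(as.integer(class_tot), 1), 2),
                 stringsAsFactors = FALSE)
    }
    out$by_support <- list(supported = strat(TRUE),
                           unsupported = strat(FALSE))
    out$bulk_support_pct <- fraction_pct(sum(calls$bulk_support),
                                         nrow(calls))
  }
  out
}

#' Flag calls supported by bulk-tissue reads
#'
#' @param calls a `somatic_calls` data.frame.
#' @param bulk bulk read-count table (site_id, mut_reads).
#' @param min_reads minimum mutant reads for support (default 1).
#' @return `calls` with a `bulk_support` logical column; attributes
#'   `support_pct` (percentage supported among all calls, 2 decimals) and
#'   `n_uncovered` (call sites absent from the bulk table, counted
#'   unsupported).
#' @export
bulk_support <- function(calls, bulk, min_reads = 1) {
  j <- match(calls$site_id, bulk$site_id)
  supp <- !is.na(j) & bulk$mut_reads[j] >= min_reads
  calls$bulk_support <- supp
  attr(calls, "support_pct") <- fraction_pct(sum(supp), nrow(calls))
  attr(calls, "n_uncovered") <- sum(is.na(j))
  calls
}
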