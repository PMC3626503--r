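#' Count-based mutant allele frequency at one site
#'
#' The unfolded site frequency: mutant haploids (heterozygotes count one,
#' homozygous mutants two) over total haploids (2 x covered cells).
#'
#' @param genotypes character vector of genotype calls (NN/NC/CC) of the
#'   covered cells at the site.
#' @return frequency in [0, 1].
#' @examples
#' count_frequency(rep("NC", 44))  # 0.5
#' @export
count_frequency <- function(genotypes) {
  n <- length(genotypes)
  if (n == 0) stop("no covered cells at site")
  (sum(genotypes == "NC") + 2 * sum(genotypes == "CC")) / (2 * n)
}

#' Maximum-likelihood mutant allele frequency at one site
#'
#' Error-aware frequency estimate: maximizes over f the marginal likelihood
#' sum over cells of log sum over genotypes g in {NN, NC, CC} of
#' P(obs | g; rates) * P(g | f), where the genotype likelihoods are the
#' ADO/FDR-calibrated read-count likelihoods of [genotype_likelihood()] and
#' P(g | f) = ((1-f)^2, 2f(1-f), f^2). The search runs on a grid of
#' resolution `grid` with golden-section refinement around the grid optimum.
#'
#' @param site_obs data.frame of the covered cells at one site with columns
#'   mut_reads, depth, genotype.
#' @param rates an [error_rates()] object.
#' @param grid grid resolution for the global search (default 1e-3).
#' @return the ML frequency in [0, 1].
#' @export
ml_frequency <- function(site_obs, rates, grid = 1e-3) {
  if (nrow(site_obs) == 0) stop("no covered cells at site")
  L <- t(mapply(genotype_likelihood, site_obs$mut_reads, site_obs$depth,
                site_obs$genotype, MoreArgs = list(rates = rates)))
  if (nrow(site_obs) == 1) L <- matrix(L, nrow = 1)
  loglik_of <- function(f) {
    P <- rbind((1 - f)^2, 2 * f * (1 - f), f^2)
    colSums(log(L %*% P + 1e-300))
  }
  fs <- seq(0, 1, by = grid)
  ll <- loglik_of(fs)
  f0 <- fs[which.max(ll)]
  lo <- max(0, f0 - grid); hi <- min(1, f0 + grid)
  opt <- stats::optimize(function(f) loglik_of(f), c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  if (opt$objective >= max(ll)) opt$maximum else f0
}

#' Build the somatic mutant allele frequency spectrum (SMAFS)
#'
#' Ten frequency bins, left-closed right-open with the final bin closed:
#' [0, 0.1), [0.1, 0.2), ..., [0.9, 1.0]. A frequency of exactly 0.5 falls
#' in bin 6 ([0.5, 0.6)).
#'
#' @param frequencies numeric vector of per-site frequencies in [0, 1].
#' @param classes optional character vector of consequence classes parallel
#'   to `frequencies` (stratifies the spectrum).
#' @return object of class `smafs_spectrum`: integer matrix bins x classes
#'   (single column "all" when `classes` is NULL) with a `mid` attribute of
#'   bin midpoints.
#' @export
build_spectrum <- function(frequencies, classes = NULL) {
  if (any(frequencies < 0 | frequencies > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  breaks <- seq(0, 1, by = 0.1)
  bin <- findInterval(frequencies, breaks, rightmost.closed = TRUE)
  labs <- paste0("[", format(breaks[-11]), ",", format(breaks[-1]),
                 c(rep(")", 9), "]"))
  if (is.null(classes)) classes <- rep("all", length(frequencies))
  m <- table(factor(bin, levels = 1:10), factor(classes))
  m <- matrix(as.integer(m), nrow = 10,
              dimnames = list(bin = labs, class = colnames(m)))
  structure(m, mid = seq(0.05, 0.95, by = 0.1), class = "smafs_spectrum")
}

#' @export
print.smafs_spectrum <- function(x, ...) {
  cat("Somatic mutant allele frequency spectrum\n")
  print(unclass(x))
  invisible(x)
}

#' Fit a hyperbolic decay to the SMAFS and test goodness of fit
#'
#' Under neutral expansion, expected mutation counts decay as c / f with
#' frequency f. The scale c is fitted by minimum chi-square on the
#' non-excluded bins (expected count c / f_mid per bin); Pearson's
#' goodness-of-fit statistic is then computed over all bins, so an excess at
#' the clonal 40-60% bins (bins 5 and 6) inflates the statistic. The peak
#' flag is raised when an observed 40-60% bin exceeds three times its fitted
#' expectation.
#'
#' @param spectrum a `smafs_spectrum` or a length-10 vector of bin counts.
#' @param exclude_bins bins (1-10) excluded from fitting the scale, e.g.
#'   `c(5, 6)` to fit the neutral tail around the clonal peak.
#' @param intercept if TRUE fit c / f + d instead of c / f.
#' @return object of class `hyperbolic_fit`: list with `c` (and `d`),
#'   `expected`, `observed`, `statistic`, `df`, `p_value`, `peak_excess`.
#' @export
fit_hyperbolic <- function(spectrum, exclude_bins = integer(0),
                           intercept = FALSE) {
  obs <- if (inherits(spectrum, "smafs_spectrum")) rowSums(spectrum)
         else as.numeric(spectrum)
  if (length(obs) != 10) stop("spectrum must have 10 bins")
  if (sum(obs) == 0) stop("degenerate all-zero spectrum")
  mid <- seq(0.05, 0.95, by = 0.1)
  fit_idx <- setdiff(which(obs >= 0), exclude_bins)
  if (sum(obs[fit_idx] > 0) < 3) stop("need >= 3 non-excluded bins with counts")
  chisq <- function(par) {
    e <- par[1] / mid[fit_idx] + if (intercept) par[2] else 0
    if (any(e <= 0)) return(Inf)
    sum((obs[fit_idx] - e)^2 / e)
  }
  if (intercept) {
    start <- c(sum(obs[fit_idx]) / sum(1 / mid[fit_idx]), 0.1)
    op <- stats::optim(start, chisq, method = "Nelder-Mead")
    cc <- op$par[1]; dd <- op$par[2]
  } else {
    op <- stats::optimize(function(cc) chisq(cc),
                          c(1e-9, 10 * sum(obs)))
    cc <- op$minimum; dd <- 0
  }
  expected <- cc / mid + dd
  stat <- sum((obs - expected)^2 / expected)
  npar <- if (intercept) 2L else 1L
  df <- 10L - 1L - npar
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  peak <- any(obs[5:6] > 3 * expected[5:6])
  structure(list(c = cc, d = dd, observed = obs, expected = expected,
                 statistic = stat, df = df, p_value = p,
                 peak_excess = peak, exclude_bins = exclude_bins),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic SMAFS fit: c = %.2f%s\n", x$c,
              if (x$d != 0) sprintf(", d = %.2f", x$d) else ""))
  cat(sprintf("  Pearson X2 = %.2f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  clonal 40-60%% peak excess: %s\n",
              if (x$peak_excess) "yes" else "no"))
  invisible(x)
}

#' Test for a frequency shift of nonsynonymous versus synonymous mutations
#'
#' One-sided Fisher exact test of whether nonsynonymous mutations are
#' enriched above a frequency cutoff relative to synonymous ones -- the
#' signature of positive selection. Also reports the same test after
#' removing the 40-60% clonal peak frequencies, which could otherwise drive
#' the shift on their own.
#'
#' @param ns_freqs,s_freqs frequencies of nonsynonymous and synonymous
#'   mutations.
#' @param cutoff frequency cutoff (default 0.1).
#' @param alternative "greater" (NS enriched above cutoff, default) or
#'   "two.sided".
#' @return list with `p_value`, `table` (2x2), `p_value_excl_peak`,
#'   `table_excl_peak`.
#' @export
test_ns_shift <- function(ns_freqs, s_freqs, cutoff = 0.1,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(ns_freqs) == 0 || length(s_freqs) == 0)
    stop("both mutation classes must be nonempty")
  mk <- function(ns, s) {
    m <- rbind(NS = c(sum(ns > cutoff), sum(ns <= cutoff)),
               S = c(sum(s > cutoff), sum(s <= cutoff)))
    colnames(m) <- c("high", "low")
    m
  }
  tab <- mk(ns_freqs, s_freqs)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  in_peak <- function(f) f >= 0.4 & f < 0.6
  ns2 <- ns_freqs[!in_peak(ns_freqs)]; s2 <- s_freqs[!in_peak(s_freqs)]
  if (length(ns2) && length(s2)) {
    tab2 <- mk(ns2, s2)
    p2 <- stats::fisher.test(tab2, alternative = alternative)$p.value
  } else {
    tab2 <- NULL; p2 <- NA_real_
  }
  list(p_value = p, table = tab,
       p_value_excl_peak = p2, table_excl_peak = tab2)
}

#' Coefficient of determination between cell-population and bulk frequencies
#'
#' Least-squares R-squared of bulk mutant-read frequency on the single-cell
#' population frequency over paired sites.
#'
#' @param cell_freqs,bulk_freqs paired per-site frequencies.
#' @return R-squared.
#' @export
correlate_with_bulk <- function(cell_freqs, bulk_freqs) {
  if (length(cell_freqs) != length(bulk_freqs))
    stop("frequency vectors must be paired")
  if (length(cell_freqs) < 3) stop("need >= 3 paired sites")
  summary(stats::lm(bulk_freqs ~ cell_freqs))$r.squared
}
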