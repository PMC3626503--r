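#' Configuration for the synthetic single-cell tumor population
#'
#' Builds a validated configuration for [simulate_population()]. The defaults
#' emulate a muscle-invasive bladder tumor profiled at single-cell resolution:
#' 44 tumor cells and 11 matched normal cells, a clonal structure with one
#' ancestral mutation set shared by all tumor cells (22 nonsynonymous genes)
#' and two derived subclones carrying 7 and 12 additional clone-specific
#' mutant genes, a neutral-expansion tail of low-frequency passenger
#' mutations, and a germline heterozygous background. Observation noise uses
#' an allele-dropout (ADO) rate of 0.41 per heterozygous genotype and a
#' per-site false-positive (false heterozygous) rate of 6.7e-5, with
#' overdispersed coverage around 40x.
#'
#' @param n_tumor_cells,n_normal_cells number of tumor / normal cells.
#' @param clone_fractions named numeric of length 3 (A, B, C) summing to 1;
#'   fraction of tumor cells in each subclone. Clone A carries only the
#'   ancestral mutations; clones B and C add their own mutation groups.
#' @param n_ancestral_muts somatic mutations shared by every tumor cell
#'   (heterozygous; population frequency 0.5 of tumor haploids).
#' @param n_cloneB_muts,n_cloneC_muts clone-private somatic mutation counts.
#' @param n_neutral_tail_muts low-frequency passenger mutations whose carrier
#'   counts k are drawn with P(k) proportional to 1/k (neutral-expansion
#'   spectrum).
#' @param n_germline_het_sites germline heterozygous background sites (NC in
#'   every cell, tumor and normal).
#' @param n_background_hom_sites homozygous-reference background sites, used
#'   by the false-discovery-rate estimator; a tenth are placed on chrX.
#' @param exome_size_bp whole-exome target size in bp (50 Mb capture design).
#' @param ado_het,ado_hom allele dropout probability for heterozygous /
#'   homozygous genotypes.
#' @param fdr_per_site probability a truly homozygous site is observed as a
#'   false heterozygote.
#' @param per_read_error per-read miscall probability feeding mutant-read
#'   counts at homozygous sites.
#' @param mean_depth mean sequencing depth per covered site.
#' @param depth_dispersion negative-binomial dispersion of depth (0 gives
#'   Poisson counts).
#' @param coverage_fraction probability a site is read-covered in a cell.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$n_tumor_cells
#' @export
sim_config <- function(n_tumor_cells = 44L,
                       n_normal_cells = 11L,
                       clone_fractions = c(A = 0.30, B = 0.35, C = 0.35),
                       n_ancestral_muts = 22L,
                       n_cloneB_muts = 7L,
                       n_cloneC_muts = 12L,
                       n_neutral_tail_muts = 400L,
                       n_germline_het_sites = 3000L,
                       n_background_hom_sites = 30000L,
                       exome_size_bp = 5e7,
                       ado_het = 0.41,
                       ado_hom = 0.41,
                       fdr_per_site = 6.7e-5,
                       per_read_error = 1e-3,
                       mean_depth = 40,
                       depth_dispersion = 0.3,
                       coverage_fraction = 0.886,
                       seed = 1L) {
  counts <- c(n_tumor_cells, n_normal_cells, n_ancestral_muts, n_cloneB_muts,
              n_cloneC_muts, n_neutral_tail_muts, n_germline_het_sites,
              n_background_hom_sites)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell/site counts must be non-negative integers")
  probs <- c(ado_het = ado_het, ado_hom = ado_hom, fdr_per_site = fdr_per_site,
             per_read_error = per_read_error,
             coverage_fraction = coverage_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (length(clone_fractions) != 3L)
    stop("clone_fractions must have three entries (A, B, C)")
  if (abs(sum(clone_fractions) - 1) > 1e-8)
    stop("clone_fractions must sum to 1")
  if (is.null(names(clone_fractions))) names(clone_fractions) <- c("A", "B", "C")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  if (exome_size_bp < 1) stop("exome_size_bp must be >= 1")
  # a declared subclone (one with its own mutations) must receive >= 1 cell
  n_per_clone <- clone_cell_counts(n_tumor_cells, clone_fractions)
  if (n_cloneB_muts > 0 && n_per_clone[["B"]] == 0L)
    stop("clone fractions give zero cells to clone B, which has mutations")
  if (n_cloneC_muts > 0 && n_per_clone[["C"]] == 0L)
    stop("clone fractions give zero cells to clone C, which has mutations")
  structure(list(
    n_tumor_cells = as.integer(n_tumor_cells),
    n_normal_cells = as.integer(n_normal_cells),
    clone_fractions = clone_fractions,
    n_ancestral_muts = as.integer(n_ancestral_muts),
    n_cloneB_muts = as.integer(n_cloneB_muts),
    n_cloneC_muts = as.integer(n_cloneC_muts),
    n_neutral_tail_muts = as.integer(n_neutral_tail_muts),
    n_germline_het_sites = as.integer(n_germline_het_sites),
    n_background_hom_sites = as.integer(n_background_hom_sites),
    exome_size_bp = exome_size_bp,
    ado_het = ado_het, ado_hom = ado_hom,
    fdr_per_site = fdr_per_site, per_read_error = per_read_error,
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    coverage_fraction = coverage_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# largest-remainder apportionment of tumor cells to clones
clone_cell_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Simulate a clonally structured cell population with ground truth
#'
#' Draws the true clonal architecture: cell-to-clone assignments, mutation
#' groups (ancestral, clone-B, clone-C, neutral tail, germline), per-cell
#' true genotypes and true per-site mutant allele frequencies. All somatic
#' mutations are planted as heterozygous (NC); the neutral tail draws, for
#' each mutation, a carrier count k in 1..n_tumor_cells with
#' P(k) proportional to 1/k, the stationary frequency spectrum of a neutrally
#' expanding population, so expected spectrum counts decay hyperbolically
#' with frequency.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_truth`: a list with `cells` (cell_id,
#'   clone, is_tumor), `sites` (site_id, chrom, pos, ref, alt, group, gene,
#'   class, true_freq), `carriers` (per-site integer vectors of carrier cell
#'   indices; germline sites implicitly carried het by every cell), and the
#'   `config` echo.
#' @examples
#' truth <- simulate_population(sim_config(seed = 3))
#' table(truth$cells$clone)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_tumor_cells
  nn <- config$n_normal_cells
  n_per_clone <- clone_cell_counts(nt, config$clone_fractions)
  clone <- c(rep(names(n_per_clone), n_per_clone), rep("N", nn))
  cell_id <- c(sprintf("BC%02d", seq_len(nt)), sprintf("BN%02d", seq_len(nn)))
  cells <- data.frame(cell_id = cell_id, clone = clone,
                      is_tumor = clone != "N", stringsAsFactors = FALSE)

  groups <- c(rep("ancestral", config$n_ancestral_muts),
              rep("cloneB", config$n_cloneB_muts),
              rep("cloneC", config$n_cloneC_muts),
              rep("neutral_tail", config$n_neutral_tail_muts),
              rep("germline", config$n_germline_het_sites),
              rep("background", config$n_background_hom_sites))
  ns <- length(groups)
  if (ns == 0) stop("configuration declares no sites")

  # chromosome layout: somatic/germline sites on autosomes; a tenth of the
  # homozygous background on chrX (male sample: hemizygous, het calls false)
  chrom <- paste0("chr", (seq_len(ns) - 1L) %% 22L + 1L)
  bg <- which(groups == "background")
  if (length(bg) >= 10) {
    x_idx <- bg[seq_len(floor(length(bg) / 10))]
    chrom[x_idx] <- "chrX"
  }
  pos <- integer(ns)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(min(config$exome_size_bp, .Machine$integer.max),
                              length(i)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  # consequence classes: clonal mutation groups are nonsynonymous (they are
  # the heat-map genes); the neutral tail mixes classes at exome-like rates
  class <- rep(NA_character_, ns)
  clonal <- groups %in% c("ancestral", "cloneB", "cloneC")
  class[clonal] <- "NS"
  tail_idx <- which(groups == "neutral_tail")
  if (length(tail_idx)) {
    class[tail_idx] <- sample(
      c("NS", "S", "UTR3", "UTR5", "intron", "intergenic"),
      length(tail_idx), replace = TRUE,
      prob = c(0.33, 0.13, 0.03, 0.02, 0.47, 0.02))
  }

  gene <- rep(NA_character_, ns)
  gene[groups == "ancestral"] <- sprintf("GI_%02d", seq_len(config$n_ancestral_muts))
  gene[groups == "cloneB"] <- sprintf("GIII_%02d", seq_len(config$n_cloneB_muts))
  gene[groups == "cloneC"] <- sprintf("GII_%02d", seq_len(config$n_cloneC_muts))
  gene[tail_idx] <- sprintf("TAIL_%04d", seq_along(tail_idx))

  tumor_idx <- which(cells$is_tumor)
  idxB <- which(cells$clone == "B")
  idxC <- which(cells$clone == "C")
  carriers <- vector("list", ns)
  for (i in seq_len(ns)) {
    carriers[[i]] <- switch(groups[i],
      ancestral = tumor_idx,
      cloneB = idxB,
      cloneC = idxC,
      background = integer(0),
      germline = integer(0),   # implicit: every cell is het at germline sites
      neutral_tail = integer(0))
  }
  # Neutral tail: carrier count k ~ 1/k (the stationary spectrum of neutral
  # expansion); carriers are drawn clade-consistently -- a neutral mutation
  # arises on one lineage branch, so its carriers sit inside one clade of
  # the clone tree ((B,C),A), not scattered across clones. Among clades
  # large enough to host k carriers, smaller clades are favoured (1/size),
  # mirroring the larger number of recent branches.
  if (length(tail_idx)) {
    k_max <- nt
    pk <- (1 / seq_len(k_max)) / sum(1 / seq_len(k_max))
    k <- sample.int(k_max, length(tail_idx), replace = TRUE, prob = pk)
    idxA <- which(cells$clone == "A")
    clades <- list(A = idxA, B = idxB, C = idxC,
                   BC = c(idxB, idxC), T = tumor_idx)
    clades <- clades[vapply(clades, length, integer(1)) > 0]
    clade_sizes <- vapply(clades, length, integer(1))
    for (j in seq_along(tail_idx)) {
      eligible <- which(clade_sizes >= k[j])
      h <- if (length(eligible) == 1) eligible else
        sample(eligible, 1L, prob = 1 / clade_sizes[eligible])
      carriers[[tail_idx[j]]] <- sort(sample(clades[[h]], k[j]))
    }
  }

  n_carriers_tumor <- vapply(carriers, length, integer(1))
  true_freq <- n_carriers_tumor / (2 * nt)
  true_freq[groups == "germline"] <- 0.5

  sites <- data.frame(
    site_id = sprintf("s%06d", seq_len(ns)),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    group = groups, gene = gene, class = class,
    true_freq = true_freq, stringsAsFactors = FALSE)

  structure(list(cells = cells, sites = sites, carriers = carriers,
                 config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic single-cell population\n")
  cat(sprintf("  cells: %d tumor (%s), %d normal\n",
              sum(x$cells$is_tumor),
              paste(sprintf("%s=%d", names(table(x$cells$clone[x$cells$is_tumor])),
                            table(x$cells$clone[x$cells$is_tumor])),
                    collapse = ", "),
              sum(!x$cells$is_tumor)))
  cat(sprintf("  sites: %s\n",
              paste(sprintf("%s=%d", names(table(x$sites$group)),
                            table(x$sites$group)), collapse = ", ")))
  invisible(x)
}

#' True genotypes of the simulated population at a set of sites
#'
#' @param truth a `sim_truth` object.
#' @param site_idx integer site indices (default all).
#' @return character matrix cells x sites with entries in NN/NC.
#' @export
true_genotypes <- function(truth, site_idx = seq_len(nrow(truth$sites))) {
  ncell <- nrow(truth$cells)
  g <- matrix("NN", ncell, length(site_idx),
              dimnames = list(truth$cells$cell_id,
                              truth$sites$site_id[site_idx]))
  for (j in seq_along(site_idx)) {
    i <- site_idx[j]
    if (truth$sites$group[i] == "germline") {
      g[, j] <- "NC"
    } else if (length(truth$carriers[[i]])) {
      g[truth$carriers[[i]], j] <- "NC"
    }
  }
  g
}

#' Simulate per-cell, per-site genotype observations
#'
#' Observes the true population through the single-cell noise model: each
#' (cell, site) pair is covered with probability `coverage_fraction`; depth
#' is drawn from a negative-binomial around `mean_depth`; a true heterozygote
#' loses one uniformly chosen allele with probability `ado_het` (observed as
#' the corresponding homozygote); a true homozygote becomes a false
#' heterozygote with probability `fdr_per_site`; mutant-read counts are
#' binomial given the post-dropout allele content with per-read error
#' `per_read_error`. Quality scores are tiered (>=20 with probability 0.95,
#' 10-19 with 0.04, <10 with 0.01) and the rank-sum p-value is uniform, so
#' every prior-weight tier downstream is exercised.
#'
#' @param truth a `sim_truth` from [simulate_population()].
#' @param config the matching [sim_config()]; noise parameters are read from
#'   it.
#' @param cells,sites optional character vectors restricting output to a
#'   subset of cell ids / site ids (used to generate large error-rate
#'   calibration sets without materialising the full table).
#' @return A `data.frame` of site observations with columns cell_id, chrom,
#'   pos, ref, alt, depth, mut_reads, qual, ranksum_p, genotype. Uncovered
#'   (cell, site) pairs are absent.
#' @export
simulate_observations <- function(truth, config = truth$config,
                                  cells = NULL, sites = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  cell_keep <- if (is.null(cells)) seq_len(nrow(truth$cells)) else
    match(cells, truth$cells$cell_id)
  site_keep <- if (is.null(sites)) seq_len(nrow(truth$sites)) else
    match(sites, truth$sites$site_id)
  if (anyNA(cell_keep) || anyNA(site_keep))
    stop("unknown cell or site ids requested")

  ncell <- length(cell_keep); nsite <- length(site_keep)
  # long grid, site-major
  ci <- rep(cell_keep, times = nsite)
  si <- rep(site_keep, each = ncell)

  covered <- stats::runif(length(ci)) < config$coverage_fraction
  ci <- ci[covered]; si <- si[covered]
  n <- length(ci)
  depth <- if (config$depth_dispersion > 0)
    stats::rnbinom(n, size = 1 / config$depth_dispersion, mu = config$mean_depth)
  else
    stats::rpois(n, config$mean_depth)
  pos_depth <- depth > 0
  ci <- ci[pos_depth]; si <- si[pos_depth]; depth <- depth[pos_depth]
  n <- length(ci)

  # true het: germline sites for everyone; somatic sites for carriers
  het <- truth$sites$group[si] == "germline"
  somatic_sites <- unique(si[truth$sites$group[si] %in%
                               c("ancestral", "cloneB", "cloneC", "neutral_tail")])
  if (length(somatic_sites)) {
    keybase <- nrow(truth$sites) + 1
    carrier_key <- unlist(lapply(somatic_sites, function(s)
      truth$carriers[[s]] * keybase + s), use.names = FALSE)
    het <- het | ((ci * keybase + si) %in% carrier_key)
  }

  obs_gt <- ifelse(het, "NC", "NN")
  u <- stats::runif(n)
  drop_evt <- het & u < config$ado_het
  # dropped allele chosen uniformly: half become NN, half CC
  drop_to_cc <- drop_evt & stats::runif(n) < 0.5
  obs_gt[drop_evt] <- "NN"
  obs_gt[drop_to_cc] <- "CC"
  false_het <- !het & u < config$fdr_per_site
  obs_gt[false_het] <- "NC"

  e <- config$per_read_error
  p_mut <- ifelse(obs_gt == "NC", 0.5, ifelse(obs_gt == "CC", 1 - e, e))
  mut_reads <- stats::rbinom(n, depth, p_mut)

  tier <- sample.int(3L, n, replace = TRUE, prob = c(0.95, 0.04, 0.01))
  qual <- c(30, 15, 5)[tier]
  ranksum_p <- stats::runif(n)

  data.frame(
    cell_id = truth$cells$cell_id[ci],
    chrom = truth$sites$chrom[si],
    pos = truth$sites$pos[si],
    ref = truth$sites$ref[si],
    alt = truth$sites$alt[si],
    depth = depth, mut_reads = mut_reads,
    qual = qual, ranksum_p = ranksum_p,
    genotype = obs_gt,
    site_id = truth$sites$site_id[si],
    stringsAsFactors = FALSE)
}

#' Simulate bulk-tissue read counts at the simulated sites
#'
#' Bulk tumor-tissue sequencing: per site, total depth is Poisson around
#' `mean_depth` and mutant reads are binomial with success probability
#' f(1-e) + (1-f)e where f is the true tumor-population mutant allele
#' frequency and e the per-read error.
#'
#' @param truth a `sim_truth`.
#' @param mean_depth mean bulk depth (the tumor tissue here was sequenced
#'   deep, 137x).
#' @param per_read_error per-read miscall probability.
#' @return data.frame with site_id, chrom, pos, depth, ref_reads, mut_reads.
#' @export
simulate_bulk <- function(truth, mean_depth = 137, per_read_error = 1e-3) {
  stopifnot(inherits(truth, "sim_truth"))
  ns <- nrow(truth$sites)
  depth <- pmax(1L, stats::rpois(ns, mean_depth))
  f <- truth$sites$true_freq
  p <- f * (1 - per_read_error) + (1 - f) * per_read_error
  mut <- stats::rbinom(ns, depth, p)
  data.frame(site_id = truth$sites$site_id,
             chrom = truth$sites$chrom, pos = truth$sites$pos,
             depth = depth, ref_reads = depth - mut, mut_reads = mut,
             stringsAsFactors = FALSE)
}

#' Simulate tissue-level genotype calls for the matched normal tissue
#'
#' Tissue sequencing has no allele dropout; a heterozygous site is observed
#' heterozygous unless, by read sampling, all reads carry one allele
#' (probability 2 * 0.5^depth), which makes the tissue heterozygous rate
#' depth-dependent -- the quantity the relative-FNR allele-dropout estimator
#' corrects for.
#'
#' @param truth a `sim_truth`.
#' @param mean_depth mean tissue depth.
#' @return data.frame with site_id, depth, genotype, qual, ranksum_p.
#' @export
simulate_tissue <- function(truth, mean_depth = 60) {
  stopifnot(inherits(truth, "sim_truth"))
  ns <- nrow(truth$sites)
  depth <- pmax(1L, stats::rpois(ns, mean_depth))
  het <- truth$sites$group == "germline"
  gt <- ifelse(het, "NC", "NN")
  mono <- het & stats::runif(ns) < 2 * 0.5^depth
  # the surviving allele is ref or alt with equal probability
  gt[mono] <- ifelse(stats::runif(sum(mono)) < 0.5, "NN", "CC")
  tier <- sample.int(3L, ns, replace = TRUE, prob = c(0.95, 0.04, 0.01))
  data.frame(site_id = truth$sites$site_id, depth = depth, genotype = gt,
             qual = c(30, 15, 5)[tier], ranksum_p = stats::runif(ns),
             stringsAsFactors = FALSE)
}

#' Target regions of the simulated capture design
#'
#' One 1-bp interval per simulated site, 0-based half-open.
#'
#' @param truth a `sim_truth`.
#' @return data.frame with chrom, start, end.
#' @export
sim_targets <- function(truth) {
  data.frame(chrom = truth$sites$chrom,
             start = truth$sites$pos - 1L,
             end = truth$sites$pos,
             stringsAsFactors = FALSE)
}
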