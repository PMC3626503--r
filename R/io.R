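OBS_COLUMNS <- c("cell_id", "chrom", "pos", "ref", "alt", "depth",
                 "mut_reads", "qual", "ranksum_p", "genotype")

#' Read a per-cell, per-site observation table
#'
#' Tab-separated with columns cell_id, chrom, pos, ref, alt, depth,
#' mut_reads, qual, ranksum_p, genotype (positions 1-based; an optional
#' site_id column is preserved). Malformed rows are rejected with their line
#' numbers.
#'
#' @param path file path.
#' @return validated data.frame of observations.
#' @export
read_observations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(OBS_COLUMNS, names(x))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!x$genotype %in% c("NN", "NC", "CC"))
  if (length(bad))
    stop("invalid genotype token at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " (expected NN/NC/CC)")
  for (col in c("pos", "depth", "mut_reads", "qual", "ranksum_p")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    x[[col]] <- v
  }
  if (any(x$depth < 1)) stop("depth must be >= 1 at covered sites")
  x
}

#' Write an observation table
#' @param obs observation data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write target regions as BED (0-based half-open)
#' @param targets data.frame chrom, start, end.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(targets, path) {
  utils::write.table(targets[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a somatic call set as VCF 4.2
#'
#' One record per call with INFO keys NCM (mutant cancer cells), NNC
#' (covered normal cells), CSQCLASS (consequence class) and BULKSUP (bulk
#' support flag, if present). Calls must be sorted by chrom, pos.
#'
#' @param calls a `somatic_calls` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  o <- order(calls$chrom, calls$pos)
  if (!identical(o, seq_len(nrow(calls)))
      && nrow(calls) > 0) stop("calls must be sorted by chrom, pos")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=scexoclone",
    "##INFO=<ID=NCM,Number=1,Type=Integer,Description=\"Mutant cancer cells\">",
    "##INFO=<ID=NNC,Number=1,Type=Integer,Description=\"Covered normal cells\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=BULKSUP,Number=0,Type=Flag,Description=\"Supported by bulk tissue reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls) > 0) {
    info <- sprintf("NCM=%d;NNC=%d;CSQCLASS=%s",
                    calls$n_cancer_mutant, calls$n_normal_covered,
                    ifelse(is.na(calls$class), ".", calls$class))
    if ("bulk_support" %in% names(calls))
      info <- paste0(info, ifelse(calls$bulk_support, ";BULKSUP", ""))
    recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    calls$chrom, calls$pos, calls$site_id,
                    calls$ref, calls$alt, info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a somatic call VCF written by [write_vcf()]
#'
#' @param path file path.
#' @return data.frame with site_id, chrom, pos, ref, alt, n_cancer_mutant,
#'   n_normal_covered, class, bulk_support.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(site_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), n_cancer_mutant = integer(0),
                      n_normal_covered = integer(0), class = character(0),
                      bulk_support = logical(0), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- f[, 8]
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    val <- rep(NA_character_, length(info))
    has <- grepl(paste0(key, "="), info)
    val[has] <- sub(paste0(key, "="), "", m)
    val
  }
  data.frame(site_id = f[, 3], chrom = f[, 1], pos = as.integer(f[, 2]),
             ref = f[, 4], alt = f[, 5],
             n_cancer_mutant = as.integer(grab("NCM")),
             n_normal_covered = as.integer(grab("NNC")),
             class = grab("CSQCLASS"),
             bulk_support = grepl("BULKSUP", info),
             stringsAsFactors = FALSE)
}

#' Write / read an error-rates object as JSON
#' @param rates an [error_rates()] object.
#' @param path file path.
#' @return `path` invisibly; `read_error_rates` returns the object.
#' @export
write_error_rates <- function(rates, path) {
  x <- unclass(rates)
  if (!is.null(x$per_cell_ado)) x$per_cell_ado <- as.list(x$per_cell_ado)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_error_rates
#' @export
read_error_rates <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- if (!is.null(x$per_cell_ado)) unlist(x$per_cell_ado)
  error_rates(ado_het = x$ado_het, fdr = x$fdr, ado_hom = x$ado_hom,
              per_cell_ado = pc)
}
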