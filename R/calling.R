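# VarScan-style SNP calling on parsed pileups.
#
# The caller applies exactly four thresholds: a per-base quality mask
# (min_avg_qual), a minimum number of variant-supporting reads (min_reads2),
# a minimum variant allele frequency (min_var_freq), and a per-site depth
# post-filter (min_site_reads, i.e. strictly more than 25 quality-passing
# reads).  Other VarScan defaults (min-coverage, p-value model, strand
# filters) are deliberately not reproduced.

#' Caller thresholds
#'
#' Defaults are the study settings: `--min-avg-qual 20 --min-var-freq 0.01
#' --min-reads2 10`, and retention of calls only at sites with more than 25
#' quality-passing reads (`min_site_reads = 26`).
#'
#' @param min_avg_qual bases below this Phred quality are masked from counts
#'   and from the depth used for the variant allele frequency.
#' @param min_var_freq minimum variant allele frequency (alt reads / quality-
#'   passing depth) for a call.
#' @param min_reads2 minimum variant-supporting reads.
#' @param min_site_reads minimum quality-passing site depth for a call to
#'   pass the site-depth post-filter.
#' @return object of class `caller_params`.
#' @export
caller_params <- function(min_avg_qual = 20L, min_var_freq = 0.01,
                          min_reads2 = 10L, min_site_reads = 26L) {
  stopifnot(is_count(min_avg_qual), is_count(min_reads2),
            is_count(min_site_reads),
            is_number(min_var_freq), min_var_freq > 0, min_var_freq <= 1)
  structure(list(min_avg_qual = as.integer(min_avg_qual),
                 min_var_freq = min_var_freq,
                 min_reads2 = as.integer(min_reads2),
                 min_site_reads = as.integer(min_site_reads)),
            class = "caller_params")
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), depth_used = integer(),
             alt_reads = integer(), vaf = numeric(),
             mean_alt_qual = numeric(), passed_site_depth = logical(),
             stringsAsFactors = FALSE)
}

#' Call SNPs on a parsed pileup
#'
#' At each site, bases below `min_avg_qual` are masked; the candidate alt is
#' the most frequent remaining non-reference base (ties to the
#' lexicographically smallest); a call is emitted iff the alt is supported by
#' at least `min_reads2` reads at a variant allele frequency of at least
#' `min_var_freq` (computed over quality-passing depth).  Each emitted call
#' carries `passed_site_depth`, the `> 25` quality-passing-reads post-filter.
#'
#' @param p a [pileup()].
#' @param params a [caller_params()].
#' @return data frame of calls (class `variant_calls`), sorted by
#'   (chrom, pos): `chrom`, `pos`, `ref`, `alt`, `depth_used`, `alt_reads`,
#'   `vaf`, `mean_alt_qual`, `passed_site_depth`.
#' @export
call_pileup <- function(p, params = caller_params()) {
  stopifnot(inherits(p, "pileup"), inherits(params, "caller_params"))
  n <- nrow(p$sites)
  if (!n) return(structure(empty_calls(), class = c("variant_calls",
                                                    "data.frame")))
  cnt <- base_counts(p, min_qual = params$min_avg_qual)
  depth_used <- rowSums(cnt)
  ref_i <- match(p$sites$ref, BASES)          # NA for ref N
  nonref <- cnt
  ok <- !is.na(ref_i)
  nonref[cbind(which(ok), ref_i[ok])] <- -1L
  alt_i <- max.col(nonref, ties.method = "first")
  alt_reads <- nonref[cbind(seq_len(n), alt_i)]
  alt_reads[alt_reads < 0L] <- 0L
  vaf <- ifelse(depth_used > 0, alt_reads / depth_used, 0)
  emit <- alt_reads >= params$min_reads2 & vaf >= params$min_var_freq &
    alt_reads > 0L
  if (!any(emit)) return(structure(empty_calls(),
                                   class = c("variant_calls", "data.frame")))
  idx <- which(emit)
  # mean quality of the alt-supporting bases that passed the mask, computed
  # only for emitted sites
  sel <- p$bq$qual >= params$min_avg_qual & p$bq$site %in% idx &
    p$bq$base == BASES[alt_i[p$bq$site]]
  bq <- p$bq[sel, , drop = FALSE]
  qs <- rowsum(bq$count * bq$qual, bq$site)
  qsum <- setNames(numeric(length(idx)), idx)
  qsum[rownames(qs)] <- qs
  mean_alt_qual <- unname(qsum[as.character(idx)]) / alt_reads[idx]
  calls <- data.frame(
    chrom = p$sites$chrom[idx], pos = p$sites$pos[idx],
    ref = p$sites$ref[idx], alt = BASES[alt_i[idx]],
    depth_used = as.integer(depth_used[idx]),
    alt_reads = as.integer(alt_reads[idx]), vaf = vaf[idx],
    mean_alt_qual = mean_alt_qual,
    passed_site_depth = depth_used[idx] >= params$min_site_reads,
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("variant_calls", "data.frame"))
}

#' Call a single pileup site
#'
#' @param site a one-site [pileup()] (e.g. from [pileup_site()]).
#' @param params a [caller_params()].
#' @return a one-row call data frame, or `NULL` when no call is made.
#' @export
call_site <- function(site, params = caller_params()) {
  stopifnot(inherits(site, "pileup"), nrow(site$sites) == 1L)
  calls <- call_pileup(site, params)
  if (!nrow(calls)) NULL else calls
}

#' Call SNPs for one sample and apply the site-depth post-filter
#'
#' @param x path to an mpileup file, or a [pileup()].
#' @param params a [caller_params()].
#' @param keep_failed_depth keep calls that fail the `> 25`-reads site filter
#'   (flagged `passed_site_depth = FALSE`) instead of dropping them.
#' @return `variant_calls` data frame sorted by (chrom, pos).
#' @export
call_sample <- function(x, params = caller_params(),
                        keep_failed_depth = FALSE) {
  p <- if (inherits(x, "pileup")) x else parse_mpileup(x)
  calls <- call_pileup(p, params)
  if (!keep_failed_depth)
    calls <- calls[calls$passed_site_depth, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Write variant calls as minimal VCF v4.2 and/or TSV
#'
#' The VCF carries `DP` (quality-passing depth), `AD` (alt-supporting reads)
#' and `VAF` in INFO, with FILTER `PASS` or `lowDepth` according to the
#' site-depth post-filter.
#'
#' @param calls a `variant_calls` data frame.
#' @param vcf_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_variant_calls <- function(calls, vcf_path = NULL, tsv_path = NULL) {
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Quality-passing depth\">",
             "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
             "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
             "##FILTER=<ID=lowDepth,Description=\"25 or fewer quality-passing reads\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (nrow(calls)) {
      sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AD=%d;VAF=%.6g",
              calls$chrom, calls$pos, calls$ref, calls$alt,
              ifelse(calls$passed_site_depth, "PASS", "lowDepth"),
              calls$depth_used, calls$alt_reads, calls$vaf)
    } else character(0)
    writeLines(c(hdr, body), vcf_path)
  }
  if (!is.null(tsv_path)) write_tsv(calls, tsv_path)
  invisible(c(vcf = vcf_path, tsv = tsv_path))
}

#' Read the TSV mirror written by [write_variant_calls()]
#'
#' @param path TSV path.
#' @return `variant_calls` data frame.
#' @export
read_variant_calls <- function(path) {
  df <- read_tsv(path)
  if (nrow(df)) df$passed_site_depth <- as.logical(df$passed_site_depth)
  structure(df, class = c("variant_calls", "data.frame"))
}
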