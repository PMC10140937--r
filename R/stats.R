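# Per-gene bi-allelic SNP-frequency statistic and the imprinting ANOVA.
#
# Filter cascade per gene and sample: calls are assigned to transcripts by
# exon containment; a transcript keeps its calls only if it carries at least
# `min_confident_snps` of them ("confident SNPs" -- isolated calls are likely
# PCR/sequencing artefacts); confident SNPs with VAF in the 20--80% window
# are "bi-allelic SNPs"; their count divided by transcript length in kb is
# the SNP frequency.  Genes below the read-total threshold are excluded from
# the model.

#' Statistic-level thresholds
#'
#' Defaults are the study settings: transcripts with fewer than three called
#' SNPs are discarded, the bi-allelic window is a VAF of 20--80% (inclusive),
#' and genes need 15,000 or more reads to enter the analysis.
#'
#' @param min_confident_snps a transcript's calls are kept only if there are
#'   at least this many.
#' @param biallelic_vaf_low,biallelic_vaf_high bounds of the bi-allelic VAF
#'   window.
#' @param vaf_bounds_inclusive whether the window bounds themselves pass.
#' @param min_transcript_reads minimum per-gene read total for inclusion.
#' @return object of class `analysis_params`.
#' @export
analysis_params <- function(min_confident_snps = 3L,
                            biallelic_vaf_low = 0.20,
                            biallelic_vaf_high = 0.80,
                            vaf_bounds_inclusive = TRUE,
                            min_transcript_reads = 15000L) {
  stopifnot(is_count(min_confident_snps),
            is_number(biallelic_vaf_low, min = 0),
            is_number(biallelic_vaf_high, max = 1),
            biallelic_vaf_low < biallelic_vaf_high,
            is_flag(vaf_bounds_inclusive),
            is_count(min_transcript_reads))
  structure(list(min_confident_snps = as.integer(min_confident_snps),
                 biallelic_vaf_low = biallelic_vaf_low,
                 biallelic_vaf_high = biallelic_vaf_high,
                 vaf_bounds_inclusive = vaf_bounds_inclusive,
                 min_transcript_reads = as.integer(min_transcript_reads)),
            class = "analysis_params")
}

#' Assign variant calls to panel genes by exon containment
#'
#' A call is assigned to every panel gene one of whose exons contains its
#' position; intronic calls and calls outside the panel are dropped.  Calls
#' shared by overlapping genes are duplicated, once per gene.
#'
#' @param calls a `variant_calls` data frame.
#' @param panel a `transcript_models` table.
#' @return the calls with a `gene_id` column prepended (one row per
#'   call-gene assignment).
#' @export
assign_calls_to_genes <- function(calls, panel) {
  stopifnot(inherits(panel, "transcript_models"))
  if (!nrow(calls))
    return(cbind(data.frame(gene_id = character()), calls))
  ex_n <- vapply(panel$exons, nrow, integer(1))
  ex_gene <- rep.int(seq_len(nrow(panel)), ex_n)
  ex_start <- unlist(lapply(panel$exons, function(e) e[, 1L]))
  ex_end <- unlist(lapply(panel$exons, function(e) e[, 2L]))
  ex_gr <- GenomicRanges::GRanges(panel$chrom[ex_gene],
                                  IRanges::IRanges(ex_start, ex_end))
  call_gr <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos, calls$pos))
  hit <- GenomicRanges::findOverlaps(call_gr, ex_gr)
  qi <- S4Vectors::queryHits(hit)
  gi <- ex_gene[S4Vectors::subjectHits(hit)]
  dup <- duplicated(paste(qi, gi))          # gene hit via two exons
  qi <- qi[!dup]; gi <- gi[!dup]
  out <- cbind(data.frame(gene_id = panel$gene_id[gi],
                          stringsAsFactors = FALSE),
               calls[qi, , drop = FALSE])
  out <- out[order(out$gene_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep a transcript's calls only if there are enough of them
#'
#' @param gene_calls calls belonging to one gene and sample.
#' @param params an [analysis_params()].
#' @return `gene_calls` unchanged if it has at least `min_confident_snps`
#'   rows, otherwise an empty call set.
#' @export
confident_snps <- function(gene_calls, params = analysis_params()) {
  if (nrow(gene_calls) >= params$min_confident_snps) gene_calls
  else gene_calls[0L, , drop = FALSE]
}

#' Keep SNPs in the bi-allelic VAF window
#'
#' @param snps confident calls for one gene and sample.
#' @param params an [analysis_params()].
#' @return the calls with VAF inside the window.
#' @export
biallelic_filter <- function(snps, params = analysis_params()) {
  keep <- if (params$vaf_bounds_inclusive)
    snps$vaf >= params$biallelic_vaf_low &
      snps$vaf <= params$biallelic_vaf_high
  else
    snps$vaf > params$biallelic_vaf_low &
      snps$vaf < params$biallelic_vaf_high
  snps[keep, , drop = FALSE]
}

#' Summarise one gene in one sample
#'
#' @param sample_id sample identifier.
#' @param gene one-row slice of a `transcript_models` panel.
#' @param gene_calls calls assigned to this gene in this sample.
#' @param total_reads the gene's read total in this sample.
#' @param params an [analysis_params()].
#' @return one-row data frame: `sample_id`, `gene_id`, `locus_id`,
#'   `imprinted`, `total_reads`, `confident_snp_count`,
#'   `biallelic_snp_count`, `transcript_length_kb`, `snp_freq_per_kb`,
#'   `included`.
#' @export
summarize_gene <- function(sample_id, gene, gene_calls, total_reads,
                           params = analysis_params()) {
  if (is.na(total_reads))
    stopf("missing read total for sample %s, gene %s",
          sample_id, gene$gene_id)
  conf <- confident_snps(gene_calls, params)
  bi <- biallelic_filter(conf, params)
  len_kb <- gene$transcript_length_bp / 1000
  data.frame(sample_id = sample_id, gene_id = gene$gene_id,
             locus_id = gene$locus_id, imprinted = gene$imprinted,
             total_reads = as.integer(total_reads),
             confident_snp_count = nrow(conf),
             biallelic_snp_count = nrow(bi),
             transcript_length_kb = len_kb,
             snp_freq_per_kb = nrow(bi) / len_kb,
             included = total_reads >= params$min_transcript_reads,
             stringsAsFactors = FALSE)
}

#' Summarise every panel gene in every sample
#'
#' Applies [assign_calls_to_genes()], the confident-SNP rule, the bi-allelic
#' VAF window and the SNP-frequency statistic to each sample's calls; a row
#' is produced for every (sample, panel gene) pair, including genes with no
#' calls.
#'
#' @param calls_by_sample named list (`sample_id` -> `variant_calls`).
#' @param panel a `transcript_models` table.
#' @param read_totals data frame `sample_id`, `gene_id`, `total_reads`
#'   covering every (sample, panel gene) pair.
#' @param params an [analysis_params()].
#' @return data frame of per-gene summaries (class `gene_snp_summary`).
#' @export
summarize_cohort <- function(calls_by_sample, panel, read_totals,
                             params = analysis_params()) {
  stopifnot(inherits(panel, "transcript_models"))
  key <- paste(read_totals$sample_id, read_totals$gene_id, sep = "\r")
  totals <- setNames(read_totals$total_reads, key)
  out <- vector("list", length(calls_by_sample))
  len_kb <- panel$transcript_length_bp / 1000
  for (si in seq_along(calls_by_sample)) {
    smp <- names(calls_by_sample)[si]
    assigned <- assign_calls_to_genes(calls_by_sample[[si]], panel)
    tot <- totals[paste(smp, panel$gene_id, sep = "\r")]
    if (anyNA(tot))
      stopf("missing read total for sample %s, gene %s", smp,
            panel$gene_id[which(is.na(tot))[1L]])
    n_raw <- integer(nrow(panel))
    n_bi <- integer(nrow(panel))
    if (nrow(assigned)) {
      gidx <- match(assigned$gene_id, panel$gene_id)
      raw <- table(factor(gidx, levels = seq_len(nrow(panel))))
      n_raw <- as.integer(raw)
      inwin <- if (params$vaf_bounds_inclusive)
        assigned$vaf >= params$biallelic_vaf_low &
          assigned$vaf <= params$biallelic_vaf_high
      else
        assigned$vaf > params$biallelic_vaf_low &
          assigned$vaf < params$biallelic_vaf_high
      bi <- table(factor(gidx[inwin], levels = seq_len(nrow(panel))))
      n_bi <- as.integer(bi)
    }
    conf <- n_raw >= params$min_confident_snps
    n_conf <- ifelse(conf, n_raw, 0L)
    n_bi <- ifelse(conf, n_bi, 0L)
    out[[si]] <- data.frame(
      sample_id = smp, gene_id = panel$gene_id, locus_id = panel$locus_id,
      imprinted = panel$imprinted, total_reads = as.integer(tot),
      confident_snp_count = as.integer(n_conf),
      biallelic_snp_count = as.integer(n_bi),
      transcript_length_kb = len_kb,
      snp_freq_per_kb = n_bi / len_kb,
      included = unname(tot >= params$min_transcript_reads),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("gene_snp_summary", "data.frame"))
}

#' Read back a summary TSV written by [report()] or [write_tsv()]
#'
#' @param path TSV path.
#' @return `gene_snp_summary` data frame.
#' @export
read_summaries <- function(path) {
  df <- read_tsv(path)
  df$imprinted <- as.logical(df$imprinted)
  df$included <- as.logical(df$included)
  structure(df, class = c("gene_snp_summary", "data.frame"))
}

anova_term_table <- function(fit) {
  at <- car::Anova(fit, type = 2)
  data.frame(term = rownames(at), sum_sq = at[["Sum Sq"]], df = at[["Df"]],
             F = at[["F value"]], p = at[["Pr(>F)"]],
             stringsAsFactors = FALSE)
}

#' Imprinting-status by group ANOVA with Tukey HSD
#'
#' For each tissue independently, fits
#' `snp_freq_per_kb ~ imprinted * group + sex` on included gene-by-sample
#' rows, reports Type II per-term F tests, and runs a Tukey HSD over the six
#' (group x imprinting status) cells -- the contrasts displayed in the
#' jittered box plots -- on `aov(snp_freq_per_kb ~ sex + cell)`.  Cell means
#' are returned alongside.
#'
#' If the response is constant (zero total variance) every F is reported as
#' 0 with p = 1 and every Tukey difference as 0 with adjusted p = 1: a flat
#' response carries no evidence for any effect.
#'
#' @param summaries a `gene_snp_summary` table.
#' @param metadata sample sheet with `sample_id`, `group`, `sex`, `tissue`.
#' @param include_interaction include the `imprinted:group` interaction
#'   (default `TRUE`; the within-group contrasts require it).
#' @param sex_covariate include sex as a covariate factor.
#' @param use_included_only drop rows failing the read-total threshold.
#' @return object of class `imprint_anova`: per-tissue list of
#'   `anova_table`, `tukey`, `cell_means`, `n`, plus the model `data`.
#' @export
imprinting_anova <- function(summaries, metadata,
                             include_interaction = TRUE,
                             sex_covariate = TRUE,
                             use_included_only = TRUE) {
  need <- c("sample_id", "group", "sex", "tissue")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stopf("metadata lacks columns: %s", paste(miss, collapse = ", "))
  d <- merge(summaries, metadata[, need], by = "sample_id")
  if (use_included_only) d <- d[d$included, , drop = FALSE]
  if (!nrow(d)) stopf("no included gene/sample rows to analyse")
  glev <- if (all(d$group %in% SIM_GROUPS))
    intersect(SIM_GROUPS, unique(d$group)) else sort(unique(d$group))
  d$group <- factor(d$group, levels = glev)
  d$status <- factor(ifelse(d$imprinted, "imprinted", "non_imprinted"),
                     levels = c("non_imprinted", "imprinted"))
  d$sex <- factor(d$sex)

  fit_one <- function(dt) {
    for (f in c("status", "group", if (sex_covariate) "sex")) {
      dt[[f]] <- droplevels(dt[[f]])
      if (nlevels(dt[[f]]) < 2L)
        stopf("factor '%s' has a single level; cannot fit ANOVA",
              if (f == "status") "imprinted" else f)
    }
    dt$cell <- interaction(dt$group, dt$status, sep = ".", drop = TRUE)
    y <- dt$snp_freq_per_kb
    degenerate <- sum((y - mean(y))^2) < 1e-20
    form <- if (include_interaction) snp_freq_per_kb ~ status * group
            else snp_freq_per_kb ~ status + group
    if (sex_covariate) form <- update(form, . ~ . + sex)
    if (degenerate) {
      terms <- c("status", "group", if (sex_covariate) "sex",
                 if (include_interaction) "status:group")
      tab <- data.frame(term = terms, sum_sq = 0, df = NA_integer_, F = 0,
                        p = 1, stringsAsFactors = FALSE)
      lev <- levels(dt$cell)
      pairs <- t(combn(lev, 2L))
      tk <- data.frame(contrast = paste(pairs[, 2L], pairs[, 1L],
                                        sep = "-"),
                       diff = 0, lwr = 0, upr = 0, p_adj = 1,
                       stringsAsFactors = FALSE)
    } else {
      fit <- lm(form, data = dt)
      tab <- anova_term_table(fit)
      tab <- tab[tab$term != "Residuals", , drop = FALSE]
      aform <- if (sex_covariate) snp_freq_per_kb ~ sex + cell
               else snp_freq_per_kb ~ cell
      tuk <- TukeyHSD(aov(aform, data = dt), "cell")$cell
      tk <- data.frame(contrast = rownames(tuk), diff = tuk[, "diff"],
                       lwr = tuk[, "lwr"], upr = tuk[, "upr"],
                       p_adj = tuk[, "p adj"], stringsAsFactors = FALSE)
    }
    rownames(tab) <- NULL
    rownames(tk) <- NULL
    cm <- aggregate(snp_freq_per_kb ~ group + status, data = dt, FUN = mean)
    names(cm)[names(cm) == "snp_freq_per_kb"] <- "mean_snp_freq_per_kb"
    cm <- cm[order(cm$group, cm$status), , drop = FALSE]
    rownames(cm) <- NULL
    list(anova_table = tab, tukey = tk, cell_means = cm, n = nrow(dt))
  }

  tissues <- sort(unique(d$tissue))
  fits <- lapply(tissues, function(ts)
    fit_one(d[d$tissue == ts, , drop = FALSE]))
  names(fits) <- tissues
  structure(list(tissues = fits, data = d,
                 include_interaction = include_interaction,
                 sex_covariate = sex_covariate),
            class = "imprint_anova")
}

#' Extract the within-group imprinted vs non-imprinted Tukey contrasts
#'
#' @param x an `imprint_anova`.
#' @param tissue tissue name (default: first fitted).
#' @return data frame with one row per group: `group`, `diff`, `p_adj`.
#' @export
within_group_contrasts <- function(x, tissue = NULL) {
  stopifnot(inherits(x, "imprint_anova"))
  tissue <- tissue %||% names(x$tissues)[1L]
  tk <- x$tissues[[tissue]]$tukey
  parts <- strsplit(tk$contrast, "-", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  ga <- sub("\\.(imprinted|non_imprinted)$", "", a)
  gb <- sub("\\.(imprinted|non_imprinted)$", "", b)
  sa <- sub("^.*\\.", "", a)
  sb <- sub("^.*\\.", "", b)
  keep <- ga == gb & sa != sb
  data.frame(group = ga[keep], diff = tk$diff[keep],
             p_adj = tk$p_adj[keep], stringsAsFactors = FALSE)
}

#' @export
print.imprint_anova <- function(x, ...) {
  for (ts in names(x$tissues)) {
    f <- x$tissues[[ts]]
    cat(sprintf("Imprinting ANOVA -- tissue '%s' (%d gene x sample rows)\n",
                ts, f$n))
    tab <- f$anova_table
    tab$p <- format.pval(tab$p, digits = 3)
    print(tab, row.names = FALSE)
    cat("\nWithin-group imprinted vs non-imprinted (Tukey HSD):\n")
    print(within_group_contrasts(x, ts), row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @method summary imprint_anova
#' @export
summary.imprint_anova <- function(object, ...) {
  print(object)
  for (ts in names(object$tissues)) {
    cat(sprintf("Cell means -- tissue '%s':\n", ts))
    print(object$tissues[[ts]]$cell_means, row.names = FALSE)
    cat("\n")
  }
  invisible(object)
}

#' Jittered box plot of SNP frequency by group and imprinting status
#'
#' Base-graphics rendering of the statistic over the six (group x status)
#' cells, one panel per tissue; point jitter is deterministic.
#'
#' @param x an `imprint_anova`.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @method plot imprint_anova
#' @export
plot.imprint_anova <- function(x, ...) {
  d <- x$data
  for (ts in names(x$tissues)) {
    dt <- d[d$tissue == ts, , drop = FALSE]
    dt$cell <- interaction(dt$group, dt$status, sep = "\n", drop = TRUE)
    boxplot(snp_freq_per_kb ~ cell, data = dt, outline = FALSE,
            ylab = "SNP frequency (per kb)", xlab = "",
            main = sprintf("Bi-allelic SNP frequency -- %s", ts),
            col = rep(c("grey85", "lightsteelblue"),
                      each = nlevels(dt$group)), ...)
    ci <- as.integer(dt$cell)
    off <- ((seq_along(ci) * 7L) %% 11L - 5L) / 25  # fixed jitter pattern
    points(ci + off, dt$snp_freq_per_kb, pch = 16, cex = 0.5,
           col = "grey40")
  }
  invisible(x)
}

#' Write analysis outputs as tidy TSVs and an optional figure
#'
#' Writes `summaries.tsv`, and per tissue `anova_<tissue>.tsv`,
#' `tukey_<tissue>.tsv`, `cell_means_<tissue>.tsv`; with `plot = TRUE` also
#' `snp_freq_boxplot.pdf`.  Output is deterministic given identical inputs.
#'
#' @param summaries a `gene_snp_summary` table.
#' @param anova an `imprint_anova` (or `NULL` to skip model tables).
#' @param out_dir output directory, created if needed.
#' @param plot write the jittered box plot.
#' @return named character vector of files written, invisibly.
#' @export
report <- function(summaries, anova, out_dir, plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output dir: %s", out_dir)
  files <- c(summaries = file.path(out_dir, "summaries.tsv"))
  write_tsv(summaries, files[["summaries"]])
  if (!is.null(anova)) {
    for (ts in names(anova$tissues)) {
      f <- anova$tissues[[ts]]
      p <- c(file.path(out_dir, sprintf("anova_%s.tsv", ts)),
             file.path(out_dir, sprintf("tukey_%s.tsv", ts)),
             file.path(out_dir, sprintf("cell_means_%s.tsv", ts)))
      write_tsv(f$anova_table, p[1L])
      write_tsv(f$tukey, p[2L])
      write_tsv(f$cell_means, p[3L])
      names(p) <- paste(c("anova", "tukey", "cell_means"), ts, sep = "_")
      files <- c(files, p)
    }
    if (plot) {
      fp <- file.path(out_dir, "snp_freq_boxplot.pdf")
      pdf(fp, width = 7, height = 5)
      plot(anova)
      dev.off()
      files <- c(files, figure = fp)
    }
  }
  invisible(files)
}
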