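# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (per-read loops, O(n*m) interval
# scans, explicit least-squares) so it shares no code path with the package.

# ---- variant-calling oracle: per-read loop over one mpileup record ----
oracle_call_line <- function(ref, bases, quals, min_avg_qual = 20,
                             min_var_freq = 0.01, min_reads2 = 10,
                             min_site_reads = 26) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  qsum <- counts
  chars <- strsplit(bases, "")[[1]]
  reads <- character(0)
  k <- 1
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "^") { k <- k + 2; next }
    if (ch == "$") { k <- k + 1; next }
    if (ch %in% c("+", "-")) {
      num <- ""
      while (k + 1 <= length(chars) && grepl("[0-9]", chars[k + 1])) {
        num <- paste0(num, chars[k + 1]); k <- k + 1
      }
      k <- k + as.integer(num) + 1
      next
    }
    reads <- c(reads, ch)
    k <- k + 1
  }
  qv <- utf8ToInt(quals) - 33
  stopifnot(length(reads) == length(qv))
  for (j in seq_along(reads)) {
    b <- if (reads[j] %in% c(".", ",")) ref else toupper(reads[j])
    if (!b %in% names(counts)) next
    if (qv[j] < min_avg_qual) next
    counts[b] <- counts[b] + 1
    qsum[b] <- qsum[b] + qv[j]
  }
  depth_used <- sum(counts)
  nonref <- counts
  nonref[ref] <- -1
  alt <- names(nonref)[which.max(nonref)]   # first max = lexicographic tie
  alt_reads <- counts[[alt]]
  vaf <- if (depth_used > 0) alt_reads / depth_used else 0
  if (alt_reads >= min_reads2 && vaf >= min_var_freq && alt_reads > 0)
    list(alt = alt, depth_used = depth_used, alt_reads = alt_reads,
         vaf = vaf, mean_alt_qual = qsum[[alt]] / alt_reads,
         passed_site_depth = depth_used >= min_site_reads)
  else NULL
}

# ---- O(n*m) interval oracle for panel membership ----
oracle_panel_genes <- function(models, windows) {
  hits <- character(0)
  for (i in seq_len(nrow(models))) {
    for (j in seq_len(nrow(windows))) {
      if (models$chrom[i] == windows$chrom[j] &&
          models$start[i] <= windows$window_end[j] &&
          models$end[i] >= windows$window_start[j]) {
        hits <- c(hits, models$gene_id[i])
        break
      }
    }
  }
  hits
}

# ---- explicit least-squares Type II ANOVA oracle ----
# Terms: status, group, sex (optional), status:group.  SS_II(T) compares the
# fit without T (holding out interactions containing T) against the fit with
# it; F uses the full-model residual mean square.
rss <- function(X, y) {
  fit <- qr(X)
  sum((y - X %*% qr.coef(fit, y))[, 1L]^2)
}

oracle_type2_anova <- function(d, sex = TRUE) {
  y <- cbind(d$snp_freq_per_kb)
  mm <- function(form) model.matrix(form, data = d)
  X_full <- mm(if (sex) ~ status * group + sex else ~ status * group)
  n <- nrow(d)
  df_res <- n - qr(X_full)$rank
  mse <- rss(X_full, y) / df_res
  base_sex <- if (sex) ~ status + group + sex else ~ status + group
  terms <- list(
    status = list(with = base_sex,
                  without = if (sex) ~ group + sex else ~ group),
    group = list(with = base_sex,
                 without = if (sex) ~ status + sex else ~ status),
    `status:group` = list(with = X_full,
                          without = base_sex))
  if (sex) terms$sex <- list(with = base_sex, without = ~ status + group)
  out <- lapply(names(terms), function(tn) {
    t <- terms[[tn]]
    Xw <- if (inherits(t$with, "formula")) mm(t$with) else t$with
    Xo <- mm(t$without)
    ss <- rss(Xo, y) - rss(Xw, y)
    df <- qr(Xw)$rank - qr(Xo)$rank
    F <- (ss / df) / mse
    data.frame(term = tn, sum_sq = ss, df = df, F = F,
               p = pf(F, df, df_res, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# ---- fixture builders ----
# a transcript_models table from a compact spec list
tiny_models <- function(spec) {
  df <- do.call(rbind, lapply(spec, function(s)
    data.frame(gene_id = s$gene, transcript_id = s$tx %||% paste0(s$gene, ".t1"),
               chrom = s$chrom, strand = s$strand %||% "+",
               stringsAsFactors = FALSE)))
  df$exons <- lapply(spec, function(s) s$exons)
  transcript_models(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random pileup with arbitrary qualities, for round-trip property tests
random_pileup <- function(n_sites, max_depth = 30) {
  chrom <- sort(sample(c("chr1", "chr2"), n_sites, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(i)
    sort(sample.int(10 * n_sites, length(i)))), use.names = FALSE)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  bq <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    nb <- sample.int(4, 1)
    b <- sample(c("A", "C", "G", "T"), nb)
    do.call(rbind, lapply(b, function(bb) {
      nq <- sample.int(2, 1)
      data.frame(site = i, base = bb,
                 qual = sample(2:41, nq),
                 count = sample.int(max_depth, nq))
    }))
  }))
  pileup(data.frame(chrom = chrom, pos = pos, ref = ref,
                    stringsAsFactors = FALSE), bq)
}

default_sheet <- sample_sheet()
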