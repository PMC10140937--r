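# Filter cascade, SNP-frequency statistic, and the ANOVA/Tukey layer.

fake_calls <- function(pos, vaf = rep(0.5, length(pos)), chrom = "chr1") {
  n <- length(pos)
  structure(data.frame(chrom = chrom, pos = as.integer(pos), ref = "A",
                       alt = "C", depth_used = 100L,
                       alt_reads = as.integer(round(vaf * 100)), vaf = vaf,
                       mean_alt_qual = 40, passed_site_depth = TRUE,
                       stringsAsFactors = FALSE),
            class = c("variant_calls", "data.frame"))
}

two_gene_panel <- tiny_models(list(
  list(gene = "G1", chrom = "chr1", exons = rbind(c(101, 200), c(301, 350))),
  list(gene = "G2", chrom = "chr1", exons = cbind(150, 1649))))

test_that("calls map to genes by exon containment, introns drop", {
  calls <- fake_calls(c(150, 250, 320, 5000))
  a <- assign_calls_to_genes(calls, two_gene_panel)
  # 150 is exonic in both overlapping genes; 250 is intronic in G1 but
  # exonic in G2; 320 exonic in G1 and G2; 5000 outside the panel
  expect_equal(sum(a$gene_id == "G1"), 2L)
  expect_equal(sort(a$pos[a$gene_id == "G1"]), c(150L, 320L))
  expect_equal(sort(a$pos[a$gene_id == "G2"]), c(150L, 250L, 320L))
  expect_false(5000 %in% a$pos)
})

test_that("assignment matches a brute-force interval scan on random data", {
  set.seed(31)
  genes <- lapply(1:30, function(i) {
    s <- sample.int(9000, 1)
    list(gene = sprintf("R%02d", i), chrom = sample(c("chr1", "chr2"), 1),
         exons = cbind(s, s + sample.int(400, 1)))
  })
  panel <- tiny_models(genes)
  calls <- fake_calls(sample.int(10000, 300), vaf = runif(300))
  calls$chrom <- sample(c("chr1", "chr2"), 300, replace = TRUE)
  calls <- calls[order(calls$chrom, calls$pos), ]
  a <- assign_calls_to_genes(calls, panel)
  brute <- 0L
  for (i in seq_len(nrow(calls))) {
    for (g in seq_len(nrow(panel))) {
      ex <- panel$exons[[g]]
      if (panel$chrom[g] == calls$chrom[i] &&
          any(calls$pos[i] >= ex[, 1] & calls$pos[i] <= ex[, 2]))
        brute <- brute + 1L
    }
  }
  expect_equal(nrow(a), brute)
})

test_that("fewer than three SNPs per transcript are discarded", {
  params <- analysis_params()
  expect_equal(nrow(confident_snps(fake_calls(1:2, c(0.5, 0.5)), params)), 0L)
  expect_equal(nrow(confident_snps(fake_calls(1:3, rep(0.5, 3)), params)), 3L)
  expect_equal(nrow(confident_snps(fake_calls(1:17, rep(0.5, 17)), params)),
               17L)
})

test_that("the 20-80% VAF window keeps bi-allelic SNPs inclusively", {
  params <- analysis_params()
  snps <- fake_calls(1:5, c(0.50, 0.19, 0.20, 0.80, 0.95))
  kept <- biallelic_filter(snps, params)
  expect_equal(kept$vaf, c(0.50, 0.20, 0.80))
  strict <- biallelic_filter(snps, analysis_params(vaf_bounds_inclusive = FALSE))
  expect_equal(strict$vaf, 0.50)
})

test_that("summarize_gene composes the cascade and the read threshold", {
  gene <- two_gene_panel[2, ]   # G2: 1500 bp
  calls <- fake_calls(c(200, 300, 400), rep(0.5, 3))
  s <- summarize_gene("s1", gene, calls, total_reads = 20000)
  expect_equal(s$snp_freq_per_kb, 2.0)       # 3 bi-allelic SNPs / 1.5 kb
  expect_equal(s$confident_snp_count, 3L)
  expect_true(s$included)
  # 0 confident SNPs -> 0 frequency
  s0 <- summarize_gene("s1", gene, fake_calls(c(200, 300), c(0.5, 0.5)),
                       total_reads = 20000)
  expect_equal(s0$snp_freq_per_kb, 0)
  expect_equal(s0$confident_snp_count, 0L)
  # inclusion threshold is >= 15,000
  expect_true(summarize_gene("s1", gene, calls, 15000)$included)
  expect_false(summarize_gene("s1", gene, calls, 14999)$included)
  expect_error(summarize_gene("s1", gene, calls, NA), "missing read total")
})

test_that("doubling transcript length halves the SNP frequency exactly", {
  panel <- tiny_models(list(
    list(gene = "A1", chrom = "chr1", exons = cbind(1, 1000)),
    list(gene = "A2", chrom = "chr2", exons = cbind(1, 2000))))
  calls <- rbind(fake_calls(c(10, 20, 30), rep(0.5, 3), chrom = "chr1"),
                 fake_calls(c(10, 20, 30), rep(0.5, 3), chrom = "chr2"))
  rt <- data.frame(sample_id = "s1", gene_id = c("A1", "A2"),
                   total_reads = 20000)
  summ <- summarize_cohort(list(s1 = calls), panel, rt)
  expect_equal(summ$snp_freq_per_kb[summ$gene_id == "A1"],
               2 * summ$snp_freq_per_kb[summ$gene_id == "A2"])
})

test_that("summarize_cohort agrees with per-gene summarize_gene", {
  set.seed(32)
  cfg <- sim_config(seed = 33, n_loci = 2, n_neighbours_per_locus = 4,
                    transcript_length_bp = 600, mean_coverage = 60,
                    het_snp_density_per_kb = 6)
  co <- simulate_cohort(cfg)
  calls <- lapply(co$pileups, call_sample)
  params <- analysis_params(min_transcript_reads = 0)
  summ <- summarize_cohort(calls, co$panel, co$read_totals, params)
  rt <- co$read_totals
  for (si in c(1, 5)) {
    smp <- names(calls)[si]
    a <- assign_calls_to_genes(calls[[si]], co$panel)
    for (gi in seq_len(nrow(co$panel))) {
      g <- co$panel[gi, ]
      gc <- a[a$gene_id == g$gene_id, -1]
      tot <- rt$total_reads[rt$sample_id == smp & rt$gene_id == g$gene_id]
      one <- summarize_gene(smp, g, gc, tot, params)
      row <- summ[summ$sample_id == smp & summ$gene_id == g$gene_id, ]
      expect_equal(row$confident_snp_count, one$confident_snp_count)
      expect_equal(row$biallelic_snp_count, one$biallelic_snp_count)
      expect_equal(row$snp_freq_per_kb, one$snp_freq_per_kb)
    }
  }
  # pipeline conservation: bi-allelic <= confident <= raw assigned calls
  expect_true(all(summ$biallelic_snp_count <= summ$confident_snp_count))
})

meta12 <- data.frame(
  sample_id = sprintf("s%d", 1:6),
  group = rep(c("control", "autologous", "heterologous"), each = 2),
  sex = rep(c("F", "M"), 3), tissue = "brain", stringsAsFactors = FALSE)

hand_table <- function(y) {
  data.frame(sample_id = rep(meta12$sample_id, 2),
             gene_id = rep(c("gI", "gN"), each = 6),
             locus_id = "L1", imprinted = rep(c(TRUE, FALSE), each = 6),
             total_reads = 20000L, confident_snp_count = 3L,
             biallelic_snp_count = 3L, transcript_length_kb = 1,
             snp_freq_per_kb = y, included = TRUE, stringsAsFactors = FALSE)
}

test_that("a constant response yields p = 1 everywhere", {
  fit <- imprinting_anova(hand_table(rep(2, 12)), meta12)
  tab <- fit$tissues$brain$anova_table
  expect_true(all(tab$p == 1))
  expect_true(all(tab$F == 0))
  expect_true(all(fit$tissues$brain$tukey$p_adj == 1))
})

test_that("a 12-row table reproduces the explicit least-squares oracle", {
  set.seed(34)
  y <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.2, 2.1, 1.8, 2.4, 2.2, 1.9, 2.6)
  fit <- imprinting_anova(hand_table(y), meta12)
  tab <- fit$tissues$brain$anova_table
  d <- merge(hand_table(y), meta12, by = "sample_id")
  d$status <- factor(ifelse(d$imprinted, "imprinted", "non_imprinted"),
                     levels = c("non_imprinted", "imprinted"))
  d$group <- factor(d$group,
                    levels = c("control", "autologous", "heterologous"))
  d$sex <- factor(d$sex)
  oracle <- oracle_type2_anova(d)
  for (tn in oracle$term) {
    expect_equal(tab$F[tab$term == tn], oracle$F[oracle$term == tn],
                 tolerance = 1e-8, label = tn)
    expect_equal(tab$p[tab$term == tn], oracle$p[oracle$term == tn],
                 tolerance = 1e-8, label = tn)
  }
  # Tukey covers all 15 pairs of the 6 (group x status) cells
  expect_equal(nrow(fit$tissues$brain$tukey), choose(6, 2))
  wg <- within_group_contrasts(fit)
  expect_equal(sort(wg$group),
               sort(c("control", "autologous", "heterologous")))
})

test_that("degenerate factors and empty inputs raise named errors", {
  m1 <- meta12
  m1$sex <- "F"
  expect_error(imprinting_anova(hand_table(rnorm(12)), m1), "sex")
  tab <- hand_table(rnorm(12))
  tab$imprinted <- FALSE
  expect_error(imprinting_anova(tab, meta12), "imprinted")
  tab2 <- hand_table(rnorm(12))
  tab2$included <- FALSE
  expect_error(imprinting_anova(tab2, meta12), "no included")
})

test_that("tissues are modelled independently", {
  meta2 <- rbind(meta12, transform(meta12, sample_id = paste0(sample_id, "b"),
                                   tissue = "liver"))
  y1 <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.2, 2.1, 1.8, 2.4, 2.2, 1.9, 2.6)
  t1 <- hand_table(y1)
  t2 <- hand_table(rep(1, 12))
  t2$sample_id <- paste0(t2$sample_id, "b")
  fit <- imprinting_anova(rbind(t1, t2), meta2)
  expect_equal(names(fit$tissues), c("brain", "liver"))
  expect_true(all(fit$tissues$liver$anova_table$p == 1))
  expect_lt(fit$tissues$brain$anova_table$p[1], 0.05)
  single <- imprinting_anova(t1, meta12)
  expect_equal(fit$tissues$brain$anova_table, single$tissues$brain$anova_table)
})

test_that("report writes deterministic TSVs that round-trip", {
  y <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.2, 2.1, 1.8, 2.4, 2.2, 1.9, 2.6)
  summ <- hand_table(y)
  fit <- imprinting_anova(summ, meta12)
  d1 <- file.path(tempdir(), "repA")
  d2 <- file.path(tempdir(), "repB")
  unlink(c(d1, d2), recursive = TRUE)
  f1 <- report(summ, fit, d1, plot = FALSE)
  f2 <- report(summ, fit, d2, plot = FALSE)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)
  back <- read_summaries(f1[["summaries"]])
  expect_equal(back$snp_freq_per_kb, summ$snp_freq_per_kb)
  expect_equal(back$imprinted, summ$imprinted)
  expect_equal(back$included, summ$included)
})
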