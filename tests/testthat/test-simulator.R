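# Allele-specific pileup simulator: determinism, generative structure,
# and the degenerate / monotone behaviour of the leakage parameter.

small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_loci = 2, n_neighbours_per_locus = 3,
             transcript_length_bp = 400, mean_coverage = 50, ...)
}

test_that("identical config and seed give byte-identical outputs", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_cohort(small_cfg(), out_dir = d1)
  simulate_cohort(small_cfg(), out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "simC")
  unlink(d3, recursive = TRUE)
  simulate_cohort(small_cfg(seed = 6), out_dir = d3)
  mp <- grep("mpileup$", f1, value = TRUE)[1]
  expect_false(identical(readLines(file.path(d1, mp)),
                         readLines(file.path(d3, mp))))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(3)
  set.seed(99)
  invisible(simulate_cohort(small_cfg()))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("per-base counts sum to the emitted depth at every site", {
  co <- simulate_cohort(small_cfg())
  for (p in co$pileups[1:3]) {
    expect_equal(unname(rowSums(base_counts(p))), p$sites$raw_depth)
  }
  # read totals equal summed site depths per gene
  p1 <- co$pileups[[1]]
  g1 <- co$panel$gene_id[1]
  span <- co$panel$exons[[1]]
  in_g1 <- p1$sites$chrom == co$panel$chrom[1] &
    p1$sites$pos >= span[1, 1] & p1$sites$pos <= span[nrow(span), 2]
  tot <- co$read_totals
  expect_equal(sum(p1$sites$raw_depth[in_g1]),
               tot$total_reads[tot$sample_id == names(co$pileups)[1] &
                                 tot$gene_id == g1])
})

test_that("strict imprinting leaves zero alt reads on the silenced allele", {
  cfg <- sim_config(seed = 9, n_loci = 3, n_neighbours_per_locus = 0,
                    transcript_length_bp = 1000, mean_coverage = 80,
                    base_error_rate = 0,
                    leakage_by_group = c(control = 0, autologous = 0,
                                         heterologous = 0))
  co <- simulate_cohort(cfg)
  hs <- co$truth$het_sites
  for (si in seq_len(nrow(co$metadata))) {
    smp <- co$metadata[si, ]
    p <- co$pileups[[smp$sample_id]]
    cnt <- base_counts(p)
    h <- hs[hs$pig_id == smp$pig_id, ]
    imp <- h[h$gene_id %in% co$panel$gene_id[co$panel$imprinted], ]
    sil <- imp[imp$alt_on_silenced_allele, ]
    if (nrow(sil)) {
      idx <- match(paste(sil$chrom, sil$pos),
                   paste(p$sites$chrom, p$sites$pos))
      expect_true(all(cnt[cbind(idx, match(sil$alt, c("A","C","G","T")))] == 0))
      # and the expressed allele carries the full depth
      expr <- imp[!imp$alt_on_silenced_allele, ]
      idx2 <- match(paste(expr$chrom, expr$pos),
                    paste(p$sites$chrom, p$sites$pos))
      af <- cnt[cbind(idx2, match(expr$alt, c("A","C","G","T")))] /
        rowSums(cnt[idx2, , drop = FALSE])
      expect_true(all(af == 1))
    }
  }
})

test_that("bi-allelic alt fractions concentrate at 0.5 at high depth", {
  cfg <- sim_config(seed = 10, n_loci = 1, n_neighbours_per_locus = 20,
                    transcript_length_bp = 1000, mean_coverage = 4000,
                    depth_dispersion = 0, base_error_rate = 0,
                    samples = sample_sheet(n_per_group = 1))
  co <- simulate_cohort(cfg)
  smp <- co$metadata[1, ]
  p <- co$pileups[[smp$sample_id]]
  cnt <- base_counts(p)
  h <- co$truth$het_sites
  h <- h[h$pig_id == smp$pig_id &
           !h$gene_id %in% co$panel$gene_id[co$panel$imprinted], ]
  idx <- match(paste(h$chrom, h$pos), paste(p$sites$chrom, p$sites$pos))
  af <- cnt[cbind(idx, match(h$alt, c("A","C","G","T")))] / rowSums(cnt[idx, ])
  # Binomial(4000, 0.5): essentially all draws within 5 sd of 0.5
  expect_true(all(abs(af - 0.5) < 0.05))
  expect_lt(abs(mean(af) - 0.5), 0.01)
})

test_that("het-site totals follow the Poisson placement model", {
  cfg <- sim_config(seed = 11, n_loci = 8, n_neighbours_per_locus = 24,
                    transcript_length_bp = 2000, het_snp_density_per_kb = 2,
                    mean_coverage = 5,
                    samples = sample_sheet(n_per_group = 1))
  co <- simulate_cohort(cfg)                  # 200 genes, lambda = 4 each
  hs <- co$truth$het_sites
  # the cohort total over 3 pigs is Poisson(3 * 200 * 4): check 3 sigma
  expect_lt(abs(nrow(hs) - 2400), 3 * sqrt(2400))
  # het sites fall within their gene's exons
  span <- do.call(rbind, lapply(seq_len(nrow(co$panel)), function(i)
    data.frame(gene_id = co$panel$gene_id[i],
               start = co$panel$start[i], end = co$panel$end[i])))
  m <- merge(hs, span, by = "gene_id")
  expect_true(all(m$pos >= m$start & m$pos <= m$end))
})

test_that("at L = 0.5 imprinted and bi-allelic alt fractions are alike", {
  cfg <- sim_config(seed = 12, n_loci = 8, n_neighbours_per_locus = 24,
                    transcript_length_bp = 1000, mean_coverage = 100,
                    base_error_rate = 0,
                    leakage_by_group = c(control = 0.5, autologous = 0.5,
                                         heterologous = 0.5),
                    samples = sample_sheet(n_per_group = 1))
  co <- simulate_cohort(cfg)
  smp <- co$metadata[1, ]
  p <- co$pileups[[smp$sample_id]]
  cnt <- base_counts(p)
  h <- co$truth$het_sites[co$truth$het_sites$pig_id == smp$pig_id, ]
  idx <- match(paste(h$chrom, h$pos), paste(p$sites$chrom, p$sites$pos))
  af <- cnt[cbind(idx, match(h$alt, c("A","C","G","T")))] / rowSums(cnt[idx, ])
  imp <- h$gene_id %in% co$panel$gene_id[co$panel$imprinted]
  ks <- suppressWarnings(stats::ks.test(af[imp], af[!imp]))
  expect_gt(ks$p.value, 0.01)
})

test_that("downstream imprinted SNP frequency is non-decreasing in leakage", {
  means <- vapply(c(0, 0.1, 0.25, 0.4, 0.5), function(L) {
    cfg <- sim_config(seed = 13, n_loci = 40, n_neighbours_per_locus = 0,
                      transcript_length_bp = 2000, mean_coverage = 120,
                      leakage_by_group = c(control = L, autologous = L,
                                           heterologous = L),
                      samples = sample_sheet(n_per_group = 1))
    co <- simulate_cohort(cfg)
    calls <- lapply(co$pileups, call_sample)
    summ <- summarize_cohort(calls, co$panel, co$read_totals,
                             analysis_params(min_transcript_reads = 0))
    mean(summ$snp_freq_per_kb[summ$imprinted])
  }, numeric(1))
  # wide spacing below the VAF window, near-ties inside it: allow small noise
  expect_true(all(diff(means) > -0.05))
  expect_gt(means[3], means[2] + 0.5)   # 0.1 -> 0.25 crosses the 20% bound
  expect_lt(means[1], 0.1)
})

test_that("the low-quality read fraction feeds the caller's mask", {
  cfg <- small_cfg(low_qual_read_fraction = 0.4, low_qual_value = 10)
  co <- simulate_cohort(cfg)
  p <- co$pileups[[1]]
  expect_setequal(unique(p$bq$qual), c(10L, 35L))
  masked <- base_counts(p, min_qual = 20)
  full <- base_counts(p, min_qual = 0)
  expect_true(sum(masked) < sum(full))
  # roughly the configured fraction is masked
  expect_lt(abs(sum(masked) / sum(full) - 0.6), 0.02)
})

test_that("config validation rejects bad leakage and empty panels", {
  expect_error(sim_config(leakage_by_group = c(control = 0.6,
                                               autologous = 0,
                                               heterologous = 0)),
               "leakage")
  expect_error(sim_config(leakage_by_group = c(control = 0)), "leakage")
  cfg <- small_cfg()
  expect_error(simulate_cohort(cfg, panel = cfg_panel <- local({
    p <- synthetic_panel(cfg)$models[0, ]
    class(p) <- c("transcript_models", "data.frame")
    p
  })), "empty")
})
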