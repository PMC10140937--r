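# Allele-specific read-pileup simulator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# cohort of pigs in three groups (control / autologous / heterologous mtDNA
# supplementation), a panel of imprinted genes plus 2 Mb neighbour genes,
# heterozygous exonic SNPs placed per pig by a Poisson process, and per-site
# read counts in which imprinted genes express (almost) only one parental
# allele.  "Leakage" L is the fraction of an imprinted gene's transcripts
# that originate from the nominally silenced allele: L = 0 is strict
# imprinting, L = 0.5 is indistinguishable from bi-allelic expression.

SIM_GROUPS <- c("control", "autologous", "heterologous")

#' Build the default cohort sample sheet
#'
#' Three pigs per group, sexes alternating within group so both sexes are
#' represented, one sample per pig and tissue.
#'
#' @param n_per_group pigs per group.
#' @param groups group labels.
#' @param tissues tissue labels (one sample per pig per tissue).
#' @return data frame with columns `sample_id`, `pig_id`, `group`, `sex`,
#'   `tissue`.
#' @export
sample_sheet <- function(n_per_group = 3, groups = SIM_GROUPS,
                         tissues = "brain") {
  pigs <- expand.grid(rep = seq_len(n_per_group), group = groups,
                      stringsAsFactors = FALSE)
  pigs$pig_id <- sprintf("pig_%s_%d", substr(pigs$group, 1, 4), pigs$rep)
  pigs$sex <- c("F", "M")[(seq_len(nrow(pigs)) - 1L) %% 2L + 1L]
  out <- do.call(rbind, lapply(tissues, function(ts) {
    data.frame(sample_id = paste0(pigs$pig_id, "_", ts),
               pig_id = pigs$pig_id, group = pigs$group, sex = pigs$sex,
               tissue = ts, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Defaults describe the cohort the package is designed around: 9 pigs
#' (3 groups x 3), a panel of 8 imprinted loci each with 10 neighbour genes,
#' 2 kb transcripts, 2 heterozygous SNPs per kb, 200x mean coverage with mild
#' negative-binomial overdispersion, 0.2% per-base sequencing error, and
#' strict imprinting in controls with substantial leakage (L = 0.35) in both
#' mtDNA-supplemented groups -- i.e. the loss-of-imprinting scenario the
#' statistic is meant to detect.
#'
#' @param seed integer; the single source of randomness for the whole cohort.
#' @param n_loci number of imprinted loci (one anchor gene each).
#' @param n_neighbours_per_locus non-imprinted genes placed within 2 Mb of
#'   each anchor.
#' @param het_snp_density_per_kb expected heterozygous SNPs per kb of
#'   transcript, per pig.
#' @param transcript_length_bp exonic length of every simulated gene.
#' @param mean_coverage mean per-site read depth.
#' @param depth_dispersion negative-binomial dispersion of depth
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson depth.
#' @param base_error_rate per-read probability of a substitution error,
#'   uniform over the three other bases.
#' @param base_quality_mean Phred quality assigned to ordinary reads.
#' @param low_qual_read_fraction fraction of reads assigned
#'   `low_qual_value` instead (exercises the caller's quality mask).
#' @param low_qual_value Phred quality of low-quality reads.
#' @param leakage_by_group named numeric, fraction (in \[0, 0.5\]) of an
#'   imprinted gene's reads drawn from the silenced allele, per group.
#' @param samples sample sheet as from [sample_sheet()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 8L,
                       n_neighbours_per_locus = 10L,
                       het_snp_density_per_kb = 2,
                       transcript_length_bp = 2000L,
                       mean_coverage = 200,
                       depth_dispersion = 0.1,
                       base_error_rate = 0.002,
                       base_quality_mean = 35L,
                       low_qual_read_fraction = 0,
                       low_qual_value = 10L,
                       leakage_by_group = c(control = 0,
                                            autologous = 0.35,
                                            heterologous = 0.35),
                       samples = sample_sheet()) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              n_neighbours_per_locus = as.integer(n_neighbours_per_locus),
              het_snp_density_per_kb = het_snp_density_per_kb,
              transcript_length_bp = as.integer(transcript_length_bp),
              mean_coverage = mean_coverage,
              depth_dispersion = depth_dispersion,
              base_error_rate = base_error_rate,
              base_quality_mean = as.integer(base_quality_mean),
              low_qual_read_fraction = low_qual_read_fraction,
              low_qual_value = as.integer(low_qual_value),
              leakage_by_group = leakage_by_group,
              samples = samples)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$seed)) stopf("seed must be a non-negative integer")
  if (!is_count(cfg$n_loci, min = 1)) stopf("n_loci must be >= 1")
  if (!is_count(cfg$n_neighbours_per_locus))
    stopf("n_neighbours_per_locus must be a non-negative integer")
  if (!is_number(cfg$het_snp_density_per_kb, min = 0))
    stopf("het_snp_density_per_kb must be >= 0")
  if (!is_count(cfg$transcript_length_bp, min = 1))
    stopf("transcript_length_bp must be a positive integer")
  if (!is_number(cfg$mean_coverage, min = 0))
    stopf("mean_coverage must be >= 0")
  if (!is_number(cfg$depth_dispersion, min = 0))
    stopf("depth_dispersion must be >= 0")
  if (!is_number(cfg$base_error_rate, min = 0, max = 0.999))
    stopf("base_error_rate must be in [0, 1)")
  if (!is_number(cfg$low_qual_read_fraction, min = 0, max = 1))
    stopf("low_qual_read_fraction must be in [0, 1]")
  lk <- cfg$leakage_by_group
  if (!all(SIM_GROUPS %in% names(lk)))
    stopf("leakage_by_group must name groups: %s",
          paste(SIM_GROUPS, collapse = ", "))
  if (any(lk < 0 | lk > 0.5))
    stopf("leakage values must lie in [0, 0.5]")
  s <- cfg$samples
  need <- c("sample_id", "pig_id", "group", "sex", "tissue")
  if (!all(need %in% names(s)))
    stopf("samples must have columns: %s", paste(need, collapse = ", "))
  if (!all(s$group %in% SIM_GROUPS))
    stopf("sample group outside {%s}", paste(SIM_GROUPS, collapse = ", "))
  if (!all(s$sex %in% c("M", "F"))) stopf("sample sex outside {M, F}")
  if (anyDuplicated(s$sample_id)) stopf("duplicate sample_id")
  invisible(TRUE)
}

#' Deterministic synthetic gene panel for the simulator
#'
#' Places each imprinted anchor gene at 5 Mb on its own chromosome with
#' `n_neighbours_per_locus` non-imprinted single-exon genes alternating up-
#' and downstream at 180 kb spacing (shrunk when needed so every neighbour
#' stays inside the 2 Mb locus window).  The layout is a pure function of
#' the configuration (no randomness), so panel geometry never interacts
#' with the cohort seed.
#'
#' @param config a [sim_config()].
#' @return list with `models` (a [transcript_models()] table) and
#'   `imprinted_ids`.
#' @export
synthetic_panel <- function(config) {
  len <- config$transcript_length_bp
  anchor_start <- 5e6
  half <- max(1L, ceiling(config$n_neighbours_per_locus / 2))
  spacing <- min(180000, floor(1.9e6 / half))
  rows <- list()
  imprinted_ids <- character(0)
  for (i in seq_len(config$n_loci)) {
    chrom <- sprintf("chr%d", i)
    gid <- sprintf("IMP%02d", i)
    imprinted_ids <- c(imprinted_ids, gid)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = chrom,
      strand = "+", start = anchor_start, stringsAsFactors = FALSE)
    for (k in seq_len(config$n_neighbours_per_locus)) {
      side <- if (k %% 2L == 1L) 1 else -1
      off <- spacing * ceiling(k / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("NBR%02d_%02d", i, k),
        transcript_id = sprintf("NBR%02d_%02d.t1", i, k), chrom = chrom,
        strand = if (side > 0) "+" else "-",
        start = anchor_start + side * off, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$exons <- lapply(df$start, function(s) cbind(s, s + len - 1L))
  df$start <- NULL
  list(models = transcript_models(df), imprinted_ids = imprinted_ids)
}

# For each base index, the other three base indices in ascending order.
OTHER_BASES <- t(vapply(1:4, function(r) setdiff(1:4, r), integer(3)))

# Split `n` error reads uniformly over three target bases via successive
# binomials; returns an n x 3 integer matrix.
split3 <- function(n) {
  x1 <- rbinom(length(n), n, 1 / 3)
  x2 <- rbinom(length(n), n - x1, 1 / 2)
  cbind(x1, x2, n - x1 - x2)
}

#' Simulate an allele-specific RNA-seq pileup cohort
#'
#' For every sample and panel gene, heterozygous sites are placed over exonic
#' positions by a Poisson process at `het_snp_density_per_kb` (sites and
#' their phase are properties of the pig, shared by all of a pig's samples);
#' per-site depth is negative-binomial around `mean_coverage`; at a
#' heterozygous site the expected alt-read fraction is 0.5 for a bi-allelic
#' gene and L or 1 - L for an imprinted gene, depending on whether the alt
#' allele sits on the silenced haplotype (Bernoulli(0.5) per site per pig);
#' every read is substituted to a uniformly chosen other base with
#' probability `base_error_rate`.  All exonic positions are emitted,
#' homozygous ones as reference plus errors.
#'
#' Identical configurations (including the seed) give byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param panel a `transcript_models` panel with `imprinted` labels; default
#'   builds one from [synthetic_panel()] + [build_panel()].
#' @param out_dir if non-`NULL`, per-sample mpileup files plus read-total,
#'   truth, metadata and panel TSVs are written there.
#' @return object of class `sim_cohort`: list with `pileups` (named list of
#'   [pileup()]s), `read_totals` (sample_id, gene_id, total_reads), `truth`
#'   (`gene_sample` and `het_sites` data frames), `metadata`, `panel`,
#'   `config`, and `files` (paths, when written).
#' @export
simulate_cohort <- function(config, panel = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (is.null(panel)) {
    sp <- synthetic_panel(config)
    panel <- build_panel(sp$models, sp$imprinted_ids)$panel
  }
  if (!nrow(panel)) stopf("panel is empty")
  samples <- config$samples
  pigs <- unique(samples$pig_id)

  # site scaffold: every exonic position of every panel gene, panel order
  gene_pos <- lapply(panel$exons, function(e)
    unlist(lapply(seq_len(nrow(e)), function(i) e[i, 1L]:e[i, 2L])))
  n_per_gene <- lengths(gene_pos)
  site_gene <- rep.int(seq_len(nrow(panel)), n_per_gene)
  site_pos <- unlist(gene_pos)
  site_chrom <- panel$chrom[site_gene]
  n_sites <- length(site_pos)
  len_kb <- n_per_gene / 1000

  with_seed(config$seed, {
    ref_idx <- sample.int(4L, n_sites, replace = TRUE)   # shared reference

    # per-pig heterozygous sites and phase
    het <- lapply(pigs, function(pg) {
      n_het <- rpois(nrow(panel), config$het_snp_density_per_kb * len_kb)
      n_het <- pmin(n_het, n_per_gene)
      idx <- unlist(lapply(seq_len(nrow(panel)), function(g) {
        if (n_het[g] == 0L) return(integer(0))
        offset <- if (g == 1L) 0L else sum(n_per_gene[seq_len(g - 1L)])
        offset + sort(sample.int(n_per_gene[g], n_het[g]))
      }))
      alt_shift <- sample.int(3L, length(idx), replace = TRUE)
      alt_idx <- (ref_idx[idx] - 1L + alt_shift) %% 4L + 1L
      on_silenced <- runif(length(idx)) < 0.5
      list(idx = idx, alt_idx = alt_idx, on_silenced = on_silenced)
    })
    names(het) <- pigs

    pileups <- vector("list", nrow(samples))
    names(pileups) <- samples$sample_id
    totals <- matrix(0L, nrow(samples), nrow(panel),
                     dimnames = list(samples$sample_id, panel$gene_id))

    for (si in seq_len(nrow(samples))) {
      smp <- samples[si, ]
      L <- unname(config$leakage_by_group[[smp$group]])
      h <- het[[smp$pig_id]]
      alt_idx <- rep.int(0L, n_sites)
      alt_idx[h$idx] <- h$alt_idx
      p_alt <- numeric(n_sites)
      imp_site <- panel$imprinted[site_gene]
      p_alt[h$idx] <- ifelse(imp_site[h$idx],
                             ifelse(h$on_silenced, L, 1 - L), 0.5)
      depth <- if (config$depth_dispersion > 0)
        rnbinom(n_sites, size = 1 / config$depth_dispersion,
                mu = config$mean_coverage)
      else rpois(n_sites, config$mean_coverage)

      n_alt <- rbinom(n_sites, depth, p_alt)
      n_ref <- depth - n_alt
      e <- config$base_error_rate
      # counts held transposed (4 x n_sites) so the non-zero scan below comes
      # out site-major and the pileup needs no sort
      counts <- matrix(0L, 4L, n_sites)
      sq <- seq_len(n_sites)
      li <- function(base, site) (site - 1L) * 4L + base
      if (e > 0) {
        err_ref <- rbinom(n_sites, n_ref, e)
        err_alt <- rbinom(n_sites, n_alt, e)
        counts[li(ref_idx, sq)] <- n_ref - err_ref
        er3 <- split3(err_ref)
        tgt <- OTHER_BASES[ref_idx, , drop = FALSE]
        for (k in 1:3) {
          ii <- li(tgt[, k], sq)
          counts[ii] <- counts[ii] + er3[, k]
        }
        ia <- which(alt_idx > 0L)
        if (length(ia)) {
          ii <- li(alt_idx[ia], ia)
          counts[ii] <- counts[ii] + n_alt[ia] - err_alt[ia]
          ea3 <- split3(err_alt[ia])
          tgta <- OTHER_BASES[alt_idx[ia], , drop = FALSE]
          for (k in 1:3) {
            ii <- li(tgta[, k], ia)
            counts[ii] <- counts[ii] + ea3[, k]
          }
        }
      } else {
        counts[li(ref_idx, sq)] <- n_ref
        ia <- which(alt_idx > 0L & n_alt > 0L)
        ii <- li(alt_idx[ia], ia)
        counts[ii] <- counts[ii] + n_alt[ia]
      }

      # long (site, base, qual, count) table with optional low-quality split
      nz <- which(counts > 0L)
      b_i <- (nz - 1L) %% 4L + 1L
      s_i <- (nz - 1L) %/% 4L + 1L
      cn <- counts[nz]
      f <- config$low_qual_read_fraction
      if (f > 0) {
        n_low <- rbinom(length(cn), cn, f)
        bq <- rbind(
          data.frame(site = s_i, base = BASES[b_i],
                     qual = config$base_quality_mean, count = cn - n_low),
          data.frame(site = s_i, base = BASES[b_i],
                     qual = config$low_qual_value, count = n_low))
        bq <- bq[bq$count > 0L, , drop = FALSE]
      } else {
        bq <- data.frame(site = s_i, base = BASES[b_i],
                         qual = config$base_quality_mean, count = cn)
      }
      sites <- data.frame(chrom = site_chrom, pos = site_pos,
                          ref = BASES[ref_idx], raw_depth = depth,
                          stringsAsFactors = FALSE)
      pileups[[si]] <- pileup(sites, bq)
      totals[si, ] <- as.integer(rowsum(depth, site_gene))
    }

    read_totals <- data.frame(
      sample_id = rep(samples$sample_id, each = nrow(panel)),
      gene_id = rep(panel$gene_id, nrow(samples)),
      total_reads = as.integer(t(totals)), stringsAsFactors = FALSE)

    het_sites <- do.call(rbind, lapply(pigs, function(pg) {
      h <- het[[pg]]
      if (!length(h$idx))
        return(NULL)
      data.frame(pig_id = pg, gene_id = panel$gene_id[site_gene[h$idx]],
                 chrom = site_chrom[h$idx], pos = site_pos[h$idx],
                 ref = BASES[ref_idx[h$idx]], alt = BASES[h$alt_idx],
                 alt_on_silenced_allele = h$on_silenced,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(het_sites))
      het_sites <- data.frame(pig_id = character(), gene_id = character(),
                              chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              alt_on_silenced_allele = logical())

    gene_sample <- data.frame(
      sample_id = rep(samples$sample_id, each = nrow(panel)),
      gene_id = rep(panel$gene_id, nrow(samples)),
      expression_mode = rep(ifelse(panel$imprinted, "monoallelic",
                                   "biallelic"), nrow(samples)),
      leakage = rep(vapply(samples$group, function(g)
        unname(config$leakage_by_group[[g]]), numeric(1)),
        each = nrow(panel)) *
        rep(as.numeric(panel$imprinted), nrow(samples)),
      total_reads = as.integer(t(totals)), stringsAsFactors = FALSE)

    out <- structure(list(pileups = pileups, read_totals = read_totals,
                          truth = list(gene_sample = gene_sample,
                                       het_sites = het_sites),
                          metadata = samples, panel = panel,
                          config = config, files = NULL),
                     class = "sim_cohort")
    if (!is.null(out_dir)) out <- write_cohort(out, out_dir)
    out
  })
}

#' Write a simulated cohort to disk
#'
#' @param cohort a `sim_cohort`.
#' @param out_dir output directory (created if needed).
#' @return the cohort with `files` filled in, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mp <- setNames(file.path(out_dir, paste0(names(cohort$pileups),
                                           ".mpileup")),
                 names(cohort$pileups))
  for (s in names(cohort$pileups)) write_mpileup(cohort$pileups[[s]], mp[[s]])
  files <- list(
    mpileup = mp,
    read_totals = file.path(out_dir, "read_totals.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    panel = file.path(out_dir, "panel.tsv"),
    truth_gene_sample = file.path(out_dir, "truth_gene_sample.tsv"),
    truth_het_sites = file.path(out_dir, "truth_het_sites.tsv"),
    config = file.path(out_dir, "sim_config.yaml"))
  write_tsv(cohort$read_totals, files$read_totals)
  write_tsv(cohort$metadata, files$metadata)
  write_panel(cohort$panel, files$panel)
  write_tsv(cohort$truth$gene_sample, files$truth_gene_sample)
  write_tsv(cohort$truth$het_sites, files$truth_het_sites)
  cfg <- unclass(cohort$config)
  cfg$samples <- NULL
  cfg$leakage_by_group <- as.list(cfg$leakage_by_group)
  yaml::write_yaml(cfg, files$config)
  cohort$files <- files
  invisible(cohort)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d samples, %d panel genes (%d imprinted), seed %d\n",
    length(x$pileups), nrow(x$panel), sum(x$panel$imprinted),
    x$config$seed))
  invisible(x)
}
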