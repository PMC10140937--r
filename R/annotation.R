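# Gene-model loading and construction of the imprinted-locus analysis panel.
#
# A "transcript model" is one representative transcript per gene: its exon
# intervals (1-based, closed), the exonic length that becomes the denominator
# of the SNP-frequency statistic, an imprinting label, and the imprinted locus
# (if any) the gene belongs to.

#' Construct a transcript-model table
#'
#' Validates and classes a data frame of representative transcripts, one row
#' per gene.  Exons are stored as a list column of two-column integer matrices
#' (start, end), 1-based closed, sorted and non-overlapping;
#' `transcript_length_bp` must equal the summed exon widths.
#'
#' @param df data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`+`/`-`), `exons` (list of matrices), and optionally
#'   `imprinted` (logical, default `FALSE`) and `locus_id` (character,
#'   default `""`).
#' @return a `transcript_models` data frame with derived columns `start`,
#'   `end`, `tss`, `transcript_length_bp`, ordered by
#'   (`chrom`, `tss`, `gene_id`).
#' @export
transcript_models <- function(df) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "exons")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene_id: %s",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  df$exons <- lapply(df$exons, function(ex) {
    ex <- matrix(as.integer(ex), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    if (any(ex[, 2L] < ex[, 1L])) stopf("exon with end < start")
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      stopf("overlapping exons within one transcript")
    ex
  })
  df$start <- vapply(df$exons, function(e) e[1L, 1L], integer(1))
  df$end <- vapply(df$exons, function(e) e[nrow(e), 2L], integer(1))
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$transcript_length_bp <-
    vapply(df$exons, function(e) sum(e[, 2L] - e[, 1L] + 1L), integer(1))
  if (is.null(df$imprinted)) df$imprinted <- FALSE
  if (is.null(df$locus_id)) df$locus_id <- ""
  df <- df[order(df$chrom, df$tss, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

# Field-count pre-scan so malformed records are reported with a line number
# before the file is handed to rtracklayer.
check_field_counts <- function(path, n_fields, skip_prefix = "#") {
  lines <- readLines(path)
  body <- !startsWith(lines, skip_prefix) & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(nf != n_fields)
  if (length(bad))
    stopf("%s: malformed record at line %d (%d fields, expected %d)",
          path, which(body)[bad[1L]], nf[bad[1L]], n_fields)
  invisible(TRUE)
}

strip_id_prefix <- function(x) sub("^(gene|transcript|mRNA):", "", x)

load_gff3_transcripts <- function(path) {
  check_field_counts(path, 9L)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (!length(ex)) stopf("%s: no exon features found", path)
  parent <- vapply(as.list(ex$Parent), function(p) {
    if (!length(p)) NA_character_ else strip_id_prefix(p[[1L]])
  }, character(1))
  if (anyNA(parent)) stopf("%s: exon without Parent attribute", path)
  # transcript -> gene map from the transcript-level features
  tx_feats <- gr[type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")]
  tx2gene <- character(0)
  if (length(tx_feats)) {
    txid <- strip_id_prefix(as.character(tx_feats$ID))
    txgene <- vapply(as.list(tx_feats$Parent), function(p) {
      if (!length(p)) NA_character_ else strip_id_prefix(p[[1L]])
    }, character(1))
    tx2gene <- setNames(txgene, txid)
  }
  split_idx <- split(seq_along(ex), parent)
  rows <- lapply(names(split_idx), function(tx) {
    i <- split_idx[[tx]]
    gene <- tx2gene[tx]
    if (is.na(gene) || !length(gene)) gene <- tx
    list(gene_id = unname(gene), transcript_id = tx,
         chrom = as.character(GenomicRanges::seqnames(ex))[i[1L]],
         strand = as.character(GenomicRanges::strand(ex))[i[1L]],
         exons = cbind(GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i]))
  })
  rows
}

load_bed12_transcripts <- function(path) {
  check_field_counts(path, 12L, skip_prefix = "track")
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stopf("%s: not BED12 (no block columns)", path)
  lapply(seq_along(gr), function(i) {
    blk <- gr$blocks[[i]]            # transcript-relative, 1-based
    name <- gr$name[i]
    # "gene|transcript" names carry both ids; otherwise the name serves as both
    parts <- strsplit(name, "|", fixed = TRUE)[[1L]]
    gene <- parts[1L]
    tx <- if (length(parts) > 1L) parts[2L] else name
    off <- GenomicRanges::start(gr)[i] - 1L
    list(gene_id = gene, transcript_id = tx,
         chrom = as.character(GenomicRanges::seqnames(gr))[i],
         strand = as.character(GenomicRanges::strand(gr))[i],
         exons = cbind(IRanges::start(blk) + off, IRanges::end(blk) + off))
  })
}

parse_exon_spec <- function(spec, line = NA) {
  parts <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  se <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(lengths(se) != 3L))
    stopf("malformed exon spec%s: %s",
          if (is.na(line)) "" else sprintf(" at line %d", line), spec)
  cbind(as.integer(vapply(se, `[`, "", 2L)),
        as.integer(vapply(se, `[`, "", 3L)))
}

load_tsv_transcripts <- function(path) {
  check_field_counts_tsv <- function() {
    lines <- readLines(path)
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    bad <- which(nf != nf[1L])
    if (length(bad))
      stopf("%s: malformed record at line %d (%d fields, expected %d)",
            path, bad[1L], nf[bad[1L]], nf[1L])
  }
  check_field_counts_tsv()
  df <- read_tsv(path)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "exons")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    list(gene_id = df$gene_id[i], transcript_id = df$transcript_id[i],
         chrom = as.character(df$chrom[i]), strand = df$strand[i],
         exons = parse_exon_spec(df$exons[i], line = i + 1L),
         imprinted = if ("imprinted" %in% names(df))
           as.logical(df$imprinted[i]) else FALSE)
  })
}

#' Load gene models and pick one representative transcript per gene
#'
#' Reads transcript structures from GFF3 (exon features grouped by their
#' transcript `Parent`), BED12 (one transcript per line; block coordinates
#' converted to 1-based closed genomic intervals), or a plain TSV
#' (`gene_id`, `transcript_id`, `chrom`, `strand`, `exons` as
#' `"start-end;start-end"`, optional `imprinted` flag).  When a gene has
#' several annotated transcripts the longest by exonic length is kept, ties
#' broken by lexicographically smallest `transcript_id`, so the selection is
#' deterministic under input reordering.
#'
#' @param path annotation file.
#' @param format one of `"gff3"`, `"bed12"`, `"tsv"`; default guessed from
#'   the file extension.
#' @return a [transcript_models()] table ordered by (`chrom`, `tss`,
#'   `gene_id`).
#' @export
load_gene_models <- function(path,
                             format = c("auto", "gff3", "bed12", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed12", "tsv")
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  rows <- switch(format,
    gff3 = load_gff3_transcripts(path),
    bed12 = load_bed12_transcripts(path),
    tsv = load_tsv_transcripts(path))
  txid <- vapply(rows, `[[`, "", "transcript_id")
  if (anyDuplicated(txid))
    stopf("duplicate transcript_id: %s",
          paste(unique(txid[duplicated(txid)]), collapse = ", "))
  gene <- vapply(rows, `[[`, "", "gene_id")
  len <- vapply(rows, function(r) sum(r$exons[, 2L] - r$exons[, 1L] + 1L),
                numeric(1))
  # representative = longest transcript, ties to smallest transcript_id
  keep <- vapply(split(seq_along(rows), gene), function(i) {
    i <- i[len[i] == max(len[i])]
    i[order(txid[i])][1L]
  }, integer(1))
  rows <- rows[keep]
  df <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$exons <- lapply(rows, `[[`, "exons")
  imp <- vapply(rows, function(r) isTRUE(r$imprinted), logical(1))
  df$imprinted <- imp
  transcript_models(df)
}

#' Build the analysis panel: imprinted loci plus 2 Mb neighbour genes
#'
#' Each imprinted anchor gene defines a locus window spanning its transcript
#' plus 2 Mb of flanking sequence on each side (clipped at position 1).
#' Windows that overlap on the same chromosome are merged into a single locus,
#' mirroring loci that contain several imprinted genes.  The panel consists of
#' the imprinted genes plus every gene whose transcript span intersects a
#' locus window; each panel gene is labelled `imprinted` and assigned the
#' `locus_id` of the (leftmost) window it intersects.
#'
#' @param models a [transcript_models()] table.
#' @param imprinted_ids character vector of imprinted anchor `gene_id`s; must
#'   all be present in `models`.
#' @param flank_bp window half-width in bp (default 2e6).
#' @return list with `loci` (data frame: `locus_id`, `chrom`,
#'   `anchor_gene_ids`, `window_start`, `window_end`) and `panel`
#'   (a `transcript_models` table restricted to panel genes, with
#'   `imprinted` and `locus_id` filled in).
#' @export
build_panel <- function(models, imprinted_ids, flank_bp = 2e6) {
  stopifnot(inherits(models, "transcript_models"))
  imprinted_ids <- unique(as.character(imprinted_ids))
  miss <- setdiff(imprinted_ids, models$gene_id)
  if (length(miss))
    stopf("imprinted gene ids not found in models: %s",
          paste(miss, collapse = ", "))
  anchors <- models[models$gene_id %in% imprinted_ids, , drop = FALSE]
  win <- data.frame(chrom = anchors$chrom,
                    start = pmax(1, anchors$start - flank_bp),
                    end = anchors$end + flank_bp,
                    anchor = anchors$gene_id,
                    stringsAsFactors = FALSE)
  win <- win[order(win$chrom, win$start, win$anchor), , drop = FALSE]
  # merge overlapping windows per chromosome
  gr <- GenomicRanges::GRanges(win$chrom,
                               IRanges::IRanges(win$start, win$end))
  red <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    window_start = GenomicRanges::start(red),
    window_end = GenomicRanges::end(red),
    anchor_gene_ids = vapply(seq_along(red), function(k)
      paste(win$anchor[grp == k], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  loci$locus_id <- sprintf("%s:%s", loci$chrom,
                           vapply(strsplit(loci$anchor_gene_ids, ","),
                                  `[`, "", 1L))
  loci <- loci[order(loci$chrom, loci$window_start), , drop = FALSE]
  rownames(loci) <- NULL

  span <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(models$start, models$end))
  wgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$window_start,
                                                 loci$window_end))
  ov <- GenomicRanges::findOverlaps(span, wgr, select = "first")
  in_panel <- !is.na(ov) | models$gene_id %in% imprinted_ids
  panel <- models[in_panel, , drop = FALSE]
  panel$locus_id <- loci$locus_id[ov[in_panel]]
  panel$locus_id[is.na(panel$locus_id)] <- ""
  panel$imprinted <- panel$gene_id %in% imprinted_ids
  rownames(panel) <- NULL
  class(panel) <- c("transcript_models", "data.frame")
  list(loci = loci[, c("locus_id", "chrom", "anchor_gene_ids",
                       "window_start", "window_end")],
       panel = panel)
}

#' Write / read the panel summary TSV
#'
#' One row per panel gene: `gene_id`, `locus_id`, `imprinted`,
#' `transcript_length_bp`.
#'
#' @param panel a `transcript_models` table (typically `build_panel()$panel`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write_tsv(panel[, c("gene_id", "locus_id", "imprinted",
                      "transcript_length_bp")], path)
}
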