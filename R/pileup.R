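# Pileup container and samtools-mpileup text I/O.
#
# A pileup holds one row per genomic site plus a long table of
# (site, base, quality, count) read aggregates.  Aggregating by quality keeps
# the representation compact at high depth while preserving everything the
# caller needs: per-base counts under any quality mask and exact mean
# qualities.

PILEUP_BASE_CODE <- local({
  m <- integer(128)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m
})

#' Construct a pileup object
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`
#'   (single base), `raw_depth`.
#' @param bq data frame with columns `site` (row index into `sites`), `base`
#'   (one of A/C/G/T), `qual` (Phred integer), `count` (positive integer).
#' @return object of class `pileup`.
#' @export
pileup <- function(sites, bq) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(sites)),
            all(c("site", "base", "qual", "count") %in% names(bq)))
  if (nrow(sites) && any(sites$pos < 1L)) stopf("positions must be >= 1")
  if (is.null(sites$raw_depth)) {
    sites$raw_depth <- integer(nrow(sites))
    if (nrow(bq)) {
      rd <- rowsum(bq$count, bq$site)
      sites$raw_depth[as.integer(rownames(rd))] <- as.integer(rd)
    }
  }
  bcode <- match(bq$base, BASES)
  key <- (bq$site * 4L + bcode) * 128L + bq$qual %% 128L
  if (is.unsorted(key))
    bq <- bq[order(key, method = "radix"), , drop = FALSE]
  rownames(sites) <- NULL
  rownames(bq) <- NULL
  structure(list(sites = sites, bq = bq), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d sites, %d reads\n",
              nrow(x$sites), sum(x$bq$count)))
  invisible(x)
}

#' @export
length.pileup <- function(x) nrow(x$sites)

#' Per-site base counts under a quality mask
#'
#' @param p a [pileup()].
#' @param min_qual bases with Phred quality below this are excluded.
#' @return integer matrix, one row per site, columns A/C/G/T.
#' @export
base_counts <- function(p, min_qual = 0L) {
  n <- nrow(p$sites)
  m <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  keep <- p$bq$qual >= min_qual
  if (any(keep)) {
    b <- match(p$bq$base[keep], BASES)
    key <- (b - 1L) * n + p$bq$site[keep]   # column-major linear index
    w <- p$bq$count[keep]
    o <- order(key, method = "radix")
    key <- key[o]
    w <- w[o]
    # name-free run aggregation over the sorted keys
    last <- c(key[-1L] != key[-length(key)], TRUE)
    cs <- cumsum(w)[last]
    m[key[last]] <- as.integer(diff(c(0, cs)))
  }
  m
}

#' Build a single pileup site from explicit reads
#'
#' Convenience constructor used for worked examples and site-level tests.
#'
#' @param chrom,pos,ref site identity.
#' @param bases character vector of read bases (one element per read).
#' @param quals integer Phred qualities, one per read.
#' @return a one-site [pileup()].
#' @export
pileup_site <- function(chrom, pos, ref, bases, quals) {
  stopifnot(length(bases) == length(quals))
  df <- data.frame(site = 1L, base = toupper(bases), qual = as.integer(quals))
  df <- df[df$base %in% BASES, , drop = FALSE]
  agg <- if (nrow(df)) {
    a <- aggregate(list(count = rep(1L, nrow(df))),
                   by = df[c("site", "base", "qual")], FUN = sum)
    a
  } else data.frame(site = integer(), base = character(),
                    qual = integer(), count = integer())
  pileup(data.frame(chrom = chrom, pos = as.integer(pos),
                    ref = toupper(ref), raw_depth = length(bases),
                    stringsAsFactors = FALSE),
         agg)
}

strip_indel_tokens <- function(b) {
  # '^' + mapping-quality char (start marker) and '$' (end marker) consume no
  # quality character and are dropped; likewise indel blocks "[+-]<n><seq>".
  b <- gsub("\\^.", "", b)
  b <- gsub("$", "", b, fixed = TRUE)
  if (any(grepl("[+-][0-9]", b))) {
    ns <- unique(unlist(regmatches(b, gregexpr("(?<=[+-])[0-9]+", b,
                                               perl = TRUE))))
    for (n in ns[order(-as.integer(ns))]) {
      b <- gsub(sprintf("[+-]%s[ACGTNacgtn*#]{%s}", n, n), "", b)
    }
  }
  b
}

#' Parse samtools mpileup text into a pileup
#'
#' Accepts the 6-column single-sample format (chrom, 1-based position,
#' reference base, depth, read-bases string, Phred+33 quality string).
#' In the read-bases string `.`/`,` denote the reference base, letters a
#' non-reference base (case marks strand, ignored here), `^x` / `$` read
#' start/end markers, and `+n<seq>` / `-n<seq>` indel blocks; markers and
#' indels are stripped, and `*`, `#`, `<`, `>` and `N` placeholders are
#' dropped from the base counts while still consuming their quality
#' character.  Parsing is strict: a record with the wrong column count or a
#' read-bases/quality length mismatch raises an error naming the line.
#'
#' @param path file to read (ignored when `text` given).
#' @param text optional character vector of mpileup lines.
#' @return a [pileup()].
#' @export
parse_mpileup <- function(path = NULL, text = NULL) {
  src <- if (is.null(text)) path else "<text>"
  if (is.null(text)) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    text <- readLines(path)
  }
  text <- text[nzchar(text)]
  n <- length(text)
  empty <- pileup(data.frame(chrom = character(), pos = integer(),
                             ref = character(), raw_depth = integer(),
                             stringsAsFactors = FALSE),
                  data.frame(site = integer(), base = character(),
                             qual = integer(), count = integer()))
  if (!n) return(empty)
  f <- strsplit(text, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 6L)) {
    i <- which(nf != 6L)[1L]
    stopf("%s: parse error at line %d: %d columns, expected 6", src, i, nf[i])
  }
  fm <- matrix(unlist(f), nrow = 6L)
  chrom <- fm[1L, ]
  pos <- as.integer(fm[2L, ])
  if (anyNA(pos))
    stopf("%s: parse error at line %d: non-numeric position",
          src, which(is.na(pos))[1L])
  ref <- toupper(fm[3L, ])
  depth <- as.integer(fm[4L, ])
  b <- fm[5L, ]
  q <- fm[6L, ]
  # depth-0 placeholder records ("0  *  *")
  zero <- depth == 0L & (b == "*" | b == "")
  b[zero] <- ""
  q[zero] <- ""
  b <- strip_indel_tokens(b)
  nb <- nchar(b)
  nq <- nchar(q)
  if (any(nb != nq)) {
    i <- which(nb != nq)[1L]
    stopf("%s: parse error at line %d: %d read bases vs %d qualities",
          src, i, nb[i], nq[i])
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref,
                      raw_depth = depth, stringsAsFactors = FALSE)
  total <- sum(nb)
  if (!total)
    return(pileup(sites, data.frame(site = integer(), base = character(),
                                    qual = integer(), count = integer())))
  bc <- utf8ToInt(paste(b, collapse = ""))
  qc <- utf8ToInt(paste(q, collapse = "")) - 33L
  line <- rep.int(seq_len(n), nb)
  # '.'/',' -> reference base; lower case -> upper case
  refb <- PILEUP_BASE_CODE[pmin(utf8ToInt(paste(ref, collapse = "")), 127L)]
  isref <- bc == 46L | bc == 44L
  low <- bc >= 97L & bc <= 122L
  bc[low] <- bc[low] - 32L
  code <- ifelse(isref, refb[line], ifelse(bc <= 127L, PILEUP_BASE_CODE[bc], 0L))
  keep <- code > 0L                     # drops *, #, <, >, N
  if (!any(keep))
    return(pileup(sites, data.frame(site = integer(), base = character(),
                                    qual = integer(), count = integer())))
  line <- line[keep]; code <- code[keep]; qual <- qc[keep]
  qlev <- sort(unique(qual))
  qi <- match(qual, qlev)
  nqv <- length(qlev)
  key <- ((line - 1L) * 4L + (code - 1L)) * nqv + qi
  cnt <- rowsum(rep.int(1L, length(key)), key)
  idx <- as.integer(rownames(cnt))
  q_i <- (idx - 1L) %% nqv + 1L
  rest <- (idx - 1L) %/% nqv
  b_i <- rest %% 4L + 1L
  s_i <- rest %/% 4L + 1L
  pileup(sites, data.frame(site = s_i, base = BASES[b_i],
                           qual = qlev[q_i], count = as.integer(cnt)))
}

#' Write a pileup as samtools mpileup text
#'
#' Emits the 6-column single-sample format.  Reads appear grouped by base and
#' quality (read order within a site is not meaningful in a pileup); the
#' reference base is written as `.` and depth equals the number of emitted
#' reads.  Sites with no reads are written as `0 * *` placeholder records.
#' Round-trips through [parse_mpileup()] losslessly on (chrom, pos, ref,
#' per-base quality-resolved counts).
#'
#' @param p a [pileup()]; sites must be sorted by (chrom, pos).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mpileup <- function(p, path) {
  stopifnot(inherits(p, "pileup"))
  s <- p$sites
  if (nrow(s) > 1L) {
    o <- order(s$chrom, s$pos)
    if (any(o != seq_len(nrow(s))))
      stopf("pileup sites are not sorted by (chrom, pos)")
  }
  if (!nrow(s)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bq <- p$bq
  bstr <- qstr <- rep.int("", nrow(s))
  if (nrow(bq)) {
    ch <- ifelse(bq$base == s$ref[bq$site], ".", bq$base)
    seg_b <- strrep(ch, bq$count)
    seg_q <- strrep(vapply(bq$qual + 33L, intToUtf8, character(1)), bq$count)
    sb <- vapply(split(seg_b, factor(bq$site, levels = seq_len(nrow(s)))),
                 paste0, character(1), collapse = "")
    sq <- vapply(split(seg_q, factor(bq$site, levels = seq_len(nrow(s)))),
                 paste0, character(1), collapse = "")
    bstr <- unname(sb)
    qstr <- unname(sq)
  }
  depth <- nchar(bstr)
  bstr[depth == 0L] <- "*"
  qstr[depth == 0L] <- "*"
  writeLines(paste(s$chrom, s$pos, s$ref, depth, bstr, qstr, sep = "\t"),
             path)
  invisible(path)
}
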