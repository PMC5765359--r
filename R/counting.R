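#' @importFrom S4Vectors queryHits subjectHits
NULL

# internal: feature table -> GRanges (1-based closed).  feats has columns
# feature_id, gene_id, kind, chrom, strand, start, end (0-based half-open).
features_to_granges <- function(feats) {
  GenomicRanges::GRanges(feats$chrom,
                         IRanges::IRanges(start = feats$start + 1L,
                                          end = feats$end),
                         strand = feats$strand)
}

# internal: strand-specific midpoint assignment of reads to features.
# Returns the feature row index for each read (NA = unassigned).  A midpoint
# falling in several same-strand features is assigned to the one whose TTS is
# nearest (deterministic; ties broken by feature order).
assign_midpoints <- function(reads, feats, tts) {
  if (nrow(reads) == 0) return(integer(0))
  mid <- (reads$start + reads$end) %/% 2          # 0-based midpoint position
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(start = mid + 1L, width = 1L),
                                strand = reads$strand)
  hits <- GenomicRanges::findOverlaps(pts, features_to_granges(feats),
                                      ignore.strand = FALSE)
  q <- queryHits(hits); s <- subjectHits(hits)
  assign <- rep(NA_integer_, nrow(reads))
  if (length(q) == 0) return(assign)
  dup <- q %in% q[duplicated(q)]
  assign[q[!dup]] <- s[!dup]
  if (any(dup)) {
    dd <- data.frame(q = q[dup], s = s[dup],
                     dist = abs(mid[q[dup]] - tts[s[dup]]))
    dd <- dd[order(dd$q, dd$dist, dd$s), ]
    dd <- dd[!duplicated(dd$q), ]
    assign[dd$q] <- dd$s
  }
  assign
}

# internal: genomic TTS coordinate per feature's gene (for tie-breaking)
gene_tts <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

# internal: build the per-scheme feature table from an annotation
scheme_features <- function(annotations, scheme) {
  g <- annotations$genes
  base <- function(kind, start, end, suffix = kind)
    data.frame(feature_id = if (identical(kind, "whole")) g$gene_id
               else paste0(g$gene_id, ":", suffix),
               gene_id = g$gene_id, kind = kind, chrom = g$chrom,
               strand = g$strand, start = start, end = end,
               stringsAsFactors = FALSE)
  if (scheme == "whole") return(base("whole", g$start, g$end))
  if (scheme == "utr_cds") {
    return(rbind(base("utr5", g$utr5_start, g$utr5_end),
                 base("cds", g$cds_start, g$cds_end),
                 base("utr3", g$utr3_start, g$utr3_end)))
  }
  if (scheme == "thirds") {
    L <- g$end - g$start
    keep <- L >= 3                       # genes shorter than 3 nt are excluded
    gk <- g[keep, , drop = FALSE]
    t <- (gk$end - gk$start) %/% 3
    plus <- gk$strand == "+"
    # thirds run in transcript orientation; the remainder goes to the last
    # (3'-most) third
    b0 <- ifelse(plus, gk$start, gk$end - t)          # third1
    e0 <- ifelse(plus, gk$start + t, gk$end)
    b1 <- ifelse(plus, gk$start + t, gk$end - 2 * t)  # third2
    e1 <- ifelse(plus, gk$start + 2 * t, gk$end - t)
    b2 <- ifelse(plus, gk$start + 2 * t, gk$start)    # third3 (+ remainder)
    e2 <- ifelse(plus, gk$end, gk$end - 2 * t)
    mk <- function(kind, s, e)
      data.frame(feature_id = paste0(gk$gene_id, ":", kind),
                 gene_id = gk$gene_id, kind = kind, chrom = gk$chrom,
                 strand = gk$strand, start = s, end = e,
                 stringsAsFactors = FALSE)
    return(rbind(mk("third1", b0, e0), mk("third2", b1, e1),
                 mk("third3", b2, e2)))
  }
  if (scheme == "introns") {
    ints <- annotations$introns
    if (nrow(ints) == 0)
      return(data.frame(feature_id = character(0), gene_id = character(0),
                        kind = character(0), chrom = character(0),
                        strand = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    ord <- order(ints$gene_id, ints$start)
    ints <- ints[ord, , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(ints)), ints$gene_id, FUN = seq_along)
    gi <- match(ints$gene_id, g$gene_id)
    return(data.frame(feature_id = paste0(ints$gene_id, ":intron", idx),
                      gene_id = ints$gene_id, kind = "intron",
                      chrom = g$chrom[gi], strand = g$strand[gi],
                      start = ints$start, end = ints$end,
                      stringsAsFactors = FALSE))
  }
  stop("unknown scheme: ", scheme)
}

# internal: normalize the reads argument into a named list of data.frames
as_read_list <- function(reads) {
  if (is.data.frame(reads)) return(list(S1 = reads))
  if (!is.list(reads) || !all(vapply(reads, is.data.frame, logical(1))))
    stop("reads must be a data.frame or a named list of data.frames")
  if (is.null(names(reads)))
    names(reads) <- paste0("S", seq_along(reads))
  reads
}

# internal shared engine for count_whole / count_regions
count_engine <- function(reads, annotations, scheme) {
  stopifnot(inherits(annotations, "ripmap_annotation"))
  read_list <- as_read_list(reads)
  g <- annotations$genes
  feats <- scheme_features(annotations, scheme)
  whole <- scheme_features(annotations, "whole")
  tts_feat <- gene_tts(g)[match(feats$gene_id, g$gene_id)]
  tts_whole <- gene_tts(g)
  known <- unique(g$chrom)

  counts <- matrix(0L, nrow = nrow(feats), ncol = length(read_list),
                   dimnames = list(feats$feature_id, names(read_list)))
  library_size <- stats::setNames(numeric(length(read_list)), names(read_list))
  skipped <- stats::setNames(integer(length(read_list)), names(read_list))
  rrna_gene <- g$gene_id[g$is_rrna]
  for (j in seq_along(read_list)) {
    rd <- read_list[[j]]
    bad <- !(rd$chrom %in% known)
    skipped[j] <- sum(bad)
    rd <- rd[!bad, , drop = FALSE]
    a <- assign_midpoints(rd, feats, tts_feat)
    tab <- table(a[!is.na(a)])
    counts[as.integer(names(tab)), j] <- as.integer(tab)
    # library size: reads assigned to any non-rRNA gene, whole-gene scheme
    aw <- if (scheme == "whole") a else assign_midpoints(rd, whole, tts_whole)
    wg <- if (scheme == "whole") feats$gene_id else whole$gene_id
    library_size[j] <- sum(!is.na(aw) & !(wg[aw] %in% rrna_gene))
  }
  gi <- match(feats$gene_id, g$gene_id)
  meta <- data.frame(feature_id = feats$feature_id, gene_id = feats$gene_id,
                     kind = feats$kind, length = feats$end - feats$start,
                     gene_length = g$end[gi] - g$start[gi],
                     is_rrna = g$is_rrna[gi], stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta, library_size = library_size,
                 scheme = scheme, qc = list(skipped_reads = skipped)),
            class = "ripmap_counts")
}

#' Count reads per whole transcript
#'
#' Assigns each read to the transcript whose interval contains the read's
#' midpoint on the matching strand (strand-specific, single assignment).
#' Reads matching nothing are left uncounted; reads on unknown chromosomes
#' are skipped and tallied in `qc$skipped_reads`.  The per-sample library
#' size is the number of reads assigned to any non-rRNA transcript — the
#' normalizer reused by all region schemes, mirroring library-size
#' normalization after rRNA filtering.
#'
#' @param reads a read data.frame or a named list of them (one per sample).
#' @param annotations a `ripmap_annotation`.
#' @return a `ripmap_counts`: list with `counts` (feature x sample integer
#'   matrix), `meta` (feature_id, gene_id, kind, length, gene_length,
#'   is_rrna), `library_size` (named per sample), `scheme`, `qc`.
#' @export
count_whole <- function(reads, annotations)
  count_engine(reads, annotations, "whole")

#' Count reads per transcript region
#'
#' Same midpoint rule as [count_whole()], against per-gene region features:
#' `utr_cds` (5'UTR, CDS, 3'UTR), `thirds` (floor-partition of the transcript
#' length in transcript orientation — the first third is 5'-most on either
#' strand, remainder nucleotides go to the last, 3'-most third; genes shorter
#' than 3 nt are excluded), or `introns`.
#'
#' @inheritParams count_whole
#' @param scheme one of `"utr_cds"`, `"thirds"`, `"introns"`.
#' @return a `ripmap_counts` (see [count_whole()]); library sizes are the
#'   whole-transcript non-rRNA assignments.
#' @export
count_regions <- function(reads, annotations,
                          scheme = c("utr_cds", "thirds", "introns")) {
  scheme <- match.arg(scheme)
  count_engine(reads, annotations, scheme)
}

#' Filter features from a count table
#'
#' Removes rRNA-flagged features (before any reproducibility or enrichment
#' computation) and, when `min_length` is set, features on genes whose
#' transcript length is `<= min_length` (the regional analyses use
#' `min_length = 400`).  Library sizes are left unchanged: they were computed
#' as non-rRNA whole-transcript assignments at count time.
#'
#' @param table a `ripmap_counts`.
#' @param drop_rrna drop features on rRNA genes.
#' @param min_length drop features on genes with transcript length
#'   `<= min_length` (0 keeps everything).
#' @return the filtered `ripmap_counts`.
#' @export
filter_features <- function(table, drop_rrna = TRUE, min_length = 0) {
  stopifnot(inherits(table, "ripmap_counts"))
  keep <- rep(TRUE, nrow(table$meta))
  if (drop_rrna) keep <- keep & !table$meta$is_rrna
  if (min_length > 0) keep <- keep & table$meta$gene_length > min_length
  table$counts <- table$counts[keep, , drop = FALSE]
  table$meta <- table$meta[keep, , drop = FALSE]
  rownames(table$meta) <- NULL
  table
}

#' @export
print.ripmap_counts <- function(x, ...) {
  cat(sprintf("ripmap_counts [%s]: %d features x %d samples; library sizes: %s\n",
              x$scheme, nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(x$library_size),
                            as.integer(x$library_size)), collapse = ", ")))
  invisible(x)
}
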