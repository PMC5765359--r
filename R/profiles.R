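#' Anchor reads to TSS or TTS in transcript orientation
#'
#' For every gene longer than `min_gene_length`, each matching-strand read
#' contributes one count at its 5'-end position expressed in transcript
#' orientation relative to the anchor (negative = upstream of the anchor),
#' and contributions are summed over genes.  Anchors follow the strand: the
#' TSS of a `+` gene is its `start` and of a `-` gene its `end` coordinate
#' (and vice versa for the TTS); on the `-` strand offsets increase toward
#' lower genomic coordinates.
#'
#' @param reads a read data.frame (pool replicates beforehand if desired).
#' @param annotations a `ripmap_annotation`.
#' @param anchor `"tss"` or `"tts"`.
#' @param window length-2 numeric `(upstream, downstream)` in nt; offsets
#'   covered are `[-upstream, downstream)`.
#' @param min_gene_length only genes with transcript length strictly greater
#'   than this contribute (default 400 nt).
#' @return integer vector of per-position 5'-end counts, names = offsets;
#'   attributes `anchor`, `window`, `n_genes`.
#' @export
anchor_profile <- function(reads, annotations, anchor = c("tss", "tts"),
                           window = c(upstream = 500, downstream = 1000),
                           min_gene_length = 400) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(annotations, "ripmap_annotation"))
  up <- window[[1]]; down <- window[[2]]
  if (up <= 0 || down <= 0) stop("window bounds must be > 0")
  g <- annotations$genes
  g <- g[(g$end - g$start) > min_gene_length, , drop = FALSE]
  if (nrow(g) == 0)
    stop("no genes longer than min_gene_length = ", min_gene_length)
  plus <- g$strand == "+"
  a <- if (anchor == "tss") ifelse(plus, g$start, g$end) else
    ifelse(plus, g$end, g$start)

  counts <- integer(up + down)
  if (nrow(reads) > 0) {
    pos5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
    pts <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(start = pos5 + 1L,
                                                   width = 1L),
                                  strand = reads$strand)
    # genomic span of offsets [-up, down): pos5 = a + o (+) or a - o (-)
    ws <- ifelse(plus, a - up, a - down + 1L)
    we <- ifelse(plus, a + down - 1L, a + up)
    win <- GenomicRanges::GRanges(g$chrom,
                                  IRanges::IRanges(start = ws + 1L, end = we + 1L),
                                  strand = g$strand)
    hits <- GenomicRanges::findOverlaps(pts, win, ignore.strand = FALSE)
    if (length(hits) > 0) {
      q <- queryHits(hits); s <- subjectHits(hits)
      off <- ifelse(plus[s], pos5[q] - a[s], a[s] - pos5[q])
      keep <- off >= -up & off < down
      counts <- tabulate(off[keep] + up + 1L, nbins = up + down)
    }
  }
  names(counts) <- seq(-up, down - 1L)
  attr(counts, "anchor") <- anchor
  attr(counts, "window") <- c(upstream = up, downstream = down)
  attr(counts, "n_genes") <- nrow(g)
  counts
}

# internal: mass-preserving (sum-conserving) moving average.  Each input bin
# spreads its mass uniformly over a centered window of k bins, shrunk at the
# edges, so the vector sum is conserved exactly.
smooth_conserve <- function(x, k) {
  if (k < 1) stop("smoothing window must be >= 1")
  n <- length(x)
  if (k == 1 || n <= 1) return(x)
  l <- (k - 1L) %/% 2L
  r <- k - 1L - l
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - l):min(n, i + r)
    out[idx] <- out[idx] + x[i] / length(idx)
  }
  out
}

#' Normalize, bin and smooth an anchored profile
#'
#' Scales per-position counts to read density per 100 million mapped reads
#' and per contributing gene, sums them into consecutive `bin_width`-nt bins,
#' and smooths with a `smooth_bins`-bin sliding-window average
#' (mass-preserving: edges shrink and the vector sum is conserved exactly).
#' `smooth_unit = "positions"` instead applies the sliding window at
#' single-nt resolution before binning — the literal reading of a 6-bp
#' window.
#'
#' @param raw per-position count vector from [anchor_profile()].
#' @param library_size total mapped reads of the sample (> 0).
#' @param bin_width bin size in nt (default 15).
#' @param smooth_bins sliding-window width (default 6).
#' @param smooth_unit `"bins"` (default) or `"positions"`.
#' @param per density denominator (default 1e8: per 100 million reads).
#' @return object of class `ripmap_profile`: list with `values` (one per
#'   bin), `bin_offsets` (bin start offsets), `anchor`, `window`,
#'   `bin_width`, `smooth_bins`, `n_genes`, `library_size`.
#' @export
normalize_bin_smooth <- function(raw, library_size, bin_width = 15,
                                 smooth_bins = 6,
                                 smooth_unit = c("bins", "positions"),
                                 per = 1e8) {
  smooth_unit <- match.arg(smooth_unit)
  if (library_size <= 0) stop("library_size must be > 0")
  if (smooth_bins < 1) stop("smooth_bins must be >= 1")
  n_genes <- attr(raw, "n_genes")
  if (is.null(n_genes)) n_genes <- 1L
  window <- attr(raw, "window")
  up <- if (is.null(window)) 0 else window[["upstream"]]

  x <- as.numeric(raw) * per / library_size / n_genes
  if (smooth_unit == "positions") x <- smooth_conserve(x, smooth_bins)
  n_bins <- length(x) %/% bin_width
  if (n_bins < 1) stop("profile shorter than one bin")
  binned <- colSums(matrix(x[seq_len(n_bins * bin_width)],
                           nrow = bin_width))
  values <- if (smooth_unit == "bins") smooth_conserve(binned, smooth_bins)
            else binned
  structure(list(values = values,
                 bin_offsets = seq_len(n_bins) * bin_width - bin_width - up,
                 anchor = attr(raw, "anchor"),
                 window = window, bin_width = bin_width,
                 smooth_bins = smooth_bins, smooth_unit = smooth_unit,
                 n_genes = n_genes, library_size = library_size),
            class = "ripmap_profile")
}

#' Composite (metagene) profile in one call
#'
#' Convenience wrapper: [anchor_profile()] then [normalize_bin_smooth()].
#' When `library_size` is NULL the number of reads supplied is used.
#'
#' @inheritParams anchor_profile
#' @inheritParams normalize_bin_smooth
#' @param library_size total mapped reads (NULL: `nrow(reads)`).
#' @return a `ripmap_profile`.
#' @export
composite_profile <- function(reads, annotations, anchor = c("tss", "tts"),
                              window = c(upstream = 500, downstream = 1000),
                              min_gene_length = 400, library_size = NULL,
                              bin_width = 15, smooth_bins = 6,
                              smooth_unit = c("bins", "positions")) {
  raw <- anchor_profile(reads, annotations, anchor, window, min_gene_length)
  if (is.null(library_size)) library_size <- nrow(reads)
  normalize_bin_smooth(raw, library_size, bin_width, smooth_bins, smooth_unit)
}

#' @export
print.ripmap_profile <- function(x, ...) {
  cat(sprintf("ripmap_profile: %s-anchored, %d bins of %d nt (smooth %d %s), %d genes, peak %.3g\n",
              toupper(x$anchor), length(x$values), x$bin_width,
              x$smooth_bins, x$smooth_unit, x$n_genes, max(x$values)))
  invisible(x)
}
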