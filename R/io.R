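#' Write a synthetic fixture to disk
#'
#' Writes the annotation as a documented TSV (`annotation.tsv`, one row per
#' gene with explicit utr5/cds/utr3 columns), `introns.tsv`, a BED12 view of
#' the gene models (`annotation.bed`, thickStart/thickEnd = CDS, blocks =
#' exons), one 6-column BED per sample replicate (`reads_<role>_<rep>.bed`,
#' name = `role:replicate`), and a ground-truth manifest
#' (`ground_truth.tsv`: gene_id, abundance, factor).  All files round-trip
#' losslessly through [read_annotation()], [read_reads_bed()] and
#' [read_ground_truth()].
#'
#' @param annotations a `ripmap_annotation`.
#' @param reads named list of read data.frames (as returned by
#'   [simulate_reads()], possibly concatenated across roles).
#' @param truth a `ripmap_truth`, or NULL to skip the manifest.
#' @param outdir output directory (created if missing).
#' @return invisibly, the named character vector of files written.
#' @export
write_fixture <- function(annotations, reads, truth, outdir) {
  stopifnot(inherits(annotations, "ripmap_annotation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- c(annotation = file.path(outdir, "annotation.tsv"),
             introns = file.path(outdir, "introns.tsv"),
             bed12 = file.path(outdir, "annotation.bed"))
  write.table(annotations$genes, files["annotation"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(annotations$introns, files["introns"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed12(annotations, files["bed12"])
  for (nm in names(reads)) {
    f <- file.path(outdir, paste0("reads_", nm, ".bed"))
    write_reads_bed(reads[[nm]], f)
    files[paste0("reads_", nm)] <- f
  }
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "ripmap_truth"))
    files["truth"] <- file.path(outdir, "ground_truth.tsv")
    tt <- data.frame(gene_id = names(truth$abundance),
                     abundance = unname(truth$abundance),
                     factor = unname(truth$factor[names(truth$abundance)]),
                     stringsAsFactors = FALSE)
    hdr <- sprintf("# bias3p=%s window3p=%s", format(truth$bias3p),
                   format(truth$window3p))
    con <- file(files["truth"], "w")
    writeLines(hdr, con)
    write.table(tt, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(files)
}

# BED12 export of the gene models: thickStart/thickEnd = CDS in genomic
# coordinates, blocks = exons (transcript minus introns).
write_bed12 <- function(annotations, path) {
  g <- annotations$genes
  ints <- annotations$introns
  blocks <- lapply(seq_len(nrow(g)), function(i) {
    gi <- ints[ints$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(gi) == 0)
      return(list(starts = 0L, sizes = g$end[i] - g$start[i]))
    gi <- gi[order(gi$start), , drop = FALSE]
    bs <- c(g$start[i], gi$end)
    be <- c(gi$start, g$end[i])
    list(starts = bs - g$start[i], sizes = be - bs)
  })
  lines <- vapply(seq_len(nrow(g)), function(i) {
    b <- blocks[[i]]
    paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0, g$strand[i],
          g$cds_start[i], g$cds_end[i], "0,0,0", length(b$sizes),
          paste0(paste(b$sizes, collapse = ","), ","),
          paste0(paste(b$starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

write_reads_bed <- function(reads, path) {
  gr <- reads_to_granges(reads)
  # paste0() recycles zero-length input to length 1; guard the empty case
  gr$name <- if (nrow(reads)) paste0(reads$sample_role, ":", reads$replicate)
             else character(0)
  gr$score <- rep(0L, nrow(reads))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read an annotation fixture written by [write_fixture()]
#'
#' @param dir_or_file fixture directory, or path to `annotation.tsv` (its
#'   sibling `introns.tsv` is read when present).
#' @return a `ripmap_annotation`.
#' @export
read_annotation <- function(dir_or_file) {
  f <- if (dir.exists(dir_or_file)) file.path(dir_or_file, "annotation.tsv")
       else dir_or_file
  genes <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  fi <- file.path(dirname(f), "introns.tsv")
  introns <- if (file.exists(fi))
    read.table(fi, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c("character", "integer", "integer"))
  else data.frame(gene_id = character(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
  structure(list(genes = genes, introns = introns),
            class = "ripmap_annotation")
}

#' Read a 6-column BED read file (0-based half-open)
#'
#' @param path BED file written by [write_fixture()] or any 6-column BED whose
#'   name field is `role:replicate`.
#' @return a read data.frame (chrom, start, end, strand, sample_role,
#'   replicate).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) gr$name else rep("input:1", length(gr))
  parts <- strsplit(nm, ":", fixed = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             sample_role = vapply(parts, `[`, character(1), 1),
             replicate = as.integer(vapply(parts, `[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Read a ground-truth manifest written by [write_fixture()]
#'
#' @param path fixture directory or `ground_truth.tsv` path.
#' @return a `ripmap_truth`.
#' @export
read_ground_truth <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "ground_truth.tsv") else path
  hdr <- readLines(f, n = 1)
  bias3p <- as.numeric(sub(".*bias3p=([^ ]+).*", "\\1", hdr))
  window3p <- as.numeric(sub(".*window3p=([^ ]+).*", "\\1", hdr))
  tt <- read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  structure(list(abundance = stats::setNames(tt$abundance, tt$gene_id),
                 factor = stats::setNames(tt$factor, tt$gene_id),
                 bound = sort(tt$gene_id[tt$factor > 1]),
                 bias3p = bias3p, window3p = window3p),
            class = "ripmap_truth")
}

#' Read a two-column gene-value table
#'
#' Generic reader for external quantitative tables (decay rates, synthesis
#' rates, expression changes, ...): TSV with a gene-id column and one or more
#' value columns.  With one value column a named numeric vector is returned;
#' with several, a named list of vectors (one per column, e.g. a time course).
#'
#' @param path TSV path with header; first column = gene id.
#' @return named numeric vector, or named list of them.
#' @export
read_gene_values <- function(path) {
  tt <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tt) < 2) stop("gene-value table needs >= 2 columns")
  if (ncol(tt) == 2) return(stats::setNames(tt[[2]], tt[[1]]))
  lapply(stats::setNames(seq(2, ncol(tt)), names(tt)[-1]),
         function(j) stats::setNames(tt[[j]], tt[[1]]))
}

# internal: read df -> GRanges (1-based closed for IRanges)
reads_to_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(start = reads$start + 1L,
                                          end = reads$end),
                         strand = reads$strand)
}
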