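test_that("transcriptome generation is deterministic and partitions cleanly", {
  a1 <- generate_transcriptome(50, intron_prob = 0.3, rrna_frac = 0.1, seed = 11)
  a2 <- generate_transcriptome(50, intron_prob = 0.3, rrna_frac = 0.1, seed = 11)
  expect_identical(a1, a2)
  a3 <- generate_transcriptome(50, intron_prob = 0.3, rrna_frac = 0.1, seed = 12)
  expect_false(identical(a1$genes$start, a3$genes$start))

  g <- a1$genes
  # utr5 + cds + utr3 lengths always sum to the transcript length
  expect_equal((g$utr5_end - g$utr5_start) + (g$cds_end - g$cds_start) +
                 (g$utr3_end - g$utr3_start), g$end - g$start)
  # 5'UTR sits at the transcript 5' end on either strand
  plus <- g$strand == "+"
  expect_true(all(g$utr5_start[plus] == g$start[plus]))
  expect_true(all(g$utr5_end[!plus] == g$end[!plus]))
  # rRNA count follows the stated rounding rule
  expect_identical(sum(g$is_rrna), 5L)
  # introns strictly inside their gene
  gi <- match(a1$introns$gene_id, g$gene_id)
  expect_true(all(a1$introns$start > g$start[gi] &
                    a1$introns$end < g$end[gi]))
  # genes never overlap within a chromosome
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(head(gg$end, -1) <= tail(gg$start, -1)))
  }
})

test_that("single-gene transcriptome satisfies the partition identity", {
  a <- generate_transcriptome(1, intron_prob = 0, rrna_frac = 0, seed = 5)
  g <- a$genes
  expect_identical(nrow(g), 1L)
  expect_equal((g$utr5_end - g$utr5_start) + (g$cds_end - g$cds_start) +
                 (g$utr3_end - g$utr3_start), g$end - g$start)
  expect_error(generate_transcriptome(0), "n_genes")
  expect_error(generate_transcriptome(10, rrna_frac = 1.5), "fractions")
})

test_that("ground truth honours bound_frac, factors and coupling", {
  annot <- generate_transcriptome(2000, rrna_frac = 0, seed = 2)
  t0 <- generate_ground_truth(annot, bound_frac = 0, seed = 2)
  expect_true(all(t0$factor == 1))
  expect_length(t0$bound, 0)

  t1 <- generate_ground_truth(annot, bound_frac = 1, enrich_logmean = log(8),
                              enrich_logsd = 0, seed = 2)
  expect_equal(unname(t1$factor), rep(8, 2000), tolerance = 1e-12)

  t15 <- generate_ground_truth(annot, bound_frac = 0.15, seed = 2)
  expect_length(t15$bound, 300)          # round(0.15 * 2000)
  expect_equal(sum(t15$abundance), 1)
  expect_true(all(t15$abundance > 0))
  expect_true(all(t15$factor[setdiff(names(t15$factor), t15$bound)] == 1))

  # negative coupling: bound genes sit at low abundance, so abundance and
  # enrichment factor are negatively rank-correlated over all genes
  tc <- generate_ground_truth(annot, bound_frac = 0.15,
                              abundance_coupling = -2, seed = 2)
  expect_lt(cor(tc$abundance, tc$factor[names(tc$abundance)],
                method = "spearman"), 0)
  # rRNA genes are never bound
  am <- generate_transcriptome(500, rrna_frac = 0.2, seed = 9)
  tm <- generate_ground_truth(am, bound_frac = 0.5, seed = 9)
  expect_length(intersect(tm$bound, am$genes$gene_id[am$genes$is_rrna]), 0)
  expect_length(tm$bound, round(0.5 * 400))
})

test_that("simulated reads conserve library size and stay inside genes", {
  annot <- generate_transcriptome(20, rrna_frac = 0, seed = 3)
  truth <- generate_ground_truth(annot, bound_frac = 0.2, seed = 3)
  reads <- simulate_reads(annot, truth, "ip", library_size = 1000,
                          n_reps = 3, seed = 3)
  expect_length(reads, 3)
  for (r in reads) expect_identical(nrow(r), 1000L)

  g <- annot$genes
  for (r in reads) {
    ov <- vapply(seq_len(nrow(r)), function(i) {
      any(g$chrom == r$chrom[i] & g$strand == r$strand[i] &
            g$start <= r$start[i] & g$end >= r$end[i])
    }, logical(1))
    expect_true(all(ov))
  }
})

test_that("IP read allocation matches the closed-form expectation", {
  # two genes, equal abundance, gene A enriched 8x: A's expected share 8/9
  annot <- toy_annotation(c(0, 2000), c(1000, 3000), c("+", "+"))
  truth <- structure(list(
    abundance = stats::setNames(c(0.5, 0.5), annot$genes$gene_id),
    factor = stats::setNames(c(8, 1), annot$genes$gene_id),
    bound = annot$genes$gene_id[1], bias3p = 0, window3p = 200),
    class = "ripmap_truth")
  n <- 20000
  reads <- simulate_reads(annot, truth, "ip", library_size = n, n_reps = 1,
                          seed = 42)[[1]]
  in_a <- sum(reads$start < 1000)
  # binomial 99% interval around p = 8/9
  expect_gt(in_a, qbinom(0.005, n, 8 / 9))
  expect_lt(in_a, qbinom(0.995, n, 8 / 9))

  # single gene: every read on that gene and its strand
  a1 <- toy_annotation(100, 900, "-")
  t1 <- structure(list(abundance = c(g0001 = 1), factor = c(g0001 = 2),
                       bound = "g0001", bias3p = 0.5, window3p = 200),
                  class = "ripmap_truth")
  r1 <- simulate_reads(a1, t1, "ip", 500, n_reps = 1, seed = 1)[[1]]
  expect_true(all(r1$strand == "-" & r1$start >= 100 & r1$end <= 900))
})

test_that("replicate RNG streams are independent of n_reps and role", {
  annot <- generate_transcriptome(30, seed = 7)
  truth <- generate_ground_truth(annot, seed = 7)
  one <- simulate_reads(annot, truth, "ip", 500, n_reps = 1, seed = 7)
  three <- simulate_reads(annot, truth, "ip", 500, n_reps = 3, seed = 7)
  expect_identical(one[[1]], three[[1]])
  mock <- simulate_reads(annot, truth, "mock", 500, n_reps = 1, seed = 7)
  expect_false(identical(mock[[1]]$start, three[[1]]$start))
})

test_that("3'-window fallback covers transcripts shorter than the window", {
  annot <- toy_annotation(0, 150, "+")
  truth <- structure(list(abundance = c(g0001 = 1), factor = c(g0001 = 8),
                          bound = "g0001", bias3p = 1, window3p = 500),
                     class = "ripmap_truth")
  reads <- simulate_reads(annot, truth, "ip", 200, n_reps = 1,
                          read_len = c(30, 50), seed = 4)
  expect_identical(attr(reads, "n_window_fallback"), 1L)
  r <- reads[[1]]
  expect_true(all(r$start >= 0 & r$end <= 150))
})

test_that("fixtures round-trip losslessly through the readers", {
  annot <- generate_transcriptome(25, intron_prob = 0.4, rrna_frac = 0.08,
                                  seed = 21)
  truth <- generate_ground_truth(annot, seed = 21)
  reads <- c(simulate_reads(annot, truth, "ip", 300, n_reps = 2, seed = 21),
             simulate_reads(annot, truth, "mock", 200, n_reps = 2, seed = 21))
  outdir <- withr::local_tempdir()
  files <- write_fixture(annot, reads, truth, outdir)
  expect_true(all(file.exists(files)))

  a2 <- read_annotation(outdir)
  expect_equal(a2$genes, annot$genes)
  expect_equal(a2$introns, annot$introns)

  r2 <- read_reads_bed(files[["reads_ip_1"]])
  expect_equal(r2, reads$ip_1)

  t2 <- read_ground_truth(outdir)
  expect_equal(t2$abundance, truth$abundance, tolerance = 1e-12)
  expect_equal(t2$factor, truth$factor, tolerance = 1e-12)
  expect_identical(t2$bound, truth$bound)
  expect_equal(t2$bias3p, truth$bias3p)

  # manifest gene count equals annotation count
  expect_identical(nrow(read.table(files[["truth"]], header = TRUE,
                                   sep = "\t", comment.char = "#")),
                   nrow(annot$genes))

  # BED12 blocks tile the transcript minus its introns
  bed <- read.table(files[["bed12"]], sep = "\t", stringsAsFactors = FALSE)
  expect_identical(nrow(bed), nrow(annot$genes))
  sizes <- lapply(strsplit(bed$V11, ","), as.integer)
  intron_len <- vapply(bed$V4, function(id) {
    ii <- annot$introns[annot$introns$gene_id == id, ]
    sum(ii$end - ii$start)
  }, numeric(1))
  expect_equal(vapply(sizes, sum, numeric(1)) + unname(intron_len),
               bed$V3 - bed$V2)
})

test_that("an empty read set writes a valid, re-readable BED", {
  empty <- mk_reads(integer(0), integer(0), character(0))
  f <- withr::local_tempfile(fileext = ".bed")
  ripmap:::write_reads_bed(empty, f)
  expect_true(file.exists(f))
  back <- read_reads_bed(f)
  expect_identical(nrow(back), 0L)
})
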