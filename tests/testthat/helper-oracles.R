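# Independent oracles and tiny fixture builders shared across tests.

# Exact conditional-binomial p-value by direct enumeration, written
# independently of the package implementation (log-factorial arithmetic,
# not dbinom).  Minimum-likelihood two-sided rule with the same relative
# tie tolerance.
oracle_exact_p <- function(y1, y2, n1, n2) {
  t <- y1 + y2
  if (t == 0) return(1)
  p0 <- n1 / (n1 + n2)
  k <- 0:t
  pr <- exp(lgamma(t + 1) - lgamma(k + 1) - lgamma(t - k + 1) +
              k * log(p0) + (t - k) * log1p(-p0))
  min(1, sum(pr[pr <= pr[y1 + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg by the literal step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# Pearson chi-square on the 2x2 overlap table, by direct table arithmetic.
oracle_chi2 <- function(n_a, n_b, overlap, N) {
  obs <- matrix(c(overlap, n_a - overlap, n_b - overlap,
                  N - n_a - n_b + overlap), 2, 2)
  rs <- rowSums(obs); cs <- colSums(obs)
  expd <- outer(rs, cs) / N
  sum((obs - expd)^2 / expd)
}

# Hand-built annotation: explicit gene intervals with UTR fractions laid out
# like the generator (5'UTR at the transcript 5' end on either strand).
toy_annotation <- function(start, end, strand, chrom = "chr1",
                           u5 = NULL, u3 = NULL, is_rrna = FALSE,
                           introns = NULL) {
  n <- length(start)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  is_rrna <- rep_len(is_rrna, n)
  len <- end - start
  if (is.null(u5)) u5 <- pmax(1, round(0.1 * len))
  if (is.null(u3)) u3 <- pmax(1, round(0.2 * len))
  plus <- strand == "+"
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)), chrom = chrom, strand = strand,
    start = start, end = end,
    utr5_start = ifelse(plus, start, end - u5),
    utr5_end = ifelse(plus, start + u5, end),
    cds_start = ifelse(plus, start + u5, start + u3),
    cds_end = ifelse(plus, end - u3, end - u5),
    utr3_start = ifelse(plus, end - u3, start),
    utr3_end = ifelse(plus, end, start + u3),
    is_rrna = is_rrna, stringsAsFactors = FALSE)
  if (is.null(introns))
    introns <- data.frame(gene_id = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  structure(list(genes = genes, introns = introns),
            class = "ripmap_annotation")
}

# Read data.frame builder (0-based half-open).
mk_reads <- function(start, end, strand, chrom = "chr1", role = "ip",
                     rep = 1L) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n),
             sample_role = rep_len(role, n),
             replicate = rep_len(as.integer(rep), n),
             stringsAsFactors = FALSE)
}

# Direct ripmap_counts constructor for enrichment unit tests.
mk_counts <- function(mat, lib, kind = "whole", gene_length = 1000) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("rep", seq_len(ncol(mat)))
  meta <- data.frame(feature_id = rownames(mat), gene_id = rownames(mat),
                     kind = kind, length = gene_length,
                     gene_length = gene_length, is_rrna = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(counts = mat, meta = meta,
                 library_size = stats::setNames(lib, colnames(mat)),
                 scheme = kind, qc = list()),
            class = "ripmap_counts")
}

# Uniform random reads over a set of genes, for property tests.
random_reads_over <- function(annot, n, len = 40) {
  g <- annot$genes
  gi <- sample.int(nrow(g), n, replace = TRUE)
  maxp <- (g$end[gi] - g$start[gi]) - len
  p <- floor(runif(n) * (maxp + 1))
  plus <- g$strand[gi] == "+"
  start <- ifelse(plus, g$start[gi] + p, g$end[gi] - p - len)
  mk_reads(as.integer(start), as.integer(start + len), g$strand[gi],
           chrom = g$chrom[gi])
}

# Strand-flipped copies, for the symmetry property (gene intervals stay put;
# only the orientation labels flip).
flip_annot <- function(annot) {
  annot$genes$strand <- ifelse(annot$genes$strand == "+", "-", "+")
  annot
}

flip_reads <- function(reads) {
  reads$strand <- ifelse(reads$strand == "+", "-", "+")
  reads
}
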