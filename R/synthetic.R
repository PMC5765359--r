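# Derive one RNG stream seed per (role, replicate) from the master seed so
# that adding replicates or roles never perturbs earlier ones.  Kept below
# 2^31 - 1 (R integer range).
derive_seed <- function(seed, role = "none", replicate = 0L) {
  role_code <- switch(role, none = 0L, input = 1L, ip = 2L, mock = 3L,
                      annot = 4L, truth = 5L,
                      stop("unknown role: ", role))
  as.integer((as.numeric(seed) * 1009 + role_code * 131071 +
                as.numeric(replicate) * 8191) %% 2147483629)
}

#' Generate a synthetic transcriptome annotation
#'
#' Lays non-overlapping transcripts on synthetic chromosomes, on both strands,
#' with a 5'UTR/CDS/3'UTR partition, optional introns (inside the CDS) and a
#' configurable fraction of rRNA genes.  All coordinates are 0-based,
#' half-open (BED convention).  On the `-` strand the TSS is the `end`
#' coordinate and the TTS is `start`.
#'
#' @param n_genes number of transcripts to generate (>= 1).
#' @param length_dist list with `meanlog`, `sdlog`, `min`: transcript lengths
#'   are drawn lognormal and floored at `min` nt.
#' @param utr_fracs named numeric with `utr5` and `utr3`: fractions of the
#'   transcript length assigned to each UTR (the CDS takes the remainder).
#' @param intron_prob probability that a gene carries one intron (placed
#'   strictly inside the CDS).
#' @param rrna_frac fraction of genes flagged as rRNA; the flagged count is
#'   `round(rrna_frac * n_genes)`.
#' @param genes_per_chrom transcripts per synthetic chromosome.
#' @param seed integer seed; identical seeds give byte-identical annotations.
#' @return an object of class `ripmap_annotation`: a list with `genes`
#'   (data.frame: gene_id, chrom, strand, start, end, utr5_start, utr5_end,
#'   cds_start, cds_end, utr3_start, utr3_end, is_rrna) and `introns`
#'   (data.frame: gene_id, start, end).
#' @export
generate_transcriptome <- function(n_genes,
                                   length_dist = list(meanlog = log(1200),
                                                      sdlog = 0.35,
                                                      min = 300),
                                   utr_fracs = c(utr5 = 0.08, utr3 = 0.15),
                                   intron_prob = 0.05,
                                   rrna_frac = 0.02,
                                   genes_per_chrom = 250,
                                   seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  fr <- c(utr_fracs[["utr5"]], utr_fracs[["utr3"]], intron_prob, rrna_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (sum(utr_fracs[c("utr5", "utr3")]) >= 1)
    stop("utr5 + utr3 fractions must be < 1")

  set.seed(derive_seed(seed, "annot"))
  len <- pmax(length_dist$min,
              round(stats::rlnorm(n_genes, length_dist$meanlog,
                                  length_dist$sdlog)))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gap <- round(stats::runif(n_genes, 100, 500))
  chrom_idx <- (seq_len(n_genes) - 1) %/% genes_per_chrom + 1
  chrom <- paste0("chrS", chrom_idx)
  # cumulative layout per chromosome, genes never overlap
  start <- integer(n_genes)
  off <- new.env()
  for (i in seq_len(n_genes)) {
    cur <- if (is.null(off[[chrom[i]]])) 0L else off[[chrom[i]]]
    start[i] <- cur + gap[i]
    off[[chrom[i]]] <- start[i] + len[i]
  }
  end <- start + len

  u5 <- pmax(1, round(len * utr_fracs[["utr5"]]))
  u3 <- pmax(1, round(len * utr_fracs[["utr3"]]))
  # genomic region boundaries follow strand orientation: the 5'UTR sits at the
  # low-coordinate end of a + gene but at the high-coordinate end of a - gene
  plus <- strand == "+"
  utr5_start <- ifelse(plus, start, end - u5)
  utr5_end   <- ifelse(plus, start + u5, end)
  utr3_start <- ifelse(plus, end - u3, start)
  utr3_end   <- ifelse(plus, end, start + u3)
  cds_start  <- ifelse(plus, utr5_end, utr3_end)
  cds_end    <- ifelse(plus, utr3_start, utr5_start)

  n_rrna <- round(rrna_frac * n_genes)
  is_rrna <- rep(FALSE, n_genes)
  if (n_rrna > 0) is_rrna[sample.int(n_genes, n_rrna)] <- TRUE

  gene_id <- sprintf("g%04d", seq_len(n_genes))
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = start, end = end,
                      utr5_start = utr5_start, utr5_end = utr5_end,
                      cds_start = cds_start, cds_end = cds_end,
                      utr3_start = utr3_start, utr3_end = utr3_end,
                      is_rrna = is_rrna, stringsAsFactors = FALSE)

  has_intron <- stats::runif(n_genes) < intron_prob & (cds_end - cds_start) > 120
  introns <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  if (any(has_intron)) {
    idx <- which(has_intron)
    cl <- cds_end[idx] - cds_start[idx]
    ilen <- pmin(cl - 2L, round(stats::runif(length(idx), 50, 300)))
    imax <- cl - ilen - 1L
    ioff <- 1L + floor(stats::runif(length(idx)) * imax)
    introns <- data.frame(gene_id = gene_id[idx],
                          start = cds_start[idx] + ioff,
                          end = cds_start[idx] + ioff + ilen,
                          stringsAsFactors = FALSE)
  }

  structure(list(genes = genes, introns = introns),
            class = "ripmap_annotation")
}

#' @export
print.ripmap_annotation <- function(x, ...) {
  g <- x$genes
  cat(sprintf("ripmap_annotation: %d transcripts on %d chromosomes (%d rRNA, %d with introns)\n",
              nrow(g), length(unique(g$chrom)), sum(g$is_rrna),
              length(unique(x$introns$gene_id))))
  invisible(x)
}

#' Generate ground-truth abundance and binding for a synthetic transcriptome
#'
#' Draws a log-skewed mRNA abundance vector (rRNA genes optionally inflated to
#' emulate dominant rRNA reads), selects a bound subset of non-rRNA genes with
#' selection probability coupled to abundance, and assigns each bound gene a
#' multiplicative IP enrichment factor.  With `abundance_coupling < 0` the
#' probability of being bound decreases with abundance, so that measured
#' enrichment is anti-correlated with expression.
#'
#' @param annotations a `ripmap_annotation`.
#' @param bound_frac fraction of non-rRNA genes that are bound; the bound set
#'   size is `round(bound_frac * n_non_rRNA)`.
#' @param enrich_logmean,enrich_logsd log-scale location/spread of the
#'   enrichment factor for bound genes (factors are floored at 1; the default
#'   `enrich_logsd = 0` gives every bound gene exactly
#'   `exp(enrich_logmean)`-fold enrichment).
#' @param abundance_logmean,abundance_logsd lognormal parameters of relative
#'   mRNA abundance.
#' @param abundance_coupling coefficient linking log-abundance (standardized)
#'   to the log-odds of being selected as bound; negative values emulate the
#'   anti-correlation between binding and abundance.
#' @param rrna_abundance_mult multiplier applied to rRNA gene abundance before
#'   normalization.
#' @param bias3p fraction of IP reads from bound genes whose 5' end falls in
#'   the 3'-terminal window (positional binding bias).
#' @param window3p length (nt) of the 3'-terminal window.
#' @param seed integer seed.
#' @return an object of class `ripmap_truth`: list with `abundance` (named,
#'   sums to 1), `factor` (named, 1 for unbound genes), `bound` (character
#'   vector of bound gene ids), `bias3p`, `window3p`.
#' @export
generate_ground_truth <- function(annotations,
                                  bound_frac = 0.15,
                                  enrich_logmean = log(8),
                                  enrich_logsd = 0,
                                  abundance_logmean = 0,
                                  abundance_logsd = 1,
                                  abundance_coupling = -2,
                                  rrna_abundance_mult = 20,
                                  bias3p = 0.8,
                                  window3p = 200,
                                  seed = 1) {
  stopifnot(inherits(annotations, "ripmap_annotation"))
  if (bound_frac < 0 || bound_frac > 1) stop("bound_frac must lie in [0, 1]")
  if (bias3p < 0 || bias3p > 1) stop("bias3p must lie in [0, 1]")
  g <- annotations$genes
  set.seed(derive_seed(seed, "truth"))

  ab <- stats::rlnorm(nrow(g), abundance_logmean, abundance_logsd)
  ab[g$is_rrna] <- ab[g$is_rrna] * rrna_abundance_mult
  abundance <- ab / sum(ab)
  names(abundance) <- g$gene_id

  non_rrna <- g$gene_id[!g$is_rrna]
  n_bound <- round(bound_frac * length(non_rrna))
  factor <- rep(1, nrow(g))
  names(factor) <- g$gene_id
  bound <- character(0)
  if (n_bound > 0) {
    z <- scale(log(abundance[non_rrna]))[, 1]
    w <- exp(abundance_coupling * z)
    bound <- sample(non_rrna, n_bound, prob = w)
    f <- exp(stats::rnorm(n_bound, enrich_logmean, enrich_logsd))
    factor[bound] <- pmax(1, f)
  }

  structure(list(abundance = abundance, factor = factor, bound = sort(bound),
                 bias3p = bias3p, window3p = window3p),
            class = "ripmap_truth")
}

#' @export
print.ripmap_truth <- function(x, ...) {
  cat(sprintf("ripmap_truth: %d genes, %d bound (median factor %.1f), bias3p=%.2f/%d nt\n",
              length(x$abundance), length(x$bound),
              if (length(x$bound)) stats::median(x$factor[x$bound]) else NA,
              x$bias3p, x$window3p))
  invisible(x)
}

#' Simulate replicate read sets for one sample role
#'
#' Draws `library_size` reads per replicate.  Gene-sampling weights are
#' abundance for `input`, abundance times enrichment factor for `ip`, and
#' abundance mixed with a flat contaminant floor for `mock` (the mock is an
#' untagged-strain IP: background with the same abundance structure plus a
#' low-complexity contaminant component).  For bound genes in the IP a
#' fraction `bias3p` of reads start (5' end, strand-aware) within the
#' 3'-terminal `window3p` nt of the transcript.  Reads always lie within
#' their transcript and carry its strand.
#'
#' @param annotations a `ripmap_annotation`.
#' @param truth a `ripmap_truth`.
#' @param role one of `"input"`, `"ip"`, `"mock"`.
#' @param library_size reads per replicate (>= 1).
#' @param n_reps number of replicates.
#' @param read_len integer length-2 vector: uniform read-length bounds (nt).
#' @param mock_floor for `role = "mock"`, weight of the flat contaminant
#'   component (0 disables it).
#' @param seed master seed; each (role, replicate) gets its own derived RNG
#'   stream, so adding replicates does not perturb earlier ones.
#' @return a list of `n_reps` data.frames (chrom, start, end, strand,
#'   sample_role, replicate), 0-based half-open coordinates.  If `window3p`
#'   exceeded a bound transcript's length the whole transcript was used as
#'   the window; the number of such genes is recorded in the attribute
#'   `n_window_fallback`.
#' @export
simulate_reads <- function(annotations, truth, role = c("input", "ip", "mock"),
                           library_size, n_reps = 3,
                           read_len = c(30, 50), mock_floor = 0.05,
                           seed = 1) {
  role <- match.arg(role)
  stopifnot(inherits(annotations, "ripmap_annotation"),
            inherits(truth, "ripmap_truth"))
  if (library_size < 1) stop("library_size must be >= 1")
  g <- annotations$genes
  L <- g$end - g$start
  if (any(read_len[1] > L)) stop("read_len exceeds the shortest transcript")
  a <- truth$abundance[g$gene_id]
  w <- switch(role,
              input = a,
              ip = a * truth$factor[g$gene_id],
              mock = (1 - mock_floor) * a + mock_floor / nrow(g))
  bound_idx <- match(truth$bound, g$gene_id)
  is_bound <- rep(FALSE, nrow(g))
  is_bound[bound_idx] <- TRUE
  n_fallback <- if (role == "ip") sum(truth$window3p > L[is_bound]) else 0L

  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, role, r))
    gi <- sample.int(nrow(g), library_size, replace = TRUE, prob = w)
    len <- if (read_len[1] == read_len[2]) rep(read_len[1], library_size) else
      read_len[1] + floor(stats::runif(library_size) * (read_len[2] - read_len[1] + 1))
    len <- pmin(len, L[gi])
    maxp <- L[gi] - len                      # max 5'-end offset, transcript coords
    p <- floor(stats::runif(library_size) * (maxp + 1))
    if (role == "ip" && truth$bias3p > 0 && any(is_bound[gi])) {
      biased <- is_bound[gi] & stats::runif(library_size) < truth$bias3p
      if (any(biased)) {
        lo <- pmax(0, L[gi][biased] - truth$window3p)   # whole-transcript fallback
        lo <- pmin(lo, maxp[biased])
        p[biased] <- lo + floor(stats::runif(sum(biased)) * (maxp[biased] - lo + 1))
      }
    }
    plus <- g$strand[gi] == "+"
    start <- ifelse(plus, g$start[gi] + p, g$end[gi] - p - len)
    out[[r]] <- data.frame(chrom = g$chrom[gi], start = as.integer(start),
                           end = as.integer(start + len),
                           strand = g$strand[gi],
                           sample_role = role, replicate = r,
                           stringsAsFactors = FALSE)
  }
  names(out) <- paste0(role, "_", seq_len(n_reps))
  attr(out, "n_window_fallback") <- n_fallback
  out
}
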