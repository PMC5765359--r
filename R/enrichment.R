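#' Exact two-sample Poisson rate test
#'
#' Tests equality of Poisson rates between an IP count and a mock count given
#' their library sizes.  Conditional on the total `t = y_ip + y_mock`, the IP
#' count is Binomial(t, n_ip/(n_ip + n_mock)) under the null of equal
#' normalized rates; the two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (minimum-likelihood method;
#' `method = "doubled"` doubles the smaller tail instead).  `t = 0` carries
#' no information and yields p = 1.  Vectorized over counts.
#'
#' @param y_ip,y_mock non-negative integer counts (recycled).
#' @param n_ip,n_mock positive library sizes.
#' @param method `"minlik"` (default) or `"doubled"`.
#' @return p-values in (0, 1].
#' @export
exact_poisson_test <- function(y_ip, y_mock, n_ip, n_mock,
                               method = c("minlik", "doubled")) {
  method <- match.arg(method)
  if (any(n_ip <= 0) || any(n_mock <= 0)) stop("library sizes must be > 0")
  if (any(y_ip < 0) || any(y_mock < 0)) stop("counts must be >= 0")
  n <- max(length(y_ip), length(y_mock))
  y1 <- rep_len(y_ip, n); y2 <- rep_len(y_mock, n)
  p1 <- rep_len(n_ip, n) / (rep_len(n_ip, n) + rep_len(n_mock, n))
  vapply(seq_len(n), function(i) {
    t <- y1[i] + y2[i]
    if (t == 0) return(1)
    if (method == "doubled") {
      lo <- pbinom(y1[i], t, p1[i])
      hi <- pbinom(y1[i] - 1, t, p1[i], lower.tail = FALSE)
      return(min(1, 2 * min(lo, hi)))
    }
    d <- dbinom(0:t, t, p1[i])
    # relative tolerance guards float asymmetry among tied outcome probabilities
    min(1, sum(d[d <= d[y1[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Library-size-normalized log2 IP/mock enrichment
#'
#' `log2(((y_ip + prior)/n_ip) / ((y_mock + prior)/n_mock))`.  The prior
#' count (default 1, added to the raw counts of both samples) keeps the ratio
#' finite when the mock has zero reads.
#'
#' @inheritParams exact_poisson_test
#' @param prior pseudocount added to both raw counts (> 0).
#' @return finite log2 enrichment values.
#' @export
log2_enrichment <- function(y_ip, y_mock, n_ip, n_mock, prior = 1) {
  if (prior <= 0) stop("prior must be > 0")
  log2(((y_ip + prior) / n_ip) / ((y_mock + prior) / n_mock))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i)(p_(j) * m / j)` capped at 1 and
#' mapped back to input order (a thin wrapper over
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return adjusted q-values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Replicate-pair enrichment
#'
#' Processes the replicates two at a time in all pairwise combinations (three
#' pairs for three replicates: 1v2, 2v3, 1v3).  Under the default
#' `pairing = "pooled"` the two IP replicates of a pair are pooled (counts
#' and library sizes summed) and likewise the two mock replicates, then each
#' feature gets an exact Poisson test, a prior-count log2 enrichment and a
#' BH adjustment across features.  `pairing = "crossed"` instead tests IP
#' replicate i against mock replicate j, unpooled (the alternative reading
#' of "two of three replicates at a time").  The combined enrichment is the
#' mean of per-pair log2 values over the pairs with FDR below `fdr_cutoff`;
#' when no pair passes, all pairs are averaged and the feature is flagged
#' (`all_pairs_averaged`), keeping a defined value for percentile analyses
#' while the FDR gate still governs target calling.  Features with zero
#' counts in every replicate of both tables are reported with
#' `combined_log2 = 0` and p = 1.
#'
#' @param ip_table,mock_table `ripmap_counts` with identical feature sets and
#'   >= 2 replicate columns each.
#' @param prior pseudocount for [log2_enrichment()].
#' @param pairing `"pooled"` or `"crossed"`.
#' @param fdr_cutoff FDR gate (default 0.01, i.e. FDR < 1%).
#' @param log2_cutoff enrichment gate for pair passing (default 1, twofold).
#' @param min_reps pairs required for a target call (default 2 of 3).
#' @param method p-value method, see [exact_poisson_test()].
#' @return data.frame with one row per feature: feature_id, gene_id, kind,
#'   per-pair `log2_pairK`, `p_pairK`, `fdr_pairK` columns, `combined_log2`,
#'   `all_pairs_averaged`, `n_pairs_passing`, `is_target`.  The pair
#'   definition is attached as attribute `"pairs"`.
#' @export
enrich_pairs <- function(ip_table, mock_table, prior = 1,
                         pairing = c("pooled", "crossed"),
                         fdr_cutoff = 0.01, log2_cutoff = 1, min_reps = 2,
                         method = c("minlik", "doubled")) {
  pairing <- match.arg(pairing)
  method <- match.arg(method)
  stopifnot(inherits(ip_table, "ripmap_counts"),
            inherits(mock_table, "ripmap_counts"))
  if (!identical(rownames(ip_table$counts), rownames(mock_table$counts)))
    stop("IP and mock tables must share the same feature list")
  n_ip_reps <- ncol(ip_table$counts)
  n_mock_reps <- ncol(mock_table$counts)
  if (n_ip_reps < 2 || n_mock_reps < 2)
    stop("need >= 2 replicates in each table")
  if (pairing == "crossed" && n_ip_reps != n_mock_reps)
    stop("crossed pairing needs matched replicate counts")

  pairs <- combn(min(n_ip_reps, n_mock_reps), 2)
  n_pairs <- ncol(pairs)
  nf <- nrow(ip_table$counts)
  all_zero <- rowSums(ip_table$counts) + rowSums(mock_table$counts) == 0

  log2m <- pm <- fdrm <- matrix(NA_real_, nf, n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (pairing == "pooled") {
      yi <- ip_table$counts[, i] + ip_table$counts[, j]
      ni <- sum(ip_table$library_size[c(i, j)])
      ym <- mock_table$counts[, i] + mock_table$counts[, j]
      nm <- sum(mock_table$library_size[c(i, j)])
    } else {
      yi <- ip_table$counts[, i]; ni <- ip_table$library_size[i]
      ym <- mock_table$counts[, j]; nm <- mock_table$library_size[j]
    }
    pm[, k] <- exact_poisson_test(yi, ym, ni, nm, method = method)
    log2m[, k] <- log2_enrichment(yi, ym, ni, nm, prior = prior)
    pm[all_zero, k] <- 1
    log2m[all_zero, k] <- 0
    fdrm[, k] <- bh_adjust(pm[, k])
  }

  pass <- fdrm < fdr_cutoff
  any_pass <- rowSums(pass) > 0
  combined <- ifelse(any_pass,
                     rowSums(log2m * pass) / pmax(1, rowSums(pass)),
                     rowMeans(log2m))
  n_pairs_passing <- rowSums(pass & log2m > log2_cutoff)

  out <- data.frame(feature_id = ip_table$meta$feature_id,
                    gene_id = ip_table$meta$gene_id,
                    kind = ip_table$meta$kind,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    out[[paste0("log2_pair", k)]] <- log2m[, k]
    out[[paste0("p_pair", k)]] <- pm[, k]
    out[[paste0("fdr_pair", k)]] <- fdrm[, k]
  }
  out$combined_log2 <- combined
  out$all_pairs_averaged <- !any_pass
  out$n_pairs_passing <- as.integer(n_pairs_passing)
  out$is_target <- n_pairs_passing >= min_reps
  attr(out, "pairs") <- pairs
  attr(out, "cutoffs") <- c(fdr = fdr_cutoff, log2 = log2_cutoff,
                            min_reps = min_reps)
  out
}

#' Call consensus targets from replicate-pair enrichment
#'
#' A feature is a target when at least `min_reps` of its replicate pairs show
#' enrichment above `log2_cutoff` at an FDR below `fdr_cutoff` (defaults:
#' > 1 log2, FDR < 1%, 2 of 3 pairs).
#'
#' @param results data.frame from [enrich_pairs()].
#' @param log2_cutoff,fdr_cutoff,min_reps calling thresholds.
#' @return character vector of target feature ids.
#' @export
call_targets <- function(results, log2_cutoff = 1, fdr_cutoff = 0.01,
                         min_reps = 2) {
  log2m <- as.matrix(results[, grep("^log2_pair", names(results)),
                             drop = FALSE])
  fdrm <- as.matrix(results[, grep("^fdr_pair", names(results)),
                            drop = FALSE])
  n_pass <- rowSums(fdrm < fdr_cutoff & log2m > log2_cutoff)
  results$feature_id[n_pass >= min_reps]
}

#' Tally strongly enriched regions per region kind
#'
#' Counts, per region kind (utr5/cds/utr3, thirds, or introns), the features
#' whose combined enrichment exceeds `fold_cutoff`-fold (fourfold for the
#' UTR/CDS and thirds analyses, twofold for introns).
#'
#' @param results data.frame from [enrich_pairs()] on a region-scheme table.
#' @param fold_cutoff fold-change cutoff on the linear scale.
#' @return named integer vector of counts per region kind.
#' @export
region_enrichment_tally <- function(results, fold_cutoff = 4) {
  hit <- results$combined_log2 > log2(fold_cutoff)
  tab <- tapply(hit, results$kind, sum)
  kinds <- unique(results$kind)
  stats::setNames(as.integer(tab[kinds]), kinds)
}

#' RPKM with a pseudocount, averaged over input replicates
#'
#' `(count + pseudocount) / ((gene_length/1000) * (library_size/1e6))`,
#' computed per replicate and then averaged.  The 0.5 pseudocount keeps later
#' logarithms finite for zero-count genes.
#'
#' @param counts numeric vector (one sample) or feature x replicate matrix.
#' @param gene_length transcript lengths in nt (> 0).
#' @param library_size per-replicate library sizes (> 0), recycled to the
#'   number of columns.
#' @param pseudocount added to each count (default 0.5).
#' @return per-feature RPKM (averaged over replicates for a matrix).
#' @export
compute_rpkm <- function(counts, gene_length, library_size, pseudocount = 0.5) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (is.matrix(counts)) {
    ls <- rep_len(library_size, ncol(counts))
    per_rep <- sweep(counts + pseudocount, 2, ls / 1e6, "/") /
      (gene_length / 1000)
    return(rowMeans(per_rep))
  }
  (counts + pseudocount) / ((gene_length / 1000) * (library_size / 1e6))
}
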