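# internal: accept a named numeric vector or a 2-column data.frame
as_gene_values <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("gene-value table needs gene ids and values")
    return(stats::setNames(as.numeric(x[[2]]), as.character(x[[1]])))
  }
  if (!is.numeric(x) || is.null(names(x)))
    stop("gene values must be a named numeric vector or 2-column data.frame")
  x
}

#' Percent ranks (spreadsheet PERCENTRANK convention)
#'
#' `rank(x) = (# values strictly below x) / (n - 1)`; tied values share a
#' rank; the minimum maps to 0 and a unique maximum to 1.
#'
#' @param values numeric vector, length >= 2 (names preserved).
#' @return percent ranks in `[0, 1]`.
#' @export
percent_rank <- function(values) {
  if (length(values) < 2) stop("need >= 2 values for percent ranks")
  (rank(values, ties.method = "min") - 1) / (length(values) - 1)
}

#' Top fraction of a gene-value vector by percent rank
#'
#' Selects genes with percent rank `>= 1 - fraction`; values tying the
#' boundary are all included.  In the degenerate heavy-tie case where no gene
#' reaches the rank threshold, the genes tying the maximum are returned.
#'
#' @param values named numeric vector (or 2-column data.frame).
#' @param fraction fraction in (0, 1].
#' @return character vector of gene ids.
#' @export
top_fraction <- function(values, fraction) {
  values <- as_gene_values(values)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  pr <- percent_rank(values)
  sel <- pr >= 1 - fraction
  if (!any(sel)) sel <- values == max(values)       # all-tied degenerate case
  boundary <- min(values[sel])
  names(values)[values >= boundary]
}

# internal: bottom counterpart (ties included), used by time-course overlaps
bottom_fraction <- function(values, fraction) {
  values <- as_gene_values(values)
  top_fraction(-values, fraction)
}

#' Percentile bins of a gene-value vector
#'
#' Divides genes into `n_bins` groups by percent rank: bin k holds genes with
#' percent rank in `[(k-1)/n_bins, k/n_bins)`, last bin closed; the bins
#' partition the gene set.  Heavy ties can leave bins empty (all-equal input
#' collapses into bin 1, with a message).
#'
#' @param values named numeric vector (or 2-column data.frame), length
#'   >= `n_bins`.
#' @param n_bins number of percentile groups (default 5).
#' @return named integer vector: gene -> bin in 1..n_bins (1 = lowest).
#' @export
bin_by_percentile <- function(values, n_bins = 5) {
  values <- as_gene_values(values)
  if (length(values) < n_bins) stop("need at least n_bins values")
  pr <- percent_rank(values)
  bin <- pmin(floor(pr * n_bins) + 1L, n_bins)
  if (length(unique(bin)) == 1 && n_bins > 1)
    message("bin_by_percentile: ties collapse all genes into one bin")
  stats::setNames(as.integer(bin), names(values))
}

#' Wilcoxon rank-sum comparison of percentile bins against a reference
#'
#' For each bin, a two-sided Wilcoxon rank-sum test of the bin's response
#' values against the reference group (all genes with response values, or
#' the bottom bin).  The normal approximation with continuity correction is
#' used except when both groups are small (<= 25) and tie-free, where the
#' exact distribution is used.
#'
#' @param bins named vector from [bin_by_percentile()].
#' @param response named numeric vector (or 2-column data.frame) of the
#'   response variable.
#' @param reference `"all"` or `"bottom"` (bin 1).
#' @return data.frame: bin, n, median, W, p_value (NA rows for skipped bins
#'   with < 2 matched genes).
#' @export
compare_bins <- function(bins, response, reference = c("all", "bottom")) {
  reference <- match.arg(reference)
  response <- as_gene_values(response)
  shared <- intersect(names(bins), names(response))
  b <- bins[shared]; y <- response[shared]
  ref <- if (reference == "all") y else y[b == 1]
  if (length(ref) < 2) stop("reference group has < 2 response values")
  levels <- sort(unique(bins))
  rows <- lapply(levels, function(k) {
    x <- y[b == k]
    if (length(x) < 2) {
      message("compare_bins: bin ", k, " has < 2 matched genes, skipped")
      return(data.frame(bin = k, n = length(x),
                        median = if (length(x)) median(x) else NA_real_,
                        W = NA_real_, p_value = NA_real_))
    }
    use_exact <- length(x) <= 25 && length(ref) <= 25 &&
      !anyDuplicated(c(x, ref))
    wt <- wilcox.test(x, ref, alternative = "two.sided",
                      exact = use_exact, correct = TRUE)
    data.frame(bin = k, n = length(x), median = median(x),
               W = unname(wt$statistic), p_value = wt$p.value)
  })
  do.call(rbind, rows)
}

#' FDR-gated correlation panel
#'
#' Correlates an enrichment vector against each table of a panel over the
#' gene-id intersection (pairwise complete), BH-adjusts the p-values across
#' the panel, and flags the correlations that meet the FDR cutoff.
#' Comparisons with fewer than 3 shared genes are reported as NA.
#'
#' @param enrichment named numeric vector (or 2-column data.frame).
#' @param panel named list of gene-value vectors/data.frames.
#' @param method `"pearson"` or `"spearman"`.
#' @param fdr_cutoff reporting gate (default 0.01).
#' @return data.frame: name, n, r, p_value, fdr, reported.
#' @export
correlation_panel <- function(enrichment, panel,
                              method = c("pearson", "spearman"),
                              fdr_cutoff = 0.01) {
  method <- match.arg(method)
  enrichment <- as_gene_values(enrichment)
  if (is.null(names(panel))) names(panel) <- paste0("table", seq_along(panel))
  rows <- lapply(names(panel), function(nm) {
    v <- as_gene_values(panel[[nm]])
    shared <- intersect(names(enrichment), names(v))
    if (length(shared) < 3)
      return(data.frame(name = nm, n = length(shared), r = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(enrichment[shared], v[shared],
                                    method = method))
    data.frame(name = nm, n = length(shared), r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_adjust(out$p_value[ok])
  out$reported <- !is.na(out$fdr) & out$fdr < fdr_cutoff
  out
}

#' Chi-square test of overlap between two gene sets
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table {in A / not} x {in B / not} over a gene universe.  Degenerate
#' margins (A or B empty or equal to the universe) give chi2 = 0, p = 1,
#' flagged.
#'
#' @param setA,setB character vectors of gene ids (subsets of `universe`).
#' @param universe character vector of all gene ids considered.
#' @param correct apply the Yates continuity correction.
#' @return object of class `ripmap_overlap`: list with universe, size_a,
#'   size_b, overlap, expected, chi2, p_value, degenerate.
#' @export
overlap_chi2 <- function(setA, setB, universe, correct = FALSE) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  N <- length(universe)
  a <- sum(setA %in% setB)                        # in both
  b <- length(setA) - a                           # A only
  c <- length(setB) - a                           # B only
  d <- N - a - b - c
  m <- c(a + b, c + d, a + c, b + d)              # margins
  degenerate <- any(m == 0)
  if (degenerate) {
    chi2 <- 0; p <- 1
  } else {
    delta <- abs(a * d - b * c)
    if (correct) delta <- max(0, delta - N / 2)
    chi2 <- N * delta^2 / prod(as.numeric(m))
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(universe = N, size_a = length(setA), size_b = length(setB),
                 overlap = a, expected = length(setA) * length(setB) / N,
                 chi2 = chi2, p_value = p, degenerate = degenerate),
            class = "ripmap_overlap")
}

#' @export
print.ripmap_overlap <- function(x, ...) {
  cat(sprintf("ripmap_overlap: %d/%d vs %d/%d, overlap %d (expected %.1f), chi2 = %.3g, p = %.3g%s\n",
              x$size_a, x$universe, x$size_b, x$universe, x$overlap,
              x$expected, x$chi2, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Overlap of a target set with expression extremes over a time course
#'
#' For each timepoint, tests the chi-square overlap of the target set
#' against the top and the bottom `fraction` of that timepoint's expression
#' values (ties included, as in [top_fraction()]).  The universe is the
#' timepoint's gene set (optionally intersected with `universe`); targets
#' outside it are dropped.
#'
#' @param targets_top character vector of target gene ids (e.g. the top
#'   10th percentile of enrichment).
#' @param expression named list of >= 2 gene-value vectors/data.frames, one
#'   per timepoint (names = timepoint labels), or the list returned by
#'   [read_gene_values()] on a multi-column table.
#' @param fraction extreme fraction per tail (default 0.1).
#' @param universe optional gene universe to intersect with each timepoint.
#' @return data.frame: time, direction ("up"/"down"), overlap, expected,
#'   chi2, p_value, neg_log10_p.
#' @export
timecourse_overlap <- function(targets_top, expression, fraction = 0.1,
                               universe = NULL) {
  if (length(expression) < 2) stop("need >= 2 timepoints")
  if (is.null(names(expression)))
    names(expression) <- paste0("t", seq_along(expression))
  rows <- lapply(names(expression), function(tp) {
    v <- as_gene_values(expression[[tp]])
    uni <- names(v)
    if (!is.null(universe)) uni <- intersect(uni, universe)
    if (length(uni) < 2) {
      message("timecourse_overlap: timepoint ", tp, " has a degenerate universe")
      return(NULL)
    }
    v <- v[uni]
    tg <- intersect(targets_top, uni)
    do.call(rbind, lapply(c(up = "up", down = "down"), function(dir) {
      ext <- if (dir == "up") top_fraction(v, fraction)
             else bottom_fraction(v, fraction)
      ov <- overlap_chi2(tg, ext, uni)
      data.frame(time = tp, direction = dir, overlap = ov$overlap,
                 expected = ov$expected, chi2 = ov$chi2,
                 p_value = ov$p_value, neg_log10_p = -log10(ov$p_value),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent IP from qPCR cycle thresholds
#'
#' `%IP = 2^(Ct_input(avg) - Ct_IP(avg))`, reported as a percentage.  Values
#' above 100% (IP apparently exceeding input) are returned with a warning.
#'
#' @param ct_input_avg,ct_ip_avg average cycle thresholds (finite, recycled).
#' @return percent IP values.
#' @export
percent_ip <- function(ct_input_avg, ct_ip_avg) {
  if (any(!is.finite(ct_input_avg)) || any(!is.finite(ct_ip_avg)))
    stop("Ct values must be finite")
  pct <- 2^(ct_input_avg - ct_ip_avg) * 100
  if (any(pct > 100))
    warning("percent_ip: IP recovery exceeds input (> 100%)")
  pct
}
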