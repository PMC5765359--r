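#' Build a pipeline run configuration
#'
#' Collects every tunable of the simulate -> count -> enrich -> call ->
#' profile -> compare pipeline, with defaults at the analysis' canonical
#' values: prior count 1, FDR < 1%, > 1 log2 enrichment in >= 2 of 3
#' replicate pairs, fourfold region cutoff (twofold for introns), > 400 nt
#' length gate for regional/composite analyses, 15-bp bins with a 6-bin
#' sliding window, top fractions 20% and 10%.  Either simulation parameters
#' or a `fixture_dir` (a directory written by [write_fixture()]) may supply
#' the inputs.
#'
#' @param ... overrides of any default listed above (unknown names error).
#' @return a `ripmap_config` list.
#' @export
ripmap_config <- function(...) {
  cfg <- list(
    # simulation
    n_genes = 2000, rrna_frac = 0.02, intron_prob = 0.05,
    length_dist = list(meanlog = log(1200), sdlog = 0.35, min = 300),
    utr_fracs = c(utr5 = 0.08, utr3 = 0.15),
    bound_frac = 0.15, enrich_logmean = log(8), enrich_logsd = 0,
    abundance_logmean = 0, abundance_logsd = 1, abundance_coupling = -2,
    rrna_abundance_mult = 20, bias3p = 0.8, window3p = 200,
    library_size_ip = 200000, library_size_mock = 200000,
    library_size_input = 200000, n_reps = 3, read_len = c(30, 50),
    mock_floor = 0.05, seed = 1,
    # input files instead of simulation
    fixture_dir = NULL,
    # analysis thresholds
    prior = 1, fdr_cutoff = 0.01, log2_cutoff = 1, min_reps = 2,
    pairing = "pooled", region_fold = 4, intron_fold = 2,
    min_gene_length = 400, region_schemes = c("utr_cds", "thirds"),
    bin_width = 15, smooth_bins = 6,
    profile_window = c(upstream = 500, downstream = 1000),
    top_fraction_go = 0.2, top_fraction_overlap = 0.1, n_bins = 5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "ripmap_config")
}

# internal: stage logger
stage_log <- function(verbose, ...) if (verbose) message("[ripmap] ", ...)

#' Run the full RIP-seq analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic simulation under
#' `config$seed`, or a fixture directory), whole-transcript counting with
#' rRNA filtering, replicate-pair enrichment and consensus target calling,
#' regional enrichment with the > 400 nt gate and fold-cutoff tallies,
#' TSS/TTS composite profiles of the pooled IP and mock reads, input RPKM,
#' and the enrichment-vs-abundance correlation.  Every table is written as
#' TSV under `outdir` together with a JSON manifest of md5 checksums;
#' re-running an identical config reproduces identical outputs.
#'
#' @param config a `ripmap_config`.
#' @param outdir output directory for tables and the manifest.
#' @param verbose log stage progress and tallies.
#' @return invisibly, a list with the in-memory objects (`annotations`,
#'   `truth`, `counts_*`, `enrichment`, `targets`, `region`, `profiles`,
#'   `rpkm`, `abundance_correlation`) plus `manifest` (path) and `files`.
#' @export
run_pipeline <- function(config = ripmap_config(), outdir = tempfile("ripmap_run_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "ripmap_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(obj, name) {
    f <- file.path(outdir, paste0(name, ".tsv"))
    write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- f
    f
  }

  # --- stage 1: inputs -------------------------------------------------
  if (!is.null(config$fixture_dir)) {
    stage_log(verbose, "loading fixture from ", config$fixture_dir)
    if (!dir.exists(config$fixture_dir))
      stop("stage inputs: fixture_dir does not exist: ", config$fixture_dir)
    annot <- read_annotation(config$fixture_dir)
    truth <- read_ground_truth(config$fixture_dir)
    read_file <- function(role, r) {
      f <- file.path(config$fixture_dir,
                     sprintf("reads_%s_%d.bed", role, r))
      if (!file.exists(f)) stop("stage inputs: missing read file ", f)
      read_reads_bed(f)
    }
    ip_reads <- lapply(seq_len(config$n_reps), function(r) read_file("ip", r))
    mock_reads <- lapply(seq_len(config$n_reps),
                         function(r) read_file("mock", r))
    input_reads <- lapply(seq_len(config$n_reps),
                          function(r) read_file("input", r))
    names(ip_reads) <- paste0("ip_", seq_len(config$n_reps))
    names(mock_reads) <- paste0("mock_", seq_len(config$n_reps))
    names(input_reads) <- paste0("input_", seq_len(config$n_reps))
  } else {
    stage_log(verbose, "simulating ", config$n_genes, " genes, seed ",
              config$seed)
    annot <- generate_transcriptome(config$n_genes, config$length_dist,
                                    config$utr_fracs, config$intron_prob,
                                    config$rrna_frac, seed = config$seed)
    truth <- generate_ground_truth(annot, config$bound_frac,
                                   config$enrich_logmean, config$enrich_logsd,
                                   config$abundance_logmean,
                                   config$abundance_logsd,
                                   config$abundance_coupling,
                                   config$rrna_abundance_mult,
                                   config$bias3p, config$window3p,
                                   seed = config$seed)
    ip_reads <- simulate_reads(annot, truth, "ip", config$library_size_ip,
                               config$n_reps, config$read_len,
                               seed = config$seed)
    mock_reads <- simulate_reads(annot, truth, "mock",
                                 config$library_size_mock, config$n_reps,
                                 config$read_len, config$mock_floor,
                                 seed = config$seed)
    input_reads <- simulate_reads(annot, truth, "input",
                                  config$library_size_input, config$n_reps,
                                  config$read_len, seed = config$seed)
  }

  # --- stage 2: whole-transcript counting ------------------------------
  stage_log(verbose, "counting whole transcripts")
  ip_counts <- filter_features(count_whole(ip_reads, annot))
  mock_counts <- filter_features(count_whole(mock_reads, annot))
  input_counts <- filter_features(count_whole(input_reads, annot))
  stage_log(verbose, sprintf("IP libraries: %s",
                             paste(ip_counts$library_size, collapse = ", ")))

  # --- stage 3: enrichment and target calling --------------------------
  stage_log(verbose, "replicate-pair enrichment (", config$pairing, ")")
  enr <- enrich_pairs(ip_counts, mock_counts, prior = config$prior,
                      pairing = config$pairing,
                      fdr_cutoff = config$fdr_cutoff,
                      log2_cutoff = config$log2_cutoff,
                      min_reps = config$min_reps)
  targets <- call_targets(enr, config$log2_cutoff, config$fdr_cutoff,
                          config$min_reps)
  stage_log(verbose, length(targets), " consensus targets")
  emit(enr, "enrichment_whole")
  emit(data.frame(gene_id = targets, stringsAsFactors = FALSE), "targets")

  # --- stage 4: regional enrichment ------------------------------------
  region <- list()
  for (scheme in config$region_schemes) {
    stage_log(verbose, "regional enrichment: ", scheme)
    fold <- if (scheme == "introns") config$intron_fold else config$region_fold
    ipr <- filter_features(count_regions(ip_reads, annot, scheme),
                           min_length = config$min_gene_length)
    mkr <- filter_features(count_regions(mock_reads, annot, scheme),
                           min_length = config$min_gene_length)
    if (nrow(ipr$counts) == 0) {
      stage_log(verbose, "  no features for scheme ", scheme, ", skipped")
      next
    }
    renr <- enrich_pairs(ipr, mkr, prior = config$prior,
                         pairing = config$pairing,
                         fdr_cutoff = config$fdr_cutoff,
                         log2_cutoff = config$log2_cutoff,
                         min_reps = config$min_reps)
    tally <- region_enrichment_tally(renr, fold)
    region[[scheme]] <- list(results = renr, tally = tally,
                             fold_cutoff = fold)
    emit(renr, paste0("enrichment_", scheme))
    emit(data.frame(kind = names(tally), n_enriched = as.integer(tally),
                    fold_cutoff = fold, stringsAsFactors = FALSE),
         paste0("tally_", scheme))
  }

  # --- stage 5: composite profiles -------------------------------------
  stage_log(verbose, "composite profiles")
  pool <- function(lst) do.call(rbind, lst)
  profiles <- list()
  for (role in c("ip", "mock")) {
    rd <- pool(if (role == "ip") ip_reads else mock_reads)
    lib <- sum(if (role == "ip") ip_counts$library_size
               else mock_counts$library_size)
    for (anc in c("tss", "tts")) {
      pr <- composite_profile(rd, annot, anc, config$profile_window,
                              config$min_gene_length, library_size = lib,
                              bin_width = config$bin_width,
                              smooth_bins = config$smooth_bins)
      profiles[[paste0(role, "_", anc)]] <- pr
      emit(data.frame(bin_offset = pr$bin_offsets, density = pr$values),
           paste0("profile_", role, "_", anc))
    }
  }

  # --- stage 6: comparative summaries ----------------------------------
  stage_log(verbose, "comparative summaries")
  rpkm <- compute_rpkm(input_counts$counts,
                       input_counts$meta$gene_length,
                       input_counts$library_size)
  ab_cor <- cor(enr$combined_log2, log(rpkm[enr$feature_id]),
                use = "complete.obs")
  emit(data.frame(gene_id = names(rpkm), rpkm = unname(rpkm)), "input_rpkm")
  pr_enr <- percent_rank(stats::setNames(enr$combined_log2, enr$feature_id))
  emit(data.frame(gene_id = names(pr_enr), percent_rank = unname(pr_enr),
                  bin = unname(bin_by_percentile(
                    stats::setNames(enr$combined_log2, enr$feature_id),
                    config$n_bins))),
       "percent_ranks")

  # --- manifest ---------------------------------------------------------
  manifest <- list(package = "ripmap",
                   version = as.character(utils::packageVersion("ripmap")),
                   seed = config$seed,
                   n_targets = length(targets),
                   abundance_correlation = ab_cor,
                   files = lapply(files, function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(annotations = annot, truth = truth,
                 counts_ip = ip_counts, counts_mock = mock_counts,
                 counts_input = input_counts,
                 enrichment = enr, targets = targets, region = region,
                 profiles = profiles, rpkm = rpkm,
                 abundance_correlation = ab_cor,
                 manifest = manifest_path, files = files, outdir = outdir))
}

#' Compare a pipeline run against synthetic ground truth
#'
#' Scores the called targets against the simulated bound set (sensitivity,
#' precision, empirical FDR) and reports the recovery of the simulated
#' enrichment structure: Pearson correlation of combined log2 enrichment
#' with log ground-truth abundance and, over bound genes, with the log
#' enrichment factor.
#'
#' @param run the list returned by [run_pipeline()].
#' @param truth a `ripmap_truth` (defaults to the run's own).
#' @return a list: n_called, n_bound, true_positives, sensitivity,
#'   precision, empirical_fdr, cor_log2_vs_log_abundance,
#'   cor_log2_vs_log_factor_bound.
#' @export
validate_run <- function(run, truth = run$truth) {
  stopifnot(inherits(truth, "ripmap_truth"))
  enr <- run$enrichment
  if (!all(enr$gene_id %in% names(truth$abundance)))
    stop("truth does not cover the genes in the run manifest")
  called <- run$targets
  bound <- truth$bound
  tp <- length(intersect(called, bound))
  sens <- if (length(bound)) tp / length(bound) else NA_real_
  prec <- if (length(called)) tp / length(called) else NA_real_
  lg <- stats::setNames(enr$combined_log2, enr$gene_id)
  bg <- intersect(names(lg), bound)
  list(n_called = length(called), n_bound = length(bound),
       true_positives = tp, sensitivity = sens, precision = prec,
       empirical_fdr = if (length(called)) 1 - prec else 0,
       cor_log2_vs_log_abundance =
         cor(lg, log(truth$abundance[names(lg)])),
       cor_log2_vs_log_factor_bound =
         if (length(bg) >= 3 && stats::sd(truth$factor[bg]) > 0)
           cor(lg[bg], log(truth$factor[bg])) else NA_real_)
}
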