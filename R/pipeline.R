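# End-to-end orchestration over a sample manifest.

# TSV writer stamping provenance (config hash + seed) as a comment header
write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", prov$hash, prov$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_manifest_checked <- function(manifest) {
  manifest <- as.data.frame(manifest)
  need <- c("sample_id", "biopsy_type", "patient_id", "er_status", "matrix_path")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id)) stopf("sample ids must be unique")
  ok_types <- c("healthy", "primary", "liver_met", "pleural_effusion")
  if (!all(manifest$biopsy_type %in% ok_types))
    stopf("biopsy_type must be one of: %s", paste(ok_types, collapse = ", "))
  for (p in manifest$matrix_path)
    if (!file.exists(paste0(p, ".bins.tsv"))) stopf("matrix not found: %s", p)
  manifest
}

#' Run the full analysis pipeline over a sample manifest
#'
#' Reads and balances every sample's matrix, then runs insulation/TAD
#' calling, compartment scoring (with cross-sample sign synchronisation
#' against the first sample), saddle/compartment strength, copy-number
#' estimation, translocation detection, the pairwise comparison tables
#' (insulation and compartment-score R-squared, boundary Jaccard matrix,
#' compartment dissimilarity and variance-explained matrices, consistent
#' delta-insulation regions), PE-SCAn for samples with peaks, and the
#' boundary-ubiquity enrichment test when peak datasets are supplied.
#' Failing stages are isolated and recorded; the pipeline continues.
#'
#' @param manifest data frame with columns `sample_id`, `biopsy_type`
#'   (healthy / primary / liver_met / pleural_effusion), `patient_id`,
#'   `er_status` (`"+"` or `"-"`), `matrix_path` (prefix for
#'   [read_matrix()]), optional `peak_path` (BED).
#' @param out_dir output directory (created).
#' @param config list of options: `seed` (default 1), `gc_path` (bedGraph of
#'   GC per bin; required for compartment scoring), `tracks_path` (TSV of
#'   per-bin covariates for CNV), `centromeres` (data frame), `window_bins`,
#'   `saddle_Q`, `n_boot`, `tile_size`, `trans_gain`, `delta_threshold`,
#'   `delta_min_bins`, `peak_datasets` (named list of BED paths),
#'   `stages` (character subset to run).
#' @return (invisibly) a report list; files are written under `out_dir`.
#' @export
run_pipeline <- function(manifest, out_dir, config = list()) {
  manifest <- read_manifest_checked(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- utils::modifyList(list(
    seed = 1, gc_path = NULL, tracks_path = NULL, centromeres = NULL,
    window_bins = 25, saddle_Q = 50, n_boot = 1000, tile_size = 1e6,
    trans_gain = 10, delta_threshold = 0.25, delta_min_bins = 10,
    peak_datasets = NULL,
    stages = c("insulation", "compartments", "cnv", "trans", "compare",
               "pescan", "boundary_enrich")), config)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg[order(names(cfg))], cfg_file, auto_unbox = TRUE,
                       force = TRUE)
  prov <- list(hash = unname(tools::md5sum(cfg_file)), seed = cfg$seed)
  report <- list(config_hash = prov$hash, seed = cfg$seed, samples = list(),
                 skipped = character())
  log_skip <- function(what, e) {
    msg <- sprintf("%s: %s", what, conditionMessage(e))
    report$skipped <<- c(report$skipped, msg)
    message("pipeline: stage skipped — ", msg)
  }

  samples <- manifest$sample_id
  mats <- list(); is_tracks <- list(); bsets <- list(); cscores <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- samples[i]
    m <- read_matrix(manifest$matrix_path[i])
    if (is.null(m$weights)) m <- balance(m)
    mats[[id]] <- m
  }
  bins <- mats[[1]]$bins
  gc <- if (!is.null(cfg$gc_path)) read_bedgraph(cfg$gc_path, bins)
  arms <- split_arms(bins, cfg$centromeres)

  for (id in samples) {
    m <- mats[[id]]
    if ("insulation" %in% cfg$stages) tryCatch({
      tr <- insulation(m, window_bins = cfg$window_bins)
      is_tracks[[id]] <- tr
      bs <- call_boundaries(tr)
      bsets[[id]] <- bs
      write_bedgraph(bins, tr$score, file.path(out_dir, paste0(id, ".is.bedgraph")))
      write_tsv_prov(bs$boundaries, file.path(out_dir, paste0(id, ".boundaries.tsv")), prov)
      write_tsv_prov(bs$tads, file.path(out_dir, paste0(id, ".tads.tsv")), prov)
    }, error = function(e) log_skip(paste0(id, "/insulation"), e))
    if ("compartments" %in% cfg$stages && !is.null(gc)) tryCatch({
      ref <- if (length(cscores)) cscores[[1]]
      cs <- compartment_score(m, gc, reference = ref, arms = arms)
      cscores[[id]] <- cs
      write_bedgraph(bins, cs$score, file.path(out_dir, paste0(id, ".cs.bedgraph")))
      sd_ <- saddle(m, cs, Q = cfg$saddle_Q)
      st <- compartment_strength(sd_, n_boot = cfg$n_boot,
                                 seed = child_seed(cfg$seed, match(id, samples)))
      write_tsv_prov(data.frame(sample = id, strength = st$strength,
                                boot_lo = stats::quantile(st$bootstrap, 0.025),
                                boot_hi = stats::quantile(st$bootstrap, 0.975)),
                     file.path(out_dir, paste0(id, ".strength.tsv")), prov)
    }, error = function(e) log_skip(paste0(id, "/compartments"), e))
    if ("cnv" %in% cfg$stages && !is.null(cfg$tracks_path)) tryCatch({
      tracks <- utils::read.table(cfg$tracks_path, header = TRUE, sep = "\t")
      tiles <- tile_coverage(m, tracks, tile_size = cfg$tile_size)
      tiles <- normalise_coverage(tiles)
      seg <- segment_cnv(tiles, seed = child_seed(cfg$seed, 11))
      write_tsv_prov(seg$segments, file.path(out_dir, paste0(id, ".cnv_segments.tsv")), prov)
    }, error = function(e) log_skip(paste0(id, "/cnv"), e))
    if ("trans" %in% cfg$stages) tryCatch({
      cand <- detect_translocations(m, gain = cfg$trans_gain,
                                    seed = child_seed(cfg$seed, 13))
      write_tsv_prov(cand, file.path(out_dir, paste0(id, ".trans_candidates.tsv")), prov)
    }, error = function(e) log_skip(paste0(id, "/trans"), e))
    if ("pescan" %in% cfg$stages) {
      pk_path <- if ("peak_path" %in% names(manifest))
        manifest$peak_path[manifest$sample_id == id] else NA
      if (!is.na(pk_path) && nzchar(pk_path) && file.exists(pk_path)) tryCatch({
        clusters <- call_clusters(read_bed(pk_path))
        ps <- pe_scan(m, clusters, n_boot = cfg$n_boot,
                      seed = child_seed(cfg$seed, 17))
        write_tsv_prov(data.frame(sample = id, n_pairs = ps$n_pairs,
                                  enrichment = ps$enrichment),
                       file.path(out_dir, paste0(id, ".pescan.tsv")), prov)
      }, error = function(e) log_skip(paste0(id, "/pescan"), e))
      else report$skipped <- c(report$skipped,
                               sprintf("%s/pescan: no peak file", id))
    }
  }

  if ("compare" %in% cfg$stages && length(samples) > 1) tryCatch({
    n <- length(samples)
    r2 <- function(x, y) {
      sh <- !is.na(x) & !is.na(y)
      if (sum(sh) < 3) return(NA_real_)
      stats::cor(x[sh], y[sh])^2
    }
    mk <- function(f) {
      mm <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
      for (i in 1:n) for (j in 1:n) mm[i, j] <- f(samples[i], samples[j])
      mm
    }
    if (length(is_tracks) == n) {
      is_r2 <- mk(function(a, b) r2(is_tracks[[a]]$score, is_tracks[[b]]$score))
      write_tsv_prov(as.data.frame(is_r2), file.path(out_dir, "is_r2.tsv"), prov)
      pairs <- utils::combn(samples, 2, simplify = FALSE)
      dpairs <- lapply(pairs, function(p)
        list(is_tracks[[p[1]]]$score, is_tracks[[p[2]]]$score))
      dreg <- delta_region_finder(dpairs, bins, threshold = cfg$delta_threshold,
                                  min_bins = cfg$delta_min_bins)
      write_tsv_prov(dreg, file.path(out_dir, "delta_is_regions.tsv"), prov)
    }
    if (length(bsets) == n) {
      ji <- mk(function(a, b) boundary_jaccard(bsets[[a]], bsets[[b]]))
      write_tsv_prov(as.data.frame(ji), file.path(out_dir, "jaccard.tsv"), prov)
    }
    if (length(cscores) == n) {
      cs_r2 <- mk(function(a, b) r2(cscores[[a]]$score, cscores[[b]]$score))
      write_tsv_prov(as.data.frame(cs_r2), file.path(out_dir, "cs_r2.tsv"), prov)
      dis <- mk(function(a, b) compartment_dissimilarity(cscores[[a]], cscores[[b]]))
      write_tsv_prov(as.data.frame(dis), file.path(out_dir, "dissimilarity.tsv"), prov)
      ve <- mk(function(a, b) compartment_variance_explained(cscores[[a]], cscores[[b]]))
      write_tsv_prov(as.data.frame(ve), file.path(out_dir, "variance_explained.tsv"), prov)
    }
  }, error = function(e) log_skip("compare", e))

  if ("boundary_enrich" %in% cfg$stages && !is.null(cfg$peak_datasets) &&
      length(bsets) >= 2) tryCatch({
    ub <- build_ubiquity_sets(unname(bsets))
    pks <- lapply(cfg$peak_datasets, read_bed)
    et <- enrichment_test(ub, pks)
    write_tsv_prov(et, file.path(out_dir, "boundary_enrichment.tsv"), prov)
  }, error = function(e) log_skip("boundary_enrich", e))

  report$samples <- as.list(samples)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, force = TRUE)
  invisible(report)
}
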