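# Shared fixtures: tiny deterministic matrices and simulation specs.

# contact matrix with explicit dense cis counts on one chromosome
dense_to_matrix <- function(counts, bin_size = 1e5, chrom = "chr1",
                            weights = rep(1, nrow(counts))) {
  n <- nrow(counts)
  bins <- data.frame(chrom = chrom, start = (0:(n - 1)) * bin_size,
                     end = (1:n) * bin_size)
  ut <- which(upper.tri(counts, diag = TRUE) & counts != 0, arr.ind = TRUE)
  px <- data.frame(bin1 = ut[, 1], bin2 = ut[, 2], count = counts[ut])
  contact_matrix(bins, px, resolution = bin_size, weights = weights)
}

# uniform off-diagonal matrix (constant rows)
uniform_matrix <- function(n = 30, value = 10, bin_size = 1e5) {
  counts <- matrix(value, n, n)
  dense_to_matrix(counts, bin_size)
}

# small genome with planted TAD boundaries at 20 kb
tad_spec <- function(depths = rep(0.6, 16), seed = 5, size = 20e6) {
  pos <- seq(50, 950, length.out = length(depths))
  synthetic_spec(c(chr1 = size), 2e4, depth = 8e6, seed = seed,
                 tads = list(boundaries = list(chr1 = data.frame(
                   bin = round(pos), depth = depths))))
}

# spec with regularly spaced cis cluster pairs for pile-up tests
cluster_spec <- function(e, seed = 7, size = 30e6, spacing = 4e6) {
  anch <- seq(2e6, size - 2e6, by = spacing)
  pairs <- t(utils::combn(anch, 2))
  pairs <- pairs[pairs[, 2] - pairs[, 1] > 3e6, , drop = FALSE]
  cp <- data.frame(chrom1 = "chr1", start1 = pairs[, 1] - 1e4,
                   end1 = pairs[, 1] + 1e4,
                   chrom2 = "chr1", start2 = pairs[, 2] - 1e4,
                   end2 = pairs[, 2] + 1e4, factor = e)
  synthetic_spec(c(chr1 = size), 2e4, depth = 1.5e7, seed = seed,
                 cluster_pairs = cp)
}

# study conditions for the translocation caller: moderate compartments,
# deep trans coverage, one planted corner
trans_spec <- function(seed, translocated = TRUE) {
  tl <- if (translocated)
    data.frame(chromA = "chr1", posA = 30e6, chromB = "chr2", posB = 40e6,
               orientation = "++")
  synthetic_spec(c(chr1 = 60e6, chr2 = 60e6), 5e5, depth = 2.4e7, seed = seed,
                 compartments = list(block_size = 5e6, strength = 0.5),
                 translocations = tl)
}

# BoundarySet from raw positions (for similarity/ubiquity tests)
boundary_set <- function(pos, chrom = "chr1") {
  structure(list(
    boundaries = data.frame(chrom = rep(chrom, length(pos)),
                            bin = rep(NA_integer_, length(pos)), pos = pos,
                            strength = rep(1, length(pos))),
    tads = data.frame(chrom = character(), start = numeric(), end = numeric())),
    class = "BoundarySet")
}

# two-sample manifest over one simulated genome, for pipeline runs
setup_run <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  spec <- synthetic_spec(c(chr1 = 20e6, chr2 = 20e6), 1e5, depth = 6e6,
                         seed = 5,
                         compartments = list(block_size = 2e6, strength = 0.7),
                         tads = list(spacing = 1e6, depth = 0.5))
  sim <- simulate_matrix(spec)
  tracks <- simulate_tracks(spec)
  for (id in c("s1", "s2"))
    write_matrix(sim$matrix, file.path(root, id))
  write_bedgraph(spec$bins, tracks$gc, file.path(root, "gc.bedgraph"))
  write.table(tracks, file.path(root, "tracks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    sample_id = c("s1", "s2"),
    biopsy_type = c("primary", "liver_met"),
    patient_id = "P01", er_status = "-",
    matrix_path = file.path(root, c("s1", "s2")))
  list(manifest = manifest,
       config = list(seed = 7, gc_path = file.path(root, "gc.bedgraph"),
                     tracks_path = file.path(root, "tracks.tsv"),
                     window_bins = 10, saddle_Q = 20, n_boot = 100))
}
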