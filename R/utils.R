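# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed, kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write a per-bin track as bedGraph
#'
#' @param bins bin table (`chrom`, `start`, `end`), 0-based half-open.
#' @param values numeric vector, one value per bin; `NA` bins are skipped.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path) {
  stopifnot(nrow(bins) == length(values))
  keep <- !is.na(values)
  df <- data.frame(chrom = bins$chrom[keep], start = bins$start[keep],
                   end = bins$end[keep], value = format(values[keep], digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track onto a bin table
#'
#' Values are matched to bins by exact (chrom, start) coordinates; bins
#' without a record get `NA`.
#'
#' @param path bedGraph file.
#' @param bins bin table to align to.
#' @return numeric vector, one value per bin.
#' @export
read_bedgraph <- function(path, bins) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  key <- paste(bins$chrom, bins$start)
  values <- df$value[match(key, paste(df$chrom, df$start))]
  values
}

#' Write peaks as BED
#' @param peaks data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  name <- peaks$name %||% paste0("peak_", seq_len(nrow(peaks)))
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of peaks
#' @param path BED file (first three columns used; optional fourth = name).
#' @return data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  out <- data.frame(chrom = df[[1]], start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    name = if (ncol(df) >= 4) df[[4]] else NA_character_)
  out
}
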