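# Evaluation quantities: percent space saving and the fraction of a file
# occupied by flow signals.

round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Space saving of a compressed file
#'
#' `space saving = 1 - compressed / uncompressed`; reported both as a
#' fraction and as a percentage.  Negative values (expansion) are allowed
#' and reported as such.
#'
#' @param compressed_bytes,uncompressed_bytes sizes in the same unit;
#'   `uncompressed_bytes` must be positive.
#' @return list with `fraction` and `percent`.
#' @export
space_saving <- function(compressed_bytes, uncompressed_bytes) {
  if (any(uncompressed_bytes <= 0)) {
    stop("domain error: uncompressed size must be positive")
  }
  fraction <- 1 - compressed_bytes / uncompressed_bytes
  list(fraction = fraction, percent = 100 * fraction)
}

#' Fraction of a file occupied by flow signals
#'
#' `100 * flow_bytes / total_bytes`, rounded half away from zero to one
#' decimal for reporting.  The convention for measuring `flow_bytes` in a
#' container file is `size(file) - size(same file with ZM stripped, same
#' codec and settings)`; see [flow_content()].
#'
#' @param flow_bytes,total_bytes sizes in the same unit; `total_bytes` must
#'   be positive.
#' @return percentage rounded to one decimal.
#' @export
flow_fraction <- function(flow_bytes, total_bytes) {
  if (any(total_bytes <= 0)) {
    stop("domain error: total size must be positive")
  }
  round_half_away(100 * flow_bytes / total_bytes, 1L)
}

#' Measure the flow-signal content of a BAM file
#'
#' Strips the ZM tags, rewrites the file with the same codec, and reports
#' the size difference as the flow-signal share of the file.
#'
#' @param bam_path a BAM (or SAM) file.
#' @return list with `total_bytes`, `stripped_bytes`, `flow_bytes` and
#'   `percent` (one-decimal flow fraction).
#' @export
flow_content <- function(bam_path) {
  recset <- read_records(bam_path)
  sp <- strip_flow_signals(recset)
  fmt <- if (grepl("\\.sam$", bam_path, ignore.case = TRUE)) "sam" else "bam"
  tmp <- tempfile(fileext = paste0(".", fmt))
  on.exit(unlink(tmp))
  write_records(sp$body, tmp, format = fmt)
  total <- file.size(bam_path)
  stripped <- file.size(tmp)
  list(total_bytes = total, stripped_bytes = stripped,
       flow_bytes = total - stripped,
       percent = flow_fraction(total - stripped, total))
}

#' Component sizes of an archive
#'
#' Lists the manifest-described components of an archive with their byte
#' sizes, plus the percent space saving relative to the recorded source
#' BAM size.
#'
#' @param archive_path archive written by [compress_archive()].
#' @return list with `components` (data.table of name and bytes),
#'   `archive_bytes`, `source_bytes` and `percent_saving`.
#' @export
archive_stats <- function(archive_path) {
  staging <- tempfile("flowcram_stats_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE))
  utils::untar(archive_path, exdir = staging)
  manifest <- read_manifest(staging)
  files <- c("manifest.json", names(manifest$checksums))
  comp <- data.table(component = files,
                     bytes = as.numeric(file.size(file.path(staging, files))))
  list(components = comp,
       archive_bytes = as.numeric(file.size(archive_path)),
       source_bytes = manifest$source_bytes,
       percent_saving = space_saving(file.size(archive_path),
                                     manifest$source_bytes)$percent)
}
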