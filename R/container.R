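# End-to-end orchestration and the on-disk archive layout: a tar container
# holding manifest.json, the flow-free body (CRAM when samtools and a
# reference genome are available, otherwise the backend-compressed BAM),
# the compressed flow-signal chunks, and the stored permutation that
# restores original record order.

FORMAT_VERSION <- 1L

samtools_binary <- function() {
  s <- Sys.which("samtools")
  if (nzchar(s)) s else NULL
}

tar_binary <- function() {
  t <- Sys.which("tar")
  if (nzchar(t)) t else NULL
}

# deterministic tar: fixed mtime/owner, members in the given order
make_tar <- function(out_path, staging, files) {
  tb <- tar_binary()
  if (!is.null(tb)) {
    status <- system2(tb, c("--format=pax",
                            "--pax-option=exthdr.name=%d/PaxHeaders/%f,delete=atime,delete=ctime,delete=mtime",
                            "--owner=0", "--group=0", "--numeric-owner",
                            "--mtime=@0",
                            "-cf", shQuote(out_path), "-C", shQuote(staging),
                            files))
    if (status != 0L) stop("tar failed with status ", status)
  } else {
    epoch <- as.POSIXct("1970-01-01", tz = "UTC")
    for (f in files) Sys.setFileTime(file.path(staging, f), epoch)
    owd <- setwd(staging); on.exit(setwd(owd))
    utils::tar(out_path, files = files, compression = "none",
               tar = "internal")
  }
  invisible(out_path)
}

encode_permutation <- function(perm) {
  varint_encode(zigzag(diff(c(0, perm))))
}

decode_permutation <- function(bytes) {
  as.integer(cumsum(unzigzag(varint_decode_all(bytes))))
}

backend_ext <- function(spec) {
  switch(spec$algorithm, gzip = "gz", xz = "xz", zstd = "zst")
}

#' Compress an Ion Torrent BAM into a flow-signal archive
#'
#' Runs the full pipeline: read the BAM, strip the ZM flow-signal tags from
#' every record, sort reads by (contig, position, strand, CIGAR), group
#' same-locus reads into blocks, delta-encode each block's flow vectors,
#' serialize and backend-compress the blocks in chunks, convert the
#' flow-free body to CRAM (via samtools, when a reference is given) or
#' backend-compress it directly, and pack everything with a JSON manifest
#' into a single tar archive.  Lossless by default; pass `bin` for the
#' explicitly lossy binning mode.
#'
#' @param bam_path input BAM or SAM file.
#' @param out_path output archive path.
#' @param backend `"xz"` (default), `"gzip"` or `"zstd"`.
#' @param level compression level; default is the backend's maximum.
#' @param strategy flow reference strategy, `"first"` (chained deltas,
#'   default) or `"median"`.
#' @param max_block_size maximum reads per block (default 65535).
#' @param bin optional positive integer bin width; when given, flow values
#'   are lossily binned (`ceiling(y/x)*x`, negatives to 0) before encoding.
#' @param keep_order keep a stored permutation so decompression restores
#'   original record order (default TRUE).
#' @param reference optional reference FASTA for a CRAM body.
#' @param body_codec `"auto"` (CRAM if possible), `"cram"` or `"bam"`.
#' @param chunk_bytes target uncompressed chunk size for the flow stream
#'   (default 16 MiB).
#' @param quiet suppress the component-size log (default TRUE).
#' @return the manifest, invisibly (class `flowcram_manifest`).
#' @export
compress_archive <- function(bam_path, out_path,
                             backend = "xz", level = NULL,
                             strategy = c("first", "median"),
                             max_block_size = 65535L,
                             bin = NULL,
                             keep_order = TRUE,
                             reference = NULL,
                             body_codec = c("auto", "cram", "bam"),
                             chunk_bytes = 16L * 1024L^2,
                             quiet = TRUE) {
  strategy <- match.arg(strategy)
  body_codec <- match.arg(body_codec)
  spec <- backend_spec(backend, level)
  if (!is.null(bin)) stopifnot(length(bin) == 1L, bin >= 1)

  recset <- read_records(bam_path)
  sp <- strip_flow_signals(recset)
  so <- sort_records(recset)
  blocks <- build_blocks(recset, so$sorted_order, max_block_size)

  flow_row <- match(recset$records$original_index, sp$flows$read_index)

  staging <- tempfile("flowcram_staging_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  # --- flow chunks ---
  ext <- backend_ext(spec)
  chunk_index <- list()
  pending <- list()
  pending_bytes <- 0L
  pending_first <- 0L
  n_chunks <- 0L
  flush_chunk <- function() {
    if (length(pending) == 0L) return(invisible())
    payload <- unlist(pending, use.names = FALSE)
    fname <- sprintf("flows_%04d.%s", n_chunks, ext)
    writeBin(compress_bytes(payload, spec), file.path(staging, fname))
    chunk_index[[length(chunk_index) + 1L]] <<- list(
      file = fname, first_block = pending_first,
      block_count = length(pending))
    n_chunks <<- n_chunks + 1L
    pending_first <<- pending_first + length(pending)
    pending <<- list()
    pending_bytes <<- 0L
    invisible()
  }
  for (b in blocks) {
    rows <- b$rows
    fr <- flow_row[rows]
    vectors <- lapply(fr, function(r) {
      if (is.na(r)) NULL else sp$flows$values[[r]]
    })
    present <- !is.na(fr)
    if (!is.null(bin)) vectors <- bin_vectors(vectors, bin)
    enc <- encode_block(vectors, strategy = strategy,
                        subtypes = sp$flows$subtype[fr[present]],
                        tag_pos = sp$flows$tag_pos[fr[present]])
    ser <- serialize_block(enc)
    pending[[length(pending) + 1L]] <- ser
    pending_bytes <- pending_bytes + length(ser)
    if (pending_bytes >= chunk_bytes) flush_chunk()
  }
  flush_chunk()

  # --- body ---
  body <- sp$body
  if (!keep_order) {
    body <- structure(list(header = body$header,
                           records = body$records[so$sorted_order]),
                      class = "flowcram_records")
  }
  body_bam <- file.path(staging, "body_plain.bam")
  write_records(body, body_bam, format = "bam")
  sam <- samtools_binary()
  use_cram <- switch(body_codec,
    cram = TRUE,
    bam = FALSE,
    auto = !is.null(reference) && !is.null(sam)
  )
  ref_info <- NULL
  if (use_cram && (is.null(sam) || is.null(reference))) {
    warning("CRAM body requested but ", if (is.null(sam)) "samtools" else
            "a reference FASTA", " is unavailable; falling back to ",
            "backend-compressed BAM body")
    use_cram <- FALSE
  }
  if (use_cram) {
    body_file <- "body.cram"
    status <- system2(sam, c("view", "-C", "--no-PG",
                             "-T", shQuote(reference),
                             "--output-fmt-option", "level=9",
                             "--output-fmt-option", "use_lzma=1",
                             "-o", shQuote(file.path(staging, body_file)),
                             shQuote(body_bam)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      warning("samtools CRAM conversion failed (status ", status,
              "); falling back to backend-compressed BAM body")
      use_cram <- FALSE
    } else {
      ref_info <- list(name = basename(reference),
                       md5 = unname(tools::md5sum(reference)))
    }
  }
  if (!use_cram) {
    body_file <- paste0("body.bam.", ext)
    writeBin(compress_bytes(read_all_bytes(body_bam), spec),
             file.path(staging, body_file))
  }
  unlink(body_bam)

  # --- permutation ---
  perm_file <- NULL
  if (keep_order) {
    perm_file <- "permutation.bin"
    writeBin(compress_bytes(encode_permutation(so$permutation), spec),
             file.path(staging, perm_file))
  }

  # --- manifest ---
  comp_files <- c(body_file, vapply(chunk_index, `[[`, character(1), "file"),
                  perm_file)
  sums <- tools::md5sum(file.path(staging, comp_files))
  names(sums) <- comp_files
  manifest <- list(
    format = "flowcram",
    format_version = FORMAT_VERSION,
    backend = list(algorithm = spec$algorithm, level = spec$level),
    strategy = strategy,
    body_codec = if (use_cram) "external_cram" else "fallback_bam",
    body_file = body_file,
    chunk_index = chunk_index,
    block_count = length(blocks),
    permutation_present = keep_order,
    permutation_file = perm_file,
    binning = if (is.null(bin)) NULL else list(x = as.integer(bin)),
    max_block_size = as.integer(max_block_size),
    source_record_count = nrow(recset$records),
    source_header = recset$header,
    source_bytes = as.numeric(file.size(bam_path)),
    reference = ref_info,
    checksums = as.list(sums)
  )
  class(manifest) <- "flowcram_manifest"
  jsonlite::write_json(unclass(manifest), file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)

  members <- c("manifest.json", comp_files)
  ok <- FALSE
  tryCatch({
    make_tar(out_path, staging, members)
    ok <- TRUE
  }, finally = if (!ok && file.exists(out_path)) unlink(out_path))

  if (!quiet) {
    sizes <- file.size(file.path(staging, members))
    for (i in seq_along(members)) {
      message(sprintf("  %-24s %10.0f bytes", members[i], sizes[i]))
    }
    message(sprintf("archive: %s (%.0f bytes, %.2f%% space saving vs source)",
                    out_path, file.size(out_path),
                    space_saving(file.size(out_path),
                                 file.size(bam_path))$percent))
  }
  invisible(manifest)
}

read_manifest <- function(staging) {
  mpath <- file.path(staging, "manifest.json")
  if (!file.exists(mpath)) {
    stop("corruption error: archive has no manifest.json")
  }
  m <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (!identical(m$format, "flowcram")) {
    stop("corruption error: not a flowcram archive")
  }
  if (!identical(as.integer(m$format_version), FORMAT_VERSION)) {
    stop("unsupported archive format version ", m$format_version,
         " (this build reads version ", FORMAT_VERSION, ")")
  }
  class(m) <- "flowcram_manifest"
  m
}

#' Decompress a flow-signal archive back to BAM
#'
#' Verifies every component checksum, then reverses the pipeline: the body
#' is decoded (CRAM via samtools, or the backend-compressed BAM), the flow
#' chunks are decompressed, deserialized and delta-decoded, and each flow
#' vector is re-inserted as a ZM tag at its original tag position.  With a
#' stored permutation the output reproduces the source record order
#' exactly; otherwise records come out in sorted order.
#'
#' @param archive_path archive written by [compress_archive()].
#' @param out_bam_path output BAM (or `.sam`) path.
#' @param reference reference FASTA, required when the body is CRAM.
#' @return number of records written, equal to the manifest's
#'   `source_record_count`.
#' @export
decompress_archive <- function(archive_path, out_bam_path, reference = NULL) {
  staging <- tempfile("flowcram_unpack_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  utils::untar(archive_path, exdir = staging)
  manifest <- read_manifest(staging)
  spec <- backend_spec(manifest$backend$algorithm, manifest$backend$level)

  # integrity first: no output is written unless every digest matches
  for (f in names(manifest$checksums)) {
    path <- file.path(staging, f)
    if (!file.exists(path)) {
      stop("corruption error: archive component '", f, "' is missing")
    }
    got <- unname(tools::md5sum(path))
    if (!identical(got, manifest$checksums[[f]])) {
      stop("corruption error: checksum mismatch for archive component '",
           f, "'")
    }
  }

  # --- flow blocks ---
  encs <- vector("list", manifest$block_count)
  for (ci in manifest$chunk_index) {
    payload <- decompress_bytes(
      read_all_bytes(file.path(staging, ci$file)), spec)
    blocks <- deserialize_blocks(payload, ci$block_count)
    encs[ci$first_block + seq_len(ci$block_count)] <- blocks
  }

  # --- body ---
  if (identical(manifest$body_codec, "external_cram")) {
    sam <- samtools_binary()
    if (is.null(sam)) {
      stop("samtools is required to decode the CRAM body of this archive")
    }
    if (is.null(reference)) {
      stop("this archive has a CRAM body; pass the reference FASTA (",
           manifest$reference$name, ", md5 ", manifest$reference$md5, ")")
    }
    if (!identical(unname(tools::md5sum(reference)),
                   manifest$reference$md5)) {
      warning("reference FASTA digest differs from the one recorded in the ",
              "manifest; decoded body may be wrong")
    }
    body_bam <- file.path(staging, "body_plain.bam")
    status <- system2(sam, c("view", "-b", "--no-PG",
                             "--input-fmt-option", "decode_md=0",
                             "-T", shQuote(reference),
                             "-o", shQuote(body_bam),
                             shQuote(file.path(staging, manifest$body_file))),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      stop("corruption error: samtools failed to decode the CRAM body")
    }
  } else {
    body_bam <- file.path(staging, "body_plain.bam")
    writeBin(decompress_bytes(
      read_all_bytes(file.path(staging, manifest$body_file)), spec),
      body_bam)
  }
  body <- read_records(body_bam)
  # CRAM/BAM conversion may annotate the header (@SQ M5/UR); the manifest
  # carries the source header verbatim
  if (!is.null(manifest$source_header)) {
    body$header <- unlist(manifest$source_header, use.names = FALSE)
  }
  n <- nrow(body$records)
  if (n != manifest$source_record_count) {
    stop("corruption error: body holds ", n, " records but the manifest ",
         "promises ", manifest$source_record_count)
  }

  # --- permutation: sorted rank -> original index ---
  if (isTRUE(manifest$permutation_present)) {
    perm <- decode_permutation(decompress_bytes(
      read_all_bytes(file.path(staging, manifest$permutation_file)), spec))
    invert_permutation(perm)  # validates bijection
  } else {
    perm <- seq_len(n) - 1L   # body already in sorted order
  }
  if (length(perm) != n) {
    stop("corruption error: permutation length ", length(perm),
         " does not match record count ", n)
  }

  # --- reassemble flow table in sorted-rank order ---
  idx_l <- vector("list", length(encs))
  val_l <- vector("list", length(encs))
  sub_l <- vector("list", length(encs))
  pos_l <- vector("list", length(encs))
  rank0 <- 0L
  for (bi in seq_along(encs)) {
    enc <- encs[[bi]]
    vecs <- decode_block(enc)
    pres <- enc$presence
    idx_l[[bi]] <- perm[rank0 + which(pres)]
    val_l[[bi]] <- vecs[pres]
    sub_l[[bi]] <- enc$subtypes
    pos_l[[bi]] <- enc$tag_pos
    rank0 <- rank0 + length(pres)
  }
  if (rank0 != n) {
    stop("corruption error: blocks cover ", rank0, " records, expected ", n)
  }
  flows <- data.table(
    read_index = as.integer(unlist(idx_l, use.names = FALSE) %||% integer(0)),
    tag_pos = as.integer(unlist(pos_l, use.names = FALSE) %||% integer(0)),
    subtype = as.character(unlist(sub_l, use.names = FALSE) %||% character(0)),
    values = do.call(c, c(val_l, list(list())))
  )
  restored <- reattach_flow_signals(body, flows)
  write_records(restored, out_bam_path)
  n
}
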