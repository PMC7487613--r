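#' @importFrom data.table data.table as.data.table setorder copy rbindlist :=
#' @importFrom stats rnorm rpois runif
NULL

# SAM integer B-array subtypes and their value ranges
.int_subtypes <- c("c", "C", "s", "S", "i", "I")

#' Read a SAM or BAM file into a record set
#'
#' Reads an aligned or unaligned SAM/BAM file and returns every record with
#' all fields and auxiliary tags preserved verbatim, plus the header lines.
#' BAM input is converted through htslib (Rsamtools); SAM text is read
#' directly.  Each record is assigned an `original_index` of 0,1,2,... in
#' file order.
#'
#' @param path path to a `.bam` or `.sam` file.
#' @return an object of class `flowcram_records`: a list with elements
#'   `header` (character vector of header lines) and `records` (a
#'   `data.table` with columns `qname`, `flag`, `rname`, `pos0` (0-based
#'   leftmost coordinate, -1 for unmapped), `mapq`, `cigar`, `rnext`,
#'   `pnext`, `tlen`, `seq`, `qual`, `tags` (list column of auxiliary tag
#'   strings in original order) and `original_index`).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  sam_path <- path
  if (is_bam_file(path)) {
    dest <- tempfile(fileext = "")
    sam_path <- tryCatch(
      Rsamtools::asSam(path, dest, overwrite = TRUE),
      error = function(e) {
        stop("unreadable or truncated BAM file '", path, "': ",
             conditionMessage(e))
      }
    )
    on.exit(unlink(sam_path))
  }
  lines <- readLines(sam_path, warn = FALSE)
  parse_sam_lines(lines, origin = path)
}

# BAM files are BGZF: gzip magic bytes 1f 8b
is_bam_file <- function(path) {
  magic <- readBin(path, raw(), n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

parse_sam_lines <- function(lines, origin = "<sam>") {
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  if (length(header) == 0L) {
    stop("format error in '", origin, "': missing SAM header")
  }
  if (any(!is_hdr & seq_along(lines) < max(which(is_hdr)))) {
    stop("format error in '", origin, "': header lines after first record")
  }
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0L) {
    rec <- data.table(
      qname = character(), flag = integer(), rname = character(),
      pos0 = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character(), tags = list(),
      original_index = integer()
    )
    return(structure(list(header = header, records = rec),
                     class = "flowcram_records"))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("format error in '", origin, "': record at line offset ", bad,
         " has fewer than 11 SAM fields")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  rec <- data.table(
    qname = get(1),
    flag = as.integer(get(2)),
    rname = get(3),
    pos0 = as.integer(get(4)) - 1L,
    mapq = as.integer(get(5)),
    cigar = get(6),
    rnext = get(7),
    pnext = as.integer(get(8)),
    tlen = as.integer(get(9)),
    seq = get(10),
    qual = get(11),
    tags = lapply(fields, function(f) if (length(f) > 11L) f[-(1:11)] else character(0)),
    original_index = seq_len(n) - 1L
  )
  if (anyNA(rec$flag) || anyNA(rec$pos0)) {
    stop("format error in '", origin, "': non-numeric FLAG or POS field")
  }
  structure(list(header = header, records = rec), class = "flowcram_records")
}

#' @export
print.flowcram_records <- function(x, ...) {
  cat("flowcram_records:", nrow(x$records), "records,",
      length(x$header), "header lines\n")
  invisible(x)
}

format_sam_lines <- function(recset) {
  rec <- recset$records
  if (nrow(rec) == 0L) return(recset$header)
  tagstr <- vapply(rec$tags, function(t) {
    if (length(t) == 0L) "" else paste0("\t", paste(t, collapse = "\t"))
  }, character(1))
  body <- paste0(
    rec$qname, "\t", rec$flag, "\t", rec$rname, "\t", rec$pos0 + 1L, "\t",
    rec$mapq, "\t", rec$cigar, "\t", rec$rnext, "\t", rec$pnext, "\t",
    rec$tlen, "\t", rec$seq, "\t", rec$qual, tagstr
  )
  c(recset$header, body)
}

#' Write a record set to SAM or BAM
#'
#' Inverse of [read_records()]: emits records in the order of the table,
#' with 1-based SAM coordinates and tags joined in their stored order.
#'
#' @param recset a `flowcram_records` object.
#' @param path output path; `.bam` output goes through htslib.
#' @param format `"bam"` or `"sam"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_records <- function(recset, path, format = NULL) {
  stopifnot(inherits(recset, "flowcram_records"))
  if (is.null(format)) {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bam"
  }
  format <- match.arg(format, c("bam", "sam"))
  lines <- format_sam_lines(recset)
  if (format == "sam") {
    writeLines(lines, path)
    return(invisible(path))
  }
  tmp_sam <- tempfile(fileext = ".sam")
  on.exit(unlink(tmp_sam))
  writeLines(lines, tmp_sam)
  dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
  out <- Rsamtools::asBam(tmp_sam, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  if (!identical(normalizePath(out), normalizePath(path)) &&
      !identical(out, path)) {
    file.rename(out, path)
  }
  invisible(path)
}

#' Per-read-group run metadata (flow order and key sequence)
#'
#' Extracts the flow cycle (`FO`) and key sequence (`KS`) strings that Ion
#' Torrent pipelines store in the `@RG` header lines.
#'
#' @param recset a `flowcram_records` object.
#' @return a `data.table` with columns `read_group_id`, `flow_order`,
#'   `key_sequence` (NA where absent); zero rows when the header has no
#'   read groups.
#' @export
run_metadata <- function(recset) {
  rg <- recset$header[startsWith(recset$header, "@RG")]
  pull <- function(line, key) {
    m <- regmatches(line, regexpr(paste0("\t", key, ":[^\t]*"), line))
    if (length(m) == 0L) NA_character_ else sub(paste0("\t", key, ":"), "", m)
  }
  out <- data.table(
    read_group_id = vapply(rg, pull, character(1), key = "ID", USE.NAMES = FALSE),
    flow_order = vapply(rg, pull, character(1), key = "FO", USE.NAMES = FALSE),
    key_sequence = vapply(rg, pull, character(1), key = "KS", USE.NAMES = FALSE)
  )
  bad <- !is.na(out$flow_order) & grepl("[^ACGT]", out$flow_order)
  if (any(bad)) {
    stop("format error: flow order contains non-ACGT characters in read group ",
         out$read_group_id[which(bad)[1]])
  }
  out
}

# Parse a ZM tag string "ZM:B:s,1,2,-3" -> list(values, subtype) or NULL
parse_zm_tag <- function(tagvec, qname = "<read>") {
  hit <- which(startsWith(tagvec, "ZM:"))
  if (length(hit) == 0L) return(NULL)
  tag <- tagvec[hit[1]]
  parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3L || parts[2] != "B") {
    stop("format error: ZM tag of read '", qname,
         "' is not an integer B array (", tag, ")")
  }
  payload <- strsplit(parts[3], ",", fixed = TRUE)[[1]]
  subtype <- payload[1]
  if (!subtype %in% .int_subtypes) {
    stop("format error: ZM tag of read '", qname,
         "' has non-integer array subtype '", subtype, "'")
  }
  values <- if (length(payload) > 1L) as.integer(payload[-1]) else integer(0)
  if (anyNA(values)) {
    stop("format error: non-numeric ZM value in read '", qname, "'")
  }
  if (length(values) && (min(values) < -32768L || max(values) > 32767L)) {
    stop("ZM values of read '", qname, "' exceed the signed 16-bit range")
  }
  list(values = values, subtype = subtype, tag_pos = hit[1])
}

format_zm_tag <- function(values, subtype = "s") {
  if (length(values) == 0L) return(paste0("ZM:B:", subtype))
  paste0("ZM:B:", subtype, ",", paste(values, collapse = ","))
}

#' Extract the flow-signal vector of one record
#'
#' Returns the integer array stored under the `ZM` auxiliary tag of record
#' `i`, or `NULL` when the record carries no `ZM` tag.  The record set is
#' never modified.
#'
#' @param recset a `flowcram_records` object.
#' @param i 1-based row number of the record.
#' @return integer vector (possibly length 0) or `NULL`.
#' @export
extract_flow_vector <- function(recset, i) {
  stopifnot(inherits(recset, "flowcram_records"),
            i >= 1L, i <= nrow(recset$records))
  zm <- parse_zm_tag(recset$records$tags[[i]], recset$records$qname[i])
  if (is.null(zm)) NULL else zm$values
}

#' Split a record set into a flow-free body and a flow-signal table
#'
#' Removes exactly the `ZM` tag from every record that carries one and
#' collects the flow vectors in a side table keyed by `original_index`,
#' remembering the tag's position among the record's tags and its array
#' subtype so that [reattach_flow_signals()] can restore it bit-for-bit.
#' All other fields, tags and the record order are untouched.
#'
#' @param recset a `flowcram_records` object.
#' @return list with elements `body` (a `flowcram_records` without any ZM
#'   tags) and `flows` (a `data.table` with columns `read_index`,
#'   `tag_pos`, `subtype` and list column `values`, one row per input
#'   record that had a ZM tag).
#' @export
strip_flow_signals <- function(recset) {
  stopifnot(inherits(recset, "flowcram_records"))
  rec <- recset$records
  n <- nrow(rec)
  zm <- vector("list", n)
  for (i in seq_len(n)) {
    v <- parse_zm_tag(rec$tags[[i]], rec$qname[i])
    if (!is.null(v)) zm[[i]] <- v
  }
  has <- !vapply(zm, is.null, logical(1))
  body <- copy(rec)
  if (any(has)) {
    body$tags <- lapply(seq_len(n), function(i) {
      if (has[i]) rec$tags[[i]][-zm[[i]]$tag_pos] else rec$tags[[i]]
    })
  }
  flows <- data.table(
    read_index = rec$original_index[has],
    tag_pos = vapply(zm[has], `[[`, integer(1), "tag_pos"),
    subtype = vapply(zm[has], `[[`, character(1), "subtype"),
    values = lapply(zm[has], `[[`, "values")
  )
  list(
    body = structure(list(header = recset$header, records = body),
                     class = "flowcram_records"),
    flows = flows
  )
}

#' Restore flow-signal vectors onto a stripped record set
#'
#' Exact inverse of [strip_flow_signals()]: each flow vector is re-inserted
#' as a `ZM` tag at its original position among the record's tags, with its
#' original array subtype.
#'
#' @param body a `flowcram_records` object without ZM tags.
#' @param flows the `flows` table produced by [strip_flow_signals()].
#' @return a `flowcram_records` object.
#' @export
reattach_flow_signals <- function(body, flows) {
  stopifnot(inherits(body, "flowcram_records"))
  rec <- copy(body$records)
  if (nrow(flows) == 0L) {
    return(structure(list(header = body$header, records = rec),
                     class = "flowcram_records"))
  }
  if (anyDuplicated(flows$read_index)) {
    stop("consistency error: duplicate read_index in flow table")
  }
  row_of <- match(flows$read_index, rec$original_index)
  if (anyNA(row_of)) {
    stop("consistency error: flow table references read_index ",
         flows$read_index[which(is.na(row_of))[1]],
         " absent from the record stream")
  }
  tags <- rec$tags
  for (k in seq_len(nrow(flows))) {
    i <- row_of[k]
    tag <- format_zm_tag(flows$values[[k]], flows$subtype[k])
    old <- tags[[i]]
    p <- flows$tag_pos[k]
    p <- min(max(p, 1L), length(old) + 1L)
    tags[[i]] <- append(old, tag, after = p - 1L)
  }
  rec$tags <- tags
  structure(list(header = body$header, records = rec),
            class = "flowcram_records")
}

#' Field-for-field equality of two record sets
#'
#' Compares headers and every record field, including auxiliary tag order.
#' Used to verify lossless round trips.
#'
#' @param a,b `flowcram_records` objects.
#' @return TRUE or FALSE.
#' @export
records_equal <- function(a, b) {
  identical(format_sam_lines(a), format_sam_lines(b))
}
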