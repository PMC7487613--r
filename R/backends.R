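# Uniform contract over the three general-purpose compressors used for the
# flow streams: gzip (zlib, RFC 1952 member), xz (.xz container) and zstd
# (zstd frame via the command-line tool).  Defaults are the maximum-
# compression settings: level 9 for gzip and xz, ultra-range 22 for zstd.
# Streams are standard single-member formats so external tools can inspect
# archive components.

.backend_levels <- list(
  gzip = c(min = 1L, max = 9L, default = 9L),
  xz = c(min = 1L, max = 9L, default = 9L),
  zstd = c(min = 1L, max = 22L, default = 22L)
)

#' Compression backend specification
#'
#' @param algorithm one of `"gzip"`, `"xz"`, `"zstd"`.
#' @param level compression level; default is the algorithm's maximum
#'   (gzip 9, xz 9, zstd 22).
#' @return a `flowcram_backend` object.
#' @export
backend_spec <- function(algorithm = c("xz", "gzip", "zstd"), level = NULL) {
  if (length(algorithm) != 1L || !algorithm %in% names(.backend_levels)) {
    algorithm <- match.arg(algorithm)
  }
  lim <- .backend_levels[[algorithm]]
  if (is.null(level)) level <- lim[["default"]]
  level <- as.integer(level)
  if (is.na(level) || level < lim[["min"]] || level > lim[["max"]]) {
    stop("configuration error: level ", level, " outside [", lim[["min"]],
         ", ", lim[["max"]], "] for ", algorithm)
  }
  structure(list(algorithm = algorithm, level = level),
            class = "flowcram_backend")
}

zstd_binary <- function() {
  z <- Sys.which("zstd")
  if (!nzchar(z)) {
    stop("configuration error: the 'zstd' executable is not on PATH")
  }
  z
}

read_all_bytes <- function(path) {
  readBin(path, raw(), n = file.size(path))
}

# drain a binary connection fully (decompressed size unknown up front)
drain_connection <- function(con) {
  chunks <- list()
  repeat {
    piece <- readBin(con, raw(), n = 1048576L)
    if (length(piece) == 0L) break
    chunks[[length(chunks) + 1L]] <- piece
  }
  unlist(chunks, use.names = FALSE) %||% raw(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compress a byte string
#'
#' Produces a standard single-member stream of the requested algorithm that
#' [decompress_bytes()] (or the matching external tool) inverts exactly.
#' Output is deterministic for a fixed payload, spec and library version.
#'
#' @param payload raw vector.
#' @param spec a `flowcram_backend` from [backend_spec()].
#' @return raw vector of compressed bytes.
#' @export
compress_bytes <- function(payload, spec = backend_spec()) {
  stopifnot(is.raw(payload), inherits(spec, "flowcram_backend"))
  switch(spec$algorithm,
    gzip = {
      tmp <- tempfile(); on.exit(unlink(tmp))
      con <- gzfile(tmp, "wb", compression = spec$level)
      writeBin(payload, con)
      close(con)
      read_all_bytes(tmp)
    },
    xz = {
      if (spec$level == 9L) {
        memCompress(payload, type = "xz")
      } else {
        tmp <- tempfile(); on.exit(unlink(tmp))
        con <- xzfile(tmp, "wb", compression = spec$level)
        writeBin(payload, con)
        close(con)
        read_all_bytes(tmp)
      }
    },
    zstd = {
      tin <- tempfile(); tout <- tempfile()
      on.exit(unlink(c(tin, tout)))
      writeBin(payload, tin)
      args <- c("-q", "-f", "-T1", paste0("-", spec$level),
                if (spec$level > 19L) "--ultra",
                "-o", tout, tin)
      status <- system2(zstd_binary(), args, stdout = FALSE, stderr = FALSE)
      if (status != 0L) stop("zstd compression failed with status ", status)
      read_all_bytes(tout)
    },
    stop("configuration error: unsupported algorithm '", spec$algorithm, "'")
  )
}

#' Decompress a byte string
#'
#' Inverse of [compress_bytes()] for the same algorithm.  A corrupt or
#' wrong-algorithm stream raises a corruption error; no partial output is
#' ever returned.
#'
#' @param payload raw vector produced by [compress_bytes()].
#' @param spec a `flowcram_backend` naming the algorithm that produced it.
#' @return raw vector of original bytes.
#' @export
decompress_bytes <- function(payload, spec = backend_spec()) {
  stopifnot(is.raw(payload), inherits(spec, "flowcram_backend"))
  corrupt <- function(e) {
    stop("corruption error: ", spec$algorithm,
         " stream failed to decompress (", conditionMessage(e), ")")
  }
  switch(spec$algorithm,
    gzip = {
      if (length(payload) < 2L || payload[1] != as.raw(0x1f) ||
          payload[2] != as.raw(0x8b)) {
        stop("corruption error: not a gzip stream")
      }
      tmp <- tempfile(); on.exit(unlink(tmp))
      writeBin(payload, tmp)
      con <- gzfile(tmp, "rb")
      on.exit(close(con), add = TRUE, after = FALSE)
      withCallingHandlers(
        tryCatch(drain_connection(con), error = corrupt),
        warning = function(w) corrupt(w)
      )
    },
    xz = {
      # a valid .xz stream starts FD 37 7A 58 5A 00 and ends with "YZ";
      # memDecompress alone can return empty output on truncated input
      magic <- as.raw(c(0xfd, 0x37, 0x7a, 0x58, 0x5a, 0x00))
      if (length(payload) < 32L ||
          !identical(payload[1:6], magic) ||
          !identical(payload[(length(payload) - 1L):length(payload)],
                     as.raw(c(0x59, 0x5a)))) {
        stop("corruption error: not a complete xz stream")
      }
      tryCatch(memDecompress(payload, type = "xz"), error = corrupt,
               warning = corrupt)
    },
    zstd = {
      # enforce the zstd frame magic: the CLI would otherwise transparently
      # decode gzip/xz input too
      if (length(payload) < 4L ||
          !identical(payload[1:4], as.raw(c(0x28, 0xb5, 0x2f, 0xfd)))) {
        stop("corruption error: not a zstd frame")
      }
      tin <- tempfile(); tout <- tempfile()
      on.exit(unlink(c(tin, tout)))
      writeBin(payload, tin)
      status <- system2(zstd_binary(), c("-d", "-q", "-f", "-o", tout, tin),
                        stdout = FALSE, stderr = FALSE)
      if (status != 0L || !file.exists(tout)) {
        stop("corruption error: zstd stream failed to decompress")
      }
      read_all_bytes(tout)
    },
    stop("configuration error: unsupported algorithm '", spec$algorithm, "'")
  )
}
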