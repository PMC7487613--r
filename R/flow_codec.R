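# Core codec: chained delta encoding of flow-signal vectors within a block.
# The decoder's reconstruction rule is F_{i+1} = F_i - D_i, so the encoder
# stores D_i = F_i - F_{i+1}.  Near-zero deltas between similar reads are
# written as zig-zag varints, which the general-purpose backend then squeezes
# further.

# ---- integer wire format ---------------------------------------------------

# zig-zag maps signed to unsigned: 0->0, -1->1, 1->2, -2->3, ...
zigzag <- function(v) {
  v <- as.double(v)
  ifelse(v >= 0, 2 * v, -2 * v - 1)
}

unzigzag <- function(z) {
  ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2)
}

# LEB128 unsigned varints, vectorised.  Values must be in [0, 2^31).
varint_encode <- function(z) {
  n <- length(z)
  if (n == 0L) return(raw(0))
  z <- as.double(z)
  if (any(z < 0) || any(z >= 2^31)) {
    stop("varint value out of range [0, 2^31)")
  }
  nb <- 1L + (z > 127) + (z > 16383) + (z > 2097151) + (z > 268435455)
  posn <- sequence(nb)
  vi <- rep.int(seq_len(n), nb)
  chunk <- (z[vi] %/% 128^(posn - 1)) %% 128
  as.raw(chunk + 128 * (posn < nb[vi]))
}

# Decode every varint in a byte string; errors on a trailing partial value.
varint_decode_all <- function(bytes) {
  b <- as.integer(bytes)
  if (length(b) == 0L) return(numeric(0))
  ends <- which(b < 128L)
  if (length(ends) == 0L || ends[length(ends)] != length(b)) {
    stop("corruption error: truncated varint stream")
  }
  starts <- c(1L, ends[-length(ends)] + 1L)
  lens <- ends - starts + 1L
  if (any(lens > 5L)) {
    stop("corruption error: varint longer than 5 bytes")
  }
  offset <- seq_along(b) - rep.int(starts, lens)
  contrib <- (b %% 128L) * 128^offset
  cs <- cumsum(contrib)
  cs[ends] - c(0, cs[ends[-length(ends)]])
}

# read one varint starting at offset; returns c(value, next_offset)
varint_read_one <- function(bytes, offset) {
  val <- 0
  shift <- 1
  repeat {
    if (offset > length(bytes)) {
      stop("corruption error: truncated varint stream")
    }
    b <- as.integer(bytes[offset])
    offset <- offset + 1L
    val <- val + (b %% 128L) * shift
    if (b < 128L) break
    shift <- shift * 128
    if (shift > 2^35) stop("corruption error: varint longer than 5 bytes")
  }
  c(val, offset)
}

# ---- median reference ------------------------------------------------------

#' Position-wise average reference vector for a block
#'
#' Computes, at every flow position, the arithmetic mean of the member
#' vectors long enough to reach that position, rounded half away from zero
#' to an integer.  Used as the alternative (non-chained) reference strategy.
#'
#' @param vectors non-empty list of integer flow vectors.
#' @return integer vector of length `max(lengths(vectors))`.
#' @export
median_reference <- function(vectors) {
  stopifnot(length(vectors) >= 1L)
  maxlen <- max(lengths(vectors))
  if (maxlen == 0L) return(integer(0))
  m <- vapply(vectors, function(v) {
    c(as.double(v), rep(NA_real_, maxlen - length(v)))
  }, numeric(maxlen))
  mu <- rowMeans(matrix(m, nrow = maxlen), na.rm = TRUE)
  as.integer(sign(mu) * floor(abs(mu) + 0.5))
}

# ---- lossy binning ---------------------------------------------------------

#' Lossy flow-value binning
#'
#' Maps a flow value y to `ceiling(y / x) * x`; negative values are set to
#' zero.  Binning is idempotent and monotone, and for y > 0 satisfies
#' `y <= bin_value(y, x) < y + x`.  It is applied once, before delta
#' encoding, and only when lossy mode is explicitly requested.
#'
#' @param y integer vector of flow values.
#' @param x positive integer bin width.
#' @return integer vector of binned values.
#' @export
bin_value <- function(y, x) {
  stopifnot(length(x) == 1L, x >= 1)
  out <- ifelse(y < 0, 0, ceiling(as.double(y) / x) * x)
  as.integer(out)
}

#' @rdname bin_value
#' @param vectors list of integer flow vectors (NULL entries pass through).
#' @export
bin_vectors <- function(vectors, x) {
  lapply(vectors, function(v) if (is.null(v)) NULL else bin_value(v, x))
}

# ---- block encode / decode -------------------------------------------------

delta_pair <- function(a, b) {
  cm <- min(length(a), length(b))
  list(
    values = if (cm > 0L) a[seq_len(cm)] - b[seq_len(cm)] else integer(0),
    tail = if (length(b) > cm) b[(cm + 1L):length(b)] else integer(0)
  )
}

#' Delta-encode the flow vectors of one block
#'
#' With `strategy = "first"` the reference is the first present vector and
#' each subsequent present vector is stored as the chained difference
#' `D_i = F_i - F_{i+1}` over the common prefix, with the remainder of the
#' longer vector stored raw.  With `strategy = "median"` the reference is
#' the position-wise average ([median_reference()]) and every present
#' member's difference is taken against that fixed reference.  Members
#' without a flow vector (`NULL`) are flagged absent and skipped in the
#' chain.  Encoding is lossless for both strategies.
#'
#' @param vectors list of integer vectors, `NULL` for members without a
#'   flow signal.
#' @param strategy `"first"` (default, chained) or `"median"`.
#' @param subtypes optional per-member ZM array subtype codes (default "s").
#' @param tag_pos optional per-member original tag positions (default 1).
#' @return an object of class `flowcram_encoded_block`.
#' @export
encode_block <- function(vectors, strategy = c("first", "median"),
                         subtypes = NULL, tag_pos = NULL) {
  strategy <- match.arg(strategy)
  k <- length(vectors)
  stopifnot(k >= 1L)
  presence <- !vapply(vectors, is.null, logical(1))
  if (is.null(subtypes)) subtypes <- rep("s", sum(presence))
  if (is.null(tag_pos)) tag_pos <- rep(1L, sum(presence))
  stopifnot(length(subtypes) == sum(presence),
            length(tag_pos) == sum(presence))
  pv <- vectors[presence]
  np <- length(pv)
  if (np == 0L) {
    return(structure(list(strategy = strategy, presence = presence,
                          lengths = integer(0), subtypes = character(0),
                          tag_pos = integer(0), reference = NULL,
                          deltas = list()),
                     class = "flowcram_encoded_block"))
  }
  lens <- lengths(pv)
  if (strategy == "first") {
    reference <- pv[[1]]
    deltas <- if (np > 1L) {
      lapply(seq_len(np - 1L), function(j) delta_pair(pv[[j]], pv[[j + 1L]]))
    } else list()
  } else {
    reference <- median_reference(pv)
    deltas <- lapply(pv, function(v) delta_pair(reference, v))
  }
  structure(list(strategy = strategy, presence = presence,
                 lengths = as.integer(lens), subtypes = subtypes,
                 tag_pos = as.integer(tag_pos), reference = reference,
                 deltas = deltas),
            class = "flowcram_encoded_block")
}

#' Decode a delta-encoded block
#'
#' Exact inverse of [encode_block()].  The chained strategy reconstructs
#' `F_{i+1} = F_i - D_i` member by member, appending each stored tail; the
#' median strategy subtracts each delta from the fixed reference.
#'
#' @param enc a `flowcram_encoded_block`.
#' @return list of integer vectors with `NULL` at absent-member positions.
#' @export
decode_block <- function(enc) {
  stopifnot(inherits(enc, "flowcram_encoded_block"))
  k <- length(enc$presence)
  out <- vector("list", k)
  np <- sum(enc$presence)
  if (np == 0L) return(out)
  if (length(enc$lengths) != np) {
    stop("corruption error: block length table does not match presence map")
  }
  slots <- which(enc$presence)
  pv <- vector("list", np)
  if (enc$strategy == "first") {
    if (length(enc$deltas) != np - 1L) {
      stop("corruption error: chained block carries ", length(enc$deltas),
           " deltas for ", np, " present members")
    }
    cur <- enc$reference
    if (length(cur) != enc$lengths[1]) {
      stop("corruption error: reference length disagrees with length table")
    }
    pv[[1]] <- cur
    for (j in seq_len(np - 1L)) {
      d <- enc$deltas[[j]]
      cm <- min(enc$lengths[j], enc$lengths[j + 1L])
      if (length(d$values) != cm ||
          length(d$tail) != enc$lengths[j + 1L] - cm) {
        stop("corruption error: delta ", j, " length bookkeeping mismatch")
      }
      nxt <- c(if (cm > 0L) cur[seq_len(cm)] - d$values else integer(0),
               d$tail)
      cur <- nxt
      pv[[j + 1L]] <- nxt
    }
  } else {
    if (length(enc$deltas) != np) {
      stop("corruption error: median block carries ", length(enc$deltas),
           " deltas for ", np, " present members")
    }
    rl <- length(enc$reference)
    for (j in seq_len(np)) {
      d <- enc$deltas[[j]]
      cm <- min(rl, enc$lengths[j])
      if (length(d$values) != cm ||
          length(d$tail) != enc$lengths[j] - cm) {
        stop("corruption error: delta ", j, " length bookkeeping mismatch")
      }
      pv[[j]] <- c(if (cm > 0L) enc$reference[seq_len(cm)] - d$values
                   else integer(0),
                   d$tail)
    }
  }
  for (j in seq_len(np)) out[[slots[j]]] <- as.integer(pv[[j]])
  out
}

# ---- serialization ---------------------------------------------------------

.strategy_codes <- c(first = 0L, median = 1L)

#' Serialize an encoded block to bytes
#'
#' Self-delimiting layout: a varint total payload length, then member count,
#' strategy byte, presence bitmap, per-present-member subtype bytes, and a
#' varint region holding the reference length, per-member lengths and tag
#' positions, and the zig-zag-encoded reference, delta and tail values.
#' [deserialize_block()] inverts it exactly and errors on truncation.
#'
#' @param enc a `flowcram_encoded_block`.
#' @return raw vector.
#' @export
serialize_block <- function(enc) {
  stopifnot(inherits(enc, "flowcram_encoded_block"))
  k <- length(enc$presence)
  np <- sum(enc$presence)
  bitmap <- packBits(c(enc$presence, rep(FALSE, (8L - k %% 8L) %% 8L)),
                     type = "raw")
  head <- c(varint_encode(k),
            as.raw(.strategy_codes[[enc$strategy]]),
            bitmap,
            as.raw(vapply(enc$subtypes, utf8ToInt, integer(1),
                          USE.NAMES = FALSE)))
  if (np > 0L) {
    nums <- c(length(enc$reference), enc$lengths, enc$tag_pos,
              zigzag(enc$reference),
              unlist(lapply(enc$deltas, function(d) {
                c(zigzag(d$values), zigzag(d$tail))
              }), use.names = FALSE))
    region <- varint_encode(nums)
  } else {
    region <- raw(0)
  }
  payload <- c(head, region)
  c(varint_encode(length(payload)), payload)
}

#' Deserialize one block from a byte stream
#'
#' @param bytes raw vector containing one or more serialized blocks.
#' @param offset 1-based position of the block to read.
#' @return list with `block` (a `flowcram_encoded_block`) and `next_offset`.
#' @export
deserialize_block <- function(bytes, offset = 1L) {
  vr <- varint_read_one(bytes, offset)
  payload_len <- vr[1]
  start <- vr[2]
  if (start + payload_len - 1 > length(bytes)) {
    stop("corruption error: block payload truncated (need ", payload_len,
         " bytes at offset ", start, ")")
  }
  p <- bytes[start:(start + payload_len - 1L)]
  vr <- varint_read_one(p, 1L)
  k <- as.integer(vr[1])
  at <- as.integer(vr[2])
  if (k < 1L) stop("corruption error: block member count must be >= 1")
  if (at > length(p)) stop("corruption error: block header truncated")
  scode <- as.integer(p[at]); at <- at + 1L
  strategy <- names(.strategy_codes)[match(scode, .strategy_codes)]
  if (is.na(strategy)) {
    stop("corruption error: unknown block strategy code ", scode)
  }
  nbm <- (k + 7L) %/% 8L
  if (at + nbm - 1L > length(p)) {
    stop("corruption error: presence bitmap truncated")
  }
  presence <- as.logical(rawToBits(p[at:(at + nbm - 1L)]))[seq_len(k)]
  at <- at + nbm
  np <- sum(presence)
  if (np > 0L) {
    if (at + np - 1L > length(p)) {
      stop("corruption error: subtype table truncated")
    }
    subtypes <- vapply(as.integer(p[at:(at + np - 1L)]),
                       function(i) intToUtf8(i), character(1))
    at <- at + np
    nums <- varint_decode_all(p[seq.int(at, length.out = length(p) - at + 1L)])
    if (length(nums) < 1L + 2L * np) {
      stop("corruption error: block numeric region truncated")
    }
    ref_len <- as.integer(nums[1])
    lens <- as.integer(nums[1L + seq_len(np)])
    tag_pos <- as.integer(nums[1L + np + seq_len(np)])
    consumed <- 1L + 2L * np
    take <- function(n) {
      if (consumed + n > length(nums)) {
        stop("corruption error: block value region truncated")
      }
      v <- nums[consumed + seq_len(n)]
      consumed <<- consumed + n
      as.integer(unzigzag(v))
    }
    reference <- take(ref_len)
    if (strategy == "first") {
      if (ref_len != lens[1]) {
        stop("corruption error: reference length disagrees with length table")
      }
      nd <- np - 1L
      deltas <- if (nd > 0L) lapply(seq_len(nd), function(j) {
        cm <- min(lens[j], lens[j + 1L])
        list(values = take(cm), tail = take(lens[j + 1L] - cm))
      }) else list()
    } else {
      deltas <- lapply(seq_len(np), function(j) {
        cm <- min(ref_len, lens[j])
        list(values = take(cm), tail = take(lens[j] - cm))
      })
    }
    if (consumed != length(nums)) {
      stop("corruption error: ", length(nums) - consumed,
           " unexpected trailing values in block")
    }
  } else {
    subtypes <- character(0)
    lens <- integer(0)
    tag_pos <- integer(0)
    reference <- NULL
    deltas <- list()
    if (at <= length(p)) {
      stop("corruption error: unexpected trailing bytes in empty block")
    }
  }
  enc <- structure(list(strategy = strategy, presence = presence,
                        lengths = lens, subtypes = subtypes,
                        tag_pos = tag_pos,
                        reference = reference, deltas = deltas),
                   class = "flowcram_encoded_block")
  list(block = enc, next_offset = as.integer(start + payload_len))
}

# serialize a list of encoded blocks into one byte stream
serialize_blocks <- function(encs) {
  if (length(encs) == 0L) return(raw(0))
  unlist(lapply(encs, serialize_block), use.names = FALSE)
}

# deserialize exactly n blocks from a byte stream
deserialize_blocks <- function(bytes, n) {
  out <- vector("list", n)
  at <- 1L
  for (i in seq_len(n)) {
    r <- deserialize_block(bytes, at)
    out[[i]] <- r$block
    at <- r$next_offset
  }
  if (at != length(bytes) + 1L) {
    stop("corruption error: ", length(bytes) - at + 1L,
         " trailing bytes after last block in chunk")
  }
  out
}

# Fixed-width little-endian int16 serialization of raw vectors (no deltas);
# the baseline the delta codec is measured against.
serialize_raw_vectors <- function(vectors) {
  present <- !vapply(vectors, is.null, logical(1))
  lens <- integer(length(vectors))
  lens[present] <- lengths(vectors[present])
  head <- varint_encode(c(length(vectors), as.integer(present), lens))
  vals <- unlist(vectors[present], use.names = FALSE)
  body <- writeBin(as.integer(vals), raw(), size = 2L, endian = "little")
  c(head, body)
}
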