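# Reads mapped to the same locus carry near-identical flow signals; sorting
# by (contig rank, position, strand, CIGAR) makes them adjacent so the delta
# codec can exploit the similarity.  Unmapped reads have no locus: they are
# grouped after all mapped reads, ordered by sequence prefix so near-duplicate
# unmapped reads still end up adjacent.

UNMAPPED_PREFIX_LEN <- 32L

contig_ranks <- function(recset) {
  sq <- recset$header[startsWith(recset$header, "@SQ")]
  m <- regmatches(sq, regexpr("\tSN:[^\t]*", sq))
  sub("\tSN:", "", m)
}

#' Sort records for block building
#'
#' Mapped reads are ordered by (contig rank in header order, 0-based
#' position, strand, CIGAR text, read name, original index); the CIGAR
#' comparison is plain lexicographic in the C locale.  Unmapped reads come
#' after all mapped reads, ordered by (sequence prefix of
#' `r UNMAPPED_PREFIX_LEN` bases, read name, original index).  The sort is
#' stable and deterministic.
#'
#' @param recset a `flowcram_records` object.
#' @return list with `sorted_order` (integer vector: position k holds the
#'   1-based row in `recset$records` of the k-th sorted record) and
#'   `permutation` (integer vector mapping sorted rank to `original_index`,
#'   a bijection on 0..N-1).
#' @export
sort_records <- function(recset) {
  rec <- recset$records
  n <- nrow(rec)
  if (n == 0L) {
    return(list(sorted_order = integer(0), permutation = integer(0)))
  }
  contigs <- contig_ranks(recset)
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  rank <- match(rec$rname, contigs)
  if (any(!unmapped & is.na(rank))) {
    bad <- which(!unmapped & is.na(rank))[1]
    stop("format error: mapped read '", rec$qname[bad],
         "' references contig '", rec$rname[bad], "' absent from the header")
  }
  strand <- as.integer(bitwAnd(rec$flag, 16L) != 0L)

  mi <- which(!unmapped)
  ui <- which(unmapped)
  om <- mi[order(rank[mi], rec$pos0[mi], strand[mi], rec$cigar[mi],
                 rec$qname[mi], rec$original_index[mi], method = "radix")]
  prefix <- substr(rec$seq[ui], 1L, UNMAPPED_PREFIX_LEN)
  ou <- ui[order(prefix, rec$qname[ui], rec$original_index[ui],
                 method = "radix")]
  sorted_order <- c(om, ou)
  list(sorted_order = sorted_order,
       permutation = rec$original_index[sorted_order])
}

#' Partition sorted records into same-locus blocks
#'
#' Consecutive mapped reads sharing (contig rank, position, strand) form one
#' block, split into chunks of at most `max_block_size`; unmapped reads form
#' trailing blocks bounded only by `max_block_size`.  Concatenating the
#' blocks reproduces the sorted stream exactly.
#'
#' @param recset a `flowcram_records` object.
#' @param sorted_order integer vector from [sort_records()].
#' @param max_block_size maximum reads per block (default 65535).
#' @return list of blocks; each block is a list with `rows` (1-based rows of
#'   `recset$records` in sorted order) and `locus` (`c(rank, pos0, strand)`
#'   or `NULL` for unmapped blocks).
#' @export
build_blocks <- function(recset, sorted_order, max_block_size = 65535L) {
  stopifnot(max_block_size >= 1L)
  rec <- recset$records
  n <- length(sorted_order)
  if (n == 0L) return(list())
  contigs <- contig_ranks(recset)
  unmapped <- bitwAnd(rec$flag[sorted_order], 4L) != 0L
  rank <- match(rec$rname[sorted_order], contigs)
  pos <- rec$pos0[sorted_order]
  strand <- as.integer(bitwAnd(rec$flag[sorted_order], 16L) != 0L)
  if (any(unmapped) && any(!unmapped) &&
      min(which(unmapped)) < max(which(!unmapped))) {
    stop("precondition error: input to build_blocks is not in sorted order ",
         "(unmapped read precedes a mapped read)")
  }
  mi <- which(!unmapped)
  if (length(mi) > 1L) {
    r <- rank[mi]; p <- pos[mi]; s <- strand[mi]
    dec <- r[-1] < r[-length(r)] |
      (r[-1] == r[-length(r)] & (p[-1] < p[-length(p)] |
        (p[-1] == p[-length(p)] & s[-1] < s[-length(s)])))
    if (any(dec)) {
      stop("precondition error: input to build_blocks is not in sorted order ",
           "(locus key decreases at sorted rank ", mi[which(dec)[1] + 1L], ")")
    }
  }
  blocks <- list()
  if (length(mi)) {
    key <- paste(rank[mi], pos[mi], strand[mi], sep = "\r")
    grp <- rle(key)
    at <- 1L
    for (g in seq_along(grp$lengths)) {
      len <- grp$lengths[g]
      idx <- mi[at:(at + len - 1L)]
      at <- at + len
      locus <- c(rank[idx[1]], pos[idx[1]], strand[idx[1]])
      for (start in seq(1L, len, by = max_block_size)) {
        end <- min(start + max_block_size - 1L, len)
        blocks[[length(blocks) + 1L]] <-
          list(rows = sorted_order[idx[start:end]], locus = locus)
      }
    }
  }
  uix <- which(unmapped)
  if (length(uix)) {
    for (start in seq(1L, length(uix), by = max_block_size)) {
      end <- min(start + max_block_size - 1L, length(uix))
      blocks[[length(blocks) + 1L]] <-
        list(rows = sorted_order[uix[start:end]], locus = NULL)
    }
  }
  blocks
}

#' Invert a permutation
#'
#' Given the sorted-rank-to-original-index mapping from [sort_records()],
#' returns for each original index (0-based) the sorted rank (1-based) it
#' came from, so original file order can be restored exactly.
#'
#' @param permutation integer vector, a bijection on 0..N-1.
#' @return integer vector `inv` with `inv[orig_index + 1] = sorted_rank`.
#' @export
invert_permutation <- function(permutation) {
  n <- length(permutation)
  if (any(sort(permutation) != 0:(n - 1L))) {
    stop("corruption error: permutation is not a bijection on 0..N-1")
  }
  inv <- integer(n)
  inv[permutation + 1L] <- seq_len(n)
  inv
}
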