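# In-code fixtures: small SAM record sets and random flow blocks.

sam_recset <- function(record_lines,
                       header = c("@HD\tVN:1.6\tSO:unknown",
                                  "@SQ\tSN:chr1\tLN:100000",
                                  "@SQ\tSN:chr2\tLN:100000",
                                  "@RG\tID:rg1\tFO:TACG\tKS:TCAG")) {
  flowcram:::parse_sam_lines(c(header, record_lines))
}

sam_line <- function(qname, flag = 0L, rname = "chr1", pos1 = 100L,
                     cigar = "4M", seq = "ACGT", tags = character(0)) {
  paste(c(qname, flag, rname, pos1, 60L, cigar, "*", 0L, 0L, seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}

# a small record set with ZM tags in assorted positions
tiny_zm_recset <- function() {
  sam_recset(c(
    sam_line("r1", tags = c("RG:Z:rg1", "ZM:B:s,512,3,-2,260", "XY:i:7")),
    sam_line("r2", pos1 = 50L, tags = c("ZM:B:s,100", "RG:Z:rg1")),
    sam_line("r3", rname = "chr2", pos1 = 10L, tags = "RG:Z:rg1")
  ))
}

# random block of flow vectors with optional absences and length jitter
random_block <- function(k, n = 12L, absent_prob = 0.2, jitter = TRUE) {
  lapply(seq_len(k), function(i) {
    if (runif(1) < absent_prob) return(NULL)
    len <- if (jitter) max(0L, n + sample(-3:3, 1)) else n
    as.integer(sample(-500:500, len, replace = TRUE))
  })
}

# brute-force chained reconstruction: prefix "sums" of the stored deltas
prefix_sum_decode <- function(enc) {
  out <- vector("list", length(enc$presence))
  slots <- which(enc$presence)
  if (length(slots) == 0L) return(out)
  cur <- enc$reference
  out[[slots[1]]] <- cur
  for (j in seq_along(enc$deltas)) {
    d <- enc$deltas[[j]]
    cm <- length(d$values)
    cur <- c(cur[seq_len(cm)] - d$values, d$tail)
    out[[slots[j + 1L]]] <- as.integer(cur)
  }
  out
}

quick_fixture <- function(path, ..., seed = 1L) {
  spec <- simulation_spec(..., seed = seed)
  generate_bam_fixture(spec, path)
}
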