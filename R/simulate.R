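# Seeded simulator of Ion Torrent-like data: homopolymer-proportional
# integer flow signals over a cyclic flow order, near-zero (optionally
# negative) noise at non-incorporating flows, and multi-read loci whose
# reads share a template and therefore carry similar flow vectors.  A
# threshold base caller inverts the flowgram at zero noise, validating the
# simulation.

#' Simulation parameters for synthetic Ion Torrent fixtures
#'
#' @param reference_length reference length in bases.
#' @param depth reads per locus.
#' @param read_length read length in bases.
#' @param n_loci number of loci; default places one locus every two read
#'   lengths along the reference.
#' @param flow_order nucleotide cycle introduced by the simulated sequencer.
#' @param key_sequence control prefix ligated before each fragment
#'   (default "TCAG"); it is sequenced (so contributes to the flowgram) but
#'   is not part of the aligned read.
#' @param signal_scale integer signal per incorporated base (default 256).
#' @param noise_sd standard deviation of the additive, integer-rounded
#'   Gaussian flow noise.
#' @param negative_noise allow sub-zero values at non-incorporating flows
#'   (default TRUE).
#' @param unmapped_fraction,missing_zm_fraction fractions of reads emitted
#'   unmapped / without a ZM tag (defaults 0.01).
#' @param seed random seed; fixes the entire output byte stream.
#' @return a `flowcram_sim_spec` list.
#' @export
simulation_spec <- function(reference_length = 10000L, depth = 20L,
                            read_length = 200L, n_loci = NULL,
                            flow_order = "TACG", key_sequence = "TCAG",
                            signal_scale = 256L, noise_sd = 10,
                            negative_noise = TRUE,
                            unmapped_fraction = 0.01,
                            missing_zm_fraction = 0.01,
                            seed = 1L) {
  stopifnot(signal_scale >= 1L, noise_sd >= 0, reference_length >= read_length,
            nchar(flow_order) >= 1L, !grepl("[^ACGT]", flow_order))
  if (is.null(n_loci)) {
    n_loci <- max(1L, reference_length %/% (2L * read_length))
  }
  structure(list(reference_length = as.integer(reference_length),
                 depth = as.integer(depth),
                 read_length = as.integer(read_length),
                 n_loci = as.integer(n_loci),
                 flow_order = flow_order, key_sequence = key_sequence,
                 signal_scale = as.integer(signal_scale),
                 noise_sd = noise_sd,
                 negative_noise = isTRUE(negative_noise),
                 unmapped_fraction = unmapped_fraction,
                 missing_zm_fraction = missing_zm_fraction,
                 seed = as.integer(seed)),
            class = "flowcram_sim_spec")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Simulate the flowgram of a template sequence
#'
#' Walks the flow order cyclically.  Each flow of a base matching the
#' current template position incorporates the whole homopolymer there and
#' emits `signal_scale * homopolymer_length` plus rounded Gaussian noise;
#' non-incorporating flows emit noise around zero (negative values allowed
#' when `negative_noise`).  Flows stop once the template is consumed.
#' Values are clipped to the signed 16-bit range.
#'
#' @param seq template nucleotide string (A/C/G/T).
#' @param spec a [simulation_spec()]; `noise_sd = 0` gives the noise-free
#'   flowgram.
#' @return integer flow-signal vector.
#' @export
sequence_to_flowgram <- function(seq, spec = simulation_spec()) {
  stopifnot(nchar(seq) >= 1L)
  if (grepl("[^ACGT]", seq)) {
    stop("input error: template contains non-ACGT characters")
  }
  cycle <- strsplit(spec$flow_order, "", fixed = TRUE)[[1]]
  L <- length(cycle)
  runs <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  if (!all(unique(runs$values) %in% cycle)) {
    stop("input error: template contains bases absent from the flow order")
  }
  # 0-based cycle positions of each base
  pos_of <- lapply(c(A = "A", C = "C", G = "G", T = "T"),
                   function(b) which(cycle == b) - 1L)
  f <- -1L  # absolute index of the last incorporating flow (0-based)
  inc_at <- integer(length(runs$values))
  for (j in seq_along(runs$values)) {
    pb <- pos_of[[runs$values[j]]]
    d <- (pb - (f %% L)) %% L
    d[d == 0L] <- L
    f <- f + min(d)
    inc_at[j] <- f
  }
  # the instrument finishes the cycle it is in when the template runs out
  n <- as.integer(ceiling((f + 1L) / L) * L)
  signal <- numeric(n)
  signal[inc_at + 1L] <- as.double(spec$signal_scale) * runs$lengths
  if (spec$noise_sd > 0) {
    signal <- signal + round(rnorm(n, 0, spec$noise_sd))
    if (!spec$negative_noise) signal <- pmax(signal, 0)
  }
  as.integer(pmin(pmax(signal, -32768), 32767))
}

#' Threshold base caller for simulated flowgrams
#'
#' For each flow, emits `round(value / signal_scale)` copies of the flowed
#' base.  Exact inverse of [sequence_to_flowgram()] at zero noise.
#'
#' @param flowgram integer flow-signal vector.
#' @param flow_order nucleotide cycle used to produce it.
#' @param signal_scale integer signal per incorporated base.
#' @return called nucleotide string.
#' @export
call_bases <- function(flowgram, flow_order = "TACG", signal_scale = 256L) {
  if (length(flowgram) == 0L) return("")
  cycle <- strsplit(flow_order, "", fixed = TRUE)[[1]]
  bases <- cycle[((seq_along(flowgram) - 1L) %% length(cycle)) + 1L]
  h <- pmax(0L, as.integer(round(flowgram / signal_scale)))
  paste(strrep(bases, h), collapse = "")
}

#' Generate a synthetic Ion Torrent-like BAM fixture
#'
#' Writes a coordinate-plausible BAM: a random reference, loci spread along
#' it, `depth` reads per locus sharing a template (so same-locus reads have
#' similar but non-identical flow signals), per-read ZM flowgrams from
#' [sequence_to_flowgram()], FO/KS read-group metadata in the header, and
#' configurable fractions of unmapped and ZM-less reads.  The sequenced
#' template of every read is `key_sequence` followed by the (strand-
#' oriented) reference insert; the aligned SEQ field holds the insert only.
#' Identical specs (including the seed) give byte-identical output.
#'
#' @param spec a [simulation_spec()].
#' @param out_path output `.bam` (or `.sam`) path.
#' @param ref_fasta_path optional path to also write the reference FASTA
#'   (needed for a CRAM body).
#' @return list with `read_count`, `loci_count`, `path` and (when written)
#'   `reference`.
#' @export
generate_bam_fixture <- function(spec = simulation_spec(), out_path,
                                 ref_fasta_path = NULL) {
  stopifnot(inherits(spec, "flowcram_sim_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  bases <- c("A", "C", "G", "T")
  reference <- paste(sample(bases, spec$reference_length, replace = TRUE),
                     collapse = "")
  max_start <- spec$reference_length - spec$read_length
  loci_pos0 <- sort(sample.int(max_start + 1L, spec$n_loci,
                               replace = spec$n_loci > max_start + 1L)) - 1L
  loci_strand <- sample(0:1, spec$n_loci, replace = TRUE)

  qname <- character(0); flag <- integer(0); pos0 <- integer(0)
  cig <- character(0); seqs <- character(0); zm <- list()
  ridx <- 0L
  add_read <- function(fl, p0, cg, sq, template) {
    ridx <<- ridx + 1L
    qname[ridx] <<- sprintf("sim_%06d", ridx)
    flag[ridx] <<- fl
    pos0[ridx] <<- p0
    cig[ridx] <<- cg
    seqs[ridx] <<- sq
    zm[[ridx]] <<- sequence_to_flowgram(template, spec)
  }
  for (l in seq_len(spec$n_loci)) {
    insert <- substr(reference, loci_pos0[l] + 1L,
                     loci_pos0[l] + spec$read_length)
    template <- paste0(spec$key_sequence,
                       if (loci_strand[l] == 1L) revcomp(insert) else insert)
    for (m in seq_len(spec$depth)) {
      add_read(if (loci_strand[l] == 1L) 16L else 0L, loci_pos0[l],
               paste0(spec$read_length, "M"), insert, template)
    }
  }
  n_unmapped <- as.integer(round(spec$unmapped_fraction * ridx))
  for (u in seq_len(n_unmapped)) {
    sq <- paste(sample(bases, spec$read_length, replace = TRUE),
                collapse = "")
    add_read(4L, -1L, "*", sq, paste0(spec$key_sequence, sq))
  }
  n <- ridx
  drop_zm <- rep(FALSE, n)
  n_drop <- as.integer(round(spec$missing_zm_fraction * n))
  if (n_drop > 0L) drop_zm[sample.int(n, n_drop)] <- TRUE

  tags <- lapply(seq_len(n), function(i) {
    t <- "RG:Z:rg1"
    if (!drop_zm[i]) t <- c(t, format_zm_tag(zm[[i]], "s"))
    t
  })
  unmapped <- flag == 4L
  # per-base qualities drawn from the Phred 24-37 band, as real base callers
  # emit: keeps the non-flow body realistically incompressible
  quals <- vapply(nchar(seqs), function(len) {
    paste(sample(strsplit("9:;<=>?@ABCDEF", "")[[1]], len, replace = TRUE),
          collapse = "")
  }, character(1))
  rec <- data.table(
    qname = qname, flag = flag,
    rname = ifelse(unmapped, "*", "ref1"),
    pos0 = pos0, mapq = ifelse(unmapped, 0L, 60L), cigar = cig,
    rnext = "*", pnext = 0L, tlen = 0L, seq = seqs,
    qual = quals,
    tags = tags, original_index = seq_len(n) - 1L
  )
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:ref1\tLN:", spec$reference_length),
    paste0("@RG\tID:rg1\tFO:", spec$flow_order, "\tKS:", spec$key_sequence,
           "\tPL:IONTORRENT")
  )
  recset <- structure(list(header = header, records = rec),
                      class = "flowcram_records")
  write_records(recset, out_path)
  out <- list(read_count = n, loci_count = spec$n_loci, path = out_path)
  if (!is.null(ref_fasta_path)) {
    writeLines(c(">ref1", reference), ref_fasta_path)
    out$reference <- ref_fasta_path
  }
  out
}
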