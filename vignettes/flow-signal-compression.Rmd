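---
title: "Compressing Ion Torrent flow signals: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing Ion Torrent flow signals: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowcram)
```

## The problem and the model

Ion Torrent base calling works by flowing the four nucleotides over the
chip in a fixed cyclic order and measuring the pH change at every flow.
The processed measurement vector — one integer per flow, proportional to
the homopolymer length incorporated at that flow, near zero (and sometimes
negative) at non-incorporating flows — is stored per read in the BAM `ZM`
auxiliary tag, with the flow cycle (`FO`) and the `TCAG` key sequence
(`KS`) in the read-group header.  These vectors are large: on our
simulated data, as on real panels and exomes, they account for roughly
three quarters of the BAM's bytes.

The compression model rests on one empirical premise: reads aligned to the
same locus sequence essentially the same template, so their flow vectors
agree up to measurement noise.  `flowcram` therefore sorts reads to bring
same-locus reads together, groups them into blocks keyed by (contig,
leftmost position, strand), and stores each block as a reference vector
$F_1$ plus chained differences $D_i = F_i - F_{i+1}$.  Decoding applies
$F_{i+1} = F_i - D_i$.  When the premise holds, the $D_i$ concentrate
tightly around zero and the downstream dictionary compressor (xz, gzip or
zstd) encodes them in a fraction of the space the raw vectors need; when
it does not hold (depth-1 data, high noise), the scheme degrades to
approximately the cost of storing the raw vectors, but never loses
information.

Strand is part of the block key because reverse-strand reads store their
bases reference-oriented while `ZM` stays in sequencing order: flow vectors
from opposite strands of the same position are dissimilar, and mixing them
would poison the delta chain.

## Tunable parameters

* `backend` (`"xz"` default, `"gzip"`, `"zstd"`) and `level` — the
  general-purpose compressor for the flow stream, body fallback and
  permutation.  Defaults are each tool's maximum-compression setting
  (gzip 9, xz 9, zstd 22, the top of its ultra range): the intended use is
  long-term archiving, where space dominates speed.
* `strategy` — `"first"` (chained deltas against $F_1$, default) or
  `"median"` (each member differenced against the block's position-wise
  rounded average, non-chained).  Chaining against a synthetic average is
  ill-defined — the average is not any member — so the median strategy
  differences every member directly against the fixed reference.  In our
  measurements the median strategy does not improve on `"first"`, which is
  why `"first"` is the default.
* `max_block_size` (65535) — caps memory per block and bounds how far a
  corrupted delta could propagate along a chain.  Same-locus runs longer
  than the cap are split; the cap is far above any realistic per-locus
  depth.
* `bin` (off by default) — lossy binning $z = \lceil y/x \rceil \cdot x$
  with negatives forced to zero, applied once, before delta encoding, and
  only on explicit request.  Archival of medical data should use the
  lossless default; binning exists to quantify the space/fidelity
  trade-off.
* `keep_order` (TRUE) — stores a delta-plus-varint-coded permutation so
  decompression restores the exact original record order; dropping it
  saves a small component and yields sorted output.
* `chunk_bytes` (16 MiB) — serialized blocks are pooled into chunks of
  this size before backend compression.  Per-block compression would
  parallelise perfectly but waste dictionary context on small blocks;
  whole-stream compression would serialise everything.  Chunks are
  independent: they can be compressed and decompressed in any order or
  concurrently, and the output is invariant to scheduling.

## Archive layout and integrity

The archive is a plain `tar` container: `manifest.json` first (format
version, backend, strategy, body codec, chunk index, per-component MD5
digests, source record count and header), then the body, the flow chunks,
and the permutation.  Every component digest is verified before any output
is written, so a flipped byte anywhere yields a corruption error rather
than a plausible-looking BAM.  Tar metadata (mtime, owner) is pinned, so
identical input and options produce byte-identical archives.

The flow-free body goes to CRAM via `samtools view -C` when a reference
FASTA is available — the reference is identified in the manifest by name
and digest, not embedded — and otherwise the ZM-stripped BAM is
backend-compressed directly (`fallback_bam`).  Re-implementing CRAM is
explicitly out of scope.

## Numerical and encoding conventions

* **Delta orientation.**  $D_i = F_i - F_{i+1}$, fixed by the decode rule
  $F_{i+1} = F_i - D_i$; the encoder is defined to match the decoder.
* **Unequal lengths.**  Reads at one locus can execute different numbers
  of flow cycles.  Differences are taken over the common prefix and the
  later vector's remainder is stored raw; true lengths are recorded, so
  decoding is exact for any length pattern.
* **Wire format.**  Values are zig-zag mapped (0, −1, 1, −2 → 0, 1, 2, 3)
  and written as LEB128 varints: near-zero deltas, the dominant case, cost
  one byte.  Each block is prefixed with its byte length, making the
  stream self-delimiting; truncated input always errors, never mis-decodes.
* **Median rounding.**  The position-wise average need not be integral;
  it is rounded half away from zero, and at each position only the members
  long enough to reach it contribute.
* **Missing `ZM` tags.**  Legal and tracked via a per-block presence
  bitmap; the delta chain skips absent members and continues between
  present neighbours.
* **`ZM` dialect.**  Read as any SAM integer `B` array subtype; values
  must fit the signed 16-bit range (the Ion convention).  The original
  subtype code and the tag's position among the read's tags travel with
  each vector, so reattachment restores the tag byte-for-byte where it
  stood.  We preserve the subtype as read rather than normalising to `s`:
  exact round-trip identity outweighs dialect tidiness.
* **Sorting.**  Plain lexicographic C-locale comparison of CIGAR text;
  final tiebreak by read name and original index, so sorting — and hence
  the archive — is fully deterministic.  Unmapped reads sort after all
  mapped reads by a 32-base sequence prefix and are blocked by size alone;
  coordinates never exist for them, so any locus rule would be arbitrary.

## The simulator, and what passing tests show

`generate_bam_fixture()` emulates the features the codec relies on: a
cyclic flow order (default `TACG`), the `TCAG` key prepended to every
sequenced template, signals of `signal_scale` (default 256) per
incorporated base — the true Torrent Suite scaling is not public, and only
relative similarity matters to the codec — additive integer-rounded
Gaussian noise (independent per flow and read, negative values allowed at
non-incorporating flows), flows completing the cycle in progress when the
template is exhausted, a fixed per-locus read count equal to `depth`,
per-base qualities drawn uniformly from the Phred 24–37 band (so the
non-flow body is realistically incompressible; with constant qualities the
flow share of the BAM is grossly overstated), and configurable fractions
of unmapped and `ZM`-less reads.  `call_bases()` inverts the flowgram by
rounding each value to a homopolymer count, which validates the simulated
signals at zero noise and at moderate noise with high probability.

The simulator does **not** emulate: real instrument error profiles
(phase, droop, inter-flow correlation), indels and clipping (all CIGARs
are full-length matches), barcodes, multi-read-group files, or the true
`ZM` scaling.  Passing round-trip tests therefore demonstrates
losslessness for arbitrary tag/field content — that argument is purely
structural — but measured compression ratios on fixtures say nothing
quantitative about multi-gigabyte clinical BAMs, whose depth, chemistry
and base-caller consistency differ.  The mechanism test (chained deltas
at least 20% smaller than raw vectors under xz at depth 50, noise sd 10)
checks the premise, not a production ratio.

Test and acceptance problem sizes — references of 1.2–4 kb, reads of
80–200 bases, depths 1–200, a few hundred reads per fixture — were chosen
so the whole suite exercises every code path, both strategies, all three
backends and both orderings in well under the time a desk check should
take.

## Degenerate inputs and edge behaviour

Header-only BAMs produce archives with empty flow and body record streams
and round trip exactly.  Blocks whose members all lack `ZM` serialize to a
presence bitmap only.  Empty flow vectors (`ZM:B:s` with no values) are
preserved as length-0 vectors.  Records with `ZM` of a non-integer array
type, values outside the 16-bit range, mapped reads naming contigs absent
from the header, and unsorted block input all raise typed errors naming
the offending read or rank.

## Known limitations

* CRAM does not preserve auxiliary-tag *order*; `flowcram` pins down the
  `ZM` tag position itself and restores the source header verbatim, and
  `MD`/`NM` regeneration is disabled on decode, but a body whose reads
  carry several other tags may come back with those tags reordered by the
  CRAM round trip.  Content is never lost.  (Bodies whose reads carry at
  most one non-ZM tag, as in all our fixtures, round trip exactly.)
* No random access: the archive must be decompressed as a whole.
* Only `ZM` receives special treatment; other Ion tags (`ZP`, `ZF`, …)
  pass through to the body untouched.
* Absolute space savings depend on the CRAM implementation and backend
  versions recorded at compression time; they are reproducible on one
  system but not guaranteed to match numbers measured elsewhere.
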