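read_bytes <- function(p) readBin(p, raw(), file.size(p))

test_that("archives round trip a mixed fixture exactly, in original order", {
  bam <- tempfile(fileext = ".bam"); arc <- tempfile(fileext = ".fcram")
  out <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, arc, out)))
  quick_fixture(bam, reference_length = 2000, depth = 20, read_length = 100,
                noise_sd = 10, unmapped_fraction = 0.05,
                missing_zm_fraction = 0.05, seed = 101)
  src <- read_records(bam)
  manifest <- compress_archive(bam, arc)
  expect_equal(manifest$source_record_count, nrow(src$records))
  n <- decompress_archive(arc, out)
  expect_equal(n, nrow(src$records))
  expect_true(records_equal(src, read_records(out)))
})

test_that("a BAM without any ZM tags still round trips", {
  rs <- sam_recset(c(
    sam_line("a", pos1 = 10L, tags = "RG:Z:rg1"),
    sam_line("b", pos1 = 10L, tags = "RG:Z:rg1"),
    sam_line("c", pos1 = 40L, tags = c("RG:Z:rg1", "XY:i:3"))
  ))
  bam <- tempfile(fileext = ".bam"); arc <- tempfile(); out <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, arc, out)))
  write_records(rs, bam)
  compress_archive(bam, arc)
  decompress_archive(arc, out)
  expect_true(records_equal(rs, read_records(out)))
})

test_that("identical input and options give byte-identical archives", {
  bam <- tempfile(fileext = ".bam")
  a1 <- tempfile(); a2 <- tempfile()
  on.exit(unlink(c(bam, a1, a2)))
  quick_fixture(bam, reference_length = 1200, depth = 10, read_length = 80,
                noise_sd = 10, seed = 5)
  compress_archive(bam, a1)
  Sys.sleep(1.1)  # would expose any timestamp leaking into the container
  compress_archive(bam, a2)
  expect_identical(read_bytes(a1), read_bytes(a2))
})

test_that("a tampered chunk byte is a corruption error and no output appears", {
  bam <- tempfile(fileext = ".bam"); arc <- tempfile()
  out <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, arc, out)))
  quick_fixture(bam, reference_length = 1200, depth = 10, read_length = 80,
                noise_sd = 10, seed = 6)
  compress_archive(bam, arc)
  bytes <- read_bytes(arc)
  # locate the flow chunk's content inside the tar and flip one byte of it
  staging <- tempfile(); dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  utils::untar(arc, exdir = staging)
  chunk <- read_bytes(list.files(staging, "^flows_", full.names = TRUE)[1])
  probe <- chunk[101:116]
  hits <- which(bytes == probe[1])
  off <- NA_integer_
  for (h in hits) {
    if (h + 15L <= length(bytes) && identical(bytes[h:(h + 15L)], probe)) {
      off <- h; break
    }
  }
  expect_false(is.na(off))
  bytes[off] <- xor(bytes[off], as.raw(0xff))
  writeBin(bytes, arc)
  expect_error(decompress_archive(arc, out), "corruption error")
  expect_false(file.exists(out))
})

test_that("binned archives restore non-negative multiples of the bin width", {
  bam <- tempfile(fileext = ".bam"); arc <- tempfile()
  out <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, arc, out)))
  quick_fixture(bam, reference_length = 1200, depth = 10, read_length = 80,
                noise_sd = 20, seed = 8)
  compress_archive(bam, arc, bin = 10)
  decompress_archive(arc, out)
  rs <- read_records(out)
  vals <- unlist(lapply(seq_len(nrow(rs$records)),
                        function(i) extract_flow_vector(rs, i)))
  expect_true(all(vals >= 0L))
  expect_true(all(vals %% 10L == 0L))
  # binning is applied once: a second round trip is lossless
  arc2 <- tempfile(); out2 <- tempfile(fileext = ".bam")
  on.exit(unlink(c(arc2, out2)), add = TRUE)
  compress_archive(out, arc2)
  decompress_archive(arc2, out2)
  expect_true(records_equal(rs, read_records(out2)))
})

test_that("a CRAM body via samtools round trips with the reference", {
  bam <- tempfile(fileext = ".bam"); ref <- tempfile(fileext = ".fa")
  arc <- tempfile(); out <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, ref, arc, out)))
  spec <- simulation_spec(reference_length = 1500, depth = 12,
                          read_length = 90, noise_sd = 10, seed = 9)
  generate_bam_fixture(spec, bam, ref_fasta_path = ref)
  src <- read_records(bam)
  manifest <- compress_archive(bam, arc, reference = ref)
  expect_equal(manifest$body_codec, "external_cram")
  expect_error(decompress_archive(arc, out), "reference")
  decompress_archive(arc, out, reference = ref)
  expect_true(records_equal(src, read_records(out)))
})

test_that("dropping the permutation emits records in sorted order", {
  bam <- tempfile(fileext = ".bam"); arc <- tempfile()
  out <- tempfile(fileext = ".bam")
  on.exit(unlink(c(bam, arc, out)))
  quick_fixture(bam, reference_length = 1200, depth = 6, read_length = 80,
                noise_sd = 10, seed = 10)
  src <- read_records(bam)
  compress_archive(bam, arc, keep_order = FALSE)
  decompress_archive(arc, out)
  got <- read_records(out)
  so <- sort_records(src)
  expected_names <- src$records$qname[so$sorted_order]
  expect_equal(got$records$qname, expected_names)
  # same multiset of records: compare sorted SAM lines
  lines_src <- sort(flowcram:::format_sam_lines(src))
  lines_got <- sort(flowcram:::format_sam_lines(got))
  expect_identical(lines_got, lines_src)
})

test_that("archive_stats reports components and saving vs the source", {
  bam <- tempfile(fileext = ".bam"); arc <- tempfile()
  on.exit(unlink(c(bam, arc)))
  quick_fixture(bam, reference_length = 1200, depth = 10, read_length = 80,
                noise_sd = 10, seed = 12)
  compress_archive(bam, arc)
  st <- archive_stats(arc)
  expect_true(any(grepl("^flows_", st$components$component)))
  expect_equal(st$source_bytes, file.size(bam))
  expect_equal(st$percent_saving,
               space_saving(file.size(arc), file.size(bam))$percent)
})
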