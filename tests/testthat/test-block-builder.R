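test_that("sorting orders by coordinates then CIGAR text", {
  rs <- sam_recset(c(
    sam_line("a", rname = "chr1", pos1 = 101L),
    sam_line("b", rname = "chr1", pos1 = 51L),
    sam_line("c", rname = "chr2", pos1 = 11L)
  ))
  so <- sort_records(rs)
  expect_equal(rs$records$qname[so$sorted_order], c("b", "a", "c"))

  # lexicographic CIGAR comparison: "100M" < "10S90M" because '0' < 'S'
  rs2 <- sam_recset(c(
    sam_line("x", pos1 = 100L, cigar = "10S90M"),
    sam_line("y", pos1 = 100L, cigar = "100M")
  ))
  so2 <- sort_records(rs2)
  expect_equal(rs2$records$qname[so2$sorted_order], c("y", "x"))
})

test_that("permutation restores original order; sorted input gives identity", {
  rs <- sam_recset(c(
    sam_line("a", pos1 = 5L), sam_line("b", pos1 = 9L),
    sam_line("c", rname = "chr2", pos1 = 1L)
  ))
  so <- sort_records(rs)
  expect_equal(so$permutation, 0:2)
  rs2 <- sam_recset(c(sam_line("a", pos1 = 900L), sam_line("b", pos1 = 5L)))
  so2 <- sort_records(rs2)
  inv <- invert_permutation(so2$permutation)
  expect_equal(so2$permutation[inv], 0:1)
  expect_error(invert_permutation(c(0L, 0L)), "bijection")
})

test_that("same-locus reads form one block, capped by max_block_size", {
  lines <- vapply(1:5, function(i) sam_line(paste0("r", i), pos1 = 100L),
                  character(1))
  rs <- sam_recset(lines)
  so <- sort_records(rs)
  b1 <- build_blocks(rs, so$sorted_order, max_block_size = 64L)
  expect_length(b1, 1L)
  expect_length(b1[[1]]$rows, 5L)
  b2 <- build_blocks(rs, so$sorted_order, max_block_size = 2L)
  expect_equal(lengths(lapply(b2, `[[`, "rows")), c(2L, 2L, 1L))
})

test_that("strand splits a locus into separate blocks", {
  rs <- sam_recset(c(
    sam_line("f", pos1 = 101L, flag = 0L),
    sam_line("r", pos1 = 101L, flag = 16L),
    sam_line("g", pos1 = 102L, flag = 0L)
  ))
  so <- sort_records(rs)
  blocks <- build_blocks(rs, so$sorted_order)
  expect_length(blocks, 3L)
})

test_that("flattened blocks reproduce the sorted stream; unsorted input errors", {
  set.seed(41)
  lines <- vapply(1:60, function(i) {
    sam_line(sprintf("q%02d", i),
             rname = sample(c("chr1", "chr2"), 1),
             pos1 = sample(1:5, 1) * 10L,
             flag = sample(c(0L, 16L), 1))
  }, character(1))
  rs <- sam_recset(lines)
  so <- sort_records(rs)
  blocks <- build_blocks(rs, so$sorted_order)
  flat <- unlist(lapply(blocks, `[[`, "rows"))
  expect_equal(flat, so$sorted_order)
  expect_error(build_blocks(rs, rev(so$sorted_order)), "precondition error")
})

test_that("block boundaries match a naive grouping oracle on random records", {
  set.seed(99)
  lines <- vapply(1:100, function(i) {
    sam_line(sprintf("n%03d", i),
             rname = sample(c("chr1", "chr2"), 1),
             pos1 = sample(1:8, 1),
             flag = sample(c(0L, 16L), 1))
  }, character(1))
  rs <- sam_recset(lines)
  so <- sort_records(rs)
  blocks <- build_blocks(rs, so$sorted_order)
  # naive O(N^2)-spirit oracle: group sorted reads by identical locus key
  key <- vapply(so$sorted_order, function(r) {
    paste(rs$records$rname[r], rs$records$pos0[r],
          bitwAnd(rs$records$flag[r], 16L), sep = "|")
  }, character(1))
  oracle_sizes <- rle(key)$lengths
  expect_equal(lengths(lapply(blocks, `[[`, "rows")),
               as.integer(oracle_sizes))
})

test_that("unmapped reads trail the mapped reads in prefix order", {
  rs <- sam_recset(c(
    sam_line("u1", flag = 4L, rname = "*", pos1 = 0L, cigar = "*",
             seq = "TTTT"),
    sam_line("m1", pos1 = 10L),
    sam_line("u2", flag = 4L, rname = "*", pos1 = 0L, cigar = "*",
             seq = "AAAA")
  ))
  so <- sort_records(rs)
  expect_equal(rs$records$qname[so$sorted_order], c("m1", "u2", "u1"))
  blocks <- build_blocks(rs, so$sorted_order)
  expect_length(blocks, 2L)
  expect_null(blocks[[2]]$locus)
})
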