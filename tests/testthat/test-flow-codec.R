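test_that("chained encoding stores the first vector and F_i - F_{i+1} deltas", {
  enc <- encode_block(list(c(5L, 3L), c(4L, 4L)))
  expect_equal(enc$reference, c(5L, 3L))
  expect_equal(enc$deltas[[1]]$values, c(1L, -1L))
  expect_equal(enc$deltas[[1]]$tail, integer(0))

  # k identical vectors -> all-zero deltas
  enc2 <- encode_block(rep(list(c(7L, 7L, 7L)), 4))
  for (d in enc2$deltas) expect_equal(d$values, c(0L, 0L, 0L))

  # unequal lengths: delta over the common prefix, true lengths recorded
  enc3 <- encode_block(list(c(5L, 3L, 7L), c(5L, 3L)))
  expect_equal(enc3$deltas[[1]]$values, c(0L, 0L))
  expect_equal(enc3$deltas[[1]]$tail, integer(0))
  expect_equal(enc3$lengths, c(3L, 2L))
  expect_equal(decode_block(enc3), list(c(5L, 3L, 7L), c(5L, 3L)))
})

test_that("decoding applies F_2 = F_1 - D_1", {
  enc <- encode_block(list(c(5L, 3L), c(4L, 4L)))
  out <- decode_block(enc)
  expect_equal(out[[2]], c(4L, 4L))
  # single present member comes back unchanged
  enc1 <- encode_block(list(c(9L, -2L, 0L)))
  expect_equal(decode_block(enc1), list(c(9L, -2L, 0L)))
})

test_that("decode is the exact inverse of encode for both strategies", {
  set.seed(7)
  for (rep_i in 1:60) {
    blk <- random_block(sample(1:8, 1))
    for (strat in c("first", "median")) {
      enc <- encode_block(blk, strategy = strat)
      expect_identical(decode_block(enc), blk)
    }
  }
  # all-absent block is legal and decodes to all NULLs
  enc0 <- encode_block(list(NULL, NULL))
  expect_null(enc0$reference)
  expect_identical(decode_block(enc0), list(NULL, NULL))
})

test_that("chained decode agrees with a brute-force prefix-sum oracle", {
  set.seed(8)
  for (rep_i in 1:40) {
    blk <- random_block(sample(2:6, 1), absent_prob = 0)
    enc <- encode_block(blk)
    expect_identical(decode_block(enc), prefix_sum_decode(enc))
  }
})

test_that("median reference is the rounded position-wise mean", {
  expect_equal(median_reference(list(c(2L, 4L), c(4L, 6L))), c(3L, 5L))
  expect_equal(median_reference(list(c(9L, 1L))), c(9L, 1L))
  # 1.5 rounds away from zero
  expect_equal(median_reference(list(c(1L, 1L), c(2L, 2L))), c(2L, 2L))
  expect_equal(median_reference(list(c(-1L, -1L), c(-2L, -2L))), c(-2L, -2L))
  # ragged lengths: positions past a member's end are averaged without it
  expect_equal(median_reference(list(c(2L, 10L), 4L)), c(3L, 10L))
  # high-precision mean oracle on random input
  set.seed(12)
  vs <- lapply(1:5, function(i) sample(-300:300, 20))
  mu <- rowMeans(sapply(vs, identity))
  expect_equal(median_reference(vs),
               as.integer(sign(mu) * floor(abs(mu) + 0.5)))
})

test_that("zig-zag maps 0,-1,1,-2 to 0,1,2,3 and inverts", {
  expect_equal(flowcram:::zigzag(c(0L, -1L, 1L, -2L)), c(0, 1, 2, 3))
  v <- -1000:1000
  expect_equal(flowcram:::unzigzag(flowcram:::zigzag(v)), as.numeric(v))
})

test_that("serialization round trips and the varint stream is compact", {
  set.seed(9)
  for (rep_i in 1:40) {
    blk <- random_block(sample(1:7, 1))
    for (strat in c("first", "median")) {
      enc <- encode_block(blk, strategy = strat,
                          tag_pos = sample(1:4, sum(!vapply(blk, is.null,
                                                            logical(1))),
                                           replace = TRUE))
      bytes <- serialize_block(enc)
      back <- deserialize_block(bytes)
      expect_equal(back$block, enc)
      expect_equal(back$next_offset, length(bytes) + 1L)
    }
  }
  # an all-zero-delta block beats its fixed-width form
  vs <- rep(list(rep(0L, 8)), 10)
  expect_lt(length(serialize_block(encode_block(vs))),
            length(flowcram:::serialize_raw_vectors(vs)))
})

test_that("truncated serialized blocks always error, never mis-decode", {
  blk <- list(c(500L, -3L, 12L), c(498L, -1L, 12L, 40L), NULL)
  bytes <- serialize_block(encode_block(blk))
  for (cut in c(1L, 3L, 8L, length(bytes) - 1L)) {
    expect_error(deserialize_block(bytes[seq_len(cut)]), "corruption error")
  }
  # flipped strategy byte
  bad <- bytes
  bad[3] <- as.raw(99)
  expect_error(deserialize_block(bad), "corruption error")
})

test_that("binning maps y to the ceiling multiple of x and zeroes negatives", {
  expect_equal(bin_value(17L, 10L), 20L)
  expect_equal(bin_value(-3L, 10L), 0L)
  expect_equal(bin_value(-3L, 7L), 0L)
  expect_equal(bin_value(20L, 10L), 20L)
  y <- 1:500
  z <- bin_value(y, 7L)
  expect_true(all(z %% 7L == 0L))
  expect_true(all(y <= z & z < y + 7L))
  expect_equal(bin_value(z, 7L), z)          # idempotent
  expect_true(all(diff(bin_value(-50:50, 5L)) >= 0L))  # monotone
  expect_identical(bin_vectors(list(c(-5L, 12L), NULL), 10L),
                   list(c(0L, 20L), NULL))
})
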