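test_that("reference sequence validates alphabet and reading frame", {
  expect_s3_class(reference_sequence("ACGT"), "reference_sequence")
  expect_error(reference_sequence("ACGU"), "A/C/G/T")
  expect_error(reference_sequence("ACGTA", is_coding = TRUE), "multiple of 3")
  expect_silent(reference_sequence("TACGTA", is_coding = TRUE,
                                   frame_offset = 0L))
  expect_silent(reference_sequence("TACGTAC", is_coding = TRUE,
                                   frame_offset = 1L))
})

test_that("quality filter requires min quality everywhere and no Ns", {
  expect_true(filter_read(toy_read("ACGT", 30), min_quality = 20))
  expect_false(filter_read(read_record("ACNT", c(40, 40, 40, 40))))
  expect_false(filter_read(read_record("ACGT", c(30, 19, 30, 30)),
                           min_quality = 20))
  expect_true(filter_read(read_record("ACGT", c(30, 20, 30, 30)),
                          min_quality = 20))
  expect_false(filter_read(read_record("", integer(0))))
  # configurable threshold (some assays use stricter cutoffs)
  expect_false(filter_read(toy_read("ACGT", 22), min_quality = 23))
})

test_that("paired-end merging keeps the higher-quality base", {
  fwd <- toy_read("ACG", 30)
  rev <- toy_rev_read("ACG", c(30, 30, 30))
  merged <- merge_paired_reads(fwd, rev)
  expect_equal(merged$bases, "ACG")
  expect_equal(merged$qualities, c(30, 30, 30))

  # enumerate every disagreement position on a 3-bp toy overlap: higher
  # quality wins and merged quality is the max of the pair
  for (pos in 1:3) {
    fb <- strsplit("ACG", "")[[1]]
    rb <- fb
    rb[pos] <- "T"
    fwd <- read_record(paste(fb, collapse = ""), c(35, 35, 35))
    rev <- toy_rev_read(paste(rb, collapse = ""), c(20, 20, 20))
    m1 <- merge_paired_reads(fwd, rev)
    expect_equal(m1$bases, "ACG")
    expect_equal(m1$qualities, c(35, 35, 35))
    # reverse read wins when it has the higher quality
    rev2 <- toy_rev_read(paste(rb, collapse = ""), c(40, 40, 40))
    m2 <- merge_paired_reads(fwd, rev2)
    expect_equal(strsplit(m2$bases, "")[[1]][pos], "T")
    expect_equal(m2$qualities, c(40, 40, 40))
  }
})

test_that("equal-quality disagreements merge to N and then fail the filter", {
  fwd <- read_record("ACG", c(30, 30, 30))
  rev <- toy_rev_read("AGG", c(30, 30, 30))
  merged <- merge_paired_reads(fwd, rev)
  expect_equal(merged$bases, "ANG")
  expect_false(filter_read(merged))
  expect_error(merge_paired_reads(toy_read("ACGT"), toy_read("ACG")),
               "overlap")
})

test_that("variant calling finds substitutions against the reference", {
  ref <- reference_sequence("ATGAAA", is_coding = TRUE)
  expect_equal(call_variant("ATGAAA", ref)$label, "_wt")
  expect_true(call_variant("ATGAAA", ref)$is_wildtype)

  v <- call_variant("ATGAGA", ref)
  expect_equal(v$substitutions$position, 5L)
  expect_equal(v$label, "c.5A>G (p.Lys2Arg)")

  expect_error(call_variant("ATGA", ref), "length")
})

test_that("multi-substitution calls match a position-wise comparison oracle", {
  ref <- toy_ref()
  set.seed(401)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    rb <- sb <- strsplit(ref$sequence, "")[[1]]
    nmut <- sample(0:4, 1)
    pos <- sort(sample(seq_along(sb), nmut))
    for (p in pos) rb[p] <- sample(setdiff(bases, sb[p]), 1)
    read <- paste(rb, collapse = "")
    key <- call_variant(read, ref)
    # oracle: brute-force position-wise diff
    expect_equal(key$substitutions$position, which(rb != sb))
    expect_equal(key$substitutions$ref, sb[rb != sb])
    expect_equal(key$substitutions$alt, rb[rb != sb])
    # round trip: applying the substitutions reproduces the read
    expect_equal(apply_variant(key, ref), read)
    # idempotence: calling the reconstructed sequence gives the same key
    expect_equal(call_variant(apply_variant(key, ref), ref)$label, key$label)
  }
})

test_that("coding labels use codon translation and position offsets", {
  ref <- toy_ref()
  # GGC -> GGT is synonymous Gly
  expect_equal(call_variant("ATGAAAGGTTAC", ref)$label, "c.9C>T (p.Gly3=)")
  # two substitutions in one codon are reported as one protein change
  expect_equal(call_variant("ATGCCAGGCTAC", ref)$label,
               "c.4A>C, c.5A>C (p.Lys2Pro)")
  # stop gain
  expect_equal(call_variant("ATGTAAGGCTAC", ref)$label,
               "c.4A>T (p.Lys2Ter)")
  off <- reference_sequence("ATGAAA", is_coding = TRUE, position_offset = 100L)
  expect_equal(call_variant("ATGAGA", off)$label, "c.105A>G (p.Lys2Arg)")
  nc <- reference_sequence("ATGAAA")
  expect_equal(call_variant("ATGAGA", nc)$label, "c.5A>G")
})

test_that("counting conserves reads between counts and rejection tallies", {
  ref <- toy_ref()
  wt <- ref$sequence
  mut <- "ATGAGAGGCTAC"
  reads <- c(
    lapply(1:10, function(i) toy_read(wt)),             # wild-type
    lapply(1:3, function(i) toy_read(mut)),             # one variant
    list(read_record(sub("A", "N", wt), rep(40, 12))),  # N-containing
    list(toy_read(wt, q = 10)),                         # low quality
    list(toy_read("ATG"))                               # wrong length
  )
  counts <- count_reads(reads, ref)
  tallies <- attr(counts, "tallies")
  expect_equal(unname(tallies["total"]), 16L)
  expect_equal(unname(tallies["counted"]), 13L)
  expect_equal(unname(tallies["low_quality"]), 2L)
  expect_equal(unname(tallies["wrong_length"]), 1L)
  expect_equal(counts$count[counts$variant == "_wt"], 10L)
  expect_equal(counts$count[counts$variant == "c.5A>G (p.Lys2Arg)"], 3L)
  # conservation: everything in is either counted or rejected
  expect_equal(sum(counts$count) + tallies[["low_quality"]] +
                 tallies[["wrong_length"]] + tallies[["unmapped_barcode"]],
               length(reads))
})

test_that("empty read streams give empty tables with zero tallies", {
  counts <- count_reads(list(), toy_ref())
  expect_equal(nrow(counts), 0L)
  expect_equal(unname(attr(counts, "tallies")["total"]), 0L)
})

test_that("barcode counting sums many-to-one and excludes unmapped barcodes", {
  map_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAAA\t_wt", "CCCC\t_wt", "GGGG\tc.5A>G"), map_path)
  map <- read_barcode_map(map_path)
  expect_length(map, 3L)

  reads <- lapply(c("AAAA", "CCCC", "AAAA", "GGGG", "TTTT"), toy_read)
  counts <- count_reads(reads, barcode_map = map)
  expect_equal(counts$count[counts$variant == "_wt"], 3L)
  expect_equal(counts$count[counts$variant == "c.5A>G"], 1L)
  expect_equal(unname(attr(counts, "tallies")["unmapped_barcode"]), 1L)

  dup_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAAA\t_wt", "AAAA\tc.5A>G"), dup_path)
  expect_error(read_barcode_map(dup_path), "duplicated")
})

test_that("FASTQ round-trips through files, including gzipped input", {
  bases <- c("ATGAAAGGCTAC", "ATGAGAGGCTAC")
  quals <- list(rep(38L, 12), c(rep(35L, 6), rep(20L, 6)))
  for (gz in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
    write_toy_fastq(path, bases, quals, gz = gz)
    reads <- read_fastq(path)
    expect_equal(length(reads), 2L)
    expect_equal(reads$bases, bases)
    expect_equal(reads$qualities, quals)
  }
})
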