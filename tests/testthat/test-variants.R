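test_that("aligned FASTA round-trips and ragged input is rejected", {
  k <- make_kir_like_msa(n_receptors = 5, n_variants = 6, seed = 3,
                         out_dir = tempfile("msa"))
  msa <- read_msa(k$paths$msa)
  expect_equal(msa$ids, k$msa$ids)
  expect_equal(msa$seqs, k$msa$seqs)

  ragged <- tempfile(fileext = ".afa")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), ragged)
  expect_error(read_msa(ragged), "ragged|lengths")

  allgap <- tempfile(fileext = ".afa")
  writeLines(c(">a", "AC-EF", ">b", "GH-KL"), allgap)
  m <- read_msa(allgap)
  expect_equal(m$length, 5)   # all-gap column retained, no silent trimming
})

test_that("variant positions map through the alignment to reference numbering", {
  msa <- epifoot:::new_msa(
    c("REF", "RECA", "GAPPY"),
    c("MKTAYIAKQR",
      "MKTQYIAKQR",
      "MK--YIAKQR")
  )
  # identity mapping on the reference itself
  expect_equal(to_reference_numbering(list(receptor = "REF", position = 4, ref = "A"),
                                      msa, "REF"), 4)
  # receptor with an upstream deletion: its position 3 (Y) is reference 5
  expect_equal(to_reference_numbering(list(receptor = "GAPPY", position = 3, ref = "Y"),
                                      msa, "REF"), 5)
  # column where the reference has a gap -> unmapped
  expect_true(is.na(to_reference_numbering(list(receptor = "RECA", position = 3, ref = "T"),
                                           msa, "GAPPY")))
  # stale numbering is caught by the ref-aa consistency check
  expect_error(to_reference_numbering(list(receptor = "RECA", position = 4, ref = "A"),
                                      msa, "REF"), "inconsistency")
  expect_error(to_reference_numbering(list(receptor = "NOPE", position = 1, ref = "M"),
                                      msa, "REF"), "not in alignment")
})

test_that("mapping is independent of MSA record order", {
  k <- make_kir_like_msa(n_receptors = 6, n_variants = 8, seed = 9)
  msa <- k$msa
  perm <- epifoot:::new_msa(rev(msa$ids), rev(msa$seqs))
  for (i in seq_len(nrow(k$variants))) {
    v <- k$variants[i, ]
    expect_equal(to_reference_numbering(v, msa, "KIR2DL3"),
                 to_reference_numbering(v, perm, "KIR2DL3"))
  }
})

test_that("epitope intersection reports every variant exactly once", {
  k <- make_kir_like_msa(n_receptors = 7, n_variants = 12, seed = 1,
                         out_dir = tempfile("msa"))
  msa <- read_msa(k$paths$msa)
  v <- read_variant_table(k$paths$variants)
  fp <- utils::read.csv(k$paths$footprint)
  rep <- intersect_epitope(v, msa, fp, reference_id = "KIR2DL3",
                           epitope_threshold = 1)
  expect_equal(nrow(rep), nrow(v))
  expect_false(any(duplicated(rep[, c("receptor", "position", "alt")])))
  # agreement with the generator's expected report
  m <- merge(rep, k$expected, by = c("receptor", "position"))
  expect_equal(nrow(m), nrow(v))
  expect_equal(m$in_epitope.x, m$in_epitope.y)
  expect_equal(m$reference_position.x, m$reference_position.y)
  # in_epitope consistent with the threshold actually used
  expect_equal(rep$in_epitope,
               !is.na(rep$buried_area) & rep$buried_area >= 1)
  # sorted by reference position
  expect_false(is.unsorted(rep$reference_position, na.rm = TRUE))
  # frequencies carried through
  expect_true(all(rep$frequency >= 0 & rep$frequency <= 1))
})

test_that("contacts touching a variant residue are listed by kind", {
  msa <- epifoot:::new_msa(c("REF", "ALT"), c("MKTAYIAKQR", "MKTAYIAKQR"))
  fp <- data.frame(position = 5, dsasa = 25)
  contacts <- data.frame(kind = c("hbond", "cation_pi"),
                         resno_b = c(5, 5))
  rep <- intersect_epitope(
    data.frame(receptor = "ALT", position = 5, ref = "Y", alt = "F",
               rs_id = "rs1", frequency = 0.01),
    msa, fp, "REF", contacts = contacts)
  expect_true(rep$in_epitope)
  expect_equal(rep$contact_kinds, "cation_pi,hbond")
})

test_that("variant table validation catches malformed input", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("receptor,position,ref,alt,rs_id,frequency",
               "KIR2DL3,47,D,D,rs1,0.1"), f)
  expect_error(read_variant_table(f), "ref == alt")
  writeLines(c("receptor,position", "KIR2DL3,47"), f)
  expect_error(read_variant_table(f), "lacks column")
})
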