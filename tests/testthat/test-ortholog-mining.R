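test_that("identity self-alignment has no gaps and percent score 100", {
  a <- global_align(protein_record("a", "ACDE"), protein_record("b", "ACDE"))
  expect_equal(a$aligned_ref, "ACDE")
  expect_equal(a$aligned_query, "ACDE")
  expect_equal(a$percent_score, 100)
})

test_that("global alignment score matches the exhaustive enumeration oracle", {
  # classic textbook pair, expected value frozen from the oracle
  a <- global_align(protein_record("a", "HEAGAWGHEE"),
                    protein_record("b", "PAWHEAE"))
  expect_equal(a$raw_score, 1)
  expect_equal(a$raw_score, align_score_oracle("HEAGAWGHEE", "PAWHEAE"))

  set.seed(7)
  for (i in 1:40) {
    p <- random_protein_string(sample(1:7, 1))
    q <- random_protein_string(sample(1:7, 1))
    expect_equal(global_align(p, q)$raw_score, align_score_oracle(p, q),
                 info = paste(p, q))
  }
})

test_that("alignment score is symmetric for symmetric matrices", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_protein_string(sample(3:12, 1))
    q <- random_protein_string(sample(3:12, 1))
    expect_equal(global_align(p, q)$raw_score, global_align(q, p)$raw_score)
  }
})

test_that("degenerate alignment inputs are rejected", {
  expect_error(global_align(protein_record("a", "ACDE"), ","),
               "invalid residue")
  expect_error(protein_record("a", ""), "empty")
  expect_error(global_align("ACDE", "ACDE", matrix = "NOSUCHMATRIX"),
               "unknown substitution matrix")
})

test_that("percent score is self-normalized and clamped", {
  expect_equal(percent_blosum_score(350, 700), 50)
  expect_equal(percent_blosum_score(-10, 700), 0)
  expect_error(percent_blosum_score(10, 0), "positive")
  a <- global_align("MKQWLE", "MKQWLE")
  expect_equal(a$percent_score, 100)
})

test_that("ortholog filtering keeps the >= threshold tier and partitions the input", {
  ref <- make_reference()
  # identical copy is kept at the default threshold
  flt <- filter_orthologs(list(protein_record("copy", ref$sequence)), ref)
  expect_length(flt$kept, 1)

  fam <- gen_ortholog_family(ref, 12, rep(c(TIER_LOW, TIER_HIGH), each = 6),
                             seed = 3)
  flt <- filter_orthologs(fam$records, ref, threshold = 70)
  expect_length(flt$kept, 6)
  expect_length(flt$discarded, 6)
  expect_setequal(vapply(flt$kept, function(r) r$id, character(1)),
                  sprintf("ortho_%03d", 7:12))
  # independent recomputation of each percent score
  self <- global_align(ref, ref)$raw_score
  for (r in fam$records) {
    expect_equal(flt$percent_scores[[r$id]],
                 percent_blosum_score(global_align(ref, r)$raw_score, self))
  }
  # partition invariant and degenerate thresholds
  expect_equal(length(flt$kept) + length(flt$discarded), length(fam$records))
  expect_length(filter_orthologs(fam$records, ref, threshold = 101)$kept, 0)
  expect_warning(out <- filter_orthologs(list(), ref), "empty")
  expect_length(out$kept, 0)
})

test_that("reference positions map through alignment columns", {
  ident <- global_align("ACDEF", "ACDEF")
  m <- map_reference_positions(ident, 3)
  expect_equal(m$query_position, 3)
  expect_equal(m$query_residue, "D")

  # single-deletion toy: ACDEF vs ACEF aligns as ACDEF / AC-EF
  aln <- global_align("ACDEF", "ACEF")
  m <- map_reference_positions(aln, 1:5)
  expect_equal(m$query_position, c(1L, 2L, NA, 3L, 4L))
  expect_equal(m$query_residue, c("A", "C", "-", "E", "F"))
  expect_error(map_reference_positions(aln, 6), "out of reference range")

  # round-trip: every mapped query position reads back the query residue
  qc <- strsplit("ACEF", "")[[1]]
  mapped <- m[!is.na(m$query_position), ]
  expect_equal(qc[mapped$query_position], mapped$query_residue)
})

test_that("planted contact-residue divergence is read out by the logo", {
  ref <- make_reference(len = 60)
  contacts <- c(28, 30)
  fam <- gen_ortholog_family(ref, 20, 0.05, contact_positions = contacts,
                             planted_residues = list(`4` = c("Q", "Q"),
                                                     `9` = c("Q", "Q")),
                             seed = 5)
  prof <- build_residue_logo(fam$records, ref, contacts, window = 11)
  expect_length(prof$window_positions, 11)
  expect_true(all(contacts %in% prof$window_positions))
  for (p in contacts) {
    col <- as.character(p)
    expect_gte(prof$frequency_table["Q", col], 2)
    expect_equal(prof$residue_table[c("ortho_004", "ortho_009"), col],
                 c(ortho_004 = "Q", ortho_009 = "Q"))
  }
})

test_that("logo information content spans 0 to log2(20) bits", {
  ref <- make_reference(len = 40)
  # perfectly conserved family: every column at the maximum
  fam <- gen_ortholog_family(ref, 10, 0, seed = 1)
  prof <- build_residue_logo(fam$records, ref, 20, window = 5)
  expect_equal(unname(prof$information_content), rep(log2(20), 5))
  # a column made uniform over all 20 residues carries 0 bits
  recs <- lapply(seq_along(AA20), function(i) {
    s <- ref$sequence
    substr(s, 20, 20) <- AA20[i]
    protein_record(paste0("v", i), s)
  })
  prof <- build_residue_logo(recs, ref, 20, window = 3)
  expect_equal(unname(prof$information_content[2]), 0)
  # counts at every column sum to the number of non-gap residues
  expect_true(all(colSums(prof$frequency_table) ==
                    colSums(prof$residue_table != "-")))
  expect_error(build_residue_logo(recs, ref, 20, window = 4), "odd")
})

test_that("hybrid design grafts the donor tail at the junction", {
  scaffold <- protein_record("scaffold", "MKQWLEHGARND")
  # junction at scaffold end: product is the scaffold itself
  h <- design_hybrid(scaffold, protein_record("d", "MKQWLEHGARND"),
                     junction_ref_pos = 12)
  expect_equal(h$product$sequence, scaffold$sequence)

  # identity-alignable toy: AAAAA + donor AAACC joined after position 3
  h <- design_hybrid(protein_record("s", "AAAAA"),
                     protein_record("d", "AAACC"), junction_ref_pos = 3)
  expect_equal(h$product$sequence, "AAACC")

  # verified point mutations, in product coordinates
  h <- design_hybrid(protein_record("s", "MRNDA"),
                     protein_record("d", "MRNDA"), junction_ref_pos = 5,
                     mutations = list(c("R", 2, "K")), name = "iHybrid")
  expect_equal(h$product$sequence, "MKNDA")
  expect_error(
    design_hybrid(protein_record("s", "MGNDA"),
                  protein_record("d", "MGNDA"), junction_ref_pos = 5,
                  mutations = list(c("R", 2, "K"))),
    "product has 'G' at position 2")
})
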