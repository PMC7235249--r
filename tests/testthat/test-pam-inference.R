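test_that("embedded spacers are found on the correct strand with exact coordinates", {
  spacer <- "ACGTACGTACGTTAGCCATG"
  left <- "TTTTGGGGCCCCAAAATTTT"
  right <- "GGGGTTTTAAAACCCCGGGG"
  genome_fwd <- paste0(left, spacer, right)
  hits <- find_protospacers(spacer_record("s1", spacer),
                            dna_record("g1", genome_fwd), 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 20)
  expect_equal(hits$end, 40)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  genome_rev <- paste0(left, revcomp_chr(spacer), right)
  hits <- find_protospacers(spacer_record("s1", spacer),
                            dna_record("g1", genome_rev), 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 20)
})

test_that("mismatch tolerance is respected and matches the brute-force oracle", {
  set.seed(21)
  genome <- random_dna_string(500)
  spacer <- random_dna_string(20)
  mutated <- spacer
  substr(mutated, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                   substr(spacer, 7, 7))[1]
  genome <- paste0(substr(genome, 1, 200), mutated, substr(genome, 221, 500))
  expect_equal(nrow(find_protospacers(spacer, genome, 0)), 0)
  h1 <- find_protospacers(spacer, genome, 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$mismatches, 1)
  expect_equal(h1[, c("start", "end", "strand", "mismatches")],
               hamming_scan_oracle(spacer, genome, 1),
               ignore_attr = TRUE)
  expect_error(find_protospacers(spacer, genome, 10), "spacer length/2")
})

test_that("hit sets equal the sliding-window Hamming oracle on random cases", {
  set.seed(31)
  for (i in 1:12) {
    genome <- random_dna_string(sample(300:800, 1), gc = runif(1, 0.3, 0.7))
    spacer <- random_dna_string(16)
    mm <- sample(0:2, 1)
    got <- find_protospacers(spacer, genome, mm)
    want <- hamming_scan_oracle(spacer, genome, mm)
    expect_equal(got[, c("start", "end", "strand", "mismatches")], want,
                 ignore_attr = TRUE)
  }
})

test_that("hits are strand-closed under reverse complement of the genome", {
  set.seed(41)
  genome <- random_dna_string(400)
  spacer <- random_dna_string(18)
  genome <- paste0(substr(genome, 1, 100), spacer,
                   substr(genome, 119, 300), revcomp_chr(spacer),
                   substr(genome, 319, 400))
  L <- nchar(genome)
  fwd <- find_protospacers(spacer, genome, 0)
  rev <- find_protospacers(spacer, revcomp_chr(genome), 0)
  expect_equal(nrow(fwd), nrow(rev))
  remapped <- data.frame(start = L - rev$end, end = L - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         mismatches = rev$mismatches)
  remapped <- remapped[order(remapped$start, remapped$strand), ]
  expect_equal(fwd[, c("start", "end", "strand", "mismatches")], remapped,
               ignore_attr = TRUE)
  # flank extraction is invariant under the same transformation
  flanks_fwd <- sort(vapply(seq_len(nrow(fwd)), function(i) {
    extract_pam_flank(fwd[i, ], dna_record("g", genome), 6)
  }, character(1)))
  flanks_rev <- sort(vapply(seq_len(nrow(rev)), function(i) {
    extract_pam_flank(rev[i, ], dna_record("g", revcomp_chr(genome)), 6)
  }, character(1)))
  expect_equal(flanks_fwd, flanks_rev)
})

test_that("PAM flanks are taken 3' of the protospacer on the matching strand", {
  spacer <- "GGGGCCCCAAAATTTTGGCC"
  genome <- paste0("AAAA", spacer, "TTCAAGGA")
  hit <- find_protospacers(spacer, genome, 0)
  expect_equal(extract_pam_flank(hit, dna_record("g", genome), 4), "TTCA")

  # reverse hit: flank is the reverse complement of the upstream context
  genome_rev <- paste0("AACGTGCA", revcomp_chr(spacer), "TTTT")
  hit <- find_protospacers(spacer, genome_rev, 0)
  expect_equal(hit$strand, "-")
  expect_equal(extract_pam_flank(hit, dna_record("g", genome_rev), 4),
               revcomp_chr("TGCA"))

  # flank flush with the genome end is excluded
  genome_end <- paste0("AAAA", spacer)
  hit <- find_protospacers(spacer, genome_end, 0)
  expect_true(is.na(extract_pam_flank(hit, dna_record("g", genome_end), 8)))
})

test_that("PAM matrix counts conserve observations", {
  m <- build_pam_matrix(c("AA", "AA", "AA"))
  expect_equal(m$n_observations, 3)
  expect_equal(unname(m$counts["A", ]), c(3, 3))
  expect_equal(unname(colSums(m$counts)), c(3, 3))
  expect_error(build_pam_matrix(character(0)), "no flanks")
  expect_error(build_pam_matrix(c("AAA", "AA")), "ragged")

  # sampled flanks match an independent per-column tally
  set.seed(51)
  flanks <- replicate(200, paste0(
    sample(c("A", "C", "G", "T"), 1),
    sample(c("A", "C", "G", "T"), 1, prob = c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3)),
    sample(c("A", "C", "G", "T"), 1, prob = c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3)),
    sample(c("A", "C", "G", "T"), 1, prob = c(0.1, 0.1, 0.7, 0.1))))
  m <- build_pam_matrix(flanks)
  chars <- do.call(rbind, strsplit(flanks, ""))
  for (j in 1:4) {
    expect_equal(unname(m$counts[, j]),
                 unname(vapply(c("A", "C", "G", "T"),
                               function(b) sum(chars[, j] == b), numeric(1))))
  }
  expect_true(all(colSums(m$counts) == 200))
})

test_that("information content follows 2 - H and is bounded", {
  expect_equal(information_content(build_pam_matrix(rep("A", 5)))[1], 2)
  expect_equal(information_content(build_pam_matrix(c("A", "C", "G", "T")))[1], 0)
  # counts (A:3, C:1): IC = 2 - H(0.75, 0.25)
  m <- build_pam_matrix(c("A", "A", "A", "C"))
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(information_content(m)[1], 2 - h, tolerance = 1e-12)
  expect_equal(2 - h, 1.18872, tolerance = 1e-5)
  # invariant to flank order
  set.seed(61)
  flanks <- replicate(50, random_dna_string(6))
  expect_equal(information_content(build_pam_matrix(flanks)),
               information_content(build_pam_matrix(sample(flanks))))
})

test_that("consensus calling applies the relative-frequency rule and IC floor", {
  m <- build_pam_matrix(rep("TAAG", 12))
  cc <- call_consensus(m)
  expect_equal(substr(cc$iupac, 2, 3), "AA")
  # perfectly uniform matrix is all N
  m <- build_pam_matrix(c("AAAA", "CCCC", "GGGG", "TTTT"),
                        weights = rep(3, 4))
  expect_warning(cc <- call_consensus(m, min_observations = 13), "low-confidence")
  expect_equal(cc$iupac, "NNNN")
  expect_true(cc$low_confidence)
})

test_that("a planted NAAN motif is recovered end to end from a phage cohort", {
  x <- gen_phage_cohort(3, 5000, 30, spacer_len = 20,
                        pam_profile = list("N", c(A = 0.9), c(A = 0.9), "N"),
                        mismatch_rate = 0, seed = 17)
  res <- infer_pam(x$spacers, x$genomes, max_mismatches = 0)
  expect_equal(substr(res$consensus$iupac, 2, 3), "AA")
  # every hit is a planted protospacer with its planted flank
  truth <- x$truth$params$planted
  merged <- merge(res$hits, truth, by = c("spacer_id", "genome_id"),
                  suffixes = c("", ".truth"))
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(merged$start, merged$start.truth)
  expect_equal(merged$strand, merged$strand.truth)
  expect_equal(merged$pam_flank,
               substr(merged$pam_flank.truth, 1, 8))
})

test_that("multi-hit spacer weighting keeps repeats from dominating", {
  genome <- paste0("ACGT", strrep("GGTTAACCGGTTAACCAAGG", 1),
                   "TTTTAAAA", strrep("GGTTAACCGGTTAACCAAGG", 1),
                   "CCCCGGGGTTTT")
  sp <- spacer_record("rep", "GGTTAACCGGTTAACCAAGG")
  res <- infer_pam(list(sp), list(dna_record("g", genome)),
                   max_mismatches = 0, flank_len = 4,
                   weight_multi_hits = TRUE,
                   min_observations = 1)
  expect_equal(res$matrix$n_observations, 1)
  expect_equal(unname(colSums(res$matrix$counts)), rep(1, 4))
})
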