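test_that("identical sequences align gap-free at 100% identity", {
  p <- random_protein(40, seed = 21)
  aln <- global_align(p, p)
  expect_equal(aln$aligned_a, p)
  expect_equal(aln$aligned_b, p)
  st <- identity_stats(aln)
  expect_equal(st$pct_identity, 100)
  expect_equal(st$pct_similarity, 100)
  expect_equal(st$n_columns_scored, 40L)
})

test_that("global scores match exhaustive enumeration", {
  expect_equal(global_align("MFW", "MW")$score,
               align_score_exhaustive("MFW", "MW"))
  set.seed(22)
  for (k in 1:60) {
    a <- random_protein(sample(2:6, 1))
    b <- random_protein(sample(2:6, 1))
    expect_equal(global_align(a, b)$score, align_score_exhaustive(a, b),
                 info = paste(a, b))
  }
})

test_that("local scores match exhaustive enumeration and clamp at zero", {
  set.seed(23)
  for (k in 1:40) {
    a <- random_protein(sample(2:6, 1))
    b <- random_protein(sample(2:6, 1))
    expect_equal(local_align(a, b)$score,
                 align_score_exhaustive(a, b, local = TRUE),
                 info = paste(a, b))
  }
  # all-negative scoring pairs give the empty alignment
  aln <- local_align("AAAA", "WWWW")
  expect_equal(aln$score, 0)
  expect_equal(nchar(aln$aligned_a), 0L)
})

test_that("a planted identical segment is recovered exactly by local alignment", {
  set.seed(24)
  core <- random_protein(25)
  a <- paste0(random_protein(15), core, random_protein(10))
  b <- paste0(random_protein(8), core, random_protein(12))
  aln <- local_align(a, b)
  expect_true(grepl(core, aln$aligned_a, fixed = TRUE))
  # the hit contains the core; chance matches may extend it a little
  expect_lte(aln$a_span[1], 16)
  expect_gte(aln$a_span[2], 40)
  expect_lte(aln$a_span[2] - aln$a_span[1] + 1, 25 + 12)
})

test_that("alignment score properties hold", {
  set.seed(25)
  for (k in 1:20) {
    a <- random_protein(sample(3:10, 1))
    b <- random_protein(sample(3:10, 1))
    # symmetry under a symmetric matrix
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    # appending an identical residue never decreases the global score
    r <- random_protein(1)
    expect_gte(global_align(paste0(a, r), paste0(b, r))$score,
               global_align(a, b)$score)
  }
  expect_error(global_align("ACGT", "MKQE", matrix = "DNA"),
               "alphabet error")
})

test_that("identity statistics follow the declared column conventions", {
  mk <- function(a, b) {
    structure(list(aligned_a = a, aligned_b = b, score = 0,
                   matrix_id = "BLOSUM62", gap_open = 10, gap_extend = 1,
                   type = "global"), class = "pair_alignment")
  }
  expect_equal(identity_stats(mk("AAAA", "AAAV"))$pct_identity, 75)
  # terminal-gap columns are excluded from the denominator
  st <- identity_stats(mk("MF-", "MFW"))
  expect_equal(st$n_columns_scored, 2L)
  expect_equal(st$pct_identity, 100)
  # internal gaps count as mismatches
  st2 <- identity_stats(mk("MA-W", "MAAW"))
  expect_equal(st2$n_columns_scored, 4L)
  expect_equal(st2$pct_identity, 75)
  # similarity counts within-group substitutions (I and V are one group)
  st3 <- identity_stats(mk("MI", "MV"))
  expect_equal(st3$pct_identity, 50)
  expect_equal(st3$pct_similarity, 100)
  expect_error(identity_stats(mk("--", "AB")), "degenerate alignment")
  # randomized pairs match an independent column-counting oracle
  set.seed(26)
  for (k in 1:10) {
    aln <- global_align(random_protein(30), random_protein(25))
    a <- strsplit(aln$aligned_a, "")[[1]]
    b <- strsplit(aln$aligned_b, "")[[1]]
    scored <- which(cumsum(a != "-") > 0 & cumsum(b != "-") > 0 &
                      rev(cumsum(rev(a != "-")) > 0) &
                      rev(cumsum(rev(b != "-")) > 0))
    expect_equal(identity_stats(aln)$pct_identity,
                 100 * sum(a[scored] == b[scored] & a[scored] != "-") /
                   length(scored))
  }
})
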