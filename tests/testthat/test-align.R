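test_that("known alignment scores and the local floor", {
  m <- load_matrix("BLOSUM62")
  # perfect 4-residue match: 4 * s(A,A) = 16; no gap can improve it
  expect_equal(sw_score("AAAA", "AAAA", m), 16L)
  expect_equal(sw_score("AAAA", "AAAA", m, method = "wavefront"), 16L)
  # all substitution scores <= 0 floors the local score at 0
  expect_equal(sw_score("W", "P", m), 0L)
  expect_equal(sw_score("WWWW", "PPGG", m), 0L)
  expect_error(sw_score("", "AAAA", m), "empty")
})

test_that("scores match the exhaustive chaining enumerator on small instances", {
  m <- load_matrix("BLOSUM62")
  set.seed(101)
  for (rep in 1:60) {
    a <- random_residues(sample(1:8, 1))
    b <- random_residues(sample(1:8, 1))
    expect_equal(
      sw_score(a, b, m),
      oracle_local_align(a, b, m$scores, 10, 2),
      info = paste(a, b)
    )
  }
  # and under a different gap regime
  for (rep in 1:40) {
    a <- random_residues(sample(1:8, 1))
    b <- random_residues(sample(1:8, 1))
    expect_equal(
      sw_score(a, b, m, gap_open = 5L, gap_extend = 1L),
      oracle_local_align(a, b, m$scores, 5, 1),
      info = paste(a, b)
    )
  }
})

test_that("scores match an independent alignment library on longer pairs", {
  suppressMessages(library(Biostrings))
  ref_mat <- get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  m <- load_matrix("BLOSUM62")
  set.seed(202)
  for (rep in 1:30) {
    a <- random_residues(sample(20:60, 1), aa_standard())
    b <- random_residues(sample(20:60, 1), aa_standard())
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = ref_mat, gapOpening = 10, gapExtension = 2
    ))
    expect_equal(sw_score(a, b, m), as.integer(ref), info = paste(a, b))
  }
})

test_that("symmetry, monotonicity and wavefront identity hold", {
  m <- load_matrix("BLOSUM62")
  set.seed(303)
  for (rep in 1:25) {
    a <- random_residues(sample(5:40, 1), aa_standard())
    b <- random_residues(sample(5:40, 1), aa_standard())
    s_ab <- sw_score(a, b, m)
    # symmetric matrix => symmetric score
    expect_equal(s_ab, sw_score(b, a, m))
    # anti-diagonal evaluation order changes nothing
    expect_equal(s_ab, sw_score(a, b, m, method = "wavefront"))
    # appending residues never decreases the optimal local score
    expect_gte(sw_score(paste0(a, random_residues(5, aa_standard())), b, m), s_ab)
    expect_gte(sw_score(a, paste0(b, random_residues(5, aa_standard())), m), s_ab)
  }
})

test_that("matrix and local-profile scoring agree exactly", {
  m <- load_matrix("BLOSUM62")
  set.seed(404)
  for (rep in 1:20) {
    a <- random_residues(sample(5:50, 1), aa_standard())
    b <- random_residues(sample(5:50, 1), aa_standard())
    prof <- build_local_profile(a, m)
    expect_identical(sw_score(a, b, m), sw_score(a, b, prof))
  }
  # a profile of the wrong length is rejected
  prof <- build_local_profile("AAAA", m)
  expect_error(sw_score("AAAAA", "ARND", prof), "does not match profile length")
})

test_that("batched scoring equals the loop of singles and preserves order", {
  m <- load_matrix("BLOSUM62")
  set.seed(505)
  q <- random_residues(30, aa_standard())
  subjects <- vapply(1:50, function(i) random_residues(sample(10:40, 1), aa_standard()),
                     character(1))
  batch <- sw_score_batch(q, subjects, m)
  singles <- vapply(subjects, function(s) sw_score(q, s, m), integer(1),
                    USE.NAMES = FALSE)
  expect_identical(batch, singles)
  # wavefront batch path agrees too
  expect_identical(sw_score_batch(q, subjects, m, method = "wavefront"), singles)
  # a batch of identical subjects gives identical scores
  expect_equal(unique(sw_score_batch(q, rep(subjects[1], 5), m)), singles[1])
  expect_equal(sw_score_batch(q, subjects[3], m), singles[3])
})
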