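cfg_small <- function(...) {
  psse_config(n_permutations = 100L, master_seed = 17, ...)
}

test_that("single-pair runs are deterministic end to end", {
  seqs <- generate_random_sequences(2, 120, seed = 3)
  r1 <- single_pair_psse(seqs[1, ], seqs[2, ], cfg_small())
  r2 <- single_pair_psse(seqs[1, ], seqs[2, ], cfg_small())
  expect_identical(r1, r2)
  expect_true(r1$pss >= 0 && r1$pss <= 1)
  expect_equal(r1$N, 100L)
  fit <- attr(r1, "fit")
  expect_s3_class(fit, "gumbel_fit")
  # pss recomputable bit-identically from (K, lambda, m, n, x)
  e <- r1$K * 120 * 120 * exp(-r1$lambda * r1$score)
  expect_identical(r1$pss, -expm1(-e))
})

test_that("a length-1 subject degenerates to a fit error with scores attached", {
  q <- generate_random_sequences(1, 80, seed = 5)
  err <- tryCatch(
    single_pair_psse(q, "A", cfg_small()),
    error = function(e) e
  )
  expect_s3_class(err, "error")
  # every permutation of a length-1 sequence is identical
  expect_length(unique(err$scores), 1L)
})

test_that("multi-pair grids have the contracted shape and reduce to single-pair", {
  qs <- generate_random_sequences(2, 90, seed = 21)
  ss <- generate_random_sequences(3, 90, seed = 22)
  ss$id <- paste0("subj", 1:3)
  res <- multi_pair_psse(qs, ss, cfg_small())
  expect_equal(nrow(res), 6L)
  # query-major, subject-minor order
  expect_equal(res$query_id, rep(qs$id, each = 3))
  expect_equal(res$subject_id, rep(ss$id, times = 2))
  ok <- is.na(res$error)
  expect_true(all(res$pss[ok] >= 0 & res$pss[ok] <= 1))

  single <- single_pair_psse(qs[1, ], ss[1, ], cfg_small())
  expect_equal(result_frame(single), result_frame(res[1, ]))
})

test_that("the three strategies return identical tables with the stated permutation counts", {
  qs <- generate_random_sequences(2, 80, seed = 31)
  ss <- generate_random_sequences(3, 80, seed = 32)
  runs <- lapply(c("intuitive", "data_reuse", "tiled"), function(st) {
    multi_pair_psse(qs, ss, cfg_small(strategy = st))
  })
  expect_identical(result_frame(runs[[1]]), result_frame(runs[[2]]))
  expect_identical(result_frame(runs[[2]]), result_frame(runs[[3]]))
  # intuitive re-permutes per pair; the others permute each subject once
  expect_equal(attr(runs[[1]], "permutation_count"), 2 * 3 * 100)
  expect_equal(attr(runs[[2]], "permutation_count"), 3 * 100)
  expect_equal(attr(runs[[3]], "permutation_count"), 3 * 100)
  # every strategy aligns each pair against N permutations plus the original
  for (r in runs) expect_equal(attr(r, "alignment_count"), 6 * 101)
})

test_that("self-comparison scores dominate the null and look significant", {
  set.seed(47)
  n_pairs <- 20
  self_pss <- numeric(n_pairs)
  rand_pss <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    s <- generate_random_sequences(2, 100, seed = 1000 + i)
    cfg <- psse_config(n_permutations = 100L, master_seed = i)
    rs <- single_pair_psse(s[1, ], s[1, ], cfg)
    self_pss[i] <- rs$pss
    # observed self-score is at least every permuted score
    expect_gte(rs$score, max(attr(rs, "fit")$scores))
    rr <- single_pair_psse(s[1, ], s[2, ], cfg)
    rand_pss[i] <- rr$pss
  }
  expect_lt(median(self_pss), median(rand_pss))
})

test_that("tile partitioning covers the subjects in order with a short last tile", {
  cfg <- psse_config(n_permutations = 1000L)
  big <- tibble::tibble(id = paste0("s", 1:2771), residues = strrep("A", 3))
  plan <- plan_tiled_run(big, cfg)
  expect_equal(attr(plan, "tile_size"), 14L)
  expect_equal(nrow(plan), 198L)
  expect_equal(sum(plan$size == 14L), 197L)
  expect_equal(plan$size[198], 13L)
  expect_equal(unlist(plan$subject_index), 1:2771)
  expect_equal(plan$n_tasks, plan$size * 1000L)

  exact <- plan_tiled_run(tibble::tibble(id = paste0("s", 1:14), residues = strrep("A", 3)), cfg)
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$size, 14L)

  rem <- plan_tiled_run(tibble::tibble(id = paste0("s", 1:5), residues = strrep("A", 3)), cfg)
  expect_equal(nrow(rem), 1L)
  expect_equal(rem$size, 5L)
})

test_that("PSSM-scored queries flow through the pipeline", {
  qs <- generate_random_sequences(1, 60, seed = 51)
  qs$id <- "q1"
  ss <- generate_random_sequences(2, 60, seed = 52)
  pssm_path <- tempfile(fileext = ".pssm")
  on.exit(unlink(pssm_path))
  write_ascii_pssm(qs[1, ], pssm_path, jitter = 2L, seed = 9)
  cfg <- cfg_small(pssm = list(q1 = pssm_path))
  res <- multi_pair_psse(qs, ss, cfg)
  expect_equal(nrow(res), 2L)
  expect_true(all(is.na(res$error)))
  # a PSSM of the wrong length is rejected
  qs2 <- qs
  qs2$residues <- substr(qs2$residues, 1, 50)
  qs2$length <- 50L
  expect_error(multi_pair_psse(qs2, ss, cfg), "50 residues")
})

test_that("result tables serialise to a self-describing TSV", {
  qs <- generate_random_sequences(1, 70, seed = 61)
  ss <- generate_random_sequences(2, 70, seed = 62)
  cfg <- cfg_small()
  res <- multi_pair_psse(qs, ss, cfg)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_psse_results(res, path, cfg)
  lines <- readLines(path)
  expect_true(any(grepl("^# master_seed: 17", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(body[1],
               "query_id\tsubject_id\tscore\tlambda\tK\tE_value\tpss\tN\tcensored")
  expect_equal(length(body), 3L)
  expect_s3_class(plot_psse_grid(res), "ggplot")
})
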