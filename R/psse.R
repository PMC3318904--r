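#' Configuration for a PSSE run
#'
#' Collects every tunable of the pipeline. Defaults are the standard study
#' conditions: BLOSUM62, affine gap penalty 10 + 2k, N = 1000 permutations,
#' quartile censoring, and the bundled 14-SM device profile for the tile
#' planner.
#'
#' @param n_permutations Number of permutations N of each subject (>= 50,
#'   the fit precondition).
#' @param gap_open,gap_extend Affine gap penalty magnitudes (gap of length k
#'   costs `gap_open + gap_extend * k`).
#' @param matrix Substitution matrix name or path (see [load_matrix()]).
#' @param pssm `NULL`, or a named list/character vector mapping query ids to
#'   PSI-BLAST ASCII PSSM paths; queries with an entry are scored with their
#'   position-specific profile, the rest with the matrix.
#' @param censor_value Censoring rule passed to [fit_censored_evd()].
#' @param master_seed Master seed; every random draw in a run derives from
#'   it.
#' @param strategy Batching strategy for multi-pair runs: `"tiled"` (the
#'   adaptive tile planner), `"data_reuse"` ("one permutation, all queries"),
#'   or `"intuitive"` (re-permute for every pair). All three produce
#'   identical results; they differ only in how much permutation work is
#'   repeated.
#' @param device A `device_model` for the tile planner.
#' @return A `psse_config` list.
#' @export
psse_config <- function(n_permutations = 1000L, gap_open = 10L, gap_extend = 2L,
                        matrix = "BLOSUM62", pssm = NULL,
                        censor_value = "auto", master_seed = 42,
                        strategy = c("tiled", "data_reuse", "intuitive"),
                        device = device_profile("tesla-c2050")) {
  strategy <- match.arg(strategy)
  if (n_permutations < 50) abort("`n_permutations` must be >= 50 (fit precondition)")
  structure(
    list(n_permutations = as.integer(n_permutations),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         matrix = matrix, pssm = pssm, censor_value = censor_value,
         master_seed = master_seed, strategy = strategy, device = device),
    class = "psse_config"
  )
}

#' @export
print.psse_config <- function(x, ...) {
  cat(sprintf("<psse_config> N = %d, gaps %d + %dk, matrix %s, censor %s, seed %s, strategy %s\n",
              x$n_permutations, x$gap_open, x$gap_extend,
              if (is.character(x$matrix)) x$matrix else "custom",
              format(x$censor_value), format(x$master_seed), x$strategy))
  invisible(x)
}

# Per-subject permutation seeds: subject j's N seeds come from a stream
# seeded with the j-th draw of the master stream. They depend only on
# (master_seed, j, N) -- never on the query or the batching strategy -- which
# is what makes the three strategies produce identical results.
subject_seed_plan <- function(master_seed, n_subjects, n_permutations) {
  masters <- lcg_draws_(lcg_seed(master_seed), n_subjects)$draws
  lapply(masters, function(s) lcg_draws_(lcg_seed_(s %% 2^32), n_permutations)$draws)
}

# normalize queries/subjects input to a sequence tibble
as_seq_tbl <- function(x, what) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    if (nrow(x) == 0L) abort(sprintf("empty %s set", what))
    return(seq_tbl(x$id, toupper(x$residues)))
  }
  if (is.character(x) && length(x) >= 1L) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0(what, seq_along(x))
    return(seq_tbl(ids, toupper(x)))
  }
  abort(sprintf("`%s` must be a sequence tibble or a character vector", what))
}

# resolve the scoring profile for one query under a config
query_scheme <- function(query_id, query_residues, mat, cfg) {
  path <- NULL
  if (!is.null(cfg$pssm)) path <- cfg$pssm[[query_id]]
  if (is.null(path)) return(build_local_profile(
    seq_tbl(query_id, query_residues), mat))
  prof <- read_ascii_pssm(path, fallback_matrix = mat)
  if (prof$length != nchar(query_residues)) {
    abort(sprintf("PSSM '%s' has %d positions but query '%s' has %d residues",
                  path, prof$length, query_id, nchar(query_residues)))
  }
  prof$query_id <- query_id
  prof
}

# score one (profile, subject) pair against its permutation null and fit
run_pair <- function(prof, subj_codes, seeds, cfg) {
  scores <- sw_permuted_scores_(subj_codes, seeds, prof$scores,
                                cfg$gap_open, cfg$gap_extend)
  x <- sw_score_(subj_codes, prof$scores, cfg$gap_open, cfg$gap_extend)
  fit <- fit_censored_evd(scores, censor_value = cfg$censor_value,
                          m = prof$length, n = length(subj_codes))
  sig <- pvalue(x, fit)
  list(score = x, lambda = fit$lambda, K = fit$K, E_value = sig$e_value,
       pss = sig$p_value, censored = fit$n_censored, fit = fit)
}

empty_result_row <- function(query_id, subject_id, n, err = NA_character_) {
  tibble::tibble(query_id = query_id, subject_id = subject_id,
                 score = NA_integer_, lambda = NA_real_, K = NA_real_,
                 E_value = NA_real_, pss = NA_real_, N = n,
                 censored = NA_integer_, error = err)
}

#' Pairwise statistical significance of a single sequence pair
#'
#' The single-pair pipeline: derive N permutation seeds from the master
#' seed, produce N permuted copies of the subject, score the query against
#' every copy and against the original subject (the observed score x), fit
#' the null scores to a Gumbel distribution by censored maximum likelihood,
#' and report `pss = 1 - exp(-K * m * n * exp(-lambda * x))`.
#'
#' @param query,subject One-row sequence tibbles or residue strings.
#' @param config A [psse_config()].
#' @return A one-row tibble with columns `query_id`, `subject_id`, `score`,
#'   `lambda`, `K`, `E_value`, `pss`, `N`, `censored` and `error`
#'   (`NA` unless the fit failed). The full `gumbel_fit` is attached as
#'   attribute `"fit"`.
#' @export
#' @examples
#' \donttest{
#' seqs <- generate_random_sequences(2, 120, seed = 3)
#' single_pair_psse(seqs[1, ], seqs[2, ],
#'                  psse_config(n_permutations = 200, master_seed = 7))
#' }
single_pair_psse <- function(query, subject, config = psse_config()) {
  q <- as_seq_tbl(query, "query")
  s <- as_seq_tbl(subject, "subject")
  stopifnot(nrow(q) == 1L, nrow(s) == 1L)
  res <- multi_pair_psse(q, s, config)
  if (!is.na(res$error[1])) {
    abort(res$error[1], scores = attr(res, "score_samples")[[1]])
  }
  res
}

#' Pairwise statistical significance over a query x subject grid
#'
#' Runs the PSSE pipeline for every (query, subject) pair under one of three
#' batching strategies. Per-subject permutation seeds depend only on
#' `(master_seed, subject index)`, so all strategies return bit-identical
#' tables; they differ in permutation work: `"intuitive"` re-permutes each
#' subject for every query (Q x S x N permutations), while `"data_reuse"`
#' and `"tiled"` permute every subject exactly once (S x N). The tiled
#' strategy additionally processes subjects in chunks sized by
#' [tile_size()] for the configured device.
#'
#' @param queries,subjects Sequence tibbles (columns `id`, `residues`) or
#'   character vectors.
#' @param config A [psse_config()].
#' @return A tibble with Q x S rows, query-major and subject-minor, columns
#'   `query_id`, `subject_id`, `score`, `lambda`, `K`, `E_value`, `pss`,
#'   `N`, `censored`, `error`. Per-pair failures (e.g. a degenerate null)
#'   are recorded in `error` and leave the numeric fields `NA`; the run
#'   continues. Attributes: `"permutation_count"`, `"alignment_count"`,
#'   `"score_samples"` (list of per-pair null score vectors, pair order) and
#'   `"tile_plan"` (tiled strategy only).
#' @export
multi_pair_psse <- function(queries, subjects, config = psse_config()) {
  stopifnot(inherits(config, "psse_config"))
  q <- as_seq_tbl(queries, "query")
  s <- as_seq_tbl(subjects, "subject")
  mat <- if (inherits(config$matrix, "substitution_matrix")) config$matrix
         else load_matrix(config$matrix)
  profs <- lapply(seq_len(nrow(q)),
                  function(i) query_scheme(q$id[i], q$residues[i], mat, config))
  for (p in profs) {
    if (!identical(p$alphabet, mat$alphabet)) {
      abort("all query profiles must share the substitution matrix alphabet")
    }
  }
  subj_codes <- lapply(s$residues, encode_residues, alphabet = mat$alphabet)
  seeds <- subject_seed_plan(config$master_seed, nrow(s), config$n_permutations)

  nq <- nrow(q); ns <- nrow(s); N <- config$n_permutations
  perm_count <- 0
  align_count <- 0
  # results indexed query-major, subject-minor
  rows <- vector("list", nq * ns)
  samples <- vector("list", nq * ns)
  slot <- function(qi, si) (qi - 1L) * ns + si

  do_pair <- function(qi, si, permuted = NULL) {
    prof <- profs[[qi]]
    scores <- if (is.null(permuted)) {
      sw_permuted_scores_(subj_codes[[si]], seeds[[si]], prof$scores,
                          config$gap_open, config$gap_extend)
    } else {
      sw_score_batch_(permuted, prof$scores, config$gap_open,
                      config$gap_extend, FALSE)
    }
    x <- sw_score_(subj_codes[[si]], prof$scores, config$gap_open,
                   config$gap_extend)
    row <- tryCatch({
      fit <- fit_censored_evd(scores, censor_value = config$censor_value,
                              m = prof$length, n = s$length[si])
      sig <- pvalue(x, fit)
      tibble::tibble(
        query_id = q$id[qi], subject_id = s$id[si], score = x,
        lambda = fit$lambda, K = fit$K, E_value = sig$e_value,
        pss = sig$p_value, N = N, censored = fit$n_censored,
        error = NA_character_)
    }, error = function(e) {
      out <- empty_result_row(q$id[qi], s$id[si], N, conditionMessage(e))
      out$score <- x
      out
    })
    rows[[slot(qi, si)]] <<- row
    samples[[slot(qi, si)]] <<- scores
    align_count <<- align_count + N + 1
  }

  tile_plan <- NULL
  if (config$strategy == "intuitive") {
    for (qi in seq_len(nq)) {
      for (si in seq_len(ns)) {
        do_pair(qi, si)          # permutes inside the alignment kernel
        perm_count <- perm_count + N
      }
    }
  } else if (config$strategy == "data_reuse") {
    for (si in seq_len(ns)) {
      permuted <- lapply(seeds[[si]], function(sd) permute_codes_(subj_codes[[si]], sd))
      perm_count <- perm_count + N
      for (qi in seq_len(nq)) do_pair(qi, si, permuted)
    }
  } else {  # tiled
    tile_plan <- plan_tiled_run(s, config)
    for (ti in seq_len(nrow(tile_plan))) {
      members <- tile_plan$subject_index[[ti]]
      permuted_tile <- lapply(members, function(si) {
        lapply(seeds[[si]], function(sd) permute_codes_(subj_codes[[si]], sd))
      })
      perm_count <- perm_count + length(members) * N
      for (qi in seq_len(nq)) {
        for (k in seq_along(members)) do_pair(qi, members[k], permuted_tile[[k]])
      }
    }
  }

  res <- dplyr::bind_rows(rows)
  attr(res, "permutation_count") <- perm_count
  attr(res, "alignment_count") <- align_count
  attr(res, "score_samples") <- samples
  if (!is.null(tile_plan)) attr(res, "tile_plan") <- tile_plan
  if (nq * ns == 1L && is.na(res$error[1])) {
    attr(res, "fit") <- fit_censored_evd(samples[[1]],
                                         censor_value = config$censor_value,
                                         m = q$length[1], n = s$length[1])
  }
  res
}

#' Partition subjects into device-sized tiles
#'
#' Splits the subject set into consecutive chunks of `T = tile_size(device,
#' N)` sequences (the last chunk may be smaller). Each tile carries
#' `size x N` alignment tasks per query, feeding `size` fits per round.
#'
#' @param subjects Sequence tibble or character vector.
#' @param config A [psse_config()].
#' @return A tibble with one row per tile: `tile`, `subject_index`
#'   (list-column of subject indices), `size`, `n_tasks` (= size x N).
#'   The tile size is attached as attribute `"tile_size"`.
#' @export
#' @examples
#' subjects <- generate_random_sequences(30, 50, seed = 1)
#' plan_tiled_run(subjects, psse_config(n_permutations = 1000))
plan_tiled_run <- function(subjects, config = psse_config()) {
  s <- as_seq_tbl(subjects, "subject")
  tsz <- tile_size(config$device, config$n_permutations)
  n <- nrow(s)
  starts <- seq(1L, n, by = tsz)
  plan <- tibble::tibble(
    tile = seq_along(starts),
    subject_index = lapply(starts, function(a) seq(a, min(a + tsz - 1L, n))),
    size = vapply(starts, function(a) min(a + tsz - 1L, n) - a + 1L, integer(1))
  )
  plan$n_tasks <- plan$size * config$n_permutations
  attr(plan, "tile_size") <- tsz
  plan
}

#' Write a PSSE result table as TSV
#'
#' Tab-separated with the configuration echoed as `#`-prefixed header
#' comments, so a result file is self-describing and reproducible.
#'
#' @param results Tibble from [multi_pair_psse()].
#' @param path Output path.
#' @param config The [psse_config()] used to produce `results` (echoed in
#'   the header), or `NULL`.
#' @return `path`, invisibly.
#' @export
write_psse_results <- function(results, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(c(
      sprintf("# n_permutations: %d", config$n_permutations),
      sprintf("# gap_open: %d", config$gap_open),
      sprintf("# gap_extend: %d", config$gap_extend),
      sprintf("# matrix: %s", if (is.character(config$matrix)) config$matrix else "custom"),
      sprintf("# censor_value: %s", format(config$censor_value)),
      sprintf("# master_seed: %s", format(config$master_seed)),
      sprintf("# strategy: %s", config$strategy)
    ), con)
  }
  cols <- c("query_id", "subject_id", "score", "lambda", "K", "E_value",
            "pss", "N", "censored")
  tab <- as.data.frame(results)[, cols]
  for (nm in c("lambda", "K", "E_value", "pss")) {
    tab[[nm]] <- sprintf("%.10g", tab[[nm]])
  }
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}

#' Significance heat map for a PSSE result table
#'
#' Tiles the query x subject grid coloured by -log10 of the pairwise
#' statistical significance, so related pairs stand out.
#'
#' @param results Tibble from [multi_pair_psse()].
#' @return A ggplot object.
#' @export
plot_psse_grid <- function(results) {
  stopifnot(all(c("query_id", "subject_id", "pss") %in% names(results)))
  df <- dplyr::mutate(results,
                      neglog = -log10(pmax(.data$pss, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id, y = .data$query_id,
                                   fill = .data$neglog)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 pss") +
    ggplot2::labs(x = "subject", y = "query") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
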