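# Exhaustive chaining enumerator for gapped local alignment: the optimum
# over all monotone chains of aligned residue pairs, charging the closed-form
# affine cost G + GE*k for each internal run of k unaligned residues and
# trimming the ends for free. Exhaustive over alignment structures and
# algorithmically independent of the Gotoh E/F recurrences it checks.
oracle_local_align <- function(a, b, scores, gap_open, gap_extend) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(ac)
  n <- length(bc)
  gap <- function(k) if (k > 0) gap_open + gap_extend * k else 0
  f <- matrix(-Inf, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best_prev <- 0
      if (i > 1 && j > 1) {
        for (i2 in seq_len(i - 1)) {
          for (j2 in seq_len(j - 1)) {
            v <- f[i2, j2] - gap(i - i2 - 1) - gap(j - j2 - 1)
            if (v > best_prev) best_prev <- v
          }
        }
      }
      f[i, j] <- scores[ac[i], bc[j]] + best_prev
    }
  }
  max(0, max(f))
}

# quantile-free Gumbel sampler: location mu, rate lambda
rgumbel <- function(n, mu, lambda) {
  mu - log(-log(runif(n))) / lambda
}

# random residue string over a given alphabet (uses R's RNG; callers set the
# seed)
random_residues <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# drop the run-bookkeeping attributes so result tables can be compared on
# their data alone
result_frame <- function(x) {
  out <- as.data.frame(x)
  for (a in c("permutation_count", "alignment_count", "score_samples",
              "tile_plan", "fit")) {
    attr(out, a) <- NULL
  }
  out
}

local_fasta <- function(lines, envir = parent.frame()) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  withr::defer(unlink(path), envir = envir)
  path
}
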