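#' Seed a 48-bit LCG stream
#'
#' The package's random number generator is the POSIX `lrand48` linear
#' congruential generator: state' = (a * state + c) mod 2^48 with
#' a = 25214903917 and c = 11, each draw being the top 31 bits of the
#' successor state. Seeding follows the `srand48` convention,
#' state = (seed mod 2^32) << 16 | 0x330E, so streams are bit-compatible
#' with the C library generator.
#'
#' States are held in doubles (every value below 2^48 is exact) and all
#' modular arithmetic runs in compiled 64-bit code.
#'
#' @param seed_value Nonnegative integer seed; reduced mod 2^32.
#' @return The stream state, a numeric scalar in `[0, 2^48)`.
#' @seealso [lcg_next()], [derive_permutation_seeds()], [permute_sequence()]
#' @export
#' @examples
#' lcg_seed(0)    # 0x330E
#' lcg_next(lcg_seed(0))$draw
lcg_seed <- function(seed_value) {
  if (!is.numeric(seed_value) || length(seed_value) != 1L || is.na(seed_value) ||
      seed_value < 0) {
    abort("`seed_value` must be a single nonnegative number")
  }
  lcg_seed_(seed_value %% 2^32)
}

#' Advance an LCG stream by one draw
#'
#' @param state A stream state from [lcg_seed()] or a previous draw.
#' @return A list with elements `state` (the successor state) and `draw`
#'   (an integer-valued numeric in `[0, 2^31)`).
#' @export
lcg_next <- function(state) {
  stopifnot(is.numeric(state), length(state) == 1L, state >= 0, state < 2^48)
  lcg_next_(state)
}

#' Take several draws from an LCG stream
#'
#' @param state A stream state.
#' @param n Number of draws.
#' @return A list with elements `state` and `draws` (numeric vector of
#'   length `n`, values in `[0, 2^31)`).
#' @export
lcg_draws <- function(state, n) {
  stopifnot(is.numeric(state), length(state) == 1L, state >= 0, state < 2^48)
  if (!is.numeric(n) || n < 0) abort("`n` must be a nonnegative integer")
  lcg_draws_(state, as.integer(n))
}

#' Derive independent per-permutation seeds from one master seed
#'
#' Seeds are generated centrally and each permutation later runs its own
#' stream: the i-th per-permutation seed is the i-th draw from a master
#' stream seeded with `master_seed`. Permutation i can therefore be
#' reproduced in isolation, and permutations i and j (i != j) use disjoint
#' streams.
#'
#' @param master_seed Master seed for the central stream.
#' @param n_permutations Number of permutation streams to provision (N >= 1).
#' @return A `permutation_plan`: list with `master_seed`, `n_permutations`
#'   and `seeds` (numeric vector of N 31-bit seeds).
#' @export
#' @examples
#' plan <- derive_permutation_seeds(0, 3)
#' plan$seeds
derive_permutation_seeds <- function(master_seed, n_permutations) {
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    abort("`n_permutations` must be >= 1")
  }
  n_permutations <- as.integer(n_permutations)
  out <- lcg_draws_(lcg_seed(master_seed), n_permutations)
  structure(
    list(
      master_seed = master_seed,
      n_permutations = n_permutations,
      seeds = out$draws
    ),
    class = "permutation_plan"
  )
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat("<permutation_plan> master_seed =", x$master_seed,
      " N =", x$n_permutations, "\n")
  cat("  seeds:", paste(head(x$seeds, 5), collapse = ", "),
      if (x$n_permutations > 5) "..." else "", "\n")
  invisible(x)
}

#' Permute a sequence with a dedicated LCG stream
#'
#' Durstenfeld Fisher-Yates in descending order: for i from n-1 down to 1
#' (0-based), j = draw mod (i + 1) and positions i and j are swapped. Draws
#' come from a fresh stream seeded with `stream_seed`, so a permutation is
#' fully determined by `(residues, stream_seed)`. The modulo reduction
#' carries a bias that is negligible for n far below 2^31.
#'
#' @param residues A residue string (or a one-row sequence tibble, in which
#'   case the permuted tibble is returned).
#' @param stream_seed Seed for the permutation's own stream, typically one
#'   entry of [derive_permutation_seeds()].
#' @return A string (or one-row tibble) with the same residue multiset.
#' @export
#' @examples
#' permute_sequence("ARND", 0)
permute_sequence <- function(residues, stream_seed) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1L, "residues" %in% names(residues))
    out <- residues
    out$residues <- permute_sequence(residues$residues, stream_seed)
    return(out)
  }
  stopifnot(is.character(residues), length(residues) == 1L, nchar(residues) >= 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  perm <- permute_indices_(length(chars), stream_seed)
  paste(chars[perm + 1L], collapse = "")
}
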