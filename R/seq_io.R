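#' The 24-letter protein alphabet
#'
#' The ordered residue alphabet used throughout the package: the 20 standard
#' amino acids followed by the ambiguity codes B (Asx), Z (Glx), X (any) and
#' the stop/terminator symbol `*`. This is the row/column set of the bundled
#' BLOSUM62 matrix, so every validated sequence can be scored against it.
#'
#' @return Character vector of 24 single-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
    "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
}

#' The 20 standard amino acids
#'
#' @return Character vector of the 20 standard residue codes, in the same
#'   order as the first 20 entries of [aa_alphabet()].
#' @export
aa_standard <- function() {
  aa_alphabet()[1:20]
}

# Validate one residue string against the alphabet. Returns the uppercased
# string; errors name the record and the first offending position.
validate_residues <- function(residues, id = "?", map_unknown_to_x = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) {
    abort(sprintf("sequence '%s' is empty; length >= 1 required", id))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0L) {
    if (map_unknown_to_x) {
      chars[bad] <- "X"
      return(paste(chars, collapse = ""))
    }
    abort(sprintf(
      "sequence '%s' has residue '%s' at position %d not in the 24-letter protein alphabet",
      id, chars[bad[1]], bad[1]
    ))
  }
  residues
}

# Build the canonical sequence tibble from parallel id / residue vectors.
seq_tbl <- function(id, residues) {
  tibble::tibble(
    id = as.character(id),
    residues = as.character(residues),
    length = nchar(residues)
  )
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order with residues uppercased and validated
#' against the 24-letter protein alphabet (see [aa_alphabet()]). Validation is
#' strict by default; `map_unknown_to_x = TRUE` instead replaces any residue
#' outside the alphabet with `X`.
#'
#' @param path Path to a FASTA file.
#' @param map_unknown_to_x Replace out-of-alphabet residues with `X` instead
#'   of raising an error.
#' @return A tibble with columns `id`, `residues` and `length`, one row per
#'   record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">q1", "ARNDCQ", ">q2", "WYV"), fa)
#' read_fasta(fa)
read_fasta <- function(path, map_unknown_to_x = FALSE) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no sequences in FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  residues <- as.character(set)
  residues <- vapply(
    seq_along(residues),
    function(i) validate_residues(residues[i], ids[i], map_unknown_to_x),
    character(1)
  )
  seq_tbl(ids, residues)
}

#' Write sequences to a FASTA file
#'
#' Residue lines are wrapped at 60 columns so output is byte-stable across
#' platforms and re-reading with [read_fasta()] is the identity on
#' `(id, residues)`.
#'
#' @param seqs A sequence tibble as returned by [read_fasta()] or
#'   [generate_random_sequences()] (columns `id`, `residues`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Generate random protein sequences
#'
#' A reproducible fixture generator: residues are drawn from the package's
#' 48-bit LCG stream (see [lcg_seed()]), so output depends only on the
#' arguments, never on R's global random number state.
#'
#' @param count Number of sequences.
#' @param length Length of every sequence, in residues.
#' @param composition Either `"uniform"` (equal frequency over the 20 standard
#'   amino acids) or a named numeric vector of residue frequencies summing
#'   to 1 (names must be members of the alphabet).
#' @param seed Integer seed for the generator stream.
#' @return A tibble with columns `id` (`"seq1"`, `"seq2"`, ...), `residues`
#'   and `length`.
#' @export
#' @examples
#' generate_random_sequences(3, 25, seed = 7)
generate_random_sequences <- function(count, length, composition = "uniform",
                                      seed = 0) {
  if (!is.numeric(count) || count < 1) abort("`count` must be a positive integer")
  if (!is.numeric(length) || length < 1) abort("`length` must be a positive integer")
  count <- as.integer(count)
  length <- as.integer(length)
  if (identical(composition, "uniform")) {
    residues <- aa_standard()
    freq <- rep(1 / 20, 20)
  } else {
    if (is.null(names(composition)) || !is.numeric(composition)) {
      abort("`composition` must be \"uniform\" or a named numeric frequency vector")
    }
    if (!all(names(composition) %in% aa_alphabet())) {
      abort("`composition` names must be members of the 24-letter alphabet")
    }
    if (abs(sum(composition) - 1) > 1e-9) {
      abort("`composition` frequencies must sum to 1 (tolerance 1e-9)")
    }
    residues <- names(composition)
    freq <- as.numeric(composition)
  }
  cum <- cumsum(freq)
  cum[base::length(cum)] <- 1  # guard against rounding at the top end
  state <- lcg_seed(seed)
  out <- lcg_draws_(state, count * length)
  # map the 31-bit draws to (0, 1) and invert the cumulative frequencies
  u <- (out$draws + 0.5) / 2^31
  idx <- findInterval(u, cum, left.open = TRUE) + 1L
  chars <- residues[idx]
  mat <- matrix(chars, nrow = length, ncol = count)
  seqs <- apply(mat, 2, paste, collapse = "")
  seq_tbl(paste0("seq", seq_len(count)), seqs)
}
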