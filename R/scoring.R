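#' Load a substitution matrix
#'
#' Reads a scoring matrix in NCBI text format (comment lines starting with
#' `#`, a header row giving the alphabet, then one row of integer scores per
#' residue). The canonical BLOSUM62 over the 24-letter protein alphabet is
#' bundled and available by name.
#'
#' @param name_or_path `"BLOSUM62"` for the bundled matrix, otherwise a path
#'   to an NCBI-format matrix file.
#' @return A `substitution_matrix`: list with `name`, `alphabet` (ordered
#'   residue vector) and `scores` (square integer matrix with residue
#'   dimnames).
#' @export
#' @examples
#' m <- load_matrix("BLOSUM62")
#' m$scores["A", "A"]
#' m$scores["W", "W"]
load_matrix <- function(name_or_path = "BLOSUM62") {
  stopifnot(is.character(name_or_path), length(name_or_path) == 1L)
  path <- name_or_path
  name <- name_or_path
  if (toupper(name_or_path) == "BLOSUM62") {
    path <- system.file("extdata", "BLOSUM62", package = "psse", mustWork = TRUE)
    name <- "BLOSUM62"
  } else if (!file.exists(path)) {
    abort(sprintf("substitution matrix not found: '%s' (not a file, and not a built-in name)", path))
  } else {
    name <- basename(path)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(sprintf("matrix file '%s' has no score rows", path))
  alphabet <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  k <- length(alphabet)
  rows <- lines[-1]
  if (length(rows) != k) {
    abort(sprintf("matrix file '%s': %d header columns but %d score rows", path, k, length(rows)))
  }
  scores <- matrix(NA_integer_, k, k, dimnames = list(alphabet, alphabet))
  for (r in seq_len(k)) {
    fields <- strsplit(trimws(rows[r]), "\\s+")[[1]]
    if (length(fields) != k + 1L) {
      abort(sprintf("matrix file '%s': row %d has %d score columns, expected %d",
                    path, r, length(fields) - 1L, k))
    }
    if (fields[1] != alphabet[r]) {
      abort(sprintf("matrix file '%s': row %d is labelled '%s', expected '%s'",
                    path, r, fields[1], alphabet[r]))
    }
    vals <- suppressWarnings(as.integer(fields[-1]))
    if (anyNA(vals)) abort(sprintf("matrix file '%s': non-integer score in row %d", path, r))
    scores[r, ] <- vals
  }
  structure(list(name = name, alphabet = alphabet, scores = scores),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix>", x$name, sprintf("(%d x %d)\n",
      nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

# residues -> 0-based alphabet codes (for the compiled kernels)
encode_residues <- function(residues, alphabet) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  codes <- match(chars, alphabet)
  if (anyNA(codes)) {
    abort(sprintf("residue '%s' not in scoring alphabet", chars[which(is.na(codes))[1]]))
  }
  codes - 1L
}

#' Build a local query profile from a substitution matrix
#'
#' Reindexes the substitution matrix by (subject residue, query position):
#' column i of the profile is the matrix column of the query's i-th residue,
#' so `scores[a, i] == matrix[a, query[i]]` everywhere. This changes the
#' lookup layout only — alignment scores under the profile are identical to
#' alignment scores under the matrix.
#'
#' @param query A residue string or one-row sequence tibble.
#' @param matrix A `substitution_matrix` from [load_matrix()].
#' @return A `query_profile` of kind `"local"`: list with `query_id`,
#'   `query`, `length`, `alphabet`, `scores` (|alphabet| x L integer matrix)
#'   and `kind`.
#' @export
#' @examples
#' build_local_profile("AAAA", load_matrix("BLOSUM62"))$scores["A", ]
build_local_profile <- function(query, matrix) {
  stopifnot(inherits(matrix, "substitution_matrix"))
  query_id <- "query"
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    query_id <- query$id
    query <- query$residues
  }
  stopifnot(is.character(query), length(query) == 1L)
  if (nchar(query) < 1L) abort("empty query: profile length must be >= 1")
  codes <- encode_residues(query, matrix$alphabet)
  scores <- matrix$scores[, codes + 1L, drop = FALSE]
  colnames(scores) <- NULL
  structure(
    list(query_id = query_id, query = query, length = nchar(query),
         alphabet = matrix$alphabet, scores = scores, kind = "local"),
    class = "query_profile"
  )
}

#' @export
print.query_profile <- function(x, ...) {
  cat("<query_profile>", x$kind, "profile for", x$query_id,
      sprintf("(|alphabet| = %d, L = %d)\n", length(x$alphabet), x$length))
  invisible(x)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per query
#' position carrying the position index, the query residue and 20 integer
#' log-odds scores (columns ordered A R N D C Q E G H I L K M F P S T W Y V).
#' Only the first 20 score columns are read; the weighted-percentage and
#' information-content columns that PSI-BLAST appends are ignored.
#'
#' ASCII PSSMs carry no scores for the ambiguity codes B, Z, X and `*`; those
#' profile rows are filled from the fallback substitution matrix's column for
#' the query residue at each position (default BLOSUM62), or with a constant
#' penalty when `ambiguity = "constant"`.
#'
#' @param path Path to the ASCII PSSM file.
#' @param ambiguity `"matrix"` (fill B/Z/X/`*` rows from `fallback_matrix`)
#'   or `"constant"` (fill with `ambiguity_score`).
#' @param fallback_matrix A `substitution_matrix`; default BLOSUM62.
#' @param ambiguity_score Constant used when `ambiguity = "constant"`.
#' @return A `query_profile` of kind `"position_specific"`.
#' @export
read_ascii_pssm <- function(path, ambiguity = c("matrix", "constant"),
                            fallback_matrix = load_matrix("BLOSUM62"),
                            ambiguity_score = -4L) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) abort(sprintf("PSSM file not found: %s", path))
  lines <- readLines(path)
  is_row <- grepl("^\\s*\\d+\\s+[A-Za-z]\\s", lines)
  if (!any(is_row)) {
    abort(sprintf("PSSM file '%s' has no position rows (truncated or wrong format?)", path))
  }
  row_idx <- which(is_row)
  std <- aa_standard()
  alphabet <- fallback_matrix$alphabet
  L <- length(row_idx)
  scores <- matrix(NA_integer_, length(alphabet), L,
                   dimnames = list(alphabet, NULL))
  query_chars <- character(L)
  for (r in seq_len(L)) {
    ln <- row_idx[r]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 22L) {
      abort(sprintf("PSSM file '%s', line %d: %d columns, need at least 22 (index, residue, 20 scores)",
                    path, ln, length(fields)))
    }
    pos <- suppressWarnings(as.integer(fields[1]))
    if (is.na(pos) || pos != r) {
      abort(sprintf("PSSM file '%s', line %d: position index '%s', expected %d",
                    path, ln, fields[1], r))
    }
    res <- toupper(fields[2])
    if (!res %in% alphabet) {
      abort(sprintf("PSSM file '%s', line %d: query residue '%s' not in alphabet", path, ln, res))
    }
    vals <- suppressWarnings(as.integer(fields[3:22]))
    if (anyNA(vals)) {
      abort(sprintf("PSSM file '%s', line %d: non-integer score column", path, ln))
    }
    query_chars[r] <- res
    scores[std, r] <- vals
  }
  ambig <- setdiff(alphabet, std)
  if (ambiguity == "matrix") {
    qcodes <- match(query_chars, fallback_matrix$alphabet)
    scores[ambig, ] <- fallback_matrix$scores[ambig, qcodes, drop = FALSE]
  } else {
    scores[ambig, ] <- as.integer(ambiguity_score)
  }
  structure(
    list(query_id = tools::file_path_sans_ext(basename(path)),
         query = paste(query_chars, collapse = ""), length = L,
         alphabet = alphabet, scores = scores, kind = "position_specific"),
    class = "query_profile"
  )
}

#' Look up one profile score
#'
#' @param profile A `query_profile`.
#' @param subject_residue Single residue character.
#' @param query_position 1-based query position, `1 <= position <= L`.
#' @return Integer score of `subject_residue` against the query position.
#' @export
profile_score <- function(profile, subject_residue, query_position) {
  stopifnot(inherits(profile, "query_profile"))
  if (!is.numeric(query_position) || query_position < 1 ||
      query_position > profile$length) {
    abort(sprintf("`query_position` must be in [1, %d]", profile$length))
  }
  a <- match(toupper(subject_residue), profile$alphabet)
  if (is.na(a)) abort(sprintf("residue '%s' not in profile alphabet", subject_residue))
  unname(profile$scores[a, as.integer(query_position)])
}

#' Write a synthetic PSI-BLAST style ASCII PSSM
#'
#' A fixture generator: emits an ASCII PSSM in the PSI-BLAST
#' `-out_ascii_pssm` layout whose log-odds scores are the substitution
#' matrix's columns for the query residues, optionally perturbed by integer
#' jitter drawn from the package LCG. Files are synthetic stand-ins for
#' PSI-BLAST output and are marked as such in their header line.
#'
#' @param query A residue string or one-row sequence tibble.
#' @param path Output path.
#' @param matrix Substitution matrix supplying the base scores.
#' @param jitter Maximum absolute integer perturbation added per cell
#'   (0 = none, giving a PSSM exactly equivalent to the local profile).
#' @param seed LCG seed for the jitter stream.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(query, path, matrix = load_matrix("BLOSUM62"),
                             jitter = 0L, seed = 0) {
  query_id <- "query"
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    query_id <- query$id
    query <- query$residues
  }
  chars <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  std <- aa_standard()
  base <- matrix$scores[std, match(chars, matrix$alphabet), drop = FALSE]
  if (jitter > 0) {
    out <- lcg_draws_(lcg_seed(seed), length(base))
    base <- base + matrix(as.integer(out$draws %% (2L * jitter + 1L)) - jitter,
                          nrow = nrow(base))
  }
  header <- c(
    "",
    sprintf("Last position-specific scoring matrix computed (synthetic profile for %s)", query_id),
    paste0("           ", paste(sprintf("%3s", std), collapse = ""))
  )
  rows <- vapply(seq_along(chars), function(i) {
    paste0(sprintf("%5d %s ", i, chars[i]),
           paste(sprintf("%3d", base[, i]), collapse = ""))
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
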