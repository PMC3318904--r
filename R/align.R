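# Resolve a scheme (substitution_matrix or query_profile) into the profile
# used by the compiled kernels; validates profile length against the query.
resolve_profile <- function(query, scheme) {
  if (inherits(scheme, "query_profile")) {
    if (nchar(query) != scheme$length) {
      abort(sprintf("query length %d does not match profile length %d",
                    nchar(query), scheme$length))
    }
    scheme
  } else if (inherits(scheme, "substitution_matrix")) {
    build_local_profile(query, scheme)
  } else {
    abort("`scheme` must be a substitution_matrix or a query_profile")
  }
}

#' Affine-gap Smith-Waterman local alignment score
#'
#' Score-only local alignment under the Gotoh recurrences with an affine gap
#' penalty: a gap of length k costs `gap_open + gap_extend * k`, so the first
#' gap residue is charged `gap_open + gap_extend` (with the defaults, a
#' length-k gap costs 10 + 2k). The score is the maximum cell of
#' `H[i][j] = max(0, H[i-1][j-1] + s(i,j), E[i][j], F[i][j])` with
#' `E[i][j] = max(H[i][j-1] - (open+extend), E[i][j-1] - extend)` and `F`
#' the vertical analogue; the floor at 0 makes the score nonnegative.
#'
#' Two evaluation orders are available behind the same contract: `"rowmajor"`
#' (the default, one pass per subject residue) and `"wavefront"`
#' (anti-diagonal order, the intra-task schedule in which all cells of one
#' anti-diagonal are mutually independent). Both return identical scores.
#'
#' @param query,subject Residue strings or one-row sequence tibbles.
#' @param scheme A `substitution_matrix` or `query_profile` (profile length
#'   must equal the query length).
#' @param gap_open,gap_extend Nonnegative gap penalty magnitudes.
#' @param method Evaluation order, `"rowmajor"` or `"wavefront"`.
#' @return The optimal local alignment score, a nonnegative integer.
#' @export
#' @examples
#' sw_score("AAAA", "AAAA", load_matrix("BLOSUM62"))  # 16
sw_score <- function(query, subject, scheme = load_matrix("BLOSUM62"),
                     gap_open = 10L, gap_extend = 2L,
                     method = c("rowmajor", "wavefront")) {
  method <- match.arg(method)
  if (is.data.frame(query)) query <- query$residues
  if (is.data.frame(subject)) subject <- subject$residues
  stopifnot(is.character(query), length(query) == 1L,
            is.character(subject), length(subject) == 1L)
  if (nchar(query) < 1L || nchar(subject) < 1L) {
    abort("alignment requires nonempty query and subject")
  }
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be nonnegative")
  prof <- resolve_profile(query, scheme)
  subj <- encode_residues(subject, prof$alphabet)
  if (method == "wavefront") {
    sw_score_wavefront_(subj, prof$scores, as.integer(gap_open), as.integer(gap_extend))
  } else {
    sw_score_(subj, prof$scores, as.integer(gap_open), as.integer(gap_extend))
  }
}

#' Batched Smith-Waterman scores for one query
#'
#' Scores one query against an ordered collection of subjects; element i of
#' the result equals `sw_score(query, subjects[i], ...)`. This is the
#' inter-task path: tasks are independent and evaluated in subject order, so
#' results are order- and value-deterministic.
#'
#' @param query Residue string or one-row sequence tibble.
#' @param subjects Character vector of residue strings, or a sequence tibble
#'   with a `residues` column.
#' @inheritParams sw_score
#' @return Integer vector of nonnegative scores, one per subject, in input
#'   order.
#' @export
sw_score_batch <- function(query, subjects, scheme = load_matrix("BLOSUM62"),
                           gap_open = 10L, gap_extend = 2L,
                           method = c("rowmajor", "wavefront")) {
  method <- match.arg(method)
  if (is.data.frame(query)) query <- query$residues
  if (is.data.frame(subjects)) subjects <- subjects$residues
  stopifnot(is.character(subjects))
  prof <- resolve_profile(query, scheme)
  codes <- lapply(seq_along(subjects), function(i) {
    tryCatch(encode_residues(subjects[i], prof$alphabet),
             error = function(e) abort(sprintf("subject %d: %s", i, conditionMessage(e))))
  })
  sw_score_batch_(codes, prof$scores, as.integer(gap_open),
                  as.integer(gap_extend), method == "wavefront")
}
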