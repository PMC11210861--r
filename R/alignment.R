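#' Default pairwise-alignment scoring scheme
#'
#' Global (Needleman-Wunsch) alignment with the BLOSUM62 substitution
#' matrix and affine gaps: a gap of length L costs
#' `gap_opening + L * gap_extension`. Values are configuration, not code:
#' pass a modified list to [align_pair()] to change the scheme.
#'
#' @return A list with elements `substitution_matrix` (name of a matrix
#'   shipped with Biostrings), `gap_opening` and `gap_extension`.
#' @export
alignment_defaults <- function() {
  list(substitution_matrix = "BLOSUM62", gap_opening = 10, gap_extension = 1)
}

#' Global pairwise alignment of two mature-domain sequences
#'
#' Optimal global alignment under the configured scoring scheme
#' (dynamic programming via Biostrings). Used in place of a multiple
#' alignment because only one reference column is ever consulted
#' downstream.
#'
#' @param candidate_mature,reference_mature Amino-acid strings.
#' @param params Scoring scheme, see [alignment_defaults()].
#' @return An object of class `alignment_result`: `candidate_aligned` and
#'   `reference_aligned` (gapped strings of equal length), `score`, and
#'   `column_map`, an integer vector over reference positions giving the
#'   aligned candidate position (NA where the candidate has a gap).
#' @export
align_pair <- function(candidate_mature, reference_mature,
                       params = alignment_defaults()) {
  attributes(candidate_mature) <- NULL
  attributes(reference_mature) <- NULL
  stopifnot(nchar(candidate_mature) > 0L, nchar(reference_mature) > 0L)
  e <- new.env()
  utils::data(list = params$substitution_matrix, package = "Biostrings",
              envir = e)
  submat <- get(params$substitution_matrix, envir = e)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(candidate_mature),
    subject = Biostrings::AAString(reference_mature),
    type = "global", substitutionMatrix = submat,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  cand <- as.character(Biostrings::alignedPattern(al))
  ref <- as.character(Biostrings::alignedSubject(al))
  cc <- seq_chars(cand); rc <- seq_chars(ref)
  stopifnot(length(cc) == length(rc))
  cmap <- rep(NA_integer_, nchar(reference_mature))
  ci <- 0L; ri <- 0L
  for (k in seq_along(cc)) {
    if (cc[k] != "-") ci <- ci + 1L
    if (rc[k] != "-") {
      ri <- ri + 1L
      if (cc[k] != "-") cmap[ri] <- ci
    }
  }
  structure(list(candidate_aligned = cand, reference_aligned = ref,
                 score = Biostrings::score(al), column_map = cmap),
            class = "alignment_result")
}

#' Residue occupying the dimerization-cysteine column
#'
#' Aligns a candidate mature domain to a reference family member that
#' retains the interchain dimerization cysteine, and reads off the
#' candidate residue in the reference cysteine's alignment column. Most
#' TGF-beta family ligands form an interchain disulfide through this
#' cysteine; in a few members it is substituted (lysine in TIG-2/TIG-3,
#' serine in GDF-9/BMP-15), which rules out a covalently linked dimer.
#'
#' @param candidate_mature Candidate mature-domain sequence.
#' @param reference_mature Reference mature-domain sequence.
#' @param reference_dimer_cys_position 1-based position of the
#'   dimerization cysteine in the reference (must be `C`).
#' @param params Scoring scheme, see [alignment_defaults()].
#' @return A list: `residue` (one-letter code, `"-"` for a gap),
#'   `position` (candidate 1-based position, NA for a gap), `substituted`
#'   (`TRUE` iff the column residue is not cysteine), `gap`, and the
#'   underlying `alignment`.
#' @examples
#' ref <- synthetic_bmp2_like_reference()
#' tig2 <- synthetic_tig2_precursor()
#' mat <- split_at_site(tig2,
#'   scan_cleavage_sites(tig2)[scan_cleavage_sites(tig2)$motif == "KVKR", ])$mature
#' dimerization_residue(mat, ref, 80)
#' @export
dimerization_residue <- function(candidate_mature, reference_mature,
                                 reference_dimer_cys_position,
                                 params = alignment_defaults()) {
  attributes(candidate_mature) <- NULL
  attributes(reference_mature) <- NULL
  pos <- as.integer(reference_dimer_cys_position)
  if (substr(reference_mature, pos, pos) != "C")
    stop("reference position ", pos, " is not a cysteine")
  al <- align_pair(candidate_mature, reference_mature, params)
  cand_pos <- al$column_map[pos]
  if (is.na(cand_pos)) {
    res <- "-"; gap <- TRUE
  } else {
    res <- substr(candidate_mature, cand_pos, cand_pos); gap <- FALSE
  }
  list(residue = res, position = cand_pos,
       substituted = !identical(res, "C"), gap = gap, alignment = al)
}
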