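#' Synthetic stand-in precursors for TIG-2, TIG-3 and a BMP-2-like
#' reference
#'
#' These functions build deterministic, fully synthetic precursor
#' sequences that reproduce the published annotation features of the
#' C. elegans ligands TIG-2 and TIG-3 (isoform B) without being the real
#' sequences: filler positions are pseudo-random draws from an alphabet
#' that excludes Cys/Arg/Lys, and every biologically meaningful feature is
#' planted at its reported coordinate. They exist so that the sequence
#' pipeline can be exercised end-to-end with known answers.
#'
#' `synthetic_tig2_precursor()` (300 aa, 22-residue signal) carries two
#' convertase sites, RSRR and KVKR, yielding 134- and 116-residue mature
#' forms; the mature domain (KVKR numbering) has the six-cysteine knot
#' skeleton at positions 15, 44, 48, 81, 113, 115 and a lysine at
#' position 80 where the family's dimerization cysteine would sit. Its
#' prodomain contains no cysteines.
#'
#' `synthetic_tig3_precursor()` (250 aa, 20-residue signal) carries one
#' consensus site (RSKR) and a 120-residue mature domain with the
#' eight-cysteine skeleton at 22, 25, 26, 54, 59, 82, 114, 116 and a
#' lysine at position 81 in the dimerization column; its prodomain
#' contains exactly two cysteines, at prodomain positions 60 and 70.
#'
#' `synthetic_bmp2_like_reference()` is a synthetic mature-domain homolog
#' representing a conventional family member that keeps the interchain
#' dimerization cysteine: it shares the TIG-2 stand-in's knot skeleton
#' but has Cys (not Lys) at mature position 80, plus scattered point
#' differences elsewhere. Use it as the `reference_mature` for
#' [dimerization_residue()].
#'
#' A window around the dimerization column is sequence-identical (up to
#' the Cys/Lys swap, offset by one residue in TIG-3) across the three
#' stand-ins, mimicking the strong local conservation that anchors this
#' column in real family alignments.
#'
#' @return A [precursor_record()] (or, for the reference, a plain mature
#'   sequence string) carrying a `ground_truth` attribute that records
#'   every planted feature.
#' @examples
#' tig2 <- synthetic_tig2_precursor()
#' scan_cleavage_sites(tig2, require_knot_downstream = TRUE)
#' @name synthetic_ligands
NULL

# Shared deterministic filler: position-indexed so overlapping designs
# stay reproducible.
synth_filler <- function(n, seed) {
  with_local_seed(seed, sample(AA_FILLER, n, replace = TRUE))
}

#' @rdname synthetic_ligands
#' @export
synthetic_tig2_precursor <- function() {
  L <- 300L
  chars <- synth_filler(L, seed = 4202L)
  chars[1] <- "M"
  signal_end <- 22L
  # RSRR -> 134-residue mature form; KVKR -> 116-residue mature form
  chars[163:166] <- seq_chars("RSRR")
  chars[181:184] <- seq_chars("KVKR")
  mat0 <- 184L                       # KVKR mature domain starts at mat0 + 1
  knot_local <- c(15L, 44L, 48L, 81L, 113L, 115L)
  chars[mat0 + knot_local] <- "C"
  chars[mat0 + 80L] <- "K"           # substituted dimerization column
  p <- precursor_record("TIG-2-synthetic", paste(chars, collapse = ""),
                        signal_end = signal_end)
  attr(p, "ground_truth") <- list(
    sites = data.frame(motif = c("RSRR", "KVKR"), start = c(163L, 181L),
                       spacer_n = c(2L, 2L), mature_start = c(167L, 185L),
                       mature_length = c(134L, 116L)),
    knot_cys_mature = knot_local,
    dimer_column_mature = 80L,
    dimer_column_residue = "K")
  p
}

#' @rdname synthetic_ligands
#' @export
synthetic_tig3_precursor <- function() {
  L <- 250L
  chars <- synth_filler(L, seed = 4203L)
  chars[1] <- "M"
  signal_end <- 20L
  chars[127:130] <- seq_chars("RSKR")
  # exactly two prodomain cysteines, prodomain-local 60 and 70
  chars[signal_end + c(60L, 70L)] <- "C"
  mat0 <- 130L
  knot_local <- c(22L, 25L, 26L, 54L, 59L, 82L, 114L, 116L)
  chars[mat0 + knot_local] <- "C"
  chars[mat0 + 81L] <- "K"
  # conserved window around the dimerization column, shared with the
  # reference at a +1 offset (one net insertion upstream in TIG-3)
  ref <- seq_chars(synthetic_bmp2_like_reference())
  anchor <- ref[65:95]
  anchor[80L - 64L] <- "K"           # the reference's Cys80 column
  chars[mat0 + (66:96)] <- anchor
  p <- precursor_record("TIG-3-synthetic", paste(chars, collapse = ""),
                        signal_end = signal_end)
  attr(p, "ground_truth") <- list(
    sites = data.frame(motif = "RSKR", start = 127L, spacer_n = 2L,
                       mature_start = 131L, mature_length = 120L),
    prodomain_cys_local = c(60L, 70L),
    knot_cys_mature = knot_local,
    dimer_column_mature = 81L,
    dimer_column_residue = "K")
  p
}

#' @rdname synthetic_ligands
#' @export
synthetic_bmp2_like_reference <- function() {
  tig2 <- synthetic_tig2_precursor_core()
  mat <- seq_chars(substr(tig2, 185L, 300L))   # 116-residue KVKR mature form
  mat[80L] <- "C"                              # retained dimerization cysteine
  # scattered point differences outside the conserved window and the
  # cysteine skeleton, so the reference is a homolog rather than a copy
  fixed <- c(15L, 44L, 48L, 80L, 81L, 113L, 115L, 65:95)
  subs_at <- with_local_seed(4204L, sample(setdiff(1:116, fixed), 12L))
  repl <- with_local_seed(4205L, sample(AA_FILLER, 12L, replace = TRUE))
  mat[subs_at] <- repl
  ref <- paste(mat, collapse = "")
  attr(ref, "ground_truth") <- list(dimer_cys = 80L,
                                    knot_cys = c(15L, 44L, 48L, 81L, 113L, 115L))
  ref
}

# TIG-2 stand-in sequence without the ground-truth attribute; broken out
# so the reference builder cannot recurse through the anchor-window logic.
synthetic_tig2_precursor_core <- function() {
  L <- 300L
  chars <- synth_filler(L, seed = 4202L)
  chars[1] <- "M"
  chars[163:166] <- seq_chars("RSRR")
  chars[181:184] <- seq_chars("KVKR")
  chars[184L + c(15L, 44L, 48L, 81L, 113L, 115L)] <- "C"
  chars[184L + 80L] <- "K"
  paste(chars, collapse = "")
}
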