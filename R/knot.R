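#' Positions of cysteine residues in a sequence
#'
#' @param sequence Amino-acid string (or a [precursor_record()], in which
#'   case the full precursor sequence is used).
#' @return Ordered integer vector of 1-based positions of `C`.
#' @examples
#' cysteine_positions("ACCA")
#' @export
cysteine_positions <- function(sequence) {
  if (inherits(sequence, "precursor_record")) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L)
  which(seq_chars(toupper(sequence)) == "C")
}

#' Rule-based cystine-knot disulfide connectivity
#'
#' Assigns intrachain disulfide partners from cysteine positions alone,
#' for the two skeletons that occur among the ligands considered here.
#' With six cysteines C1..C6 the canonical growth-factor knot pairing is
#' (C1,C4), (C2,C5), (C3,C6). With eight cysteines C1..C8 the pairing is
#' (C1,C3), (C2,C6), (C4,C7), (C5,C8) — the arrangement attested for the
#' TIG-3 mature domain; it is flagged as attested for that skeleton only,
#' not a general rule. Both rules yield a perfect matching, so no
#' unpaired (dimerization) cysteine remains.
#'
#' @param positions Sorted integer vector of cysteine positions (length 6
#'   or 8).
#' @return An object of class `cysteine_topology`: fields `positions`,
#'   `pairs` (two-column matrix of paired positions), `dimer_cys_present`
#'   (`FALSE` under these rules), and `rule`.
#' @examples
#' assign_knot_connectivity(c(15, 44, 48, 81, 113, 115))
#' @export
assign_knot_connectivity <- function(positions) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("cysteine positions must be strictly increasing")
  idx <- switch(as.character(length(positions)),
    "6" = rbind(c(1L, 4L), c(2L, 5L), c(3L, 6L)),
    "8" = rbind(c(1L, 3L), c(2L, 6L), c(4L, 7L), c(5L, 8L)),
    stop("no connectivity rule for ", length(positions),
         " cysteines (supported skeletons: 6, 8)"))
  pairs <- cbind(positions[idx[, 1]], positions[idx[, 2]])
  colnames(pairs) <- c("cys_a", "cys_b")
  cysteine_topology(positions, pairs,
                    rule = if (length(positions) == 6L) "canonical_6"
                           else "attested_8_tig3")
}

#' Construct and validate a cysteine topology
#'
#' @param positions Cysteine positions.
#' @param pairs Two-column matrix of paired positions (intrachain
#'   disulfides).
#' @param dimer_cys_present Is an interchain dimerization cysteine
#'   present (i.e. an unpaired cysteine in the dimerization column)?
#' @param dimer_cys_column_residue One-letter code occupying the
#'   dimerization-cysteine alignment column, with its position as the
#'   vector's name (optional).
#' @param rule Provenance label for the pairing rule.
#' @return Object of class `cysteine_topology`.
#' @export
cysteine_topology <- function(positions, pairs,
                              dimer_cys_present = FALSE,
                              dimer_cys_column_residue = NULL,
                              rule = "manual") {
  positions <- as.integer(positions)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (!all(pairs %in% positions))
    stop("pairs reference positions not in the cysteine list")
  if (anyDuplicated(as.vector(pairs)))
    stop("a cysteine may appear in at most one pair")
  if (isTRUE(dimer_cys_present) &&
      !identical(unname(dimer_cys_column_residue), "C"))
    stop("dimer_cys_present requires a C in the dimerization column")
  structure(list(positions = positions, pairs = pairs,
                 dimer_cys_present = isTRUE(dimer_cys_present),
                 dimer_cys_column_residue = dimer_cys_column_residue,
                 rule = rule),
            class = "cysteine_topology")
}

#' @export
print.cysteine_topology <- function(x, ...) {
  cat("<cysteine_topology> ", length(x$positions), " Cys; pairs: ",
      paste(apply(x$pairs, 1, paste, collapse = "-"), collapse = ", "),
      "; dimerization Cys ",
      if (x$dimer_cys_present) "present" else "absent", "\n", sep = "")
  invisible(x)
}

#' Detect disulfide bonds from structure coordinates
#'
#' Pairs cysteines whose S-gamma atoms lie within a geometric bonding
#' threshold. Matching is greedy nearest-first and mutually exclusive, so
#' the output is a deterministic partial matching.
#'
#' @param structure A `structure_model` from [read_structure()].
#' @param chain Chain identifier to analyse.
#' @param threshold Maximum S-gamma to S-gamma distance in Angstrom
#'   (default 2.5, covering the ~2.05 A canonical bond with model noise).
#' @return Two-column matrix (`cys_a`, `cys_b`) of residue numbers;
#'   zero rows when no pair qualifies.
#' @export
detect_structural_disulfides <- function(structure, chain, threshold = 2.5) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  if (!chain %in% at$chain)
    stop("chain '", chain, "' not present in structure")
  sg <- at[at$chain == chain & at$resid == "CYS" & at$elety == "SG", ,
           drop = FALSE]
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("cys_a", "cys_b")))
  if (nrow(sg) < 2L) return(empty)
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  out <- empty
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      out <- rbind(out, c(sg$resno[i], sg$resno[j]))
    }
  }
  out
}
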