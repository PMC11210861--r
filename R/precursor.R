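#' Create a ligand precursor record
#'
#' A precursor is a full-length translated TGF-beta family chain:
#' signal sequence, prodomain and mature bioactive domain. The signal
#' sequence boundary is an input (typically taken from a dedicated signal
#' peptide predictor); it is not predicted here.
#'
#' @param name Identifier for the precursor.
#' @param sequence Amino-acid sequence, one-letter codes.
#' @param signal_end 1-based index of the last signal-sequence residue;
#'   use 0 when the chain has no signal sequence.
#' @return An object of class `precursor_record` with fields `name`,
#'   `sequence` and `signal_end`.
#' @examples
#' p <- precursor_record("toy", "MALWMRSRRGGCGGCG", signal_end = 4)
#' @export
precursor_record <- function(name, sequence, signal_end = 0L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("empty precursor sequence")
  bad <- setdiff(unique(seq_chars(sequence)), AA_ALPHABET)
  if (length(bad))
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  signal_end <- as.integer(signal_end)
  if (is.na(signal_end) || signal_end < 0L || signal_end >= nchar(sequence))
    stop("signal_end must satisfy 0 <= signal_end < length(sequence)")
  structure(list(name = name, sequence = sequence, signal_end = signal_end),
            class = "precursor_record")
}

#' @export
print.precursor_record <- function(x, ...) {
  cat("<precursor_record> ", x$name, ": ", nchar(x$sequence),
      " aa, signal 1-", x$signal_end, "\n", sep = "")
  invisible(x)
}

#' Scan a precursor for proprotein-convertase cleavage sites
#'
#' Applies the basic/dibasic convertase rule (R/K)-Xn-(R/K): the first and
#' last motif residues are Arg or Lys and the spacer X has even length n
#' with 0 <= n <= 6. Scanning is restricted to positions downstream of the
#' signal sequence, and a site whose motif runs to the precursor terminus
#' (leaving an empty mature domain) is not reported.
#'
#' Overlapping matches that imply the same scission point are common (e.g.
#' `RSRR` contains both the 4-residue R-X2-R match and the terminal `RR`
#' dibasic pair). By default matches are deduplicated by their
#' `mature_start`, keeping the longest motif; set `dedupe = FALSE` to see
#' every raw match.
#'
#' @param precursor A [precursor_record()].
#' @param require_knot_downstream If `TRUE`, retain only sites whose
#'   downstream fragment contains every cysteine of the knot skeleton, so
#'   that cleavage preserves the cystine-knot domain.
#' @param knot_cys Knot skeleton specification used when
#'   `require_knot_downstream = TRUE`: either an integer k (the skeleton is
#'   the k most C-terminal cysteines of the precursor; default 6, use 8 for
#'   the four-disulfide skeleton) or an integer vector of explicit 1-based
#'   precursor positions.
#' @param dedupe Deduplicate overlapping matches by `mature_start`
#'   (default `TRUE`).
#' @return A data frame of class `cleavage_sites` with columns `name`,
#'   `motif`, `start`, `spacer_n` and `mature_start`, sorted by `start`.
#'   Zero rows when no site matches (not an error).
#' @examples
#' p <- precursor_record("toy", "AAAARSRRGGGG", signal_end = 0)
#' scan_cleavage_sites(p)
#' @export
scan_cleavage_sites <- function(precursor, require_knot_downstream = FALSE,
                                knot_cys = 6L, dedupe = TRUE) {
  stopifnot(inherits(precursor, "precursor_record"))
  chars <- seq_chars(precursor$sequence)
  L <- length(chars)
  basic <- chars %in% c("R", "K")
  rows <- list()
  for (n in c(0L, 2L, 4L, 6L)) {
    first <- seq_len(L)
    last <- first + n + 1L
    ok <- first > precursor$signal_end & last <= L &
      basic[first] & basic[pmin(last, L)]
    # motif must leave a non-empty mature domain
    ok <- ok & (last + 1L) <= L
    for (s in which(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = precursor$name,
        motif = paste(chars[s:(s + n + 1L)], collapse = ""),
        start = s, spacer_n = n, mature_start = s + n + 2L,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), motif = character(), start = integer(),
               spacer_n = integer(), mature_start = integer(),
               stringsAsFactors = FALSE)
  if (dedupe && nrow(sites)) {
    sites <- sites[order(sites$mature_start, -sites$spacer_n), , drop = FALSE]
    sites <- sites[!duplicated(sites$mature_start), , drop = FALSE]
  }
  if (require_knot_downstream && nrow(sites)) {
    knot <- knot_skeleton_positions(precursor, knot_cys)
    if (length(knot) == 0L)
      stop("require_knot_downstream = TRUE but precursor has no cysteines")
    keep <- vapply(sites$mature_start, function(m) all(knot >= m), logical(1))
    sites <- sites[keep, , drop = FALSE]
  }
  sites <- sites[order(sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("cleavage_sites", "data.frame")
  sites
}

# Resolve a knot skeleton spec (count or explicit positions) to precursor
# coordinates.
knot_skeleton_positions <- function(precursor, knot_cys) {
  cys <- cysteine_positions(precursor$sequence)
  if (length(knot_cys) == 1L && knot_cys <= length(cys)) {
    k <- as.integer(knot_cys)
    if (k < 1L) stop("knot_cys count must be positive")
    return(utils::tail(cys, k))
  }
  if (length(knot_cys) > 1L) {
    knot_cys <- as.integer(knot_cys)
    if (!all(knot_cys %in% cys))
      stop("explicit knot_cys positions must all be cysteines")
    return(sort(knot_cys))
  }
  cys
}

#' Split a precursor at a cleavage site
#'
#' Partitions the chain into signal sequence (residues `1..signal_end`),
#' prodomain (from `signal_end + 1` through the last motif residue — the
#' prodomain includes the cleavage site) and mature domain (everything
#' downstream of the motif).
#'
#' @param precursor A [precursor_record()].
#' @param site One row of the data frame returned by
#'   [scan_cleavage_sites()] (or any list with `start` and `spacer_n`).
#' @return An object of class `domain_split`: character fields `signal`,
#'   `prodomain`, `mature` plus `offsets`, a named integer vector giving
#'   the 1-based precursor position of the first residue of each domain
#'   (NA for an empty signal). The three domains concatenate back to the
#'   precursor sequence.
#' @export
split_at_site <- function(precursor, site) {
  stopifnot(inherits(precursor, "precursor_record"))
  if (is.data.frame(site)) {
    if (nrow(site) != 1L) stop("site must be a single row")
    site <- as.list(site)
  }
  start <- as.integer(site$start)
  spacer_n <- as.integer(site$spacer_n)
  L <- nchar(precursor$sequence)
  motif_end <- start + spacer_n + 1L
  if (is.na(start) || start <= precursor$signal_end || motif_end >= L)
    stop("cleavage site out of range for this precursor")
  se <- precursor$signal_end
  split <- structure(list(
    signal = substr(precursor$sequence, 1L, se),
    prodomain = substr(precursor$sequence, se + 1L, motif_end),
    mature = substr(precursor$sequence, motif_end + 1L, L),
    offsets = c(signal = if (se > 0L) 1L else NA_integer_,
                prodomain = se + 1L, mature = motif_end + 1L)),
    class = "domain_split")
  stopifnot(paste0(split$signal, split$prodomain, split$mature) ==
              precursor$sequence)
  split
}

#' Mature-domain length implied by a cleavage site
#'
#' @inheritParams split_at_site
#' @return Integer length of the mature domain,
#'   `length(sequence) - mature_start + 1`.
#' @export
mature_length <- function(precursor, site) {
  nchar(split_at_site(precursor, site)$mature)
}

#' Choose a default cleavage site
#'
#' When a single split is needed, the default is the most C-terminal
#' knot-preserving site, i.e. the shortest mature form (shortest
#' disordered leader ahead of the knot). Multi-site precursors keep all
#' their sites reportable; this helper only picks one for downstream
#' convenience.
#'
#' @param sites A `cleavage_sites` data frame.
#' @param prefer `"shortest_mature"` (default) or `"longest_mature"`.
#' @return A single-row `cleavage_sites` data frame.
#' @export
select_site <- function(sites, prefer = c("shortest_mature", "longest_mature")) {
  prefer <- match.arg(prefer)
  if (nrow(sites) == 0L) stop("no cleavage sites to select from")
  i <- if (prefer == "shortest_mature") which.max(sites$mature_start)
       else which.min(sites$mature_start)
  sites[i, , drop = FALSE]
}

#' Read precursor records from FASTA plus a signal-boundary table
#'
#' @param fasta Path to a (multi-record) FASTA file of precursor
#'   sequences.
#' @param signals Either a data frame with columns `name` and
#'   `signal_end`, or a path to a TSV file with those columns. Records
#'   missing from the table get `signal_end = 0`.
#' @return A named list of [precursor_record()] objects.
#' @export
read_precursors <- function(fasta, signals = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  nm <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (is.character(signals)) signals <- utils::read.delim(signals)
  ends <- setNames(rep(0L, length(nm)), nm)
  if (!is.null(signals)) {
    stopifnot(all(c("name", "signal_end") %in% names(signals)))
    hit <- intersect(nm, signals$name)
    ends[hit] <- as.integer(signals$signal_end[match(hit, signals$name)])
  }
  out <- lapply(seq_along(aa), function(i)
    precursor_record(nm[i], as.character(aa[[i]]), ends[[nm[i]]]))
  setNames(out, nm)
}

#' Write mature and prodomain fragments to FASTA
#'
#' @param precursor A [precursor_record()].
#' @param sites A `cleavage_sites` data frame (one FASTA record pair per
#'   site).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(precursor, sites, path) {
  recs <- character(0)
  for (i in seq_len(nrow(sites))) {
    sp <- split_at_site(precursor, sites[i, ])
    tag <- paste0(precursor$name, "_", sites$motif[i])
    recs <- c(recs,
              paste0(">", tag, "_prodomain"), sp$prodomain,
              paste0(">", tag, "_mature"), sp$mature)
  }
  writeLines(recs, path)
  invisible(path)
}
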