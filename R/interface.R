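#' Interchain residue contacts
#'
#' Two residues on different chains are in contact when the minimum
#' distance between any of their heavy atoms is at or below the cutoff
#' (default 4 Angstrom). One record is emitted per residue pair, carrying
#' that minimum distance.
#'
#' @param structure A `structure_model` with at least two chains.
#' @param cutoff_A Heavy-atom distance cutoff in Angstrom.
#' @return A data frame of class `contact_set` with columns `chain_a`,
#'   `res_a`, `chain_b`, `res_b`, `dist`; attribute `cutoff_A`.
#' @export
interchain_contacts <- function(structure, cutoff_A = 4.0) {
  stopifnot(inherits(structure, "structure_model"))
  chains <- structure$chains
  if (length(chains) < 2L)
    stop("interchain contacts require at least two chains")
  at <- structure$atoms
  out <- list()
  for (i in seq_len(length(chains) - 1L)) {
    for (j in (i + 1L):length(chains)) {
      a <- at[at$chain == chains[i], , drop = FALSE]
      b <- at[at$chain == chains[j], , drop = FALSE]
      pa <- as.matrix(a[, c("x", "y", "z")])
      pb <- as.matrix(b[, c("x", "y", "z")])
      d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
        outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
      d <- sqrt(pmax(d2, 0))
      # min distance per residue pair
      fa <- factor(a$resno); fb <- factor(b$resno)
      mins <- tapply(as.vector(d),
                     list(fa[row(d)[seq_along(d)]], fb[col(d)[seq_along(d)]]),
                     min)
      hit <- which(mins <= cutoff_A, arr.ind = TRUE)
      if (nrow(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          chain_a = chains[i],
          res_a = as.integer(rownames(mins)[hit[, 1]]),
          chain_b = chains[j],
          res_b = as.integer(colnames(mins)[hit[, 2]]),
          dist = mins[hit], stringsAsFactors = FALSE)
      }
    }
  }
  contacts <- if (length(out)) do.call(rbind, out) else
    data.frame(chain_a = character(), res_a = integer(),
               chain_b = character(), res_b = integer(), dist = numeric(),
               stringsAsFactors = FALSE)
  contacts <- contacts[order(contacts$chain_a, contacts$chain_b,
                             contacts$res_a, contacts$res_b), , drop = FALSE]
  rownames(contacts) <- NULL
  attr(contacts, "cutoff_A") <- cutoff_A
  class(contacts) <- c("contact_set", "data.frame")
  contacts
}

# Map (chain, resno) pairs to global PAE indices via the residue map.
pae_index <- function(pae, chain, resno) {
  rm <- attr(pae, "residue_map")
  if (is.null(rm))
    stop("PAE matrix lacks a residue map; read it with read_pae(path, structure)")
  idx <- rm$index[match(paste(chain, resno), paste(rm$chain, rm$resno))]
  if (anyNA(idx)) stop("contact residue absent from PAE residue map")
  idx
}

# Per-contact PAE, symmetrized according to `combine`.
contact_pae <- function(contacts, pae, combine = c("mean", "min", "max")) {
  combine <- match.arg(combine)
  i <- pae_index(pae, contacts$chain_a, contacts$res_a)
  j <- pae_index(pae, contacts$chain_b, contacts$res_b)
  ij <- pae[cbind(i, j)]; ji <- pae[cbind(j, i)]
  switch(combine, mean = (ij + ji) / 2, min = pmin(ij, ji),
         max = pmax(ij, ji))
}

#' Confidence-filtered interface
#'
#' Flags each contact as confident when its (symmetrized) PAE is strictly
#' below the cutoff, and derives per-chain interface tracks: the residues
#' participating in at least one confident contact. PAE matrices are not
#' symmetric in general; the per-contact value is by default the mean of
#' the two directions (configurable to min or max).
#'
#' @param contacts A `contact_set` from [interchain_contacts()].
#' @param pae A `pae_matrix` from [read_pae()] (with residue map).
#' @param pae_cutoff_A PAE cutoff in Angstrom; strict `<` as in the
#'   interface-track convention "PAE < 5 A".
#' @param combine How to symmetrize PAE for a contact: `"mean"`
#'   (default), `"min"` or `"max"`.
#' @return A list of class `confident_interface`: `contacts` (input plus
#'   `pae` and `confident` columns) and `tracks`, a named list per chain
#'   of sorted residue numbers in the confident interface.
#' @export
confident_interface <- function(contacts, pae, pae_cutoff_A = 5.0,
                                combine = c("mean", "min", "max")) {
  combine <- match.arg(combine)
  contacts <- as.data.frame(contacts)
  if (nrow(contacts)) {
    contacts$pae <- contact_pae(contacts, pae, combine)
    contacts$confident <- contacts$pae < pae_cutoff_A
  } else {
    contacts$pae <- numeric(0); contacts$confident <- logical(0)
  }
  rm <- attr(pae, "residue_map")
  chains <- unique(rm$chain)
  conf <- contacts[contacts$confident, , drop = FALSE]
  tracks <- lapply(setNames(chains, chains), function(ch)
    sort(unique(c(conf$res_a[conf$chain_a == ch],
                  conf$res_b[conf$chain_b == ch]))))
  structure(list(contacts = contacts, tracks = tracks,
                 pae_cutoff_A = pae_cutoff_A),
            class = "confident_interface")
}

#' Region-pair contact summaries for procomplex interfaces
#'
#' Splits the interchain contact set by annotated monomer regions
#' (prodomain `pro` vs mature domain `mat`) and reports, per ordered
#' region pair, the contact subset and its arithmetic mean PAE — the
#' "column mean" of a procomplex interface plot. The `full`-`full` column
#' is the whole interchain contact set (union of the others).
#'
#' @param contacts A `contact_set`.
#' @param pae A `pae_matrix` with residue map.
#' @param regions Data frame with columns `chain`, `region` (`"pro"` or
#'   `"mat"`), `start`, `end` (author residue numbers, closed interval),
#'   jointly covering every residue of each chain.
#' @param combine PAE symmetrization, as in [confident_interface()].
#' @return A list of class `region_pair_contacts`; each element has
#'   `region_a`, `region_b`, `contacts` (with `pae` column) and
#'   `column_mean_pae` (NA when the column is empty). Use
#'   [summary.region_pair_contacts()] for a flat table.
#' @export
region_pair_contacts <- function(contacts, pae, regions,
                                 combine = c("mean", "min", "max")) {
  combine <- match.arg(combine)
  stopifnot(all(c("chain", "region", "start", "end") %in% names(regions)))
  if (!all(regions$region %in% c("pro", "mat")))
    stop("regions must be labelled 'pro' or 'mat'")
  rm <- attr(pae, "residue_map")
  if (is.null(rm)) stop("PAE matrix lacks a residue map")
  assign_region <- function(chain, resno) {
    hit <- regions$chain == chain & regions$start <= resno &
      regions$end >= resno
    if (sum(hit) != 1L)
      stop("region annotation does not uniquely cover residue ",
           chain, ":", resno)
    regions$region[hit]
  }
  # annotation must cover all residues
  invisible(mapply(assign_region, rm$chain, rm$resno))
  contacts <- as.data.frame(contacts)
  contacts$pae <- if (nrow(contacts))
    contact_pae(contacts, pae, combine) else numeric(0)
  reg_a <- vapply(seq_len(nrow(contacts)), function(k)
    assign_region(contacts$chain_a[k], contacts$res_a[k]), character(1))
  reg_b <- vapply(seq_len(nrow(contacts)), function(k)
    assign_region(contacts$chain_b[k], contacts$res_b[k]), character(1))
  cols <- list(c("full", "full"), c("pro", "pro"), c("pro", "mat"),
               c("mat", "pro"), c("mat", "mat"))
  out <- lapply(cols, function(rp) {
    keep <- if (rp[1] == "full") rep(TRUE, nrow(contacts))
            else reg_a == rp[1] & reg_b == rp[2]
    sub <- contacts[keep, , drop = FALSE]
    list(region_a = rp[1], region_b = rp[2], contacts = sub,
         column_mean_pae = if (nrow(sub)) mean(sub$pae) else NA_real_)
  })
  names(out) <- vapply(cols, paste, character(1), collapse = "-")
  class(out) <- "region_pair_contacts"
  out
}

#' @describeIn region_pair_contacts Flat summary table (one row per
#'   region-pair column).
#' @param object A `region_pair_contacts` object.
#' @param ... Unused.
#' @export
summary.region_pair_contacts <- function(object, ...) {
  do.call(rbind, lapply(object, function(el)
    data.frame(region_a = el$region_a, region_b = el$region_b,
               n_contacts = nrow(el$contacts),
               column_mean_pae = el$column_mean_pae)))
}
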