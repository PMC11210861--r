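#' Specification for synthetic pipeline inputs
#'
#' Collects, with defaults, every parameter the generators need. All
#' randomness flows from the single `seed`; each generator draws from its
#' own sub-stream (a fixed offset of the seed), so adding one kind of
#' output never shifts another.
#'
#' Defaults mirror the study conditions the pipeline is meant to handle:
#' a 116-residue mature domain behind a 4-residue convertase motif and a
#' six-cysteine knot; dimer models with a planted interface at 3.5 A
#' against a 10 A decoy separation and bimodal PAE (2 A interface, 20 A
#' background); survival cohorts of 100 animals per arm with baseline
#' hazard 0.1/day, hazard multipliers 2.5 per mutated gene, and
#' administrative censoring at a 14-day assay horizon.
#'
#' @param seed Integer master seed.
#' @param precursor,structure,survival Named lists overriding individual
#'   defaults (see the generator documentation for the meaning of each
#'   field).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, precursor = list(), structure = list(),
                       survival = list()) {
  merge_in <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  p <- merge_in(list(
    signal_len = 22L, prodomain_len = 150L, mature_len = 116L,
    motifs = "RSRR",           # planted in order; last one ends the prodomain
    motif_spacing = 14L,       # gap between consecutive planted motifs
    cys_skeleton = 6L,         # 6 or 8; 0 for no knot
    mature_cys = NULL,         # explicit mature-local positions (optional)
    extra_cys_mature = integer(0)), precursor)
  s <- merge_in(list(
    chain_len = 20L, n_interface = 5L, interface = NULL,
    contact_target_A = 3.5, decoy_sep_A = 10,
    interface_pae_A = 2, background_pae_A = 20,
    plddt_interface = 95, plddt_background = 70,
    cys_positions = integer(0), ss_pairs = NULL), structure)
  v <- merge_in(list(
    model = "independent",     # independent | same-pathway | antagonistic
    h_wt = 0.1, r_a = 2.5, r_b = 2.5, n_per_arm = 100L,
    horizon = 14, double_multiplier = NULL,
    strains = c(wt = "control", a = "mutantA", b = "mutantB",
                double = "double")), survival)
  if (v$h_wt <= 0 || v$r_a <= 0 || v$r_b <= 0)
    stop("hazard parameters must be positive")
  structure(list(seed = as.integer(seed), precursor = p, structure = s,
                 survival = v),
            class = "synth_spec")
}

sub_seed <- function(spec, offset) (spec$seed + offset) %% .Machine$integer.max

default_skeleton <- function(k, mature_len) {
  base <- switch(as.character(k),
                 "6" = c(15L, 44L, 48L, 81L, 113L, 115L),
                 "8" = c(22L, 25L, 26L, 54L, 59L, 82L, 114L, 116L),
                 stop("cys_skeleton must be 6 or 8"))
  if (mature_len < max(base) + 1L)
    stop("mature_len too short for the ", k, "-cysteine skeleton")
  base
}

#' Generate a synthetic knot-bearing precursor
#'
#' Builds `signal + prodomain body + planted motifs + mature domain`.
#' Filler residues are drawn uniformly from the 17 amino acids that are
#' not C, R or K, so no accidental cleavage motifs or cysteines arise;
#' every feature in the output is planted and recorded.
#'
#' Precursor parameters (in `spec$precursor`): `signal_len`,
#' `prodomain_len` (includes the planted motifs; the last motif ends the
#' prodomain), `mature_len`, `motifs` (character vector of motif strings,
#' each satisfying the (R/K)-Xn-(R/K) rule with non-basic spacer),
#' `motif_spacing`, `cys_skeleton` (6, 8, or 0 for none), `mature_cys`
#' (explicit mature-local cysteine positions overriding the skeleton
#' default) and `extra_cys_mature` (additional planted cysteines, e.g. an
#' unpaired dimerization cysteine).
#'
#' @param spec A [synth_spec()].
#' @return A [precursor_record()] with attribute `ground_truth`: planted
#'   `sites` (motif, start, spacer_n, mature_start), `signal_end`,
#'   `mature_cys_local` and `cys_precursor`.
#' @export
gen_precursor <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- spec$precursor
  for (m in p$motifs) {
    ch <- seq_chars(m)
    n <- length(ch) - 2L
    if (!(n %in% c(0L, 2L, 4L, 6L)) ||
        !all(ch[c(1, length(ch))] %in% c("R", "K")))
      stop("planted motif '", m, "' violates the convertase rule")
    # basic residues in the spacer are fine (they only add submatches at
    # the same scission point, e.g. the RR inside RSRR); cysteines would
    # corrupt the planted skeleton
    if (n > 0 && any(ch[2:(n + 1L)] == "C"))
      stop("planted motif spacer must not contain C: ", m)
  }
  span <- sum(nchar(p$motifs)) + p$motif_spacing * (length(p$motifs) - 1L)
  if (length(p$motifs) && span > p$prodomain_len)
    stop("prodomain too short for the planted motifs")
  L <- p$signal_len + p$prodomain_len + p$mature_len
  chars <- with_local_seed(sub_seed(spec, 101L),
                           sample(AA_FILLER, L, replace = TRUE))
  chars[1] <- "M"
  pro_end <- p$signal_len + p$prodomain_len
  sites <- NULL
  if (length(p$motifs)) {
    # place motifs back-to-front so the last motif ends the prodomain
    starts <- integer(length(p$motifs))
    e <- pro_end
    for (i in rev(seq_along(p$motifs))) {
      starts[i] <- e - nchar(p$motifs[i]) + 1L
      e <- starts[i] - p$motif_spacing - 1L
    }
    if (starts[1] <= p$signal_len)
      stop("prodomain too short for the planted motifs")
    for (i in seq_along(p$motifs))
      chars[starts[i]:(starts[i] + nchar(p$motifs[i]) - 1L)] <-
        seq_chars(p$motifs[i])
    sites <- data.frame(motif = p$motifs, start = starts,
                        spacer_n = nchar(p$motifs) - 2L,
                        mature_start = starts + nchar(p$motifs),
                        stringsAsFactors = FALSE)
  }
  cys_local <- p$mature_cys
  if (is.null(cys_local) && p$cys_skeleton > 0L)
    cys_local <- default_skeleton(p$cys_skeleton, p$mature_len)
  cys_local <- sort(unique(c(cys_local, p$extra_cys_mature)))
  if (length(cys_local)) {
    if (max(cys_local) > p$mature_len)
      stop("cysteine positions exceed the mature domain")
    chars[pro_end + cys_local] <- "C"
  }
  rec <- precursor_record(paste0("synthetic_", spec$seed),
                          paste(chars, collapse = ""),
                          signal_end = p$signal_len)
  attr(rec, "ground_truth") <- list(
    sites = sites, signal_end = p$signal_len,
    mature_start = pro_end + 1L,
    mature_cys_local = cys_local,
    cys_precursor = pro_end + cys_local)
  rec
}

# Minimal residue atom template: backbone plus Sgamma for cysteines.
# Offsets along the chain axis (x); enough geometry for contact and
# disulfide logic, no rotamer realism.
residue_atoms <- function(resid) {
  at <- data.frame(elety = c("N", "CA", "C", "O"),
                   dx = c(-1.2, 0, 1.2, 2.3), dy = 0, dz = 0,
                   stringsAsFactors = FALSE)
  if (resid == "CYS")
    at <- rbind(at, data.frame(elety = "SG", dx = 0, dy = 0, dz = 3))
  at
}

build_chain <- function(chain_id, resids, origin = c(0, 0, 0), spacing = 8) {
  rows <- lapply(seq_along(resids), function(i) {
    at <- residue_atoms(resids[i])
    data.frame(chain = chain_id, resno = i, resid = resids[i],
               elety = at$elety,
               x = origin[1] + spacing * (i - 1L) + at$dx,
               y = origin[2] + at$dy, z = origin[3] + at$dz,
               b = NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic two-chain dimer model with known interface
#'
#' Two chains of glycines laid out on parallel axes 8 A apart per
#' residue. Chain B sits `decoy_sep_A` away from chain A except at the
#' planted interface residues, which are brought to exactly
#' `contact_target_A` (minimum heavy-atom distance, achieved between the
#' matching backbone atoms of residue i on each chain). The PAE matrix is
#' `background_pae_A` everywhere except the planted contact pairs (both
#' directions), which get `interface_pae_A`; pLDDT goes to the B-factor
#' column. With the defaults, every planted residue pair is a 3.5 A
#' contact with PAE 2 and everything else is beyond 10 A with PAE 20.
#'
#' @param spec A [synth_spec()]; see `spec$structure` for parameters.
#' @param dir If non-NULL, write `model.pdb`, `model.cif`,
#'   `pae_colabfold.json` and `pae_afdb.json` into this directory.
#' @return A list of class `synth_dimer`: `model` (a `structure_model`),
#'   `pae` (a `pae_matrix`), `ground_truth` (planted interface residues
#'   and contact list), and `paths` (when written).
#' @export
gen_dimer_structure <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  s <- spec$structure
  n <- s$chain_len
  interface <- s$interface
  if (is.null(interface))
    interface <- with_local_seed(sub_seed(spec, 202L),
                                 sort(sample(n, s$n_interface)))
  if (any(interface > n)) stop("interface larger than chain")
  if (s$decoy_sep_A <= s$contact_target_A)
    stop("decoy separation must exceed the contact target")
  a <- build_chain("A", rep("GLY", n))
  b <- build_chain("B", rep("GLY", n), origin = c(0, s$decoy_sep_A, 0))
  b$y[b$resno %in% interface] <- s$contact_target_A
  atoms <- rbind(a, b)
  plddt <- function(resno) ifelse(resno %in% interface,
                                  s$plddt_interface, s$plddt_background)
  atoms$b <- plddt(atoms$resno)
  key <- !duplicated(paste(atoms$chain, atoms$resno))
  residues <- data.frame(chain = atoms$chain[key], resno = atoms$resno[key],
                         resid = atoms$resid[key], plddt = atoms$b[key],
                         stringsAsFactors = FALSE)
  residues$index <- seq_len(nrow(residues))
  model <- structure(list(atoms = atoms, residues = residues,
                          chains = c("A", "B")),
                     class = "structure_model")
  pae <- matrix(s$background_pae_A, 2L * n, 2L * n)
  diag(pae) <- 0
  for (i in interface) {
    pae[i, n + i] <- s$interface_pae_A
    pae[n + i, i] <- s$interface_pae_A
  }
  attr(pae, "residue_map") <- residues
  class(pae) <- c("pae_matrix", class(pae))
  truth <- list(interface = interface,
                contacts = data.frame(chain_a = "A", res_a = interface,
                                      chain_b = "B", res_b = interface,
                                      dist = s$contact_target_A))
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(pdb = file.path(dir, "model.pdb"),
                  cif = file.path(dir, "model.cif"),
                  pae_colabfold = file.path(dir, "pae_colabfold.json"),
                  pae_afdb = file.path(dir, "pae_afdb.json"))
    write_structure(model, paths$pdb, "pdb")
    write_structure(model, paths$cif, "cif")
    write_pae(pae, paths$pae_colabfold, "colabfold")
    write_pae(pae, paths$pae_afdb, "afdb")
  }
  structure(list(model = model, pae = pae, ground_truth = truth,
                 paths = paths),
            class = "synth_dimer")
}

#' Generate a single-chain structure with planted disulfide bonds
#'
#' Places cysteines at the requested residue positions and moves the
#' S-gamma atoms of each planted pair to a shared bond site 2.03 A apart
#' (the canonical S-S bond length); unpaired cysteines keep their
#' S-gamma on the backbone frame, far from every bond site. Geometry is
#' schematic: only the S-gamma distances carry meaning.
#'
#' @param spec A [synth_spec()]; uses `spec$structure$chain_len`,
#'   `cys_positions` (residue numbers) and `ss_pairs` (two-column matrix
#'   or list of position pairs; default pairs them by the rule of
#'   [assign_knot_connectivity()] when the count allows).
#' @return A list of class `synth_knot`: `model` and `ground_truth`
#'   (`pairs`, `unpaired`).
#' @export
gen_knot_structure <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  s <- spec$structure
  cys <- sort(as.integer(s$cys_positions))
  if (length(cys) == 0L) stop("cys_positions must be non-empty")
  if (max(cys) > s$chain_len) stop("cysteine position beyond chain end")
  pairs <- s$ss_pairs
  if (is.null(pairs)) pairs <- assign_knot_connectivity(cys)$pairs
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (!all(pairs %in% cys)) stop("ss_pairs must reference cys_positions")
  resids <- rep("GLY", s$chain_len)
  resids[cys] <- "CYS"
  atoms <- build_chain("A", resids)
  for (k in seq_len(nrow(pairs))) {
    site_x <- 8 * s$chain_len + 50 + 10 * k
    for (m in 1:2) {
      sel <- atoms$resno == pairs[k, m] & atoms$elety == "SG"
      atoms$x[sel] <- site_x
      atoms$y[sel] <- c(-1.015, 1.015)[m]
      atoms$z[sel] <- 0
    }
  }
  atoms$b <- 90
  key <- !duplicated(atoms$resno)
  residues <- data.frame(chain = "A", resno = atoms$resno[key],
                         resid = atoms$resid[key], plddt = 90,
                         stringsAsFactors = FALSE)
  residues$index <- seq_len(nrow(residues))
  model <- structure(list(atoms = atoms, residues = residues, chains = "A"),
                     class = "structure_model")
  structure(list(model = model,
                 ground_truth = list(pairs = pairs,
                                     unpaired = setdiff(cys, pairs))),
            class = "synth_knot")
}

#' Generate survival cohorts under a known interaction model
#'
#' Event times are exponential (constant hazard). The four arms have
#' hazards `h_wt`, `h_wt * r_a`, `h_wt * r_b`, and a double-mutant hazard
#' determined by the generative model: `independent` multiplies the
#' single-mutant effects (`h_wt * r_a * r_b`), `same-pathway` takes the
#' larger single-mutant hazard, and `antagonistic` suppresses the double
#' mutant below the larger single (default: the *smaller* single-mutant
#' hazard, i.e. the milder phenotype). Records past the assay horizon
#' are administratively right-censored at the horizon.
#'
#' @param spec A [synth_spec()]; see `spec$survival` for parameters
#'   (`double_multiplier` overrides the model's double-mutant hazard
#'   multiplier).
#' @return A [survival_dataset()] with attribute `ground_truth`
#'   (hazards per arm and the generative model).
#' @export
gen_survival <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  v <- spec$survival
  h <- c(wt = v$h_wt, a = v$h_wt * v$r_a, b = v$h_wt * v$r_b)
  h["double"] <- if (!is.null(v$double_multiplier)) {
    v$h_wt * v$double_multiplier
  } else {
    switch(v$model,
           "independent" = v$h_wt * v$r_a * v$r_b,
           "same-pathway" = max(h["a"], h["b"]),
           "antagonistic" = min(h["a"], h["b"]),
           stop("unknown survival model: ", v$model))
  }
  recs <- with_local_seed(sub_seed(spec, 303L), {
    do.call(rbind, lapply(names(h), function(arm) {
      t <- stats::rexp(v$n_per_arm, rate = h[[arm]])
      data.frame(strain = v$strains[[arm]],
                 time = pmin(t, v$horizon),
                 event = as.integer(t <= v$horizon),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- survival_dataset(recs)
  attr(out, "ground_truth") <- list(hazards = h, model = v$model,
                                    horizon = v$horizon)
  out
}
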