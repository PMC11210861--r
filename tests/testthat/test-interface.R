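make_dimer <- function(seed, ...) {
  gen_dimer_structure(synth_spec(seed, structure = list(...)))
}

test_that("structure files round-trip through both formats", {
  dir <- tempfile()
  dm <- gen_dimer_structure(synth_spec(3), dir = dir)
  mp <- read_structure(dm$paths$pdb)
  mc <- read_structure(dm$paths$cif)
  expect_equal(nrow(mp$atoms), nrow(dm$model$atoms))
  expect_equal(mp$residues$plddt, dm$model$residues$plddt)
  expect_equal(mp$atoms[, c("x", "y", "z", "b")],
               mc$atoms[, c("x", "y", "z", "b")], tolerance = 1e-6)
  expect_identical(mp$chains, c("A", "B"))
})

test_that("files without atom records are rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(read_structure(f), "no ATOM records")
})

test_that("both PAE dialects parse to the same matrix", {
  dir <- tempfile()
  dm <- gen_dimer_structure(synth_spec(5), dir = dir)
  m <- read_structure(dm$paths$pdb)
  p1 <- read_pae(dm$paths$pae_colabfold, m)
  p2 <- read_pae(dm$paths$pae_afdb, m)
  expect_equal(unclass(p1), unclass(p2), ignore_attr = TRUE)
  expect_equal(dim(p1), rep(nrow(m$residues), 2))
})

test_that("PAE dimension mismatches are caught", {
  dm <- gen_dimer_structure(synth_spec(5))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = matrix(1, 7, 7)), f)
  expect_error(read_pae(f, dm$model), "does not match")
  jsonlite::write_json(list(pae = matrix(1, 4, 5)), f)
  expect_error(read_pae(f), "not square")
  jsonlite::write_json(list(pae = matrix(-1, 4, 4)), f)
  expect_error(read_pae(f), "non-negative")
})

test_that("contact extraction honors the distance cutoff boundary", {
  mk_two_res <- function(d) {
    atoms <- data.frame(
      chain = c("A", "B"), resno = 1L, resid = "GLY", elety = "CA",
      x = c(0, d), y = 0, z = 0, b = 50)
    residues <- data.frame(chain = c("A", "B"), resno = 1L, resid = "GLY",
                           plddt = 50, index = 1:2)
    structure(list(atoms = atoms, residues = residues,
                   chains = c("A", "B")), class = "structure_model")
  }
  expect_equal(nrow(interchain_contacts(mk_two_res(3.5))), 1L)
  expect_equal(nrow(interchain_contacts(mk_two_res(4.0))), 1L)  # <= cutoff
  expect_equal(nrow(interchain_contacts(mk_two_res(4.1))), 0L)
})

test_that("single-chain structures are rejected for contact analysis", {
  ks <- gen_knot_structure(synth_spec(2, structure = list(
    chain_len = 20L, cys_positions = c(2L, 5L, 8L, 11L, 14L, 17L))))
  expect_error(interchain_contacts(ks$model), "two chains")
})

test_that("contact sets equal the brute-force oracle on generated dimers", {
  for (seed in 1:30) {
    dm <- make_dimer(seed, chain_len = 12L,
                     n_interface = 1L + seed %% 5L)
    got <- as.data.frame(interchain_contacts(dm$model))
    oracle <- brute_force_contacts(dm$model)
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, tolerance = 1e-12, info = seed, ignore_attr = TRUE)
    # and equals the planted ground truth
    expect_equal(got$res_a, dm$ground_truth$contacts$res_a, info = seed)
  }
})

test_that("confidence filtering recovers the planted interface exactly", {
  dm <- make_dimer(13, chain_len = 25L, n_interface = 6L)
  ct <- interchain_contacts(dm$model)
  ci <- confident_interface(ct, dm$pae)
  expect_equal(ci$tracks$A, dm$ground_truth$interface)
  expect_equal(ci$tracks$B, dm$ground_truth$interface)
  expect_true(all(ci$contacts$confident))
})

test_that("uniform high PAE empties the track regardless of geometry", {
  dm <- make_dimer(14, interface_pae_A = 30, background_pae_A = 30)
  ci <- confident_interface(interchain_contacts(dm$model), dm$pae)
  expect_length(ci$tracks$A, 0)
  expect_length(ci$tracks$B, 0)
})

test_that("the PAE cutoff is strictly below 5", {
  for (v in c(4.9, 5.0)) {
    dm <- make_dimer(15, interface_pae_A = v)
    ci <- confident_interface(interchain_contacts(dm$model), dm$pae)
    if (v < 5) expect_true(all(ci$contacts$confident))
    else expect_false(any(ci$contacts$confident))
  }
})

test_that("filtering is monotone in both cutoffs", {
  dm <- make_dimer(16, chain_len = 20L, n_interface = 8L,
                   interface_pae_A = 4, background_pae_A = 8)
  ct4 <- interchain_contacts(dm$model, cutoff_A = 4)
  ct3 <- interchain_contacts(dm$model, cutoff_A = 3)
  expect_true(nrow(ct3) <= nrow(ct4))
  lo <- confident_interface(ct4, dm$pae, pae_cutoff_A = 3)
  hi <- confident_interface(ct4, dm$pae, pae_cutoff_A = 10)
  expect_true(all(lo$contacts$confident <= hi$contacts$confident))
  expect_true(all(unlist(lo$tracks) %in% unlist(hi$tracks)))
})

test_that("region-pair columns partition contacts and average their PAE", {
  dm <- make_dimer(17, chain_len = 20L, interface = c(3L, 4L, 12L, 13L))
  regions <- rbind(
    data.frame(chain = "A", region = "pro", start = 1L, end = 10L),
    data.frame(chain = "A", region = "mat", start = 11L, end = 20L),
    data.frame(chain = "B", region = "pro", start = 1L, end = 10L),
    data.frame(chain = "B", region = "mat", start = 11L, end = 20L))
  ct <- interchain_contacts(dm$model)
  rp <- region_pair_contacts(ct, dm$pae, regions)
  tab <- summary(rp)
  expect_equal(tab$n_contacts[tab$region_a == "full"], nrow(ct))
  # the four directed columns partition the full set
  expect_equal(sum(tab$n_contacts[tab$region_a != "full"]), nrow(ct))
  # column means agree with an independent groupby on the raw table
  aug <- rp$`full-full`$contacts
  reg_of <- function(r) ifelse(r <= 10, "pro", "mat")
  key <- paste(reg_of(aug$res_a), reg_of(aug$res_b))
  means <- tapply(aug$pae, key, mean)
  for (nm in names(means)) {
    parts <- strsplit(nm, " ")[[1]]
    col <- rp[[paste(parts, collapse = "-")]]
    expect_equal(col$column_mean_pae, unname(means[nm]))
  }
  expect_equal(rp$`full-full`$column_mean_pae, mean(aug$pae))
})

test_that("two contacts with PAE 2 and 4 average to 3", {
  dm <- make_dimer(18, chain_len = 6L, interface = c(2L, 5L),
                   interface_pae_A = 2)
  # bump one planted pair to PAE 4 in both directions
  pae <- dm$pae
  n <- nrow(dm$model$residues) / 2
  pae[5, n + 5] <- 4; pae[n + 5, 5] <- 4
  regions <- rbind(
    data.frame(chain = c("A", "B"), region = "pro", start = 1L, end = 3L),
    data.frame(chain = c("A", "B"), region = "mat", start = 4L, end = 6L))
  rp <- region_pair_contacts(interchain_contacts(dm$model), pae, regions)
  expect_equal(rp$`full-full`$column_mean_pae, 3.0)
})

test_that("incomplete region annotation is an error", {
  dm <- make_dimer(19, chain_len = 10L)
  regions <- data.frame(chain = "A", region = "pro", start = 1L, end = 10L)
  expect_error(region_pair_contacts(interchain_contacts(dm$model),
                                    dm$pae, regions), "cover")
})

test_that("contact relation is symmetric under chain relabeling", {
  dm <- make_dimer(20, chain_len = 15L, n_interface = 4L)
  m <- dm$model
  sw <- m
  sw$atoms$chain <- ifelse(m$atoms$chain == "A", "B", "A")
  sw$atoms <- sw$atoms[order(match(sw$atoms$chain, c("A", "B")),
                             sw$atoms$resno), ]
  sw$residues <- sw$residues[order(match(
    ifelse(m$residues$chain == "A", "B", "A"), c("A", "B"))), ]
  sw$residues$chain <- sort(ifelse(m$residues$chain == "A", "B", "A"))
  sw$residues$index <- seq_len(nrow(sw$residues))
  a <- as.data.frame(interchain_contacts(m))
  b <- as.data.frame(interchain_contacts(sw))
  expect_equal(a$res_a, b$res_b)
  expect_equal(a$dist, b$dist)
})
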