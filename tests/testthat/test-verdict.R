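test_that("reported ligand metrics classify as printed", {
  v <- classify_dimer_support(tig_multimer_metrics())
  homo2 <- v[v$complex == "TIG-2/TIG-2", ]
  hetero <- v[v$complex == "TIG-2/TIG-3", ]
  homo3 <- v[v$complex == "TIG-3/TIG-3" & v$form == "mature", ]
  expect_true(homo2$structure_confident && homo2$dimer_supported)
  expect_true(hetero$structure_confident && hetero$dimer_supported)
  expect_false(homo3$structure_confident)
  expect_false(homo3$dimer_supported)
})

test_that("the pLDDT threshold is inclusive at 70", {
  m <- multimer_metrics("x", "a", "b", form = "mature",
                        mean_plddt = 70, ptm = 0.5, iptm = 0.5)
  expect_true(classify_dimer_support(m)$structure_confident)
  m$mean_plddt <- 69.999
  expect_false(classify_dimer_support(m)$structure_confident)
})

test_that("out-of-range metrics are rejected", {
  expect_error(multimer_metrics("x", "a", "b", form = "mature",
                                mean_plddt = 101, ptm = 0.5, iptm = 0.5),
               "mean_plddt")
  expect_error(multimer_metrics("x", "a", "b", form = "mature",
                                mean_plddt = 50, ptm = 1.2, iptm = 0.5),
               "ptm")
  m <- multimer_metrics("x", "a", "b", form = "mature",
                        mean_plddt = 50, ptm = 0.5, iptm = 0.5)
  m$iptm <- 2
  expect_error(classify_dimer_support(m), "out of range")
})

test_that("verdicts are monotone in the metrics", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(1, 0, 100); q <- runif(1)
    m1 <- multimer_metrics("x", "a", "b", form = "mature",
                           mean_plddt = p, ptm = 0.5, iptm = q)
    m2 <- multimer_metrics("x", "a", "b", form = "mature",
                           mean_plddt = min(p + runif(1, 0, 20), 100),
                           ptm = 0.5, iptm = min(q + runif(1, 0, 0.3), 1))
    v1 <- classify_dimer_support(m1); v2 <- classify_dimer_support(m2)
    expect_true(v2$structure_confident >= v1$structure_confident)
    expect_true(v2$dimer_supported >= v1$dimer_supported)
  }
})

make_panel <- function() {
  rbind(
    multimer_metrics("known-dimer-1", "p", "q", form = "mature",
                     mean_plddt = 90, ptm = 0.85, iptm = 0.85,
                     label = "dimer"),
    multimer_metrics("known-dimer-2", "p", "r", form = "mature",
                     mean_plddt = 88, ptm = 0.8, iptm = 0.8,
                     label = "dimer"),
    multimer_metrics("non-dimer-control", "s", "s", form = "mature",
                     mean_plddt = 60, ptm = 0.4, iptm = 0.2,
                     label = "negative-control"))
}

test_that("a candidate identical to a panel member groups with it at distance zero", {
  panel <- make_panel()
  cand <- panel[2, ]
  cmp <- benchmark_panel_compare(cand, panel)
  expect_equal(cmp$nearest$distance[1], 0)
  expect_identical(cmp$groups_with, "dimer")
})

test_that("well-separated candidates group with the correct side", {
  panel <- make_panel()
  pos <- multimer_metrics("cand", "a", "b", form = "mature",
                          mean_plddt = 90, ptm = 0.87, iptm = 0.88)
  expect_identical(benchmark_panel_compare(pos, panel)$groups_with, "dimer")
  neg <- multimer_metrics("cand", "a", "a", form = "mature",
                          mean_plddt = 62, ptm = 0.38, iptm = 0.25)
  expect_identical(benchmark_panel_compare(neg, panel)$groups_with,
                   "negative-control")
  expect_error(benchmark_panel_compare(pos, panel[0, ]), "empty")
})

test_that("benchmark distance is a metric on random panels", {
  set.seed(22)
  vec <- function(m) c(m$mean_plddt / 100, m$ptm, m$iptm)
  rand_m <- function(nm) multimer_metrics(nm, "a", "b", form = "mature",
                                          mean_plddt = runif(1, 0, 100),
                                          ptm = runif(1), iptm = runif(1),
                                          label = "dimer")
  for (i in 1:25) {
    x <- rand_m("x"); y <- rand_m("y"); z <- rand_m("z")
    dxy <- benchmark_panel_compare(x, y)$nearest$distance[1]
    dyx <- benchmark_panel_compare(y, x)$nearest$distance[1]
    dxz <- benchmark_panel_compare(x, z)$nearest$distance[1]
    dzy <- benchmark_panel_compare(z, y)$nearest$distance[1]
    expect_equal(dxy, dyx)
    expect_true(dxy <= dxz + dzy + 1e-12)
  }
})

test_that("nearest-neighbour label recovery on separated Gaussian clusters", {
  set.seed(23)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  correct <- 0L
  n <- 1000L
  for (i in seq_len(n)) {
    truth <- sample(c("dimer", "negative-control"), 1)
    mu <- if (truth == "dimer") c(0.9, 0.85, 0.85) else c(0.6, 0.4, 0.2)
    x <- clamp(mu + rnorm(3, 0, 0.03), 0, 1)
    cand <- multimer_metrics("cand", "a", "b", form = "mature",
                             mean_plddt = 100 * x[1], ptm = x[2],
                             iptm = x[3])
    panel <- rbind(
      multimer_metrics("p1", "a", "b", form = "mature",
                       mean_plddt = 100 * clamp(0.9 + rnorm(1, 0, 0.03), 0, 1),
                       ptm = clamp(0.85 + rnorm(1, 0, 0.03), 0, 1),
                       iptm = clamp(0.85 + rnorm(1, 0, 0.03), 0, 1),
                       label = "dimer"),
      multimer_metrics("p2", "a", "b", form = "mature",
                       mean_plddt = 100 * clamp(0.6 + rnorm(1, 0, 0.03), 0, 1),
                       ptm = clamp(0.4 + rnorm(1, 0, 0.03), 0, 1),
                       iptm = clamp(0.2 + rnorm(1, 0, 0.03), 0, 1),
                       label = "negative-control"))
    got <- benchmark_panel_compare(cand, panel)$groups_with
    if (got == truth) correct <- correct + 1L
  }
  expect_gte(correct / n, 0.99)
})
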