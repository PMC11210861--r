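# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Brute-force interchain contact scan: nested loop over residue pairs,
# min over all heavy-atom pairs, no spatial indexing.
brute_force_contacts <- function(model, cutoff = 4.0) {
  at <- model$atoms
  chains <- unique(at$chain)
  out <- list()
  for (ci in seq_len(length(chains) - 1L)) for (cj in (ci + 1L):length(chains)) {
    a <- at[at$chain == chains[ci], ]
    b <- at[at$chain == chains[cj], ]
    for (ra in unique(a$resno)) for (rb in unique(b$resno)) {
      pa <- a[a$resno == ra, c("x", "y", "z")]
      pb <- b[b$resno == rb, c("x", "y", "z")]
      dmin <- Inf
      for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
        d <- sqrt(sum((as.numeric(pa[i, ]) - as.numeric(pb[j, ]))^2))
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          chain_a = chains[ci], res_a = ra,
          chain_b = chains[cj], res_b = rb, dist = dmin)
    }
  }
  if (!length(out))
    return(data.frame(chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      dist = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chain_a, res$chain_b, res$res_a, res$res_b), ]
}

# Exhaustive global-alignment score by recursion over alignment paths,
# affine gaps costing opening + length * extension (end gaps included).
# Tractable only for very short sequences.
enumerate_alignment_score <- function(a, b, submat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    if (i <= n) {
      open <- if (state == "gb") 0 else gap_open
      best <- max(best, -open - gap_ext + rec(i + 1, j, "gb"))
    }
    if (j <= m) {
      open <- if (state == "ga") 0 else gap_open
      best <- max(best, -open - gap_ext + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# Direct (vectorized, loop-free over subjects) Mantel-Cox computation on
# pooled data; independent of the package's per-time loop.
logrank_hand_formula <- function(time_a, event_a, time_b, event_b) {
  tt <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  n1 <- vapply(tt, function(t) sum(time_a >= t), numeric(1))
  n2 <- vapply(tt, function(t) sum(time_b >= t), numeric(1))
  d1 <- vapply(tt, function(t) sum(time_a == t & event_a == 1), numeric(1))
  d2 <- vapply(tt, function(t) sum(time_b == t & event_b == 1), numeric(1))
  n <- n1 + n2; d <- d1 + d2
  keep <- n > 1 & d > 0
  e1 <- d * n1 / n
  v <- (d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1))[keep]
  ome <- sum(d1[d > 0]) - sum(e1[d > 0])
  list(chi = ome^2 / sum(v), o_minus_e = ome)
}

# Shorthand: exponential cohort with administrative censoring.
exp_cohort <- function(n, rate, horizon, strain = "x") {
  t <- rexp(n, rate)
  data.frame(strain = strain, time = pmin(t, horizon),
             event = as.integer(t <= horizon))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
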