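#' Validate a right-censored survival dataset
#'
#' @param data Data frame with columns `strain` (cohort label), `time`
#'   (days, non-negative) and `event` (1 = death observed, 0 =
#'   right-censored).
#' @return The validated data frame, class `survival_dataset`.
#' @export
survival_dataset <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("strain", "time", "event") %in% names(data)))
  if (any(is.na(data$time)) || any(data$time < 0))
    stop("times must be non-negative")
  if (!all(data$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)")
  if (any(is.na(data$strain))) stop("every record needs a strain label")
  class(data) <- c("survival_dataset", "data.frame")
  data
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Standard product-limit estimator with the usual tie convention:
#' subjects censored at t are still at risk for deaths at t. Implemented
#' directly from the formula; survival starts at 1 and steps down only at
#' observed death times.
#'
#' @param data A [survival_dataset()] (or plain data frame with the same
#'   columns).
#' @param strain Cohort label to estimate; if `NULL`, `data` is assumed
#'   to be a single cohort.
#' @return An object of class `km_fit`: data frame `table` with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (one row per
#'   distinct event or censoring time), plus `strain` and `n`.
#' @examples
#' d <- data.frame(strain = "x", time = 1:3, event = 1)
#' km_estimate(d, "x")$table$surv   # 2/3, 1/3, 0
#' @export
km_estimate <- function(data, strain = NULL) {
  data <- as.data.frame(data)
  if (!is.null(strain)) {
    if (!strain %in% data$strain) stop("unknown strain: ", strain)
    data <- data[data$strain == strain, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("empty cohort")
  tt <- sort(unique(data$time))
  n_risk <- vapply(tt, function(t) sum(data$time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(data$time == t & data$event == 1),
                    numeric(1))
  n_censor <- vapply(tt, function(t) sum(data$time == t & data$event == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(table = data.frame(time = tt, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv),
                 strain = strain %||% "cohort", n = nrow(data)),
            class = "km_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> ", x$strain, ": n = ", x$n, ", ",
      sum(x$table$n_event), " events\n", sep = "")
  invisible(x)
}

#' Log-rank (Mantel-Cox) test for two censored cohorts
#'
#' At each distinct death time the observed number of deaths in group A
#' is compared with its expectation under the pooled-risk null, with the
#' hypergeometric variance
#' `d * (n1/n) * (1 - n1/n) * (n - d) / (n - 1)`; the summed
#' observed-minus-expected score squared over the summed variance is
#' chi-square distributed with one degree of freedom. The sign of the
#' observed-minus-expected sum for group A gives the direction of the
#' effect: positive means group A died more than expected (worse
#' survival).
#'
#' @param dataset_a,dataset_b Data frames with `time` and `event`
#'   columns (strain labels, if present, are ignored; each argument is a
#'   single cohort).
#' @return An object of class `logrank_result`: `chi_square`, `df` (1),
#'   `p_value`, `o_minus_e` (group A), `variance`, and the per-group
#'   observed/expected totals.
#' @export
logrank_test <- function(dataset_a, dataset_b) {
  a <- as.data.frame(dataset_a); b <- as.data.frame(dataset_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both cohorts must be non-empty")
  if (sum(a$event) + sum(b$event) == 0L)
    stop("no events in either cohort; log-rank test undefined")
  times <- sort(unique(c(a$time[a$event == 1], b$time[b$event == 1])))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t); n <- n1 + n2
    d1 <- sum(a$time == t & a$event == 1)
    d2 <- sum(b$time == t & b$event == 1)
    d <- d1 + d2
    if (n == 0 || d == 0) next
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  ome <- o1 - e1
  chi <- if (v > 0) ome^2 / v else 0
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, 1L, lower.tail = FALSE),
                 o_minus_e = ome, variance = v,
                 observed = c(a = o1, b = sum(b$event)),
                 expected = c(a = e1)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> chi-square = ", signif(x$chi_square, 4),
      " (df 1), p = ", signif(x$p_value, 3), ", O-E(A) = ",
      signif(x$o_minus_e, 3), "\n", sep = "")
  invisible(x)
}

#' Genetic-interaction call from survival of double-mutant cohorts
#'
#' Implements the epistasis decision procedure over four cohorts:
#' wild-type, two single mutants, and the double mutant. If two genes
#' act independently, the double mutant should be more severely affected
#' (worse survival) than either single mutant, reflecting disruption of
#' two independent pathways. If they act together — for instance as
#' subunits of one heterodimeric ligand — the double mutant should
#' phenocopy the single mutants. A double mutant that survives
#' significantly *better* than the worse single mutant indicates (at
#' least partial) antagonism.
#'
#' Pre-condition: both single mutants must themselves be significantly
#' worse than wild type, else the comparison is `inconclusive`. All
#' pairwise comparisons use the log-rank (Mantel-Cox) test at level
#' `alpha` per comparison (the field's asterisk convention, "ns" when
#' p > alpha); direction of effect is taken from the sign of the
#' observed-minus-expected score, which stays well defined under heavy
#' censoring.
#'
#' Decision table (after the pre-condition):
#' * double significantly better than the worse single -> `antagonistic`
#' * double significantly worse than both singles -> `independent`
#' * double not significantly different from either single ->
#'   `same-pathway`
#' * otherwise -> `inconclusive`
#'
#' @param data A [survival_dataset()] containing all four cohorts.
#' @param wt,a,b,double Strain labels of the wild-type, single-mutant and
#'   double-mutant cohorts.
#' @param alpha Per-comparison significance level (default 0.05).
#' @param bonferroni If `TRUE`, divide `alpha` by the number of
#'   double-vs-single and single-vs-single comparisons (3).
#' @return An object of class `interaction_call`: `call` (one of
#'   `independent`, `same-pathway`, `antagonistic`, `inconclusive`),
#'   `tests` (the supporting `logrank_result`s), `worse_single`, and
#'   `alpha`.
#' @export
interaction_call <- function(data, wt, a, b, double, alpha = 0.05,
                             bonferroni = FALSE) {
  data <- as.data.frame(data)
  cohort <- function(s) {
    d <- data[data$strain == s, , drop = FALSE]
    if (nrow(d) == 0L) stop("empty cohort for strain: ", s)
    d
  }
  cw <- cohort(wt); ca <- cohort(a); cb <- cohort(b); cd <- cohort(double)
  alpha_adj <- if (bonferroni) alpha / 3 else alpha
  t_a_wt <- logrank_test(ca, cw)
  t_b_wt <- logrank_test(cb, cw)
  tests <- list(a_vs_wt = t_a_wt, b_vs_wt = t_b_wt)
  sig_worse <- function(t) t$p_value <= alpha & t$o_minus_e > 0
  result <- function(call, worse_single = NA_character_)
    structure(list(gene_pair = c(a, b), call = call, tests = tests,
                   worse_single = worse_single, alpha = alpha_adj),
              class = "interaction_call")
  if (!(sig_worse(t_a_wt) && sig_worse(t_b_wt)))
    return(result("inconclusive"))
  # identify the worse single mutant
  t_ab <- logrank_test(ca, cb)
  tests$a_vs_b <- t_ab
  worse <- if (t_ab$p_value <= alpha_adj) {
    if (t_ab$o_minus_e > 0) a else b
  } else {
    # not separable: fall back to the larger standardized excess vs wt
    if (t_a_wt$o_minus_e / sqrt(t_a_wt$variance) >=
        t_b_wt$o_minus_e / sqrt(t_b_wt$variance)) a else b
  }
  t_d_a <- logrank_test(cd, ca)
  t_d_b <- logrank_test(cd, cb)
  tests$double_vs_a <- t_d_a
  tests$double_vs_b <- t_d_b
  t_d_worse <- if (worse == a) t_d_a else t_d_b
  call <- if (t_d_worse$p_value <= alpha_adj && t_d_worse$o_minus_e < 0) {
    "antagonistic"
  } else if (t_d_a$p_value <= alpha_adj && t_d_a$o_minus_e > 0 &&
             t_d_b$p_value <= alpha_adj && t_d_b$o_minus_e > 0) {
    "independent"
  } else if (t_d_a$p_value > alpha_adj && t_d_b$p_value > alpha_adj) {
    "same-pathway"
  } else {
    "inconclusive"
  }
  result(call, worse)
}

#' @export
print.interaction_call <- function(x, ...) {
  cat("<interaction_call> ", paste(x$gene_pair, collapse = " x "), ": ",
      x$call, " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
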