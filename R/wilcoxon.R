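#' One-sided Wilcoxon signed-rank test on paired differences
#'
#' Tests whether paired differences are shifted upward (alternative:
#' positive). Zero differences are dropped; |differences| are mid-ranked.
#' For `n <= exact_max_n` retained pairs the exact null distribution of the
#' positive-rank sum is used — via [stats::psignrank()] when the ranks are
#' untied, and via a dynamic-programming enumeration over doubled midranks
#' when ties occur, so the p-value stays exact either way. Larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param d Numeric vector of paired differences (a minus b, oriented so
#'   positive means "a better").
#' @param exact_max_n Largest n for which the exact null is used.
#' @return List with `p` (one-sided p-value, `NA` when no non-zero pairs
#'   remain), `n` (retained pairs), `statistic` (positive-rank sum W+) and
#'   `method` (`"exact"`, `"normal"` or `"undefined"`).
#' @export
wilcoxon_signed_rank <- function(d, exact_max_n = 25) {
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = NA_real_, n = 0L, statistic = NA_real_,
                method = "undefined"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    if (anyDuplicated(abs(d)) == 0) {
      # untied ranks: closed-form exact null
      p <- stats::psignrank(w - 1, n, lower.tail = FALSE)
    } else {
      p <- exact_signed_rank_tail(r, w)
    }
    return(list(p = p, n = n, statistic = w, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - 0.5) / sqrt(sigma2)
  list(p = stats::pnorm(z, lower.tail = FALSE), n = n, statistic = w,
       method = "normal")
}

# Exact P(W+ >= w) for arbitrary (possibly tied mid-) ranks r, by dynamic
# programming over doubled ranks (midranks are multiples of 1/2, so 2r is
# integral). Equivalent to enumerating all 2^n sign assignments.
exact_signed_rank_tail <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # dist[k+1] = #assignments with 2*W+ == k
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(total + 1L - ri)])
    dist <- dist + shifted
  }
  w2 <- as.integer(round(2 * w))
  sum(dist[(w2 + 1L):(total + 1L)]) / 2^length(r2)
}

#' Per-bin one-sided Wilcoxon comparison of two models
#'
#' Pairs the two evaluation tables by slice reference, bins slices by
#' Fisher's-ratio contrast, and within each bin runs a one-sided Wilcoxon
#' signed-rank test per metric with the alternative "model A outperforms
#' model B". Orientation per metric: higher detection and DSC are better;
#' lower HD and lower |RAAD| are better. Bins with no non-zero paired
#' difference are reported as undefined, never raised.
#'
#' @param evals_a,evals_b data.frames from [evaluate_dataset()] covering
#'   the same slice ids.
#' @param contrasts data.frame with `slice_id` and `fisher`.
#' @param bin_edges Increasing numeric vector of Fisher's-ratio bin edges.
#' @return data.frame with one row per (bin, metric): `bin_low`,
#'   `bin_high`, `metric`, `n`, `p`, `method`.
#' @export
wilcoxon_bin_compare <- function(evals_a, evals_b, contrasts, bin_edges) {
  cg_assert(setequal(evals_a$slice_id, evals_b$slice_id) &&
            nrow(evals_a) == nrow(evals_b),
            "cg_error_unpaired", "evaluations are not paired by slice id")
  b <- evals_b[match(evals_a$slice_id, evals_b$slice_id), ]
  f <- contrasts$fisher[match(evals_a$slice_id, contrasts$slice_id)]
  cg_assert(all(is.finite(f)), "cg_error_unpaired",
            "missing contrast for some evaluated slices")
  diffs <- list(
    detection = evals_a$detection - b$detection,
    dsc = evals_a$dsc - b$dsc,
    hd = b$hd - evals_a$hd,
    raad = abs(b$raad) - abs(evals_a$raad))
  bin <- cut(f, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  out <- list()
  for (lev in seq_len(length(bin_edges) - 1L)) {
    in_bin <- !is.na(bin) & as.integer(bin) == lev
    for (metric in names(diffs)) {
      res <- wilcoxon_signed_rank(diffs[[metric]][in_bin])
      out[[length(out) + 1L]] <- data.frame(
        bin_low = bin_edges[lev], bin_high = bin_edges[lev + 1L],
        metric = metric, n = res$n, p = res$p, method = res$method,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
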