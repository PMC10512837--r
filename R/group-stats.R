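# Mann-Whitney U comparisons of segmental CDA and TMI values between
# groups, with exact enumeration for the small samples typical of animal
# cohorts (n = 7 per group).

# Cache of combn index matrices keyed by "n.na".
.mw_cache <- new.env(parent = emptyenv())

mw_combinations <- function(n, na) {
  key <- paste(n, na, sep = ".")
  if (is.null(.mw_cache[[key]]))
    .mw_cache[[key]] <- combn(n, na)
  .mw_cache[[key]]
}

#' Mann-Whitney U test
#'
#' The statistic counts, over all cross pairs, the times a value of
#' `sample_a` exceeds one of `sample_b`, with ties counted one half:
#' `U = sum[a > b] + 0.5 sum[a == b]`. For combined sample sizes up to
#' `exact_limit` the p-value is computed by exact enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings of the pooled values; larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param sample_a,sample_b Numeric vectors with at least 2 finite values
#'   each.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param exact Force exact enumeration on/off; default decides by
#'   `exact_limit`.
#' @param exact_limit Combined-size cutover for exact enumeration
#'   (default 16).
#' @return A list of class `htest`: `statistic` (U of `sample_a`),
#'   `p.value`, `alternative`, `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two.sided", "greater", "less"),
                           exact = NULL, exact_limit = 16) {
  alternative <- match.arg(alternative)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b))))
    stop_invalid("both samples need >= 2 finite values")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (is.null(exact)) exact <- n <= exact_limit
  eps <- 1e-9
  if (exact) {
    idx <- mw_combinations(n, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      greater = mean(Us >= U - eps),
      less = mean(Us <= U + eps))
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- switch(alternative,
        two.sided = (abs(U - mu) - 0.5) / sqrt(sigma2),
        greater = (U - mu - 0.5) / sqrt(sigma2),
        less = -(U - mu + 0.5) / sqrt(sigma2))
      p <- if (alternative == "two.sided") 2 * pnorm(-abs(max(z, 0)))
           else pnorm(-z)
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(statistic = c(U = U), p.value = p,
                 alternative = alternative, method = method,
                 data.name = "sample_a vs sample_b"),
            class = "htest")
}

parse_comparisons <- function(comparisons) {
  if (is.character(comparisons))
    comparisons <- strsplit(comparisons, ":", fixed = TRUE)
  lapply(comparisons, function(p) {
    p <- as.character(p)
    if (length(p) != 2) stop_invalid("each comparison must be a group pair")
    p
  })
}

#' Compare groups across segments and metrics
#'
#' Runs the Mann-Whitney U test for every requested group pair, for every
#' segment and metric in a long-format results table (one row per subject x
#' segment x metric). Significance is flagged at `alpha` with no
#' multiplicity correction by default; Benjamini-Hochberg adjustment is
#' available as an option.
#'
#' @param results_table Data frame with columns `group`, `segment`,
#'   `metric`, `value`.
#' @param comparisons Character vector `"A:B"` or list of length-2 group
#'   pairs.
#' @param metrics Metrics to compare (default: all present).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param ... Passed to [mann_whitney_u()].
#' @return Data frame: `group_a`, `group_b`, `segment`, `metric`, `n_a`,
#'   `n_b`, `U`, `p_value`, `significant`.
#' @export
compare_all <- function(results_table, comparisons, metrics = NULL,
                        alpha = 0.05, p_adjust = c("none", "BH"), ...) {
  p_adjust <- match.arg(p_adjust)
  need <- c("group", "segment", "metric", "value")
  if (!all(need %in% names(results_table)))
    stop_invalid("results_table needs columns: ", paste(need, collapse = ", "))
  pairs <- parse_comparisons(comparisons)
  available <- unique(results_table$group)
  for (p in pairs)
    if (!all(p %in% available))
      stop_invalid("group(s) ", paste(setdiff(p, available), collapse = ", "),
                   " not found; available: ", paste(available, collapse = ", "))
  if (is.null(metrics)) metrics <- unique(results_table$metric)
  segments <- unique(results_table$segment)
  rows <- list()
  for (p in pairs) for (s in segments) for (m in metrics) {
    va <- results_table$value[results_table$group == p[1] &
                              results_table$segment == s &
                              results_table$metric == m]
    vb <- results_table$value[results_table$group == p[2] &
                              results_table$segment == s &
                              results_table$metric == m]
    tst <- mann_whitney_u(va, vb, ...)
    rows[[length(rows) + 1]] <- data.frame(
      group_a = p[1], group_b = p[2], segment = s, metric = m,
      n_a = length(va), n_b = length(vb),
      U = unname(tst$statistic), p_value = tst$p.value)
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out
}
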