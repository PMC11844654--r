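# Per-mouse aggregation and group comparisons.
#
# Spectral properties are averaged on a mouse-by-mouse basis; call-type
# proportions are computed on a per-call (pooled) basis so a mouse that
# makes only one or two calls is not over-weighted. Group comparisons use
# the classical pooled-variance unpaired t-test and the two-sided Fisher
# exact test.

#' Summarize one mouse's calls
#'
#' Computes per-category counts and spectral means plus slope statistics
#' for a single mouse. Categories with zero calls contribute a count of 0
#' and *missing* (not zero) spectral means. Slope statistics are computed
#' over simple USVs: mean absolute slope, mean positive and mean negative
#' slope, and the +/- ratio.
#'
#' @param calls Annotated call data.frame (see [annotate_calls()]) for one
#'   mouse; must share a single `mouse_id`.
#' @param test_type `"courtship"` or `"distress"` (fixes the category set).
#' @param ratio `"count"` (default): +/- ratio is the count ratio
#'   `n_pos / n_neg`; `"mean_slope"`: ratio of mean positive slope to mean
#'   `|negative slope|`. Missing when the denominator is empty.
#' @return One-row data.frame: `mouse_id`, `genotype` (if present),
#'   `total_calls`, `n_<category>`, `<category>_f_mean` / `_f_range` /
#'   `_duration_ms` / `_power_db`, `n_simple`, `n_complex`,
#'   `prop_complex`, `mean_abs_slope`, `mean_pos_slope`, `mean_neg_slope`,
#'   `slope_ratio`.
#' @export
summarize_mouse <- function(calls, test_type = c("courtship", "distress"),
                            ratio = c("count", "mean_slope")) {
  test_type <- match.arg(test_type)
  ratio <- match.arg(ratio)
  if (length(unique(calls$mouse_id)) > 1L) {
    stop("calls mix multiple mouse_ids", call. = FALSE)
  }
  cats <- CATEGORIES[[test_type]]
  out <- data.frame(
    mouse_id = if (nrow(calls)) calls$mouse_id[1L] else NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(calls$genotype) && nrow(calls)) out$genotype <- calls$genotype[1L]
  out$total_calls <- nrow(calls)
  for (cat in cats) {
    sub <- calls[!is.na(calls$category) & calls$category == cat, , drop = FALSE]
    out[[paste0("n_", tolower(cat))]] <- nrow(sub)
    for (f in c("f_mean", "f_range", "duration_ms", "power_db")) {
      out[[paste0(tolower(cat), "_", f)]] <-
        if (nrow(sub)) mean(sub[[f]]) else NA_real_
    }
  }

  usv <- calls[!is.na(calls$category) & calls$category == "USV", , drop = FALSE]
  simple <- usv[!is.na(usv$complexity) & usv$complexity == "simple", , drop = FALSE]
  out$n_simple <- nrow(simple)
  out$n_complex <- sum(usv$complexity == "complex", na.rm = TRUE)
  out$prop_complex <- if (nrow(usv)) out$n_complex / nrow(usv) else NA_real_
  out$mean_abs_slope <- if (nrow(simple)) mean(abs(simple$slope)) else NA_real_
  pos <- simple$slope[simple$slope_sign == "+"]
  neg <- simple$slope[simple$slope_sign == "-"]
  out$mean_pos_slope <- if (length(pos)) mean(pos) else NA_real_
  out$mean_neg_slope <- if (length(neg)) mean(neg) else NA_real_
  out$slope_ratio <- if (ratio == "count") {
    if (length(neg)) length(pos) / length(neg) else NA_real_
  } else {
    if (length(neg)) mean(pos) / abs(mean(neg)) else NA_real_
  }
  out
}

#' Summarize every mouse in a call table
#'
#' @param calls Annotated call data.frame with `mouse_id` (and optionally
#'   `genotype`) columns.
#' @param mice Optional character vector of mouse ids to include (mice with
#'   zero calls get a zero-count row); defaults to the ids present.
#' @inheritParams summarize_mouse
#' @return Data.frame with one row per mouse; see [summarize_mouse()].
#' @export
summarize_cohort <- function(calls, test_type = c("courtship", "distress"),
                             mice = NULL, ratio = c("count", "mean_slope")) {
  test_type <- match.arg(test_type)
  ratio <- match.arg(ratio)
  mice <- mice %||% unique(calls$mouse_id)
  rows <- lapply(mice, function(m) {
    s <- summarize_mouse(calls[calls$mouse_id == m, , drop = FALSE],
                         test_type, ratio)
    s$mouse_id <- m
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled per-call category proportions by genotype
#'
#' Proportions are computed over pooled calls within each genotype — on a
#' per-call level, not averaged across mice — so mice with very few calls
#' do not dominate.
#'
#' @param calls Annotated call data.frame with `genotype` and `category`.
#' @param categories Optional category order; defaults to those present
#'   (boundary-flagged calls are excluded).
#' @return List with `counts` (genotype x category matrix) and
#'   `proportions` (same shape; rows sum to 1, `NA` for a genotype with no
#'   calls).
#' @export
pooled_call_proportions <- function(calls, categories = NULL) {
  if (nrow(calls) == 0L) stop("no calls to pool", call. = FALSE)
  keep <- !is.na(calls$category) & calls$category != "boundary"
  calls <- calls[keep, , drop = FALSE]
  categories <- categories %||% sort(unique(calls$category))
  genotypes <- sort(unique(calls$genotype))
  counts <- matrix(0L, nrow = length(genotypes), ncol = length(categories),
                   dimnames = list(genotypes, categories))
  for (g in genotypes) {
    tab <- table(factor(calls$category[calls$genotype == g],
                        levels = categories))
    counts[g, ] <- as.integer(tab)
  }
  totals <- rowSums(counts)
  proportions <- counts / ifelse(totals > 0, totals, NA_real_)
  list(counts = counts, proportions = proportions)
}

#' Pooled-variance unpaired t-test
#'
#' Classical two-sided Student t-test with pooled variance and
#' `df = n_a + n_b - 2` (so 13 + 13 mice give t with 24 degrees of
#' freedom). Missing values are dropped listwise per group.
#'
#' @param a,b Numeric vectors (each needs >= 2 non-missing values).
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
unpaired_t_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  df <- length(a) + length(b) - 2L
  pooled_var <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled_var <= 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                df = df, p = if (equal) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  fit <- t.test(a, b, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-ordering convention: the
#' sum of hypergeometric probabilities of all tables (with the observed
#' margins) whose probability does not exceed that of the observed table.
#' Degenerate tables with an all-zero margin return p = 1.
#'
#' @param m 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)) # 2/choose(20,10)
#' @export
fisher_exact_2x2 <- function(m) {
  m <- matrix(as.numeric(m), nrow = 2, byrow = !is.matrix(m))
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m <- round(m)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(m[1, 1], r1, r2, c1)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
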