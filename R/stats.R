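# Pre/post efficacy testing and indicator-scale correlation.

# Exact null distribution of the signed-rank statistic W+ under the
# symmetric null, tie-aware: work on doubled midranks (integers) and
# convolve P(S) by dynamic programming. Returns P over S = 0..sum(u).
signed_rank_null <- function(u) {
  total <- sum(u)
  p <- numeric(total + 1L)
  p[1L] <- 1
  for (ui in u) {
    shifted <- c(numeric(ui), p[seq_len(total + 1L - ui)])
    p <- 0.5 * (p + shifted)
  }
  p
}

signed_rank_test <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("all paired differences are zero; p = 1")
    return(tibble(statistic = 0, p.value = 1, n_used = 0L,
                  method = "Wilcoxon signed-rank (degenerate)"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    u <- as.integer(round(2 * r))
    probs <- signed_rank_null(u)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu - 0.5 * sign(W - mu)) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  tibble(statistic = W, p.value = p, n_used = n, method = method)
}

#' Pre/post efficacy test
#'
#' Nonparametric two-sided test of whether paired pre- and post-training
#' scores differ. The default is the Wilcoxon signed-rank test on the
#' paired differences — the appropriate choice for a pre/post design on
#' the same patients — with zero differences dropped and the *exact*
#' null distribution for n <= 25 (computed tie-aware over midranks, so
#' integer clinical scores are handled exactly); larger n uses the
#' normal approximation with continuity correction. The unpaired rank-sum
#' (Mann-Whitney) test is available as an option.
#'
#' @param pre,post Equal-length paired numeric vectors, n >= 5.
#' @param method `"signed-rank"` (paired, default) or `"rank-sum"`.
#' @return One-row tibble `statistic, p.value, n_used, method`.
#' @examples
#' prepost_test(c(10, 12, 9, 14, 11, 13), c(12, 15, 11, 16, 14, 15))
#' @export
prepost_test <- function(pre, post, method = c("signed-rank", "rank-sum")) {
  method <- match.arg(method)
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must be paired vectors of equal length")
  }
  if (length(pre) < 5L) abort("need at least 5 pairs")
  if (method == "signed-rank") {
    signed_rank_test(post - pre)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = FALSE))
    tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
           n_used = length(pre), method = "Wilcoxon rank-sum")
  }
}

#' Pre/post tests for all three clinical scales
#'
#' Pairs each subject's pre and post rows and applies [prepost_test()] to
#' FMA, TEMPA and WMFT.
#'
#' @param scales Scales tibble with both timepoints per subject.
#' @inheritParams prepost_test
#' @return Tibble with one row per scale: `scale, pre_mean, post_mean,
#'   statistic, p.value, n_used, method`.
#' @export
prepost_scales <- function(scales, method = "signed-rank") {
  scales <- validate_scales(scales)
  wide <- tidyr::pivot_wider(scales, id_cols = "subject",
                             names_from = "timepoint",
                             values_from = c("fma", "tempa", "wmft"))
  bind_rows(lapply(c("fma", "tempa", "wmft"), function(sc) {
    pre <- wide[[paste0(sc, "_pre")]]
    post <- wide[[paste0(sc, "_post")]]
    keep <- !is.na(pre) & !is.na(post)
    res <- prepost_test(pre[keep], post[keep], method)
    mutate(res, scale = sc, pre_mean = mean(pre[keep]),
           post_mean = mean(post[keep]), .before = 1)
  }))
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of the midranks (average ranks for
#' ties); the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors; pairs with any `NA` are dropped.
#' @return One-row tibble `rho, p.value, n` (`rho = NA` with a warning
#'   when fewer than 4 complete pairs remain or a variable is constant).
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4L) {
    return(tibble(rho = NA_real_, p.value = NA_real_, n = n))
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warn("constant variable: Spearman rho undefined")
    return(tibble(rho = NA_real_, p.value = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  if (1 - r^2 <= .Machine$double.eps) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  tibble(rho = r, p.value = p, n = n)
}

p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Spearman correlation matrix between indicators and targets
#'
#' Correlates every motor indicator with every target column (the three
#' clinical scales, and/or the ordered impairment level treated as an
#' ordinal variable), two-tailed, pairwise-complete. Cells with fewer
#' than 4 complete pairs or a constant column are left missing. No
#' multiple-testing correction is applied; the report carries raw
#' p-values only, with significance stars at 0.05 (`*`) and 0.01 (`**`).
#'
#' @param indicators Indicators tibble (from [extract_indicators()] /
#'   [extract_cohort_indicators()]), keyed by `subject, timepoint`.
#' @param targets Tibble keyed by `subject, timepoint` whose remaining
#'   numeric columns (e.g. `fma, tempa, wmft, level`) are the correlation
#'   targets.
#' @return A long tibble of class `vr_correlations`: `indicator, target,
#'   n, rho, p.value, stars`, in deterministic order.
#' @export
spearman_matrix <- function(indicators, targets) {
  joined <- left_join(indicators, targets, by = c("subject", "timepoint"))
  ind_cols <- intersect(indicator_names(), names(indicators))
  tgt_cols <- setdiff(names(targets), c("subject", "timepoint"))
  if (length(tgt_cols) == 0L) abort("`targets` has no target columns")
  out <- bind_rows(lapply(ind_cols, function(ic) {
    bind_rows(lapply(tgt_cols, function(tc) {
      res <- spearman_rho(joined[[ic]], joined[[tc]])
      mutate(res, indicator = ic, target = tc, .before = 1)
    }))
  }))
  out <- mutate(out, stars = p_stars(.data$p.value))
  out <- out[, c("indicator", "target", "n", "rho", "p.value", "stars")]
  class(out) <- c("vr_correlations", class(out))
  out
}

#' Write / read a correlation report
#'
#' Long-format CSV (`indicator, target, n, rho, p.value, stars`) in
#' deterministic order with exact number formatting, so the report
#' round-trips through [read_correlation_report()].
#'
#' @param mat A `vr_correlations` tibble from [spearman_matrix()].
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
correlation_report <- function(mat, path) {
  num_fmt <- function(x) ifelse(is.na(x), "", fmt_num(x))
  lines <- c("indicator,target,n,rho,p.value,stars",
             sprintf("%s,%s,%d,%s,%s,%s", mat$indicator, mat$target,
                     mat$n, num_fmt(mat$rho), num_fmt(mat$p.value),
                     mat$stars))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname correlation_report
#' @export
read_correlation_report <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = "", colClasses = c(stars = "character"))
  df$stars[is.na(df$stars)] <- ""
  out <- as_tibble(df)
  class(out) <- c("vr_correlations", class(out))
  out
}

#' @export
autoplot.vr_correlations <- function(object, ...) {
  df <- mutate(object,
               indicator = factor(.data$indicator,
                                  levels = rev(indicator_names())))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$indicator,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho",
                  title = "Indicator-scale correlations (* p<0.05, ** p<0.01)") +
    ggplot2::theme_minimal()
}
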