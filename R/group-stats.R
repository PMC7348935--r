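#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fixed-effects one-way analysis of variance computed from between- and
#' within-group sums of squares, followed by all-pairs Tukey HSD tests on the
#' studentized-range distribution with the Tukey-Kramer correction for
#' unequal group sizes. For two groups the ANOVA F statistic equals the
#' square of the pooled-variance t statistic and the p values agree.
#' Significance is flagged at 0.05 (`*`) and 0.01 (`**`). When every value in
#' the data is identical the comparison degenerates to `F = 0`, `p = 1` and
#' no significant pair.
#'
#' @param data A data frame of replicate measurements.
#' @param value Measurement column (tidy-eval).
#' @param group Group label column (tidy-eval).
#'
#' @return A list of class `group_comparison` with `anova` (one-row tibble:
#'   `F`, `p`, degrees of freedom, sums of squares) and `pairwise` (one row
#'   per group pair: difference of means, standard error, studentized range
#'   `q`, `p_adj`, `p_raw` from an unadjusted pooled-variance comparison,
#'   and significance flags).
#' @export
#'
#' @examples
#' df <- tibble::tibble(group = rep(c("NA-CAT", "CF-CAT"), each = 5),
#'                      modulus = c(rnorm(5, 1), rnorm(5, 3)))
#' anova_tukey(df, modulus, group)
anova_tukey <- function(data, value, group) {
  df <- tibble(y = dplyr::pull(data, {{ value }}),
               g = as.character(dplyr::pull(data, {{ group }})))
  df <- df[complete.cases(df), ]
  sizes <- table(df$g)
  k <- length(sizes)
  if (k < 2) abort("need at least 2 groups to compare.")
  if (any(sizes < 2)) abort("every group needs at least 2 values for a variance estimate.")
  n <- nrow(df)

  means <- tapply(df$y, df$g, mean)
  grand <- mean(df$y)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((df$y - means[df$g])^2)
  df_between <- k - 1
  df_within <- n - k
  ms_within <- ss_within / df_within

  if (ss_within == 0 && ss_between == 0) {
    f_stat <- 0
    p <- 1
  } else if (ms_within == 0) {
    # groups internally constant but different: infinitely strong evidence
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (ss_between / df_between) / ms_within
    p <- pf(f_stat, df_between, df_within, lower.tail = FALSE)
  }

  pairs <- utils::combn(sort(names(sizes)), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    diff <- means[[g2]] - means[[g1]]
    se <- sqrt(ms_within / 2 * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p_adj <- if (diff == 0) 1 else 0
      p_raw <- p_adj
    } else {
      q <- abs(diff) / se
      p_adj <- ptukey(q, nmeans = k, df = df_within, lower.tail = FALSE)
      t_stat <- abs(diff) / sqrt(ms_within * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
      p_raw <- 2 * pt(t_stat, df_within, lower.tail = FALSE)
    }
    tibble(
      group1 = g1, group2 = g2,
      diff = diff, se = se, q = q,
      p_adj = p_adj, p_raw = p_raw,
      sig_05 = p_adj < 0.05, sig_01 = p_adj < 0.01
    )
  })

  structure(
    list(
      anova = tibble(
        F = f_stat, p = p,
        df_between = df_between, df_within = df_within,
        ss_between = ss_between, ss_within = ss_within
      ),
      pairwise = pairwise,
      groups = tibble(group = names(sizes), n = as.integer(sizes),
                      mean = as.numeric(means))
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  stars <- ifelse(x$pairwise$sig_01, "**", ifelse(x$pairwise$sig_05, "*", ""))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s vs %s: diff = %.4g, Tukey p = %.4g %s\n",
                x$pairwise$group1[i], x$pairwise$group2[i],
                x$pairwise$diff[i], x$pairwise$p_adj[i], stars[i]))
  }
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) x$anova

#' Plot group means with pairwise significance
#'
#' @param object A `group_comparison` from [anova_tukey()].
#' @param ... Unused.
#' @return A ggplot of group means.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "group mean")
}
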