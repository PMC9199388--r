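#' Welch's two-sample t-test
#'
#' Two-sided location test without the equal-variance assumption:
#' t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb) with sample variances,
#' degrees of freedom by Welch-Satterthwaite and the p-value from the t
#' distribution.  Delegates to [stats::t.test()].
#'
#' @param a,b numeric vectors, each with at least two values; at least one
#'   group must have positive variance.
#' @return an object of class `welch_result`: list with `t_stat`, `dof`
#'   and `p_two_sided`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_t_test <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    stop_input("both groups must be numeric")
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_input("each group needs at least 2 finite values")
  if (var(a) == 0 && var(b) == 0)
    stop_input("Welch's t-test is undefined when both variances are zero")
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(t_stat = unname(tt$statistic),
                 dof = unname(tt$parameter),
                 p_two_sided = tt$p.value),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4f, dof = %.3f, p (two-sided) = %.4g\n",
              x$t_stat, x$dof, x$p_two_sided))
  invisible(x)
}

#' Pairwise Welch comparisons across density groups
#'
#' Runs [welch_t_test()] on every pair of groups (e.g. per-image densities
#' under different culture media).  Raw pairwise p-values are reported by
#' default; an optional Holm correction is available.
#'
#' @param groups named list of numeric vectors (each length >= 2).
#' @param holm also report Holm-adjusted p-values.
#' @return data.frame with `group_a`, `group_b`, `t`, `dof`, `p` (and
#'   `p_holm` when requested), one row per pair.
#' @export
compare_density_groups <- function(groups, holm = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("need at least two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_input("groups must be named")
  bad <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(bad)) stop_input("group '%s' has fewer than 2 values", bad[1L])
  prs <- combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    w <- welch_t_test(groups[[prs[1L, i]]], groups[[prs[2L, i]]])
    data.frame(group_a = prs[1L, i], group_b = prs[2L, i],
               t = w$t_stat, dof = w$dof, p = w$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
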