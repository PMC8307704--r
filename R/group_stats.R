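#' Normality gate for the group-comparison pipeline
#'
#' Shapiro-Wilk applied to each group separately; the pipeline takes the
#' parametric branch only when every compared group passes (`p > alpha`).
#' Groups with fewer than 3 values (or zero variance) cannot be tested and
#' force the nonparametric branch with a warning.
#'
#' @param values numeric endpoint values.
#' @param group group label per value.
#' @param alpha significance threshold, default 0.05.
#' @return list with `branch` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (named per-group p values, `NA` where untestable).
#' @export
normality_gate <- function(values, group, alpha = 0.05) {
  stopifnot(length(values) == length(group))
  p <- vapply(split(values, group), function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (anyNA(p)) {
    warning("group(s) too small or constant for Shapiro-Wilk; ",
            "taking the nonparametric branch")
    return(list(branch = "nonparametric", shapiro_p = p))
  }
  list(branch = if (all(p > alpha)) "parametric" else "nonparametric",
       shapiro_p = p)
}

nac_groups <- function() c("NAC15", "NAC30", "NAC45")

check_degenerate <- function(df) {
  if (stats::sd(df$value) == 0)
    stop("degenerate comparison: all values identical")
}

#' Omnibus comparison of the three NAC treatment arms
#'
#' One-way ANOVA with post-hoc Tukey pairwise tests on the parametric branch,
#' Kruskal-Wallis on the nonparametric branch.
#'
#' @param table data.frame with columns `value` and `group`; all of `NAC15`,
#'   `NAC30`, `NAC45` must be present.
#' @param branch `"parametric"` or `"nonparametric"` (from
#'   [normality_gate()]).
#' @return list with `p` (omnibus), `test`, and `tukey` (named pairwise p
#'   values, parametric branch only).
#' @export
compare_nac_groups <- function(table, branch = c("parametric",
                                                 "nonparametric")) {
  branch <- match.arg(branch)
  df <- table[table$group %in% nac_groups(), c("value", "group")]
  missing <- setdiff(nac_groups(), unique(df$group))
  if (length(missing) > 0)
    stop("missing NAC group(s): ", paste(missing, collapse = ", "))
  check_degenerate(df)
  df$group <- factor(df$group)
  if (branch == "parametric") {
    fit <- stats::aov(value ~ group, data = df)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    list(p = p, test = "anova", tukey = stats::setNames(tk[, "p adj"],
                                                        rownames(tk)))
  } else {
    list(p = stats::kruskal.test(value ~ group, data = df)$p.value,
         test = "kruskal-wallis", tukey = NULL)
  }
}

#' Pool-to-gNAC decision
#'
#' The three NAC arms are pooled into a single `gNAC` group exactly when the
#' omnibus comparison finds no difference (`p > alpha`, strict, so `p` equal
#' to `alpha` keeps the arms separate).
#'
#' @param p omnibus p value in `[0, 1]`.
#' @param alpha significance threshold, default 0.05.
#' @return `TRUE` (pool) or `FALSE` (keep separate).
#' @export
pool_decision <- function(p, alpha = 0.05) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  p > alpha
}

#' Relabel the NAC arms as a pooled gNAC group
#'
#' @param table data.frame with a `group` column.
#' @return the table with `NAC15`/`NAC30`/`NAC45` relabeled `gNAC`.
#' @export
pool_groups <- function(table) {
  table$group[table$group %in% nac_groups()] <- "gNAC"
  table
}

#' Two-group comparison
#'
#' Student's two-sided equal-variance t-test on the parametric branch,
#' two-sided Mann-Whitney (Wilcoxon rank-sum) on the nonparametric branch.
#'
#' @param table data.frame with columns `value` and `group` containing
#'   exactly the two groups to compare.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param groups length-2 character giving the two group labels; defaults to
#'   the two present.
#' @return two-sided p value.
#' @export
compare_two_groups <- function(table, branch = c("parametric",
                                                 "nonparametric"),
                               groups = NULL) {
  branch <- match.arg(branch)
  if (is.null(groups)) groups <- unique(table$group)
  if (length(groups) != 2) stop("need exactly two groups")
  a <- table$value[table$group == groups[1]]
  b <- table$value[table$group == groups[2]]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  if (branch == "parametric") {
    if (length(a) < 2 || length(b) < 2) stop("t-test needs n >= 2 per group")
    stats::t.test(a, b, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
}

#' Run the full group-comparison pipeline for one endpoint
#'
#' Reproduces the study-style decision procedure on a four-group endpoint
#' table: (1) per-group Shapiro-Wilk normality gate; (2) omnibus comparison
#' of the three NAC arms (ANOVA + Tukey, or Kruskal-Wallis); (3) pooling of
#' the NAC arms into `gNAC` when the omnibus test finds no difference;
#' (4) final comparison — pooled `gNAC` vs `CONT`, or, when the arms differ,
#' each arm vs `CONT` with `NAC30` vs `CONT` reported (Tukey on the
#' four-group fit on the parametric branch, pairwise Mann-Whitney
#' otherwise).
#'
#' @param table data.frame with columns `value`, `group` (from `CONT`,
#'   `NAC15`, `NAC30`, `NAC45`), and optionally `endpoint` and `day` (carried
#'   into the result).
#' @param alpha significance threshold, default 0.05.
#' @return a `comparison_result` list with fields `endpoint`, `day`,
#'   `branch`, `shapiro_p`, `omnibus_p`, `tukey`, `pooled`,
#'   `gnac_vs_cont_p`, `nac30_vs_cont_p`, `rejected` (final-test decision at
#'   `alpha`), `alpha`.
#' @export
run_endpoint <- function(table, alpha = 0.05) {
  stopifnot(all(c("value", "group") %in% names(table)))
  gate <- suppressWarnings(normality_gate(table$value, table$group, alpha))
  omni <- compare_nac_groups(table, gate$branch)
  pooled <- pool_decision(omni$p, alpha)
  gnac_p <- NA_real_; nac30_p <- NA_real_; tukey4 <- NULL
  if (pooled) {
    gnac_p <- compare_two_groups(pool_groups(table), gate$branch,
                                 groups = c("gNAC", "CONT"))
  } else if (gate$branch == "parametric") {
    df <- table; df$group <- factor(df$group)
    tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
    tukey4 <- stats::setNames(tk[, "p adj"], rownames(tk))
    pair <- intersect(c("NAC30-CONT", "CONT-NAC30"), rownames(tk))
    nac30_p <- unname(tukey4[pair[1]])
  } else {
    nac30_p <- compare_two_groups(
      table[table$group %in% c("NAC30", "CONT"), ], "nonparametric",
      groups = c("NAC30", "CONT"))
  }
  final_p <- if (pooled) gnac_p else nac30_p
  structure(list(
    endpoint = if ("endpoint" %in% names(table)) table$endpoint[1] else NA,
    day = if ("day" %in% names(table)) table$day[1] else NA,
    branch = gate$branch, shapiro_p = gate$shapiro_p,
    omnibus_p = omni$p, tukey = if (pooled) omni$tukey else tukey4,
    pooled = pooled, gnac_vs_cont_p = gnac_p, nac30_vs_cont_p = nac30_p,
    rejected = is.finite(final_p) && final_p <= alpha, alpha = alpha
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison_result: %s day %s | %s branch\n",
              x$endpoint, x$day, x$branch))
  cat(sprintf("  omnibus p = %.4g -> %s\n", x$omnibus_p,
              if (x$pooled) "pooled (gNAC)" else "arms kept separate"))
  if (x$pooled) cat(sprintf("  gNAC vs CONT p = %.4g\n", x$gnac_vs_cont_p))
  else cat(sprintf("  NAC30 vs CONT p = %.4g\n", x$nac30_vs_cont_p))
  invisible(x)
}
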