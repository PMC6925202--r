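#' Compare measurement groups non-parametrically
#'
#' Two groups: two-tailed Mann-Whitney U (Wilcoxon rank-sum) test. Three or
#' more: Kruskal-Wallis omnibus test followed by pairwise Dunn tests with
#' Holm multiplicity correction (a parametric one-way ANOVA with Tukey HSD
#' is available as an alternative post-hoc route). Reports mean +/- SEM and
#' n per group and significance codes ns / * / ** / *** at 0.05 / 0.01 /
#' 0.001.
#'
#' @param values named list of numeric vectors, one per group; every group
#'   needs n >= 3.
#' @param design `"auto"` picks by the number of groups; `"two_group"` or
#'   `"multi_group"` force the corresponding test.
#' @param posthoc post-hoc for the multi-group design: `"dunn_holm"`
#'   (default, rank-based) or `"anova_tukey"` (parametric).
#' @return An object of class `group_comparison`: per-group summary
#'   (`mean`, `sem`, `n`), `test` name, `p_omnibus`, and a data frame
#'   `pairwise` with columns `group1, group2, statistic, p, code`.
#' @examples
#' compare_groups(list(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13)))
#' @export
compare_groups <- function(values,
                           design = c("auto", "two_group", "multi_group"),
                           posthoc = c("dunn_holm", "anova_tukey")) {
  design <- match.arg(design)
  posthoc <- match.arg(posthoc)
  if (!is.list(values) || length(values) < 2L) {
    stop("compare_groups: need a list of >= 2 groups")
  }
  if (is.null(names(values)) || any(names(values) == "")) {
    names(values) <- paste0("group", seq_along(values))
  }
  ns <- vapply(values, length, integer(1))
  if (any(ns < 3L)) {
    stop("compare_groups: every group needs n >= 3 (got n = ",
         paste(ns, collapse = ", "), ")")
  }
  if (design == "auto") {
    design <- if (length(values) == 2L) "two_group" else "multi_group"
  }
  summ <- data.frame(group = names(values),
                     mean = vapply(values, mean, numeric(1)),
                     sem = vapply(values, function(v) stats::sd(v) / sqrt(length(v)),
                                  numeric(1)),
                     n = ns, row.names = NULL)
  if (design == "two_group") {
    if (length(values) != 2L) stop("compare_groups: two_group design needs exactly 2 groups")
    wt <- suppressWarnings(stats::wilcox.test(values[[1]], values[[2]],
                                              alternative = "two.sided",
                                              exact = FALSE, correct = TRUE))
    pw <- data.frame(group1 = names(values)[1], group2 = names(values)[2],
                     statistic = unname(wt$statistic), p = wt$p.value,
                     code = signif_code(wt$p.value))
    res <- list(summary = summ, test = "Mann-Whitney U (two-tailed)",
                p_omnibus = wt$p.value, pairwise = pw)
  } else {
    kw <- stats::kruskal.test(values)
    pw <- if (posthoc == "dunn_holm") {
      dunn_pairwise(values)
    } else {
      tukey_pairwise(values)
    }
    pw$code <- signif_code(pw$p)
    res <- list(summary = summ,
                test = paste0("Kruskal-Wallis + ",
                              if (posthoc == "dunn_holm") "Dunn (Holm-adjusted)"
                              else "ANOVA Tukey HSD"),
                p_omnibus = kw$p.value, pairwise = pw)
  }
  class(res) <- "group_comparison"
  res
}

# Dunn's rank-based pairwise z tests with tie correction, Holm-adjusted.
dunn_pairwise <- function(values) {
  g <- rep(names(values), vapply(values, length, integer(1)))
  x <- unlist(values, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(names(values), 2)
  z <- p <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / sigma
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], statistic = z,
             p = pmin(1, stats::p.adjust(p, method = "holm")))
}

tukey_pairwise <- function(values) {
  g <- factor(rep(names(values), vapply(values, length, integer(1))),
              levels = names(values))
  x <- unlist(values, use.names = FALSE)
  tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(nm, `[`, character(1), 2),
             group2 = vapply(nm, `[`, character(1), 1),
             statistic = tk[, "diff"], p = tk[, "p adj"], row.names = NULL)
}

signif_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.4g +/- %.3g (n = %d)\n",
                s$group[i], s$mean[i], s$sem[i], s$n[i]))
  }
  cat(sprintf("  omnibus p = %.4g\n", x$p_omnibus))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: p = %.4g %s\n",
                pw$group1[i], pw$group2[i], pw$p[i], pw$code[i]))
  }
  invisible(x)
}
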