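#' Compare per-cell metrics between groups
#'
#' Group comparisons of a per-cell metric with the tests used for this
#' kind of data: unpaired two-sided t-test, Mann-Whitney (Wilcoxon rank
#' sum), Kruskal-Wallis, or one-way ANOVA followed by Dunnett's multiple
#' comparisons against a named reference group. Two-sample tests compare
#' either exactly two groups or every group against \code{reference}.
#' Summaries are means with sample (n-1) standard deviations.
#'
#' @param table data.frame with a \code{group} column and the metric
#'   column; at least 2 cells per compared group.
#' @param metric column name to compare (e.g. \code{"mdr_normalized"}).
#' @param test \code{"t"}, \code{"mannwhitney"}, \code{"kruskal"} or
#'   \code{"anova_dunnett"}.
#' @param reference reference group label (required for
#'   \code{anova_dunnett}; optional pivot for the two-sample tests).
#' @return data.frame, one row per comparison: group labels, per-group n,
#'   mean and sd, the test statistic and the two-sided P value (Dunnett
#'   P values are adjusted across the non-reference groups).
#' @export
compare_groups <- function(table, metric,
                           test = c("t", "mannwhitney", "kruskal", "anova_dunnett"),
                           reference = NULL) {
  test <- match.arg(test)
  if (!metric %in% names(table)) stop("unknown metric: ", metric, call. = FALSE)
  if (!"group" %in% names(table)) stop("table has no 'group' column", call. = FALSE)
  table <- table[is.finite(table[[metric]]), , drop = FALSE]
  groups <- unique(as.character(table$group))
  cnt <- table(as.character(table$group))
  if (any(cnt < 2)) {
    stop("every compared group needs at least 2 cells", call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% groups) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  x <- table[[metric]]
  g <- as.character(table$group)
  summ <- function(lab) {
    v <- x[g == lab]
    c(n = length(v), mean = mean(v), sd = sd(v))
  }
  pair_row <- function(g1, g2, stat, p, adj = FALSE) {
    s1 <- summ(g1); s2 <- summ(g2)
    data.frame(metric = metric, test = test, group1 = g1, group2 = g2,
               n1 = s1["n"], mean1 = s1["mean"], sd1 = s1["sd"],
               n2 = s2["n"], mean2 = s2["mean"], sd2 = s2["sd"],
               statistic = stat, p_value = p, adjusted = adj,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  if (test %in% c("t", "mannwhitney")) {
    pairs <- if (length(groups) == 2) {
      list(groups)
    } else if (!is.null(reference)) {
      lapply(setdiff(groups, reference), function(gg) c(reference, gg))
    } else {
      stop(test, " needs exactly 2 groups or a reference group", call. = FALSE)
    }
    out <- lapply(pairs, function(pr) {
      a <- x[g == pr[1]]; b <- x[g == pr[2]]
      ht <- if (test == "t") t.test(a, b, var.equal = FALSE)
            else wilcox.test(a, b, exact = FALSE, correct = TRUE)
      pair_row(pr[1], pr[2], unname(ht$statistic), ht$p.value)
    })
    return(do.call(rbind, out))
  }

  if (test == "kruskal") {
    ht <- kruskal.test(x, factor(g))
    s <- vapply(groups, summ, numeric(3))
    return(data.frame(metric = metric, test = test,
                      group1 = paste(groups, collapse = "|"), group2 = NA,
                      n1 = sum(s["n", ]), mean1 = NA, sd1 = NA,
                      n2 = NA, mean2 = NA, sd2 = NA,
                      statistic = unname(ht$statistic), p_value = ht$p.value,
                      adjusted = FALSE, stringsAsFactors = FALSE))
  }

  # anova_dunnett
  if (is.null(reference)) stop("anova_dunnett needs a reference group", call. = FALSE)
  d <- data.frame(y = x, group = stats::relevel(factor(g), ref = reference))
  fit <- aov(y ~ group, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  others <- setdiff(levels(d$group), reference)
  out <- lapply(seq_along(others), function(k) {
    pair_row(reference, others[k], unname(sm$test$tstat[k]),
             unname(sm$test$pvalues[k]), adj = TRUE)
  })
  do.call(rbind, out)
}

#' Per-group summary of a metrics table
#'
#' @param table metrics data.frame with a \code{group} column.
#' @param metrics metric column names to summarize.
#' @return data.frame: group, n, then mean/sd per metric.
#' @export
group_summary <- function(table,
                          metrics = c("mdr_normalized", "mdr_raw", "asymmetry")) {
  metrics <- intersect(metrics, names(table))
  groups <- unique(as.character(table$group))
  rows <- lapply(groups, function(gg) {
    sub <- table[table$group == gg, , drop = FALSE]
    row <- data.frame(group = gg, n = nrow(sub), stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_sd")]] <- sd(sub[[m]])
    }
    row
  })
  do.call(rbind, rows)
}

#' Write a tabular (and optionally graphical) report of a batch
#'
#' Writes \code{group_summary.csv} and \code{comparisons.csv} (the latter
#' only when comparisons are supplied) with deterministic names; with
#' \code{plots = TRUE} also a scatter-with-mean-and-sd panel per metric
#' (\code{plot_<metric>.pdf}).
#'
#' @param table metrics data.frame (nonempty, with \code{group}).
#' @param comparisons optional data.frame from \code{\link{compare_groups}}.
#' @param out_dir output directory (created if missing).
#' @param plots logical; draw per-metric panels.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(table, comparisons = NULL, out_dir, plots = FALSE) {
  if (nrow(table) == 0) stop("empty metrics table", call. = FALSE)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character()
  f <- file.path(out_dir, "group_summary.csv")
  write.csv(group_summary(table), f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    f <- file.path(out_dir, "comparisons.csv")
    write.csv(comparisons, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (plots) {
    for (m in intersect(c("mdr_normalized", "mdr_raw", "asymmetry"), names(table))) {
      f <- file.path(out_dir, paste0("plot_", m, ".pdf"))
      df <- data.frame(group = table$group, value = table[[m]])
      p <- ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
        ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                              linewidth = 0.4) +
        ggplot2::stat_summary(fun.data = function(v) {
          data.frame(y = mean(v), ymin = mean(v) - sd(v), ymax = mean(v) + sd(v))
        }, geom = "errorbar", width = 0.25) +
        ggplot2::labs(x = NULL, y = m) +
        ggplot2::theme_classic()
      ggplot2::ggsave(f, p, width = 4, height = 3.2)
      files <- c(files, f)
    }
  }
  invisible(files)
}

utils::globalVariables(c("group", "value"))
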