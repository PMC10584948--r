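#' Two-sample t test between groups
#'
#' Compares one metric between two groups of nuclei (or cells, or
#' traces). The default is the classic pooled-variance Student's t test;
#' Welch's unequal-variance variant is available, relevant when group
#' sizes differ.
#'
#' @param a,b Numeric sample vectors (each >= 2 finite values).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param metric Name of the compared quantity, carried into the result.
#' @return Object of class `group_comparison`: `metric`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value` (two-sided), `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `variant`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch"),
                         metric = "value") {
  variant <- match.arg(variant)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("samples must be finite")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0,
                  parameter = length(a) + length(b) - 2L,
                  p.value = 1)
    } else {
      stop("degenerate samples: zero variance in both groups with ",
           "unequal means")
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = (variant == "student"))
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter),
                p.value = ht$p.value)
  }
  structure(list(metric = metric,
                 t_statistic = res$statistic,
                 degrees_of_freedom = res$parameter,
                 p_value = res$p.value,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b),
                 variant = variant),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: t = %.4f (df = %.4g), p = %.4g [%s]\n",
    x$metric, x$t_statistic, x$degrees_of_freedom, x$p_value, x$variant))
  cat(sprintf("  group A: %.4g +/- %.4g (n = %d); group B: %.4g +/- %.4g (n = %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Thin pass-through for comparing three or more groups: standard
#' one-way analysis of variance followed by Tukey's honest significant
#' differences.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length, >= 3 levels.
#' @return List with `anova_p`, the `aov` fit, and the Tukey table.
#' @export
compare_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3L) {
    stop("need >= 3 groups; use two_sample_t() for two")
  }
  d <- data.frame(value = as.numeric(values), group = groups)
  fit <- stats::aov(value ~ group, data = d)
  structure(list(anova_p = summary(fit)[[1L]][["Pr(>F)"]][1L],
                 fit = fit,
                 tukey = stats::TukeyHSD(fit)$group),
            class = "anova_comparison")
}

#' Build a comparison report for a two-group experiment
#'
#' Runs [two_sample_t()] for each requested metric of a per-nucleus (or
#' per-cell) table, and assembles mean +/- s.d. summaries plus scatter
#' figures. Deterministic given its inputs.
#'
#' @param stats_table Data.frame with a group column plus metric columns
#'   (e.g. the `per_nucleus` table of [run_npc_pipeline()], or a
#'   [batch_nc()] table).
#' @param metrics Character vector of metric column names; default: the
#'   NPC panel columns present in the table.
#' @param group_col Name of the group column.
#' @param variant t-test variant, see [two_sample_t()].
#' @param make_figures Also build per-metric ggplot scatter figures.
#' @return List of class `comparison_report`: `comparisons` (data.frame
#'   metric / t / df / p_value / means / sds / ns), `summary`
#'   (data.frame of group means +/- s.d.), `figures` (named list of
#'   ggplot objects, possibly empty).
#' @export
build_report <- function(stats_table,
                         metrics = NULL,
                         group_col = "group",
                         variant = c("student", "welch"),
                         make_figures = FALSE) {
  variant <- match.arg(variant)
  if (!group_col %in% names(stats_table)) {
    stop("schema error: missing group column '", group_col, "'")
  }
  default_panel <- c("npc_density", "sml_density", "mean_sml_per_cluster",
                     "mean_diameter_nm", "nc_ratio", "half_time_s")
  if (is.null(metrics)) {
    metrics <- intersect(default_panel, names(stats_table))
  }
  missing <- setdiff(metrics, names(stats_table))
  if (length(missing)) {
    stop("schema error: missing metric column(s): ",
         paste(missing, collapse = ", "))
  }
  g <- factor(stats_table[[group_col]])
  if (nlevels(g) != 2L && length(metrics)) {
    stop("build_report() compares exactly two groups; got ", nlevels(g))
  }
  lv <- levels(g)

  comp_rows <- lapply(metrics, function(m) {
    v <- stats_table[[m]]
    ok <- is.finite(v)
    cmp <- two_sample_t(v[ok & g == lv[1L]], v[ok & g == lv[2L]],
                        variant = variant, metric = m)
    data.frame(metric = m, group_a = lv[1L], group_b = lv[2L],
               t_statistic = cmp$t_statistic,
               degrees_of_freedom = cmp$degrees_of_freedom,
               p_value = cmp$p_value,
               mean_a = cmp$mean_a, sd_a = cmp$sd_a, n_a = cmp$n_a,
               mean_b = cmp$mean_b, sd_b = cmp$sd_b, n_b = cmp$n_b)
  })
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows)
  else data.frame(metric = character(0), group_a = character(0),
                  group_b = character(0), t_statistic = numeric(0),
                  degrees_of_freedom = numeric(0), p_value = numeric(0),
                  mean_a = numeric(0), sd_a = numeric(0), n_a = integer(0),
                  mean_b = numeric(0), sd_b = numeric(0), n_b = integer(0))

  summary_rows <- lapply(metrics, function(m) {
    v <- stats_table[[m]]
    do.call(rbind, lapply(lv, function(l) {
      vi <- v[is.finite(v) & g == l]
      data.frame(metric = m, group = l, mean = mean(vi),
                 sd = stats::sd(vi), n = length(vi))
    }))
  })
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
  else data.frame(metric = character(0), group = character(0),
                  mean = numeric(0), sd = numeric(0), n = integer(0))

  figures <- list()
  if (make_figures && length(metrics)) {
    for (m in metrics) {
      d <- data.frame(group = g, value = stats_table[[m]])
      figures[[m]] <- ggplot2::ggplot(d,
        ggplot2::aes(x = .data$group, y = .data$value)) +
        ggplot2::geom_jitter(width = 0.1, height = 0) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar",
                              width = 0.3, linewidth = 0.3) +
        ggplot2::labs(x = NULL, y = m) +
        ggplot2::theme_classic()
    }
  }
  structure(list(comparisons = comparisons, summary = summary,
                 figures = figures),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  if (nrow(x$comparisons)) {
    print(x$comparisons[, c("metric", "t_statistic", "p_value")],
          row.names = FALSE, digits = 4L)
  } else {
    cat("  (no comparisons)\n")
  }
  invisible(x)
}

#' Write a comparison report to CSV (and optional figure files)
#'
#' @param report A `comparison_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  for (m in names(report$figures)) {
    ggplot2::ggsave(file.path(dir, paste0(m, ".pdf")),
                    report$figures[[m]], width = 3, height = 3)
  }
  invisible(dir)
}
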