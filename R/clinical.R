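# Reproduction of two-arm clinical comparison statistics from printed
# summary inputs: uncorrected Pearson chi-square on 2x2 tables, two-sample t
# from per-group (n, mean, sd) summaries, and percentage rate reports.

#' Construct a 2x2 events table from two groups
#'
#' @param a events in group 1.
#' @param n1 size of group 1.
#' @param c_ events in group 2.
#' @param n2 size of group 2.
#' @param labels group labels.
#' @param outcome optional outcome label.
#' @return A `two_by_two` list with cells `a`, `b = n1 - a`, `c`,
#'   `d = n2 - c`.
#' @export
two_by_two <- function(a, n1, c_, n2, labels = c("EG", "CG"), outcome = "") {
  vals <- c(a = a, n1 = n1, c = c_, n2 = n2)
  if (any(vals != round(vals))) stop("counts must be integers")
  if (a < 0 || c_ < 0 || a > n1 || c_ > n2)
    stop("event counts must lie within their group sizes")
  structure(list(a = a, b = n1 - a, c = c_, d = n2 - c_,
                 n1 = n1, n2 = n2, labels = labels, outcome = outcome),
            class = "two_by_two")
}

#' Uncorrected Pearson chi-square test on a 2x2 table
#'
#' Computes `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one degree
#' of freedom and an upper-tail p-value; no Yates continuity correction is
#' applied (the convention under which the published tables' statistics are
#' recovered exactly).
#'
#' @param table a [two_by_two()].
#' @return A `kg_test` list: `statistic`, `df`, `p_value`, `method`.
#' @examples
#' chisq_2x2(two_by_two(25, 80, 47, 80))  # statistic ~ 12.22
#' @export
chisq_2x2 <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0))
    stop("degenerate table: a margin is zero")
  N <- a + b + cc + d
  stat <- N * (a * d - b * cc)^2 / prod(margins)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "Pearson chi-square (no continuity correction)"),
            class = "kg_test")
}

#' Per-group summary (n, mean, sd)
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param label group label.
#' @return A `group_summary` list.
#' @export
group_summary <- function(n, mean, sd, label = "") {
  if (n < 2) stop("group size must be >= 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(n = n, mean = mean, sd = sd, label = label),
            class = "group_summary")
}

#' Two-sample t test from group summaries
#'
#' Pooled-variance (Student) t by default with `df = n1 + n2 - 2`; the Welch
#' variant is exposed for comparison (with equal group sizes the two
#' statistics coincide). Two-sided p-value.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param var `"pooled"` or `"welch"`.
#' @return A `kg_test` list: `statistic`, `df`, `p_value`, `method`.
#' @examples
#' t_from_summary(group_summary(80, 13.90, 2.37),
#'                group_summary(80, 13.423, 2.70))  # |t| ~ 1.19
#' @export
t_from_summary <- function(g1, g2, var = c("pooled", "welch")) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  var <- match.arg(var)
  diff <- g1$mean - g2$mean
  if (var == "pooled") {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2)
    if (sp2 == 0) {
      if (diff == 0)
        return(structure(list(statistic = 0, df = g1$n + g2$n - 2,
                              p_value = 1, method = "pooled two-sample t"),
                         class = "kg_test"))
      stop("zero pooled variance with unequal means: statistic undefined")
    }
    stat <- diff / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
    method <- "pooled two-sample t"
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    if (v1 + v2 == 0) {
      if (diff == 0)
        return(structure(list(statistic = 0, df = g1$n + g2$n - 2,
                              p_value = 1, method = "Welch two-sample t"),
                         class = "kg_test"))
      stop("zero variance with unequal means: statistic undefined")
    }
    stat <- diff / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
    method <- "Welch two-sample t"
  }
  structure(list(statistic = stat, df = df,
                 p_value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE),
                 method = method), class = "kg_test")
}

#' @export
print.kg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-group percentage rate report
#'
#' Percentages are computed with exact rational arithmetic
#' (`100 * events / size`) and rendered to two decimals.
#'
#' @param tables list of [two_by_two()] objects.
#' @return data.frame with `outcome`, `group`, `events`, `size`, `percent`
#'   (numeric) and `percent_label` (two-decimal string).
#' @export
rates_report <- function(tables) {
  if (inherits(tables, "two_by_two")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    if (tb$n1 == 0 || tb$n2 == 0) stop("zero group size")
    data.frame(outcome = tb$outcome,
               group = tb$labels,
               events = c(tb$a, tb$c),
               size = c(tb$n1, tb$n2),
               percent = 100 * c(tb$a / tb$n1, tb$c / tb$n2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent_label <- sprintf("%.2f%%", out$percent)
  rownames(out) <- NULL
  out
}

#' Read a clinical configuration YAML file
#'
#' The file holds printed trial tables: a `tables` list (each with `outcome`,
#' `eg_events`, `eg_n`, `cg_events`, `cg_n`) and a `summaries` list (each
#' with `measure` and per-group `n_patients`, `mean`, `sd`; note that a bare
#' `n` key would be read as a YAML 1.1 boolean).
#'
#' @param path path to the YAML file.
#' @return List with `tables` (list of [two_by_two()]) and `summaries` (list
#'   of pairs of [group_summary()]).
#' @export
read_clinical_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  tables <- lapply(cfg$tables, function(tb)
    two_by_two(tb$eg_events, tb$eg_n, tb$cg_events, tb$cg_n,
               labels = c("EG", "CG"), outcome = tb$outcome))
  summaries <- lapply(cfg$summaries, function(s)
    list(measure = s$measure,
         eg = group_summary(s$eg$n_patients, s$eg$mean, s$eg$sd, "EG"),
         cg = group_summary(s$cg$n_patients, s$cg$mean, s$cg$sd, "CG")))
  list(tables = tables, summaries = summaries)
}

#' Full clinical comparison report
#'
#' Runs the uncorrected chi-square test and the rate report on every 2x2
#' table and the pooled two-sample t on every summary pair.
#'
#' @param config as returned by [read_clinical_config()].
#' @return List with `chi_square` (data.frame), `rates` (data.frame),
#'   `t_tests` (data.frame).
#' @export
clinical_report <- function(config) {
  chi <- do.call(rbind, lapply(config$tables, function(tb) {
    ts <- chisq_2x2(tb)
    data.frame(outcome = tb$outcome, statistic = ts$statistic, df = ts$df,
               p_value = ts$p_value, stringsAsFactors = FALSE)
  }))
  tt <- do.call(rbind, lapply(config$summaries, function(s) {
    ts <- t_from_summary(s$eg, s$cg)
    data.frame(measure = s$measure, statistic = ts$statistic,
               abs_statistic = abs(ts$statistic), df = ts$df,
               p_value = ts$p_value, stringsAsFactors = FALSE)
  }))
  list(chi_square = chi, rates = rates_report(config$tables), t_tests = tt)
}
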