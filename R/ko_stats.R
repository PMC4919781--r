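## Knockout-efficiency statistics from FACS-style counts. KO efficiency
## is the raw GFP-negative percentage (no background subtraction, which
## matches the readout's definition); an optional background-corrected
## estimator is available because steric hindrance of reporter
## transcription can inflate the raw value by a few percent.

#' Knockout efficiency from FACS counts
#'
#' @param n_gfp_neg number of GFP-negative (knocked-out) cells.
#' @param n_total total cells analysed.
#' @param background optional background GFP-negative proportion of the
#'   unedited reporter line (e.g. 0.005). When given, the corrected
#'   estimator `100 * (raw - bg) / (1 - bg)` is returned instead of the
#'   raw percentage.
#' @return percentage in `[0, 100]`.
#' @examples
#' ko_efficiency(9820, 10000)  # 98.2
#' @export
ko_efficiency <- function(n_gfp_neg, n_total, background = NULL) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_gfp_neg < 0) || any(n_gfp_neg > n_total)) {
    stop("n_gfp_neg must lie in [0, n_total]", call. = FALSE)
  }
  raw <- 100 * n_gfp_neg / n_total
  if (is.null(background)) return(raw)
  if (background < 0 || background >= 1) {
    stop("background must lie in [0, 1)", call. = FALSE)
  }
  pmax(0, 100 * (raw / 100 - background) / (1 - background))
}

#' Mean and standard error of a group of percentages
#'
#' @param values numeric vector (length >= 1).
#' @return list with `mean`, `sem` (sample sd / sqrt(n); 0 with
#'   `sem_defined = FALSE` for a singleton), `n`, `sem_defined`.
#' @examples
#' summarize_group(c(75.50, 69.23, 50.47, 78.17))
#' @export
summarize_group <- function(values) {
  if (length(values) == 0L) stop("empty group", call. = FALSE)
  n <- length(values)
  if (n == 1L) {
    return(list(mean = values, sem = 0, n = 1L, sem_defined = FALSE))
  }
  list(mean = mean(values), sem = sd(values) / sqrt(n), n = n,
       sem_defined = TRUE)
}

#' Paired two-group comparison
#'
#' Two-sided paired Student's t-test or Wilcoxon signed-rank test, pairs
#' aligned by index (e.g. the same target site under 17 nt and 20 nt
#' guides). The Wilcoxon test uses the exact permutation null for
#' `n <= 25` pairs. Zero-variance differences (including `a == b`) are
#' reported as a degenerate result rather than a numeric statistic.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @param method `"paired_t"` or `"wilcoxon"`.
#' @return list with `method`, `statistic`, `p_value`, `n_pairs`,
#'   `mean_diff`, `degenerate`, `stars`.
#' @examples
#' paired_comparison(c(98, 99, 99, 99), c(71, 44, 60, 45),
#'                   method = "paired_t")
#' @export
paired_comparison <- function(a, b, method = c("paired_t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    return(list(method = method, statistic = NA_real_, p_value = NA_real_,
                n_pairs = n, mean_diff = mean(d), degenerate = TRUE,
                stars = ""))
  }
  if (method == "paired_t") {
    ht <- t.test(a, b, paired = TRUE)
  } else {
    ht <- wilcox.test(a, b, paired = TRUE, exact = n <= 25L)
  }
  p <- unname(ht$p.value)
  list(method = method, statistic = unname(ht$statistic), p_value = p,
       n_pairs = n, mean_diff = mean(d), degenerate = FALSE,
       stars = p_stars(p))
}

#' One-way ANOVA across more than two groups
#'
#' Thin wrapper around [stats::aov()] for comparing three or more
#' groups of replicate efficiencies.
#'
#' @param values numeric vector of measurements.
#' @param groups factor (or coercible) of group labels, same length.
#' @return list with `method`, `statistic` (F), `p_value`, `df`.
#' @export
anova_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3L) {
    stop("ANOVA is for more than two groups; use paired_comparison()",
         call. = FALSE)
  }
  fit <- summary(aov(values ~ groups))[[1L]]
  list(method = "anova", statistic = fit[["F value"]][1L],
       p_value = fit[["Pr(>F)"]][1L],
       df = c(fit[["Df"]][1L], fit[["Df"]][2L]))
}

#' Significance stars
#'
#' Conventional star notation: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, otherwise "ns".
#'
#' @param p p-value.
#' @return character.
#' @export
p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Summarise per-replicate KO counts by group
#'
#' @param counts data.frame with columns `cell_line`, `guide`, `class`,
#'   `replicate`, `n_total`, `n_gfp_neg` (the schema also serves
#'   antibody-staining readouts).
#' @param by columns to group by (default cell_line, guide, class).
#' @return data.frame with one row per group: mean KO percentage, SEM
#'   and n.
#' @export
summarize_ko_counts <- function(counts,
                                by = c("cell_line", "guide", "class")) {
  stopifnot(all(c(by, "n_total", "n_gfp_neg") %in% names(counts)))
  counts$ko_percent <- ko_efficiency(counts$n_gfp_neg, counts$n_total)
  key <- interaction(counts[by], drop = TRUE, sep = "|")
  rows <- lapply(levels(key), function(k) {
    sub <- counts[key == k, , drop = FALSE]
    sm <- summarize_group(sub$ko_percent)
    cbind(sub[1L, by, drop = FALSE],
          data.frame(mean = sm$mean, sem = sm$sem, n = sm$n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
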