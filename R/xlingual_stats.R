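#' Cross-language feature screening
#'
#' Each feature is tested per language for a group difference (AD vs. HC)
#' with a tie-corrected Kruskal-Wallis H-test (chi-squared statistic, 1
#' degree of freedom for two groups), reported raw and with a Bonferroni
#' adjustment, alongside a point-biserial correlation as a cross-language
#' comparable effect size.  Features significant (uncorrected p < alpha)
#' in *both* languages, excluding the task-specific subgroup, form the
#' "generalizable language" feature set.
#'
#' @name xlingual_stats
NULL

#' Kruskal-Wallis H-test for a two-group comparison
#'
#' Tie-corrected H statistic with a chi-squared (df = 1) p-value.
#' Missing values are dropped; every group must retain at least two
#' observations.  When all values are tied the test is degenerate and
#' `H = 0, p = 1` is returned.
#'
#' @param values numeric vector.
#' @param groups binary labels (two levels), same length as `values`.
#' @return named list with `H` and `p`.
#' @export
kruskal_wallis_h <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m number of tests (>= 1); defaults to the size of the full
#'   feature registry.
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni_adjust <- function(p, m = nrow(feature_registry())) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * m)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a continuous feature and the 0/1 group
#' indicator (AD = 1), so its sign matches the direction of the AD-HC
#' mean difference.
#'
#' @param values numeric vector.
#' @param groups binary labels.
#' @return correlation in `[-1, 1]`; `NA` with a warning for constant
#'   values.
#' @export
point_biserial <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- as01(groups[keep])
  if (length(unique(g)) < 2)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("constant feature; point-biserial correlation undefined")
    return(NA_real_)
  }
  stats::cor(values, g)
}

# normalize labels to 0/1 with AD (or 1/TRUE) as the positive class
as01 <- function(groups) {
  if (is.numeric(groups)) return(as.numeric(groups != 0))
  if (is.logical(groups)) return(as.numeric(groups))
  g <- toupper(as.character(groups))
  out <- ifelse(g %in% c("AD", "1", "TRUE", "POS", "POSITIVE"), 1,
                ifelse(g %in% c("HC", "0", "FALSE", "NEG", "NEGATIVE"), 0,
                       NA))
  if (anyNA(out)) stop("unrecognized group labels: ",
                       paste(unique(g[is.na(out)]), collapse = ", "))
  out
}

#' Per-language feature statistics table
#'
#' One row per feature: group means, point-biserial correlation,
#' Kruskal-Wallis H, raw and Bonferroni-adjusted p, and significance
#' flags.  Missing values are dropped per feature (pairwise deletion);
#' features with fewer than two usable values per group keep their row
#' with missing statistics and `insufficient = TRUE`.
#'
#' @param features data frame or matrix, subjects x features.
#' @param labels binary group labels (AD positive), one per subject.
#' @param language language tag recorded in the output.
#' @param registry feature registry (`feature`, `subgroup`); defaults to
#'   the packaged registry restricted to the supplied features.
#' @param m Bonferroni multiplier; defaults to the number of features
#'   tested per language in this table.
#' @param alpha significance level for the flags.
#' @return data frame with columns `feature`, `subgroup`, `language`,
#'   `r_pb`, `m_HC`, `m_AD`, `H`, `p`, `p_corr`,
#'   `significant_uncorrected`, `significant_corrected`, `insufficient`.
#' @export
build_stats_table <- function(features, labels, language,
                              registry = NULL, m = NULL, alpha = 0.05) {
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 1, nrow(features) == length(labels))
  g <- as01(labels)
  if (is.null(registry)) {
    registry <- feature_registry()
    registry <- registry[registry$feature %in% names(features), ]
    unknown <- setdiff(names(features), registry$feature)
    if (length(unknown))
      registry <- rbind(registry,
                        data.frame(feature = unknown, subgroup = "other"))
  }
  if (is.null(m)) m <- ncol(features)

  rows <- lapply(names(features), function(f) {
    v <- features[[f]]
    keep <- !is.na(v)
    ok <- sum(keep & g == 0) >= 2 && sum(keep & g == 1) >= 2
    constant <- ok && length(unique(v[keep])) == 1L
    if (ok && !constant) {
      kw <- kruskal_wallis_h(v, g)
      r <- suppressWarnings(point_biserial(v, g))
      data.frame(feature = f, language = language,
                 r_pb = r,
                 m_HC = mean(v[keep & g == 0]),
                 m_AD = mean(v[keep & g == 1]),
                 H = kw$H, p = kw$p,
                 p_corr = bonferroni_adjust(kw$p, m),
                 insufficient = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(feature = f, language = language, r_pb = NA_real_,
                 m_HC = if (ok) mean(v[keep & g == 0]) else NA_real_,
                 m_AD = if (ok) mean(v[keep & g == 1]) else NA_real_,
                 H = if (constant) 0 else NA_real_,
                 p = if (constant) 1 else NA_real_,
                 p_corr = if (constant) 1 else NA_real_,
                 insufficient = !ok, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$subgroup <- registry$subgroup[match(out$feature, registry$feature)]
  out$significant_uncorrected <- !is.na(out$p) & out$p < alpha
  out$significant_corrected <- !is.na(out$p_corr) & out$p_corr < alpha
  out[, c("feature", "subgroup", "language", "r_pb", "m_HC", "m_AD",
          "H", "p", "p_corr", "significant_uncorrected",
          "significant_corrected", "insufficient")]
}

#' Select generalizable language features
#'
#' A feature enters the generalizable set when its uncorrected
#' Kruskal-Wallis p-value is below `alpha` in both languages and it is not
#' task-specific.  The uncorrected p is used deliberately: requiring
#' agreement across two independent cohorts is itself the replication
#' filter.
#'
#' @param stats_en,stats_fr per-language tables from
#'   [build_stats_table()], over the same feature universe.
#' @param registry feature registry (`feature`, `subgroup`).
#' @param alpha significance level (strict inequality).
#' @return list with `selected` (character vector), `alpha`, and
#'   `excluded_task_count` (task features that met the significance rule
#'   but are excluded by subgroup).
#' @export
select_generalizable <- function(stats_en, stats_fr, registry,
                                 alpha = 0.05) {
  d1 <- setdiff(stats_en$feature, stats_fr$feature)
  d2 <- setdiff(stats_fr$feature, stats_en$feature)
  if (length(d1) || length(d2))
    stop("feature universes differ between languages; only in EN: [",
         paste(d1, collapse = ", "), "]; only in FR: [",
         paste(d2, collapse = ", "), "]", call. = FALSE)
  p_en <- stats_en$p[match(stats_en$feature, stats_en$feature)]
  names(p_en) <- stats_en$feature
  p_fr <- stats::setNames(stats_fr$p, stats_fr$feature)[names(p_en)]
  subgroup <- registry$subgroup[match(names(p_en), registry$feature)]

  sig_both <- !is.na(p_en) & !is.na(p_fr) & p_en < alpha & p_fr < alpha
  selected <- names(p_en)[sig_both & !is.na(subgroup) & subgroup != "task"]
  excluded_task <- sum(sig_both & !is.na(subgroup) & subgroup == "task")
  list(selected = selected, alpha = alpha,
       excluded_task_count = excluded_task)
}
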