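# Validation statistics: Dice overlap, Spearman rank correlation,
# Bonferroni-corrected group comparisons, longitudinal summaries.

#' Sorensen-Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical arrays of identical dimensions.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_grid(a, b, "masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged). Errors on constant
#' input, where the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Scalar in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  cor(x, y, method = "spearman")
}

#' Compare tumor categories against the tumor-free group
#'
#' Two-sample Student's t tests of each category against the baseline
#' category for each tissue-percentage column, flagged at a
#' Bonferroni-corrected significance level (default alpha = 0.0056).
#' Comparisons with degenerate (zero) variance are reported with an error
#' message while the others proceed.
#'
#' @param data data frame with a `category` column and one column per
#'   tissue percentage.
#' @param tissues character vector of tissue column names.
#' @param baseline category treated as tumor-free reference (default
#'   `"0"`).
#' @param alpha corrected significance level (default 0.0056).
#' @return Data frame with one row per (category, tissue): `t`, `df`,
#'   `p_value`, `significant`, `error`.
#' @export
group_compare <- function(data,
                          tissues = c("pct_lung", "pct_soft",
                                      "pct_intermediate"),
                          baseline = "0", alpha = 0.0056) {
  if (!"category" %in% names(data)) stop("data must have a 'category' column")
  cats <- setdiff(unique(as.character(data$category)), baseline)
  base <- data[as.character(data$category) == baseline, , drop = FALSE]
  if (nrow(base) < 2) stop("baseline category needs >= 2 observations")
  rows <- list()
  for (cat in cats) {
    grp <- data[as.character(data$category) == cat, , drop = FALSE]
    for (ts in tissues) {
      x <- base[[ts]]; y <- grp[[ts]]
      row <- data.frame(category = cat, tissue = ts, t = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        significant = NA, error = NA_character_,
                        stringsAsFactors = FALSE)
      if (length(y) < 2) {
        row$error <- "fewer than 2 observations"
      } else if (sd(x) == 0 && sd(y) == 0) {
        row$error <- "degenerate variance in both groups"
      } else {
        tt <- t.test(y, x)
        row$t <- unname(tt$statistic)
        row$df <- unname(tt$parameter)
        row$p_value <- tt$p.value
        row$significant <- tt$p.value < alpha
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Longitudinal change-from-baseline summary
#'
#' Adds absolute and relative lung-percentage change from each subject's
#' baseline timepoint, plus group means with standard errors. Subjects
#' lacking the baseline timepoint are skipped with a warning.
#'
#' @param data data frame with columns `subject`, `timepoint`,
#'   `pct_lung` and optionally `group`.
#' @param baseline_timepoint value of `timepoint` treated as baseline
#'   (default: the minimum present).
#' @return List with `per_scan` (input rows plus `change_abs`,
#'   `change_rel`) and `group_summary` (mean change +/- SEM per group and
#'   timepoint).
#' @export
longitudinal_summary <- function(data, baseline_timepoint = NULL) {
  need <- c("subject", "timepoint", "pct_lung")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(baseline_timepoint)) baseline_timepoint <- min(data$timepoint)
  if (!"group" %in% names(data)) data$group <- "all"
  base <- data[data$timepoint == baseline_timepoint, c("subject", "pct_lung")]
  names(base)[2] <- "baseline_pct_lung"
  skipped <- setdiff(unique(data$subject), base$subject)
  if (length(skipped)) {
    warning("subjects without baseline skipped: ",
            paste(skipped, collapse = ", "))
    data <- data[!data$subject %in% skipped, , drop = FALSE]
  }
  per <- merge(data, base, by = "subject", sort = FALSE)
  per$change_abs <- per$pct_lung - per$baseline_pct_lung
  per$change_rel <- 100 * per$change_abs / per$baseline_pct_lung
  post <- per[per$timepoint != baseline_timepoint, , drop = FALSE]
  if (nrow(post)) {
    agg <- stats::aggregate(cbind(change_abs, change_rel) ~ group + timepoint,
                     data = post, FUN = mean)
    sem <- stats::aggregate(cbind(change_abs, change_rel) ~ group + timepoint,
                     data = post,
                     FUN = function(x) sd(x) / sqrt(length(x)))
    names(agg)[3:4] <- c("mean_change_abs", "mean_change_rel")
    agg$sem_change_abs <- sem$change_abs
    agg$sem_change_rel <- sem$change_rel
  } else {
    agg <- data.frame(group = character(), timepoint = numeric(),
                      mean_change_abs = numeric(), mean_change_rel = numeric(),
                      sem_change_abs = numeric(), sem_change_rel = numeric())
  }
  list(per_scan = per, group_summary = agg)
}
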