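# Descriptive quantitative genetics of fruit-size traits: coefficient of
# variation, mid-parent value, heterosis rates, extreme-pool screening.

#' Coefficient of variation, percent
#'
#' `100 * sd / mean`. The SD is the sample SD (n-1 denominator) when
#' computed from raw values via [summarize_trait()]; here both moments are
#' supplied directly.
#'
#' @param mean trait mean (must be nonzero).
#' @param sd trait standard deviation.
#' @return CV in percent.
#' @export
#' @examples
#' cv_pct(10.50, 3.52) # 33.52 after 2-dp rounding
cv_pct <- function(mean, sd) {
  if (any(mean == 0)) stop("CV undefined for zero mean", call. = FALSE)
  100 * sd / mean
}

#' Mid-parent value
#'
#' @param p1_mean,p2_mean parental trait means.
#' @return `(p1_mean + p2_mean) / 2`.
#' @export
mid_parent_value <- function(p1_mean, p2_mean) (p1_mean + p2_mean) / 2

#' Mid-parent heterosis rate, percent
#'
#' Percent deviation of the F1 mean from the mid-parent value:
#' `100 * (f1_mean - v_mp) / v_mp`.
#'
#' @param f1_mean F1 population mean.
#' @param p1_mean,p2_mean parental trait means.
#' @return heterosis rate in percent.
#' @export
heterosis_rate <- function(f1_mean, p1_mean, p2_mean) {
  v_mp <- mid_parent_value(p1_mean, p2_mean)
  if (any(v_mp == 0)) stop("heterosis rate undefined for zero mid-parent value",
                           call. = FALSE)
  100 * (f1_mean - v_mp) / v_mp
}

#' Fruit shape index
#'
#' Ratio of fruit length to fruit diameter.
#'
#' @param length fruit length (mm).
#' @param diameter fruit diameter (mm); must be positive.
#' @return dimensionless shape index, vectorized.
#' @export
shape_index <- function(length, diameter) {
  if (any(!is.na(diameter) & diameter <= 0)) {
    stop("diameter must be positive", call. = FALSE)
  }
  length / diameter
}

#' Genetic-variation summary of one trait
#'
#' Computes the descriptive statistics of a trait table row: parental
#' means, mid-parent value, F1 mean/SD/range, coefficient of variation,
#' proportion of F1 lines exceeding the higher parent (`hh_pct`),
#' mid-parent heterosis rate (`rhm_pct`), and skewness / excess kurtosis.
#'
#' @param f1_values numeric vector of F1 trait values (>= 3).
#' @param p1_mean,p2_mean parental trait means.
#' @param trait trait label.
#' @param moment_type `type` passed to [e1071::skewness()] /
#'   [e1071::kurtosis()]; the default 1 gives the classical third-moment
#'   coefficient and excess kurtosis (normal = 0).
#' @return one-row data.frame (a `TraitSummary`).
#' @export
summarize_trait <- function(f1_values, p1_mean, p2_mean, trait = "trait",
                            moment_type = 1) {
  f1_values <- f1_values[!is.na(f1_values)]
  if (length(f1_values) < 3) stop("need at least 3 F1 values", call. = FALSE)
  m <- mean(f1_values)
  s <- stats::sd(f1_values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  data.frame(
    trait = trait,
    p1_mean = p1_mean, p2_mean = p2_mean,
    v_mp = mid_parent_value(p1_mean, p2_mean),
    f1_mean = m, f1_sd = s,
    f1_min = min(f1_values), f1_max = max(f1_values),
    cv_pct = cv_pct(m, s),
    hh_pct = 100 * mean(f1_values > max(p1_mean, p2_mean)),
    rhm_pct = heterosis_rate(m, p1_mean, p2_mean),
    kurtosis = e1071::kurtosis(f1_values, type = moment_type),
    skewness = e1071::skewness(f1_values, type = moment_type),
    stringsAsFactors = FALSE)
}

#' Trait-summary table over all fruit-size traits
#'
#' Applies [summarize_trait()] to each trait column shared by the F1 lines
#' and the two parent rows of a phenotype table (see [read_phenotypes()]).
#'
#' @param pheno phenotype data.frame with `role` column.
#' @param traits trait columns to summarize; default: all numeric columns.
#' @param digits report rounding (half-up); `NULL` for full precision.
#' @return data.frame with one row per trait.
#' @export
trait_summary_table <- function(pheno, traits = NULL, digits = 2) {
  f1 <- pheno[pheno$role == "F1", , drop = FALSE]
  pf <- pheno[pheno$role == "parent_f", , drop = FALSE]
  pm <- pheno[pheno$role == "parent_m", , drop = FALSE]
  if (nrow(pf) != 1 || nrow(pm) != 1) {
    stop("phenotype table must contain exactly one parent_f and one parent_m row",
         call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      c("line_id"))
  }
  out <- do.call(rbind, lapply(traits, function(tr) {
    summarize_trait(f1[[tr]], pf[[tr]], pm[[tr]], trait = tr)
  }))
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}

#' Screen extreme lines for pool construction
#'
#' Ranks F1 lines by single fruit weight (ties broken by line id) and
#' returns the `n` largest and `n` smallest as the large- and small-fruit
#' pools. Optionally, auxiliary traits (fruit length and diameter) act as
#' consistency filters: a line must also lie in the same tail of each
#' auxiliary trait within a slack quantile of `n/N + aux_slack` to qualify;
#' if fewer than `n` lines qualify the pool is filled with the next
#' best-ranked lines, with a warning.
#'
#' @param pheno phenotype data.frame (F1 rows are used).
#' @param n lines per pool.
#' @param weight_col main screening trait column.
#' @param aux_cols auxiliary trait columns.
#' @param aux_slack slack quantile for the auxiliary filter, or `NULL`
#'   (default) to disable it.
#' @return list with `large`, `small` (line ids) and `summary` (per pool
#'   and trait: min, max, mean, sd).
#' @export
screen_extremes <- function(pheno, n, weight_col = "single_fruit_weight_g",
                            aux_cols = c("fruit_length_mm", "fruit_diameter_mm"),
                            aux_slack = NULL) {
  f1 <- pheno[pheno$role == "F1", , drop = FALSE]
  if (nrow(f1) < 2 * n) stop("fewer than 2n lines available", call. = FALSE)
  aux_cols <- intersect(aux_cols, names(f1))
  pick <- function(sign) {  # sign = -1 for large tail, +1 for small tail
    ord <- order(sign * f1[[weight_col]], f1$line_id)
    if (is.null(aux_slack) || !length(aux_cols)) return(f1$line_id[ord][1:n])
    qcut <- n / nrow(f1) + aux_slack
    ok <- rep(TRUE, nrow(f1))
    for (ac in aux_cols) {
      qv <- rank(sign * f1[[ac]], ties.method = "first") / nrow(f1)
      ok <- ok & qv <= qcut
    }
    eligible <- f1$line_id[ord][ok[ord]]
    if (length(eligible) >= n) return(eligible[1:n])
    warning(sprintf("only %d lines pass the auxiliary screen; filling by rank",
                    length(eligible)))
    unique(c(eligible, f1$line_id[ord]))[1:n]
  }
  large <- pick(-1)
  small <- pick(+1)
  traits <- c(weight_col, aux_cols)
  summ <- do.call(rbind, lapply(c(large = "large", small = "small"),
                                function(p) {
    ids <- if (p == "large") large else small
    sub <- f1[f1$line_id %in% ids, , drop = FALSE]
    do.call(rbind, lapply(traits, function(tr) {
      data.frame(pool = p, trait = tr, min = min(sub[[tr]]),
                 max = max(sub[[tr]]), mean = mean(sub[[tr]]),
                 sd = stats::sd(sub[[tr]]), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  list(large = large, small = small, summary = summ)
}

#' Histogram counts for a trait (frequency-distribution analogue)
#'
#' Thin wrapper around [graphics::hist()] (no plotting) returning the bin
#' table; bin counts always sum to the number of non-missing values.
#'
#' @param values numeric trait values.
#' @param breaks passed to `hist()`.
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
trait_histogram <- function(values, breaks = "Sturges") {
  values <- values[!is.na(values)]
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  data.frame(lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1],
             count = h$counts)
}
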