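# EGTA calcium-switch analysis: per-replicate baseline normalisation of a
# (baseline, EGTA, washout) resistance triplet and the cross-platform
# statistical comparison. Normalisation makes 2D TEER (Ohm.cm^2), 3D Rb
# (Ohm) and ex vivo Ussing resistance (Ohm) comparable as dimensionless
# fractions of each replicate's own pre-treatment value.

switch_phases <- c("baseline", "egta", "washout")

#' Normalise a calcium-switch series to its own baseline
#'
#' Divides each replicate's EGTA-phase and washout-phase resistance by that
#' replicate's baseline, so the baseline value is exactly 1 and the other
#' phases are dimensionless fractions of it. Per-replicate normalisation is
#' what gives the reported phase means a non-zero spread while the baseline
#' is definitionally 1.
#'
#' @param series Data frame with columns `replicate_id`, `platform`,
#'   `baseline`, `egta`, `washout` (platform-native resistance units).
#' @return A tibble with the same columns, values divided by `baseline`.
#' @examples
#' normalize_switch(data.frame(
#'   replicate_id = "r1", platform = "2D",
#'   baseline = 50, egta = 41.5, washout = 34
#' ))
#' @export
normalize_switch <- function(series) {
  stopifnot(all(c("replicate_id", "platform", switch_phases) %in%
                  names(series)))
  if (any(!is.finite(series$baseline)) || any(series$baseline <= 0)) {
    stop("every `baseline` must be finite and > 0 to normalise", call. = FALSE)
  }
  series <- tibble::as_tibble(series)
  dplyr::mutate(
    series,
    egta = .data$egta / .data$baseline,
    washout = .data$washout / .data$baseline,
    baseline = 1
  )
}

#' Per-platform summary of normalised switch values
#'
#' @param normalized Output of [normalize_switch()].
#' @return A tibble `platform`, `phase` (ordered baseline/egta/washout),
#'   `n`, `mean`, `sd` (NA for a singleton platform), `sem`.
#' @export
platform_summary <- function(normalized) {
  stopifnot(all(c("platform", switch_phases) %in% names(normalized)))
  normalized |>
    tidyr::pivot_longer(dplyr::all_of(switch_phases),
                        names_to = "phase", values_to = "value") |>
    dplyr::mutate(phase = factor(.data$phase, levels = switch_phases)) |>
    dplyr::group_by(.data$platform, .data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() >= 2, stats::sd(.data$value), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n))
}

#' Classic fixed-effects one-way ANOVA
#'
#' Between/within mean-square F test across two or more groups, pooling
#' variances (the equal-variance flavour). The fully degenerate input --
#' every value identical in every group -- returns `F = 0, p = 1`.
#'
#' @param groups A list of numeric vectors, each of length >= 2.
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `method`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5 on (1, 4) df
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df1 <- nlevels(g) - 1L
  df2 <- length(value) - nlevels(g)
  if (stats::sd(value) == 0) {
    return(tibble::tibble(
      statistic = 0, df1 = df1, df2 = df2, p.value = 1,
      method = "One-way analysis of means (degenerate)"
    ))
  }
  fit <- stats::oneway.test(value ~ g, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(fit$statistic),
    df1 = unname(fit$parameter[["num df"]]),
    df2 = unname(fit$parameter[["denom df"]]),
    p.value = fit$p.value,
    method = fit$method
  )
}

#' Holm--Sidak step-down multiple-comparison adjustment
#'
#' Sorts the m raw p-values ascending, applies the Sidak correction with a
#' step-down exponent, `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces
#' monotonicity by a running maximum, caps at 1 and returns the adjusted
#' values in the original order. Adjusted values are always >= the raw ones.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' holm_sidak(c(0.01, 0.02, 0.2))
#' @export
holm_sidak <- function(p) {
  if (!is.numeric(p) || length(p) < 1) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj_sorted <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj_sorted <- pmin(cummax(adj_sorted), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Significance stars at the report thresholds
#'
#' Star conventions used in the significance tables: `*` p < 0.05,
#' `**` p < 0.005, `***` p < 0.001, `****` p < 0.0001, otherwise `ns`.
#'
#' @param p Numeric p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 5e-3 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient in \[-1, 1\], or `NA` (with a
#'   warning) if either input has zero variance.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Within-platform phase comparisons with Holm--Sidak correction
#'
#' For each platform with at least `min_replicates` complete series, runs a
#' one-way ANOVA across the three phases of the normalised values and the
#' family of pairwise Student t-tests, then adjusts the family with
#' [holm_sidak()]. The default family is the two comparisons drawn in
#' disruption/recovery reports (baseline vs EGTA, baseline vs washout);
#' `family = 3` adds EGTA vs washout. "Recovered" is operationalised as
#' non-significance of baseline vs washout at `alpha`.
#'
#' @param normalized Output of [normalize_switch()].
#' @param family 2 (default) or 3; size of the within-platform comparison
#'   family.
#' @param alpha Significance level (default 0.05).
#' @param min_replicates Minimum complete replicates per platform
#'   (default 3); platforms below it are skipped with a warning.
#' @return A tibble with one row per platform and comparison: `platform`,
#'   `comparison`, `statistic`, `df`, `p_raw`, `p_adj`, `stars`,
#'   `significant`, plus per-platform `anova_f`, `anova_p` and (on the
#'   baseline-vs-washout rows) `recovered`.
#' @export
compare_phases <- function(normalized, family = 2, alpha = 0.05,
                           min_replicates = 3) {
  stopifnot(family %in% c(2, 3))
  pairs <- list(
    c("baseline", "egta"),
    c("baseline", "washout")
  )
  if (family == 3) pairs <- c(pairs, list(c("egta", "washout")))

  platforms <- unique(normalized$platform)
  out <- purrr::map(platforms, function(pf) {
    d <- normalized[normalized$platform == pf, , drop = FALSE]
    if (nrow(d) < min_replicates ||
        any(!is.finite(unlist(d[switch_phases])))) {
      warning("platform `", pf, "` skipped: fewer than ", min_replicates,
              " complete replicates", call. = FALSE)
      return(NULL)
    }
    aov_res <- one_way_anova(lapply(switch_phases, function(ph) d[[ph]]))
    tests <- purrr::map(pairs, function(pr) {
      tt <- safe_t_test(d[[pr[[1]]]], d[[pr[[2]]]],
                        paired = FALSE, var.equal = TRUE)
      tibble::tibble(
        platform = pf,
        comparison = paste(pr, collapse = " vs "),
        statistic = unname(tt$statistic),
        df = unname(tt$parameter),
        p_raw = tt$p.value
      )
    }) |>
      dplyr::bind_rows()
    tests$p_adj <- holm_sidak(tests$p_raw)
    tests |>
      dplyr::mutate(
        stars = significance_stars(.data$p_adj),
        significant = .data$p_adj < alpha,
        anova_f = aov_res$statistic,
        anova_p = aov_res$p.value,
        recovered = ifelse(.data$comparison == "baseline vs washout",
                           .data$p_adj >= alpha, NA)
      )
  })
  dplyr::bind_rows(out)
}
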