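#' Non-zero-slope regression test
#'
#' Ordinary least-squares fit of `y` on `x` with a two-sided t-test of
#' slope = 0 — the trend-significance criterion used throughout the
#' analysis.
#'
#' @param x predictor (not constant).
#' @param y response.
#' @return An object of class `trend_fit` with `slope`, `intercept`,
#'   `r2`, `p_nonzero_slope` and `n`.
#' @export
nonzero_slope_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (var(x) == 0)
    stop("degenerate design: x is constant", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) NA_real_
       else sm$coefficients[2, 4]
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_nonzero_slope = p,
                 n = length(x)),
            class = "trend_fit")
}

#' Normality-gated group comparison
#'
#' Each group is tested for normality (Shapiro-Wilk at
#' `alpha_normality`); if every group passes, a one-way ANOVA is used,
#' otherwise a Kruskal-Wallis test. The normality decisions are recorded
#' so the branch taken is reproducible.
#'
#' @param groups named or unnamed list of numeric samples, each n >= 3.
#' @param alpha_normality significance level of the normality gate.
#' @return An object of class `group_comparison` with `test_used`
#'   (`"anova"` or `"kruskal_wallis"`), `statistic`, `p_value`,
#'   `group_ns` and `normality_p` per group.
#' @export
group_compare <- function(groups, alpha_normality = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 3))
    stop("insufficient data: every group needs n >= 3", call. = FALSE)
  norm_p <- vapply(groups, function(g) shapiro.test(g)$p.value, numeric(1))
  normal <- norm_p > alpha_normality
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), ns))
  if (all(normal)) {
    fit <- aov(values ~ fac)
    sm <- summary(fit)[[1]]
    stat <- sm$`F value`[1]
    p <- sm$`Pr(>F)`[1]
    test <- "anova"
  } else {
    kt <- kruskal.test(values, fac)
    stat <- unname(kt$statistic)
    p <- kt$p.value
    test <- "kruskal_wallis"
  }
  structure(list(test_used = test, statistic = stat, p_value = p,
                 group_ns = ns, normality_p = norm_p,
                 normal = normal, alpha_normality = alpha_normality),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.3g (groups n = %s)\n",
              x$test_used, x$statistic, x$p_value,
              paste(x$group_ns, collapse = ", ")))
  cat(sprintf("  normality gate (alpha = %g): %s\n", x$alpha_normality,
              paste(ifelse(x$normal, "normal", "non-normal"),
                    collapse = ", ")))
  invisible(x)
}

#' Exponential growth fit of projected areas
#'
#' Fits `A(t) = A0 * exp(k * t)` by nonlinear least squares initialised
#' from the log-linear OLS solution; `r2` is reported on the area scale.
#'
#' @param times acquisition times, days.
#' @param areas projected areas, um^2, strictly positive.
#' @return A list of class `growth_fit` with `A0`, `k`, `r2` and `n`.
#' @export
exponential_growth_fit <- function(times, areas) {
  stopifnot(length(times) == length(areas))
  if (length(times) < 3) stop("need >= 3 time points", call. = FALSE)
  if (any(areas <= 0))
    stop("areas must be strictly positive", call. = FALSE)
  init <- lm(log(areas) ~ times)
  fit <- nls(areas ~ A0 * exp(k * times),
             start = list(A0 = exp(unname(coef(init)[1])),
                          k = unname(coef(init)[2])),
             control = nls.control(maxiter = 200, warnOnly = TRUE))
  cf <- coef(fit)
  fitted_a <- predict(fit)
  sst <- sum((areas - mean(areas))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum((areas - fitted_a)^2) / sst))
        else 1
  structure(list(A0 = unname(cf["A0"]), k = unname(cf["k"]), r2 = r2,
                 n = length(times)),
            class = "growth_fit")
}

trend_or_na <- function(x, y) {
  if (length(x) < 3 || var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                p_nonzero_slope = NA_real_, n = length(x),
                note = "insufficient"))
  tf <- nonzero_slope_test(x, y)
  tf$note <- "ok"
  unclass(tf)
}

#' Assemble figure-style summary tables and fits
#'
#' Builds one tidy table per analysis: whole-spheroid, cytoplasmic,
#' nuclear and per-cell volume against stiffness; nuclei count against
#' spheroid volume; and, when marker measurements are supplied, each
#' marker against stiffness (linear) and against spheroid volume
#' (exponential). Fits with fewer than 3 points are marked insufficient
#' rather than fitted.
#'
#' @param morphometry data frame of [compute_morphometry()] rows.
#' @param markers optional data frame with columns `spheroid_id`,
#'   `marker_name`, `mean_intensity`, `stiffness_kPa`,
#'   `spheroid_volume_um3`.
#' @param out_dir optional directory; when given, each table is written
#'   as CSV and all fits as one JSON file.
#' @return A list with `tables` (named list of data frames) and `fits`
#'   (named list), invisibly when writing.
#' @export
assemble_report <- function(morphometry, markers = NULL, out_dir = NULL) {
  req <- c("spheroid_id", "stiffness_kPa", "spheroid_volume_um3",
           "nuclear_volume_um3", "cytoplasmic_volume_um3", "nuclei_count",
           "cell_volume_um3")
  miss <- setdiff(req, names(morphometry))
  if (length(miss))
    stop("morphometry input lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  tables <- list(
    volume_vs_stiffness =
      morphometry[, c("spheroid_id", "stiffness_kPa", "spheroid_volume_um3")],
    cytoplasmic_vs_stiffness =
      morphometry[, c("spheroid_id", "stiffness_kPa",
                      "cytoplasmic_volume_um3")],
    nuclear_vs_stiffness =
      morphometry[, c("spheroid_id", "stiffness_kPa", "nuclear_volume_um3")],
    cell_volume_vs_stiffness =
      morphometry[, c("spheroid_id", "stiffness_kPa", "cell_volume_um3")],
    count_vs_volume =
      morphometry[, c("spheroid_id", "spheroid_volume_um3", "nuclei_count")])

  fits <- list(
    volume_vs_stiffness =
      trend_or_na(morphometry$stiffness_kPa, morphometry$spheroid_volume_um3),
    cytoplasmic_vs_stiffness =
      trend_or_na(morphometry$stiffness_kPa,
                  morphometry$cytoplasmic_volume_um3),
    nuclear_vs_stiffness =
      trend_or_na(morphometry$stiffness_kPa, morphometry$nuclear_volume_um3),
    cell_volume_vs_stiffness =
      trend_or_na(morphometry$stiffness_kPa, morphometry$cell_volume_um3),
    count_vs_volume =
      trend_or_na(morphometry$spheroid_volume_um3, morphometry$nuclei_count))

  if (is.null(markers) || nrow(markers) == 0) {
    if (!is.null(markers))
      warning("marker table empty; marker analyses skipped")
  } else {
    mreq <- c("marker_name", "mean_intensity", "stiffness_kPa",
              "spheroid_volume_um3")
    mmiss <- setdiff(mreq, names(markers))
    if (length(mmiss))
      stop("marker input lacks column(s): ", paste(mmiss, collapse = ", "),
           call. = FALSE)
    for (mk in unique(markers$marker_name)) {
      sub <- markers[markers$marker_name == mk, ]
      tables[[paste0(mk, "_vs_stiffness")]] <-
        sub[, c("marker_name", "stiffness_kPa", "mean_intensity")]
      tables[[paste0(mk, "_vs_volume")]] <-
        sub[, c("marker_name", "spheroid_volume_um3", "mean_intensity")]
      fits[[paste0(mk, "_vs_stiffness")]] <-
        if (nrow(sub) >= 3)
          unclass(fit_expression_trend(sub, "stiffness", "linear", mk))
        else list(note = "insufficient", n = nrow(sub))
      fits[[paste0(mk, "_vs_volume")]] <-
        if (nrow(sub) >= 3 && all(sub$mean_intensity > 0))
          unclass(fit_expression_trend(sub, "volume", "exponential", mk))
        else list(note = "insufficient", n = nrow(sub))
    }
  }

  out <- list(tables = tables, fits = fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
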