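#' Adjusted Wald binomial confidence interval
#'
#' The adjusted Wald (Agresti-Coull) interval for a binomial proportion,
#' recommended when fewer than ~100 samples underlie the estimate: with
#' `z` the normal quantile for the chosen confidence,
#' `p~ = (x + z^2/2) / (n + z^2)` and half-width
#' `z * sqrt(p~ (1 - p~) / (n + z^2))`, clipped to `[0, 1]`. The point
#' estimate reported is the raw fraction `x / n`.
#'
#' @param successes number of successes (vectorised).
#' @param n number of trials.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return a data frame with columns `estimate`, `lower`, `upper`.
#' @examples
#' adjusted_wald_ci(12, 24)  # (0.5, 0.314, 0.686)
#' adjusted_wald_ci(0, 24)   # lower bound clipped at 0
#' @export
adjusted_wald_ci <- function(successes, n, confidence = 0.95) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
    stop("n must be a positive integer count", call. = FALSE)
  if (any(!is.finite(successes)) || any(successes < 0) ||
      any(successes != round(successes)))
    stop("successes must be a nonnegative integer count", call. = FALSE)
  if (any(successes > n))
    stop("successes cannot exceed n", call. = FALSE)
  if (!is.numeric(confidence) || length(confidence) != 1 ||
      confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
  z <- qnorm(1 - (1 - confidence) / 2)
  p_adj <- (successes + z^2 / 2) / (n + z^2)
  hw <- z * sqrt(p_adj * (1 - p_adj) / (n + z^2))
  data.frame(estimate = successes / n,
             lower = pmax(0, p_adj - hw),
             upper = pmin(1, p_adj + hw))
}

#' Per-condition growth fractions with adjusted Wald intervals
#'
#' Pools the wells of a plate-assay table within each group (replicate
#' plates of the same condition are totalled, as when several experiments
#' are combined) and reports the fraction of wells that grew together
#' with its adjusted Wald confidence interval.
#'
#' @param table a data frame of per-well records containing a logical
#'   column `grew` plus the grouping columns.
#' @param by character vector of grouping column names.
#' @param confidence confidence level, default 0.95.
#' @return a data frame with the grouping columns, `n_wells`, `n_grew`,
#'   `fraction`, `lower`, `upper`.
#' @export
growth_fraction_summary <- function(table, by = "condition",
                                    confidence = 0.95) {
  if (!is.data.frame(table) || !"grew" %in% names(table))
    stop("table must be a data frame with a logical 'grew' column",
         call. = FALSE)
  if (!all(by %in% names(table)))
    stop("grouping columns missing from table: ",
         paste(setdiff(by, names(table)), collapse = ", "), call. = FALSE)
  if (!is.logical(table$grew) || any(is.na(table$grew)))
    stop("'grew' must be logical without missing values", call. = FALSE)
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(groups, function(idx) {
    ci <- adjusted_wald_ci(sum(table$grew[idx]), length(idx), confidence)
    cbind(table[idx[1], by, drop = FALSE],
          data.frame(n_wells = length(idx), n_grew = sum(table$grew[idx]),
                     fraction = ci$estimate, lower = ci$lower,
                     upper = ci$upper))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Competition advantage from two-genotype counts
#'
#' For each well, the statistic `ln(producer count / non-producer count)`
#' is proportional to the difference in mean growth rate between the two
#' genotypes times the elapsed time, assuming equal inocula. Returns the
#' sample mean across wells and a two-sided confidence interval from the
#' one-sample Student t distribution with `k - 1` degrees of freedom.
#' Wells in which either genotype was not observed have an undefined
#' log-ratio; they are excluded and tallied.
#'
#' @param samples a data frame with numeric columns `producer_count` and
#'   `nonproducer_count` (one row per well) and optionally a
#'   `color_assignment` column recording which fluorophore marked the
#'   producer.
#' @param confidence confidence level, default 0.95.
#' @return an object of class `competition_advantage`: a list with
#'   `mean_log_ratio`, `ci_lower`, `ci_upper`, `n_wells_used`,
#'   `n_excluded`, `df`, and (when present) the per-color well counts.
#' @examples
#' wells <- data.frame(producer_count = c(2000, 1990, 2050),
#'                     nonproducer_count = c(1000, 1010, 980))
#' competition_advantage(wells)
#' @export
competition_advantage <- function(samples, confidence = 0.95) {
  need <- c("producer_count", "nonproducer_count")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("samples must be a data frame with producer_count and ",
         "nonproducer_count columns", call. = FALSE)
  p <- samples$producer_count
  q <- samples$nonproducer_count
  if (any(!is.finite(p)) || any(!is.finite(q)) || any(p < 0) || any(q < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  usable <- p > 0 & q > 0
  k <- sum(usable)
  if (k < 2)
    stop("fewer than 2 wells with both genotypes observed; ",
         "cannot form a t interval", call. = FALSE)
  lr <- log(p[usable] / q[usable])
  m <- mean(lr)
  s <- sd(lr)
  hw <- qt(1 - (1 - confidence) / 2, df = k - 1) * s / sqrt(k)
  colors <- NULL
  if ("color_assignment" %in% names(samples))
    colors <- table(samples$color_assignment[usable])
  structure(list(mean_log_ratio = m, ci_lower = m - hw, ci_upper = m + hw,
                 n_wells_used = k, n_excluded = sum(!usable), df = k - 1,
                 confidence = confidence, color_balance = colors),
            class = "competition_advantage")
}

#' @export
print.competition_advantage <- function(x, ...) {
  cat(sprintf("Competition log-ratio ln(producer/non-producer): %.4f\n",
              x$mean_log_ratio))
  cat(sprintf("  %g%% CI (t, df = %d): [%.4f, %.4f]\n",
              100 * x$confidence, x$df, x$ci_lower, x$ci_upper))
  cat(sprintf("  wells used: %d, excluded (zero count): %d\n",
              x$n_wells_used, x$n_excluded))
  if (!is.null(x$color_balance)) {
    cat("  color balance: ")
    print(x$color_balance)
  }
  invisible(x)
}

#' OD-to-cell-count calibration curve
#'
#' A monotone standard curve mapping OD595 readings to cell densities,
#' measured from dilutions of a culture of known density. Clumpy
#' cultures are counted as particles, so their cell number is recovered
#' by multiplying counts by the average clump size (`clump_multiplier`,
#' default 6.4). Separate calibration objects should be made for single
#' cells and for clumps.
#'
#' @param od OD595 values of the standard curve (increasing).
#' @param cells_per_ml matching cell densities (increasing).
#' @param clump_multiplier average cells per clump-counted particle.
#' @return an object of class `od_calibration`.
#' @export
od_calibration <- function(od, cells_per_ml, clump_multiplier = 6.4) {
  if (length(od) != length(cells_per_ml) || length(od) < 2)
    stop("od and cells_per_ml must have equal length >= 2", call. = FALSE)
  if (is.unsorted(od, strictly = TRUE) ||
      is.unsorted(cells_per_ml, strictly = TRUE))
    stop("calibration curve must be strictly increasing", call. = FALSE)
  if (!is.numeric(clump_multiplier) || clump_multiplier <= 0)
    stop("clump_multiplier must be positive", call. = FALSE)
  structure(list(od = od, cells_per_ml = cells_per_ml,
                 clump_multiplier = clump_multiplier),
            class = "od_calibration")
}

#' Convert OD readings to cell densities
#'
#' Monotone piecewise-linear interpolation on an [od_calibration()]
#' standard curve; readings outside the calibrated range are linearly
#' extrapolated from the nearest segment with a warning.
#'
#' @param od_values OD595 readings.
#' @param calibration an [od_calibration()] object.
#' @param clumpy if `TRUE`, multiply by the calibration's clump
#'   multiplier to convert particle-equivalents to cells.
#' @return cells per ml, same length as `od_values`.
#' @examples
#' cal <- od_calibration(c(0.05, 0.2, 0.6), c(1e6, 5e6, 2e7))
#' od_to_cells(0.2, cal)                    # knot reproduced exactly
#' od_to_cells(0.2, cal, clumpy = TRUE)     # x 6.4
#' @export
od_to_cells <- function(od_values, calibration, clumpy = FALSE) {
  stopifnot(inherits(calibration, "od_calibration"))
  check_nonneg(od_values, "od_values")
  rng <- range(calibration$od)
  if (any(od_values < rng[1] | od_values > rng[2]))
    warning("OD value(s) outside the calibrated range [",
            rng[1], ", ", rng[2], "]; extrapolating", call. = FALSE)
  # linear interpolation; extrapolate with the end segments' slopes
  n <- length(calibration$od)
  slope_lo <- diff(calibration$cells_per_ml[1:2]) / diff(calibration$od[1:2])
  slope_hi <- diff(calibration$cells_per_ml[(n - 1):n]) /
    diff(calibration$od[(n - 1):n])
  y <- approx(calibration$od, calibration$cells_per_ml, xout = od_values,
              rule = 2)$y
  below <- od_values < rng[1]
  above <- od_values > rng[2]
  y[below] <- calibration$cells_per_ml[1] +
    slope_lo * (od_values[below] - rng[1])
  y[above] <- calibration$cells_per_ml[n] +
    slope_hi * (od_values[above] - rng[2])
  if (clumpy) y <- y * calibration$clump_multiplier
  y
}
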