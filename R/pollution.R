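#' Residual-film coverage rate of a mask
#'
#' The pollution index: the percentage of frame pixels labelled film,
#' `L = 100 * n_film / (M * N)`, computed with exact integer counts before
#' the final division.
#'
#' @param mask a [binary_mask()] (or `{0, 1}` matrix).
#' @param source_id identifier carried into reports.
#' @return An object of class `coverage_record` with `source_id`, `L_pct`,
#'   `n_film_pixels`, `n_total_pixels`.
#' @export
coverage_rate <- function(mask, source_id = "") {
  lab <- mask_labels(mask)
  n_total <- length(lab)
  if (n_total == 0) stop_input("cannot compute coverage of an empty mask")
  n_film <- sum(lab)
  structure(
    list(source_id = source_id, L_pct = 100 * n_film / n_total,
         n_film_pixels = as.integer(n_film), n_total_pixels = n_total),
    class = "coverage_record"
  )
}

#' @export
print.coverage_record <- function(x, ...) {
  cat(sprintf("<coverage '%s': %.4f%% (%d / %d px)>\n", x$source_id,
              x$L_pct, x$n_film_pixels, x$n_total_pixels))
  invisible(x)
}

#' Regression validation of predicted vs. true coverage rates
#'
#' Validates predicted coverage rates L1 against true rates L2 with three
#' indices: a prediction R-squared
#' `1 - sum((L2 - L1)^2) / sum((L2 - mean(L2))^2)` computed on the raw
#' residuals of prediction (it can be negative for poor predictors — it is
#' not the R-squared of a fitted line); `RMSE = sqrt(mean((L1 - L2)^2))`;
#' and the mean relative error `MRE = mean(|L1 - L2| / L2) * 100`, averaged
#' over pairs with `L2 > 0` (zero-truth pairs are excluded with a warning
#' and reported, rather than poisoning the batch).  The slope and intercept
#' of an ordinary least-squares fit of L1 on L2 are reported alongside.
#'
#' @param pred numeric vector of predicted coverage rates (percent).
#' @param truth numeric vector of true coverage rates (percent).
#' @return An object of class `regression_report` with `n`, `r_squared`,
#'   `rmse`, `mre_pct`, `slope`, `intercept`, `n_excluded_zero_truth`.
#' @export
regression_eval <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_input("pred and truth must have equal length")
  }
  n <- length(pred)
  if (n < 2) stop_input("need at least 2 coverage pairs")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    stop_input("R-squared undefined: all true coverage values are identical")
  }
  r_squared <- 1 - sum((truth - pred)^2) / ss_tot
  rmse <- sqrt(mean((pred - truth)^2))
  pos <- truth > 0
  n_excl <- sum(!pos)
  if (n_excl == n) stop_input("MRE undefined: all true coverage values are zero")
  if (n_excl > 0) {
    warning(sprintf("%d pair(s) with zero true coverage excluded from MRE",
                    n_excl), call. = FALSE)
  }
  mre_pct <- mean(abs(pred - truth)[pos] / truth[pos]) * 100
  fit <- lm(pred ~ truth)
  structure(
    list(n = n, r_squared = r_squared, rmse = rmse, mre_pct = mre_pct,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_excluded_zero_truth = n_excl),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression n=%d: R2=%.4f RMSE=%.4f MRE=%.2f%% fit: y=%.4fx%+.4f>\n",
    x$n, x$r_squared, x$rmse, x$mre_pct, x$slope, x$intercept))
  invisible(x)
}

#' Full pollution report for a set of images
#'
#' Predicts a film mask for every image, computes its coverage rate, and —
#' when ground-truth masks are available — validates predicted against true
#' coverage with [regression_eval()].  Optional strictly increasing coverage
#' thresholds map each L to a pollution-degree label (no canonical class
#' boundaries exist, so degrees are user-configurable).
#'
#' @param object a fitted model ([train_model()] result or
#'   `modified_unet`), or `NULL` when `predictions` are supplied directly.
#' @param pairs list of pairs (lists with `image` and optionally `mask`,
#'   `id`).
#' @param predictions optional list of predicted masks overriding the model.
#' @param thresholds optional strictly increasing numeric vector of coverage
#'   boundaries (percent).
#' @param degree_labels labels for the `length(thresholds) + 1` degree bins.
#' @return An object of class `pollution_report`: list with `coverage`
#'   (data.frame), `regression` (a [regression_eval()] report or `NULL`),
#'   and the thresholds used.
#' @export
pollution_report <- function(object, pairs, predictions = NULL,
                             thresholds = NULL, degree_labels = NULL) {
  if (!is.null(thresholds)) {
    if (length(thresholds) > 1 && any(diff(thresholds) <= 0)) {
      stop_input("pollution-degree thresholds must be strictly increasing")
    }
    if (is.null(degree_labels)) {
      degree_labels <- paste("degree", seq_len(length(thresholds) + 1))
    }
  }
  if (is.null(predictions)) {
    if (is.null(object)) stop_input("need a model or explicit predictions")
    predictions <- lapply(pairs, function(p) predict_mask(object, p$image))
  }
  ids <- vapply(seq_along(pairs), function(i) {
    pairs[[i]]$id %||% pairs[[i]]$image$source_id %||% sprintf("image_%03d", i)
  }, character(1))
  recs <- lapply(seq_along(predictions), function(i) {
    coverage_rate(predictions[[i]], source_id = ids[i])
  })
  coverage <- data.frame(
    source_id = ids,
    L_pct = vapply(recs, `[[`, numeric(1), "L_pct"),
    n_film_pixels = vapply(recs, `[[`, numeric(1), "n_film_pixels"),
    n_total_pixels = vapply(recs, `[[`, numeric(1), "n_total_pixels"),
    stringsAsFactors = FALSE
  )
  if (!is.null(thresholds)) {
    coverage$degree <- degree_labels[findInterval(coverage$L_pct, thresholds) + 1L]
  }
  regression <- NULL
  have_truth <- all(vapply(pairs, function(p) !is.null(p$mask), logical(1)))
  if (length(pairs) >= 2 && have_truth) {
    truth_l <- vapply(pairs, function(p) coverage_rate(p$mask)$L_pct, numeric(1))
    regression <- regression_eval(coverage$L_pct, truth_l)
  }
  structure(list(coverage = coverage, regression = regression,
                 thresholds = thresholds),
            class = "pollution_report")
}

#' @export
print.pollution_report <- function(x, ...) {
  cat(sprintf("<pollution_report %d image(s), mean L=%.3f%%>\n",
              nrow(x$coverage), mean(x$coverage$L_pct)))
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}
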