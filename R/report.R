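#' Run the cohort association battery
#'
#' The fixed battery relating cervical biometry to demographics and birth
#' outcomes:
#' \itemize{
#'   \item linear models of total, stroma and canal volume, os diameters
#'     and utero-cervical angle on cervical length (when a
#'     `length_2pt_mm` column is present);
#'   \item a linear model of stroma volume on maternal age;
#'   \item a logistic model of caesarean section on total cervical volume,
#'     controlling for maternal age and ethnicity;
#'   \item a logistic model of induction of labour on external os diameter,
#'     corrected for gestational age at scan.
#' }
#' Each row reports the focal term only. Raw p-values are reported (no
#' multiple-testing correction, matching common practice for exploratory
#' cohort batteries); an optional Benjamini-Hochberg column can be added.
#'
#' @param cohort data frame with at least the columns `age`, `ethnicity`,
#'   `ga_weeks`, `stroma_vol_cm3`, `total_vol_cm3`, `ext_os_diam_mm`,
#'   `caesarean`, `induced`; optional `length_2pt_mm`, `canal_vol_cm3`,
#'   `int_os_diam_mm`, `uca_deg` extend the battery.
#' @param adjust add a Benjamini-Hochberg adjusted p-value column
#'   (default `FALSE`).
#' @param filter_outliers apply the 1.5 x IQR response filter in the linear
#'   models (default `TRUE`).
#' @return Object of class `association_report`: `table` (one row per test:
#'   `response`, `term`, `type`, `estimate`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `n_used`, `outliers_removed`) and `fits`.
#' @export
association_report <- function(cohort, adjust = FALSE,
                               filter_outliers = TRUE) {
  required <- c("age", "ethnicity", "ga_weeks", "stroma_vol_cm3",
                "total_vol_cm3", "ext_os_diam_mm", "caesarean", "induced")
  miss <- setdiff(required, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))

  rows <- list(); fits <- list()
  push_linear <- function(response, predictor, label) {
    f <- fit_linear(cohort[[response]],
                    stats::setNames(cohort[predictor], predictor),
                    filter_outliers = filter_outliers)
    tr <- f$terms[f$terms$term == predictor, ]
    rows[[length(rows) + 1]] <<- data.frame(
      response = response, term = predictor, type = "linear",
      estimate = tr$estimate, odds_ratio = NA_real_,
      ci_low = tr$ci_low, ci_high = tr$ci_high, p_value = tr$p_value,
      n_used = f$n_used, outliers_removed = f$outliers_removed,
      stringsAsFactors = FALSE)
    fits[[label]] <<- f
  }
  push_logistic <- function(response, covars, focal, label) {
    f <- fit_logistic(cohort[[response]], cohort[covars])
    tr <- f$terms[f$terms$term == focal, ]
    rows[[length(rows) + 1]] <<- data.frame(
      response = response, term = focal, type = "logistic",
      estimate = tr$estimate, odds_ratio = tr$odds_ratio,
      ci_low = tr$ci_low, ci_high = tr$ci_high, p_value = tr$p_value,
      n_used = f$n_used, outliers_removed = 0L,
      stringsAsFactors = FALSE)
    fits[[label]] <<- f
  }

  if ("length_2pt_mm" %in% names(cohort)) {
    for (resp in intersect(c("total_vol_cm3", "stroma_vol_cm3",
                             "canal_vol_cm3", "int_os_diam_mm",
                             "ext_os_diam_mm", "uca_deg"), names(cohort)))
      push_linear(resp, "length_2pt_mm", paste0(resp, "~length"))
  }
  push_linear("stroma_vol_cm3", "age", "stroma~age")
  push_logistic("caesarean", c("total_vol_cm3", "age", "ethnicity"),
                "total_vol_cm3", "caesarean~volume")
  push_logistic("induced", c("ext_os_diam_mm", "ga_weeks"),
                "ext_os_diam_mm", "induction~ext_os")

  tab <- do.call(rbind, rows)
  if (adjust) tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  structure(list(table = tab, fits = fits, n = nrow(cohort)),
            class = "association_report")
}

#' @export
print.association_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cervical biometry association battery (n = %d, %d tests)\n",
              x$n, nrow(x$table)))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$odds_ratio <- signif(tab$odds_ratio, digits)
  tab$ci_low <- signif(tab$ci_low, digits)
  tab$ci_high <- signif(tab$ci_high, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Forest plot of the battery's odds ratios
#'
#' Draws the logistic rows of an [association_report()] as a forest plot
#' (point estimate and confidence interval per test on a log-OR axis),
#' mirroring the standard cohort-study presentation of birth-outcome odds
#' ratios.
#'
#' @param x an `association_report`.
#' @param file optional path; when given, an SVG is written there.
#' @param ... unused.
#' @return The plotted subset of the table, invisibly.
#' @export
plot.association_report <- function(x, file = NULL, ...) {
  tab <- x$table[x$table$type == "logistic", , drop = FALSE]
  if (!nrow(tab)) stop("no logistic rows to plot")
  if (!is.null(file)) {
    grDevices::svg(file, width = 7, height = 1 + nrow(tab) * 0.8)
    on.exit(grDevices::dev.off())
  }
  lab <- paste(tab$response, "~", tab$term)
  yy <- rev(seq_len(nrow(tab)))
  xlim <- range(c(tab$ci_low, tab$ci_high, 1), na.rm = TRUE)
  graphics::par(mar = c(4, 12, 2, 2))
  graphics::plot(tab$odds_ratio, yy, log = "x", xlim = xlim,
                 ylim = c(0.5, nrow(tab) + 0.5), pch = 15,
                 xlab = "Odds ratio (log scale)", ylab = "", yaxt = "n",
                 main = "Birth-outcome odds ratios")
  graphics::segments(tab$ci_low, yy, tab$ci_high, yy)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = yy, labels = lab, las = 1, cex.axis = 0.8)
  invisible(tab)
}

#' Write an association report to CSV and JSON
#'
#' @param report an [association_report()].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return Invisibly, the report table.
#' @export
write_association_report <- function(report, csv_path = NULL,
                                     json_path = NULL) {
  stopifnot(inherits(report, "association_report"))
  if (!is.null(csv_path))
    write.csv(report$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$table, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report$table)
}
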