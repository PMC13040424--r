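#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Shapiro-Wilk test with the battery's
#' preconditions made explicit: sample size between 3 and 5000 and
#' non-constant input.
#'
#' @param values numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (diff(range(values)) == 0)
    stop("Shapiro-Wilk undefined for constant input")
  st <- shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' 1.5 x IQR outlier filter
#'
#' Removes values below `Q1 - k * IQR` or above `Q3 + k * IQR`, with
#' quartiles by linear interpolation (quantile type 7). The battery applies
#' the filter once per response variable, before model fitting.
#'
#' @param values numeric vector, length >= 4.
#' @param k fence multiplier (default 1.5).
#' @return List with `kept` (values inside the fences), `removed_indices`
#'   (positions in the input), and `fences` `c(lower, upper)`.
#' @export
iqr_outlier_filter <- function(values, k = 1.5) {
  if (length(values) < 4)
    stop("IQR filter requires n >= 4 (got ", length(values), ")")
  q <- quantile(values, c(0.25, 0.75), type = 7, na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  out <- which(values < fences[1] | values > fences[2])
  list(kept = if (length(out)) values[-out] else values,
       removed_indices = out, fences = fences)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' mean-squares decomposition of a complete subjects x raters matrix, with
#' the standard F-based 95% confidence interval (McGraw & Wong case A,1).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; no
#'   missing cells.
#' @param conf confidence level (default 0.95).
#' @return Object of class `icc_result`: `coefficient`, `ci_low`,
#'   `ci_high`, `model`, `n_subjects`, `n_raters`, and the mean squares.
#' @export
icc <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ICC requires a complete matrix (no missing cells)")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("ICC requires >= 2 subjects and >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  coefficient <- if (abs(denom) < 1e-300) 1 else (msr - mse) / denom

  alpha <- 1 - conf
  if (mse <= 0 && msc <= 0 && msr > 0) {
    ci <- c(1, 1)  # perfect agreement, degenerate F
  } else {
    r <- coefficient
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(coefficient, coefficient)
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      if (!is.finite(v) || v <= 0) {
        ci <- c(coefficient, coefficient)
      } else {
        fl <- qf(1 - alpha / 2, n - 1, v)
        fu <- qf(1 - alpha / 2, v, n - 1)
        lower <- n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
        upper <- n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
        ci <- c(lower, upper)
      }
      if (anyNA(ci) || any(!is.finite(ci)))
        ci <- c(coefficient, coefficient)
    }
  }
  ci[1] <- min(ci[1], coefficient)
  ci[2] <- max(ci[2], coefficient)
  structure(list(coefficient = coefficient, ci_low = ci[1], ci_high = ci[2],
                 model = "two-way random, absolute agreement, single rater",
                 n_subjects = n, n_raters = k,
                 ms = c(msr = msr, msc = msc, mse = mse), conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f, %d%% CI [%.3f, %.3f] (%d subjects x %d raters)\n",
              x$coefficient, round(x$conf * 100), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  cat("  model:", x$model, "\n")
  invisible(x)
}

# shared machinery: assemble a model frame, check completeness
.glm_frame <- function(y, covariates, yname) {
  covariates <- as.data.frame(covariates)
  if (!nrow(covariates)) stop("no covariates supplied")
  if (length(y) != nrow(covariates))
    stop("response and covariates have different lengths")
  df <- cbind(stats::setNames(data.frame(y), yname), covariates)
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Ordinary least squares with the battery's outlier handling
#'
#' Linear (Gaussian-identity) regression of `y` on the covariates with
#' Wald t-based p-values and confidence intervals. Per the battery's
#' protocol, the 1.5 x IQR outlier filter is applied to the response before
#' fitting.
#'
#' @param y numeric response.
#' @param covariates data frame (or named list) of covariates.
#' @param filter_outliers apply [iqr_outlier_filter()] to `y` first
#'   (default `TRUE`).
#' @param conf confidence level.
#' @return Object of class `cerv_glm` (family `"gaussian"`): per-term
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, plus `n_used`,
#'   `outliers_removed`, `n_missing`.
#' @export
fit_linear <- function(y, covariates, filter_outliers = TRUE, conf = 0.95) {
  covariates <- as.data.frame(covariates)
  n_input <- length(y)
  keep <- seq_len(n_input)
  removed <- 0L
  if (filter_outliers && n_input >= 4) {
    fl <- iqr_outlier_filter(y)
    if (length(fl$removed_indices)) {
      keep <- setdiff(keep, fl$removed_indices)
      removed <- length(fl$removed_indices)
    }
  }
  df <- .glm_frame(y[keep], covariates[keep, , drop = FALSE], ".y")
  n_missing <- n_input - removed - nrow(df)
  terms <- setdiff(names(df), ".y")
  if (nrow(df) <= length(terms) + 1)
    stop("too few observations for the number of terms")
  fit <- lm(stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
            data = df)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    aliased <- names(which(is.na(coef(fit))))
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- confint(fit, level = conf)
  res <- data.frame(term = rownames(sm$coefficients),
                    estimate = sm$coefficients[, 1],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p_value = sm$coefficients[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(family = "gaussian", terms = res, n_used = nrow(df),
                 outliers_removed = removed, n_missing = n_missing,
                 fit = fit),
            class = "cerv_glm")
}

#' Logistic regression with Wald odds-ratio intervals
#'
#' Maximum-likelihood logistic regression (glm IRLS, convergence tolerance
#' 1e-8, up to 100 iterations) with Wald 95% confidence intervals on the
#' odds ratios. Complete or quasi-complete separation (non-convergence or
#' diverging coefficients) is detected and flagged in the result and as a
#' warning, never silently returned.
#'
#' @param outcome binary (0/1 or logical) response; both classes must be
#'   present.
#' @param covariates data frame (or named list) of covariates.
#' @param conf confidence level.
#' @return Object of class `cerv_glm` (family `"binomial"`): per-term
#'   `estimate` (log-odds), `odds_ratio`, `ci_low`/`ci_high` (on the OR
#'   scale), `p_value`; plus `n_used`, `separation` flag.
#' @export
fit_logistic <- function(outcome, covariates, conf = 0.95) {
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  df <- .glm_frame(outcome, covariates, ".y")
  if (length(unique(df$.y)) < 2)
    stop("outcome has a single class; logistic model is undefined")
  terms <- setdiff(names(df), ".y")
  if (nrow(df) <= length(terms) + 1)
    stop("too few observations for the number of terms")
  fit <- suppressWarnings(
    glm(stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
        data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)))
  if (anyNA(coef(fit)))
    stop("rank-deficient design; collinear term(s): ",
         paste(names(which(is.na(coef(fit)))), collapse = ", "))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- !fit$converged || any(abs(est[-1]) > 15) || any(se[-1] > 50)
  if (separation)
    warning("possible complete/quasi-complete separation: ",
            "coefficients or standard errors diverge")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- 2 * pnorm(-abs(est / se))
  res <- data.frame(term = names(est),
                    estimate = unname(est),
                    odds_ratio = unname(exp(est)),
                    ci_low = unname(exp(est - z * se)),
                    ci_high = unname(exp(est + z * se)),
                    p_value = unname(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(family = "binomial", terms = res, n_used = nrow(df),
                 outliers_removed = 0L,
                 n_missing = length(outcome) - nrow(df),
                 separation = separation, fit = fit),
            class = "cerv_glm")
}

#' @export
print.cerv_glm <- function(x, digits = 3, ...) {
  cat(sprintf("%s GLM (n = %d%s)\n",
              if (x$family == "binomial") "Logistic" else "Linear",
              x$n_used,
              if (x$outliers_removed)
                sprintf(", %d outlier(s) removed", x$outliers_removed)
              else ""))
  if (isTRUE(x$separation))
    cat("  ** separation suspected; estimates unreliable **\n")
  print(format(x$terms, digits = digits), row.names = FALSE)
  invisible(x)
}
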