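# The expression-to-repression model: ordinary least squares of percent
# repression on log10 abundance, with t-based confidence intervals,
# Pearson correlations, exclusion refits, fold-change predictions,
# expression-corrected repression and Ago-1 occupancy analysis.

#' Fit the log-linear expression-to-repression model
#'
#' Ordinary least squares of percent repression on `log10(rpm +
#' pseudocount)`. The slope is the percent repression gained per decade of
#' abundance; its 95% confidence interval uses the t distribution on the
#' OLS standard error. The Pearson correlation of the same pair is
#' reported alongside.
#'
#' @param rpm Per-miRNA mean abundance (RPM, >= 0); names are carried
#'   through to diagnostics.
#' @param repression Per-miRNA percent repression, same length/order.
#' @param pseudocount Added to RPM before the log (default 0.5); only
#'   relevant when zeros are present.
#' @param names Optional miRNA names (defaults to `names(rpm)`).
#' @return An object of class `"loglin_fit"`: coefficients (intercept,
#'   slope), slope CI, Pearson r, n, sigma, and the model frame. Standard
#'   methods apply: [print.loglin_fit()], `summary`, `coef`, `confint`,
#'   `predict`, `residuals`, `fitted`, `plot`, `simulate`.
#' @examples
#' rpm <- 10^(seq(0, 6, length.out = 12))
#' fit <- fit_loglinear(rpm, 8 + 10.4 * log10(rpm))
#' coef(fit)
#' @export
fit_loglinear <- function(rpm, repression, pseudocount = 0.5,
                          names = NULL) {
  stopifnot(is.numeric(rpm), is.numeric(repression),
            length(rpm) == length(repression))
  if (length(rpm) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(rpm)) || any(rpm < 0))
    stop("rpm must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(repression)))
    stop("repression must be finite", call. = FALSE)
  if (is.null(names))
    names <- if (!is.null(base::names(rpm))) base::names(rpm)
             else paste0("m", seq_along(rpm))
  x <- log10(rpm + pseudocount)
  if (var(x) == 0) stop("zero variance in log10(rpm)", call. = FALSE)
  fm <- lm(repression ~ x)
  # noiseless inputs are legitimate here (parameter-recovery checks);
  # silence lm's perfect-fit warning only
  sm <- withCallingHandlers(summary(fm), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  slope <- unname(coef(fm)[2L])
  se_slope <- sm$coefficients[2L, 2L]
  dfres <- fm$df.residual
  tq <- qt(0.975, dfres)
  structure(list(
    coefficients = c(intercept = unname(coef(fm)[1L]), slope = slope),
    se = c(intercept = sm$coefficients[1L, 2L], slope = se_slope),
    ci_slope = c(lower = slope - tq * se_slope,
                 upper = slope + tq * se_slope),
    pearson_r = if (var(repression) == 0) 0 else cor(x, repression),
    n = length(x),
    sigma = sm$sigma,
    df_residual = dfres,
    pseudocount = pseudocount,
    data = data.frame(name = names, rpm = rpm, log10_rpm = x,
                      repression = repression,
                      fitted = unname(fitted(fm)),
                      residual = unname(residuals(fm)),
                      stringsAsFactors = FALSE)
  ), class = "loglin_fit")
}

#' @export
print.loglin_fit <- function(x, digits = 3, ...) {
  cat("Log-linear expression-repression fit\n")
  cat(sprintf("  n = %d miRNAs, pseudocount = %g RPM\n", x$n,
              x$pseudocount))
  cat(sprintf("  slope: %s %% per decade (95%% CI %s - %s)\n",
              format(x$coefficients[["slope"]], digits = digits),
              format(x$ci_slope[["lower"]], digits = digits),
              format(x$ci_slope[["upper"]], digits = digits)))
  cat(sprintf("  intercept: %s %%\n",
              format(x$coefficients[["intercept"]], digits = digits)))
  cat(sprintf("  Pearson r (log scale): %s\n",
              format(x$pearson_r, digits = digits)))
  invisible(x)
}

#' @export
summary.loglin_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  tval <- est / se
  pval <- 2 * pt(abs(tval), object$df_residual, lower.tail = FALSE)
  structure(list(
    coefficients = cbind(Estimate = est, `Std. Error` = se,
                         `t value` = tval, `Pr(>|t|)` = pval),
    ci_slope = object$ci_slope,
    pearson_r = object$pearson_r,
    r_squared = object$pearson_r^2,
    sigma = object$sigma, n = object$n,
    df_residual = object$df_residual),
    class = "summary.loglin_fit")
}

#' @export
print.summary.loglin_fit <- function(x, digits = 4, ...) {
  cat("Log-linear expression-repression fit\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nResidual SD %s on %d degrees of freedom\n",
              format(x$sigma, digits = digits), x$df_residual))
  cat(sprintf("Pearson r = %s (r^2 = %s), n = %d\n",
              format(x$pearson_r, digits = digits),
              format(x$r_squared, digits = digits), x$n))
  invisible(x)
}

#' @export
coef.loglin_fit <- function(object, ...) object$coefficients

#' @export
confint.loglin_fit <- function(object, parm = "slope", level = 0.95, ...) {
  est <- object$coefficients
  se <- object$se
  tq <- qt(1 - (1 - level) / 2, object$df_residual)
  ci <- cbind(est - tq * se, est + tq * se)
  colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  ci[parm, , drop = FALSE]
}

#' Predicted repression at given abundances
#'
#' @param object A `"loglin_fit"`.
#' @param newdata Optional numeric vector of RPM values; defaults to the
#'   fitted data.
#' @param ... Ignored.
#' @return Numeric vector of predicted percent repression.
#' @export
predict.loglin_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$data$fitted)
  stopifnot(is.numeric(newdata), all(newdata >= 0))
  unname(object$coefficients[["intercept"]] +
         object$coefficients[["slope"]] *
         log10(newdata + object$pseudocount))
}

#' @export
residuals.loglin_fit <- function(object, ...) object$data$residual

#' @export
fitted.loglin_fit <- function(object, ...) object$data$fitted

#' @export
simulate.loglin_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- object$data$fitted
    out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0,
                                                    object$sigma)))
    base::names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Scatter plot of the expression-repression relationship
#'
#' @param x A `"loglin_fit"`.
#' @param ... Passed to `plot()`.
#' @export
plot.loglin_fit <- function(x, ...) {
  plot(x$data$log10_rpm, x$data$repression,
       xlab = expression(log[10] ~ "normalised read count (RPM)"),
       ylab = "repression (%)", pch = 19, ...)
  abline(x$coefficients[["intercept"]], x$coefficients[["slope"]])
  invisible(x)
}

#' Pearson correlation on the untransformed abundance scale
#'
#' @inheritParams fit_loglinear
#' @return Pearson r of raw RPM versus repression.
#' @examples
#' pearson_linear(c(1, 10, 100), c(5, 10, 30))
#' @export
pearson_linear <- function(rpm, repression) {
  stopifnot(length(rpm) == length(repression))
  if (length(rpm) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (var(rpm) == 0 || var(repression) == 0)
    stop("zero variance", call. = FALSE)
  cor(rpm, repression)
}

#' Refit the model excluding named miRNAs
#'
#' @param fit A `"loglin_fit"`.
#' @param exclude Character vector of miRNA names to drop.
#' @return A new `"loglin_fit"` on the remaining observations.
#' @examples
#' rpm <- 10^(0:5); names(rpm) <- paste0("m", 1:6)
#' f <- fit_loglinear(rpm, 8 + 10 * log10(rpm))
#' refit_excluding(f, c("m1", "m2"))
#' @export
refit_excluding <- function(fit, exclude) {
  stopifnot(inherits(fit, "loglin_fit"))
  keep <- !(fit$data$name %in% exclude)
  if (sum(keep) < 3L)
    stop("fewer than 3 observations would remain", call. = FALSE)
  fit_loglinear(fit$data$rpm[keep], fit$data$repression[keep],
                pseudocount = fit$pseudocount,
                names = fit$data$name[keep])
}

#' Repression change predicted for a fold change in abundance
#'
#' Under the log-linear model a fold change `k` in abundance shifts
#' repression by `slope * log10(k)` percentage points; the prediction is
#' additive in log fold change.
#'
#' @param fit A `"loglin_fit"`, or a numeric slope (% per decade).
#' @param fold_change Positive fold change(s) in abundance.
#' @return Numeric vector of predicted changes in percent repression.
#' @examples
#' predict_delta_repression(10.4, 10)  # one decade -> 10.4 points
#' predict_delta_repression(10.4, 2)   # 2-fold -> ~3.1 points
#' @export
predict_delta_repression <- function(fit, fold_change) {
  slope <- if (inherits(fit, "loglin_fit"))
    fit$coefficients[["slope"]] else fit
  stopifnot(is.numeric(slope), length(slope) == 1L)
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    stop("fold_change must be positive", call. = FALSE)
  slope * log10(fold_change)
}

#' Expression-corrected repression
#'
#' Repression divided by `log10(rpm + pseudocount)` — the per-decade
#' activity of a miRNA. Undefined (non-positive) denominators yield `NA`
#' with a warning; the affected names are recorded in attribute
#' `"excluded"` and should be dropped from downstream correlations.
#'
#' @inheritParams fit_loglinear
#' @return Named numeric vector of corrected repression values.
#' @examples
#' expression_corrected_repression(c(m = 30), c(m = 1000))  # 30/3 = 10
#' @export
expression_corrected_repression <- function(repression, rpm,
                                            pseudocount = 0.5) {
  stopifnot(length(rpm) == length(repression))
  den <- log10(rpm + pseudocount)
  bad <- !is.finite(den) | den <= 0
  out <- repression / den
  out[bad] <- NA_real_
  nm <- base::names(rpm)
  if (is.null(nm)) nm <- base::names(repression)
  base::names(out) <- nm
  if (any(bad))
    warning(sprintf(
      "%d value(s) undefined (log10 abundance <= 0); returned as NA",
      sum(bad)))
  attr(out, "excluded") <- if (is.null(nm)) which(bad) else nm[bad]
  out
}

#' Ago-1 occupancy analysis
#'
#' Compares cellular and Ago-1-associated miRNA abundances on the log10
#' scale: Pearson r of log cell versus log Ago RPM, the per-miRNA
#' occupancy ratio (Ago RPM / cell RPM; deviation from constancy indicates
#' differential RISC loading), and, when repression values are supplied,
#' the Pearson r of log Ago RPM versus repression.
#'
#' @param cell_rpm,ago_rpm Named numeric vectors of mean RPM; only shared
#'   names are analysed.
#' @param repression Optional named numeric vector of percent repression.
#' @param pseudocount Added before log10.
#' @return A list of class `"occupancy_analysis"`: `records` (data.frame:
#'   mirna, cell_rpm, ago_rpm, occupancy_ratio), `r_cell_ago`,
#'   `r_ago_repression` (NA when repression not given), `n`.
#' @examples
#' cell <- c(a = 10, b = 1000); ago <- c(a = 12, b = 900)
#' occupancy_analysis(cell, ago)
#' @export
occupancy_analysis <- function(cell_rpm, ago_rpm, repression = NULL,
                               pseudocount = 0.5) {
  stopifnot(!is.null(base::names(cell_rpm)), !is.null(base::names(ago_rpm)))
  shared <- intersect(base::names(cell_rpm), base::names(ago_rpm))
  if (!length(shared)) stop("no shared miRNA names", call. = FALSE)
  cell <- cell_rpm[shared]
  ago <- ago_rpm[shared]
  ratio <- ifelse(cell > 0, ago / cell, NA_real_)
  r_ca <- cor(log10(cell + pseudocount), log10(ago + pseudocount))
  r_ar <- NA_real_
  if (!is.null(repression)) {
    shared_r <- intersect(shared, base::names(repression))
    if (length(shared_r) >= 3L)
      r_ar <- cor(log10(ago[shared_r] + pseudocount),
                  repression[shared_r])
  }
  structure(list(
    records = data.frame(mirna = shared, cell_rpm = unname(cell),
                         ago_rpm = unname(ago),
                         occupancy_ratio = unname(ratio),
                         stringsAsFactors = FALSE),
    r_cell_ago = r_ca, r_ago_repression = r_ar, n = length(shared)),
    class = "occupancy_analysis")
}

#' @export
print.occupancy_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Ago-1 occupancy analysis: %d shared miRNAs\n", x$n))
  cat(sprintf("  Pearson r, log10 cell vs log10 Ago RPM: %s\n",
              format(x$r_cell_ago, digits = digits)))
  if (!is.na(x$r_ago_repression))
    cat(sprintf("  Pearson r, log10 Ago RPM vs repression: %s\n",
                format(x$r_ago_repression, digits = digits)))
  invisible(x)
}
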