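# Dual-luciferase repression: per-day empty-vector normalisation of the
# Renilla/firefly ratio and a paired t-test against the empty construct.

#' Percent repression from raw dual-luciferase plate values
#'
#' For each construct and day the Renilla/firefly ratio is divided by the
#' empty vector's ratio on the same day, giving the normalised ratio
#' `q_d`. Repression is `100 * (1 - mean_d(q_d))`; the p-value comes from a
#' two-sided paired t-test of the per-day ratios against the empty vector
#' (equivalently, a one-sample t-test of `q_d` against 1). Negative values
#' (de-repression) are reported, not clamped.
#'
#' With fewer than 2 days, or zero variance across days, no t statistic
#' exists: the p-value is 1 when every `q_d` equals 1 exactly and `NA`
#' otherwise (never flagged significant).
#'
#' @param plates data.frame with columns `construct`, `day`, `renilla`,
#'   `firefly` (e.g. from [gen_luciferase()] or [read_plates()]). Every day
#'   on which a construct was measured must also carry an `empty` record.
#' @param alpha Significance level for the paired t-test.
#' @param empty Construct id of the empty reporter vector.
#' @return data.frame of class `"repression_table"`: `construct`,
#'   `n_days`, `repression_pct`, `sd_pct`, `p_value`, `significant`. The
#'   per-day normalised ratios are attached as attribute `"ratios"`
#'   (constructs x days).
#' @examples
#' plates <- data.frame(
#'   construct = rep(c("m1", "EMPTY"), each = 3),
#'   day = rep(1:3, 2),
#'   renilla = c(500, 500, 500, 1000, 1000, 1000),
#'   firefly = 1000)
#' repression_from_raw(plates)
#' @export
repression_from_raw <- function(plates, alpha = 0.05, empty = "EMPTY") {
  req <- c("construct", "day", "renilla", "firefly")
  if (!all(req %in% names(plates)))
    stop("plates must have columns construct, day, renilla, firefly",
         call. = FALSE)
  if (any(!is.finite(plates$renilla)) || any(!is.finite(plates$firefly)) ||
      any(plates$renilla <= 0) || any(plates$firefly <= 0))
    stop("luminescence readings must be positive", call. = FALSE)
  if (!empty %in% plates$construct)
    stop(sprintf("no '%s' (empty vector) records found", empty),
         call. = FALSE)
  key <- paste(plates$construct, plates$day)
  if (anyDuplicated(key))
    stop("duplicate (construct, day) records", call. = FALSE)
  ratio <- plates$renilla / plates$firefly
  is_empty <- plates$construct == empty
  empty_ratio <- setNames(ratio[is_empty], plates$day[is_empty])
  miss <- setdiff(unique(plates$day), plates$day[is_empty])
  if (length(miss))
    stop(sprintf("day(s) without an empty-vector record: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  constructs <- unique(plates$construct)
  days_all <- sort(unique(plates$day))
  qmat <- matrix(NA_real_, length(constructs), length(days_all),
                 dimnames = list(constructs, as.character(days_all)))
  res <- lapply(constructs, function(cn) {
    sel <- plates$construct == cn
    dd <- as.character(plates$day[sel])
    q <- ratio[sel] / empty_ratio[dd]
    qmat[cn, dd] <<- q
    repression <- 100 * (1 - mean(q))
    if (length(q) >= 2L && sd(q) > 0) {
      p <- t.test(q, mu = 1)$p.value
    } else {
      p <- if (all(q == 1)) 1 else NA_real_
    }
    data.frame(construct = cn, n_days = length(q),
               repression_pct = repression,
               sd_pct = if (length(q) >= 2L) 100 * sd(q) else NA_real_,
               p_value = p,
               significant = !is.na(p) && p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, ratios = qmat, alpha = alpha, empty = empty,
            class = c("repression_table", "data.frame"))
}

#' Constructs not significantly repressed
#'
#' Returns the constructs whose paired t-test against the empty vector did
#' not reach significance (p >= alpha, or no test possible), excluding the
#' empty vector itself.
#'
#' @param results A `"repression_table"` from [repression_from_raw()].
#' @param alpha Significance level; defaults to the one used in the fit.
#' @return A list: `n` (integer) and `names` (character).
#' @examples
#' plates <- gen_luciferase(c(m1 = 0, m2 = 60), days = 3,
#'   truth = synthetic_truth(luciferase_well_cv = 0.05), seed = 1)
#' count_nonsignificant(repression_from_raw(plates))
#' @export
count_nonsignificant <- function(results, alpha = attr(results, "alpha")) {
  stopifnot(inherits(results, "repression_table"))
  if (is.null(alpha)) alpha <- 0.05
  keep <- results$construct != attr(results, "empty")
  ns <- results$construct[keep &
    (is.na(results$p_value) | results$p_value >= alpha)]
  list(n = length(ns), names = ns)
}
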