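# Survival stratification by miRNA expression. The product-limit estimator
# and the log-rank test are delegated to the survival package; this module
# owns the stratification rules and the tidy result surface.

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator per group; censored observations decrement the
#' risk set without dropping the curve.
#'
#' @param time Numeric vector of follow-up times (days).
#' @param event Integer 0/1 event indicators.
#' @param group Group labels (coerced to factor).
#' @return A data frame of class `km_curves`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event, group = rep("all", length(time))) {
  if (any(time <= 0)) stopf("times must be positive")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (length(levels(group)) == 1) {
    out <- data.frame(group = levels(group), time = fit$time,
                      n_risk = fit$n.risk, n_event = fit$n.event,
                      n_censor = fit$n.censor, surv = fit$surv,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      group = rep(sub("^group=", "", names(fit$strata)), fit$strata),
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, surv = fit$surv, stringsAsFactors = FALSE)
  }
  class(out) <- c("km_curves", "data.frame")
  out
}

#' @export
plot.km_curves <- function(x, ..., col = NULL, xlab = "Time (days)",
                           ylab = "Survival probability") {
  groups <- unique(x$group)
  col <- col %||% seq_along(groups)
  plot(NULL, xlim = c(0, max(x$time)), ylim = c(0, 1), xlab = xlab,
       ylab = ylab, ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    graphics::lines(stats::stepfun(d$time, c(1, d$surv)), do.points = FALSE,
                    col = col[i])
  }
  graphics::legend("topright", legend = groups, col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(sum(O1 - E1))^2 / sum(V)` with hypergeometric
#' mean and variance of the group-1 event count at each distinct event time;
#' p from the chi-square distribution with 1 degree of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level group labels.
#' @return A list of class `logrank_result`: `chisq`, `df`, `p`,
#'   `n_per_group`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stopf("log-rank test needs exactly two groups")
  if (min(table(group)) == 0) stopf("both groups must be non-empty")
  if (sum(event) < 1) stopf("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(chisq = unname(sd$chisq), df = 1,
                 p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n_per_group = setNames(as.numeric(sd$n),
                                        sub("^group=", "", names(sd$n))),
                 observed = sd$obs, expected = sd$exp),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g (df = 1), p = %.4g\n",
              x$chisq, x$p))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d, O=%.0f, E=%.1f)", names(x$n_per_group),
                            x$n_per_group, x$observed, x$expected),
                    collapse = "; ")))
  invisible(x)
}

#' Stratify tumor samples by miRNA expression
#'
#' Splits tumor samples into expression strata of a miRNA on the normalized
#' scale. `"median"` assigns samples at or below the median to the low
#' group; `"tertile"` uses the outer tertiles (middle third dropped).
#' Control samples are excluded. Constant expression yields a degenerate
#' single-group labeling, returned with a warning and attribute
#' `degenerate = TRUE`.
#'
#' @param mirna miRNA feature id (matched after [normalize_mirna_ids()]).
#' @param counts miRNA count matrix.
#' @param norm Result of [median_of_ratios()] on `counts`.
#' @param meta Sample metadata.
#' @param rule `"median"` or `"tertile"`.
#' @return Named character vector (`"low"`/`"high"`) over the stratified
#'   tumor samples.
#' @export
stratify_by_mirna <- function(mirna, counts, norm, meta,
                              rule = c("median", "tertile")) {
  rule <- match.arg(rule)
  idx <- match(normalize_mirna_ids(mirna), normalize_mirna_ids(rownames(counts)))
  if (is.na(idx)) stopf("miRNA '%s' not found in the count matrix", mirna)
  tum <- meta$sample_id[meta$condition == "tumor"]
  x <- norm$normalized[idx, tum]
  if (length(unique(x)) == 1) {
    warnf("constant expression for '%s'; stratification is degenerate", mirna)
    lab <- setNames(rep("low", length(tum)), tum)
    attr(lab, "degenerate") <- TRUE
    return(lab)
  }
  if (rule == "median") {
    lab <- ifelse(x <= median(x), "low", "high")
  } else {
    qs <- quantile(x, c(1 / 3, 2 / 3))
    lab <- ifelse(x <= qs[1], "low", ifelse(x > qs[2], "high", NA))
  }
  lab <- setNames(lab, tum)
  lab[!is.na(lab)]
}

#' Survival analysis of one miRNA stratification
#'
#' Stratifies tumor samples by miRNA expression and runs the Kaplan-Meier
#' estimator and the log-rank test on the strata. Samples with missing time
#' or event are excluded and counted.
#'
#' @inheritParams stratify_by_mirna
#' @param surv Data frame with `sample_id`, `time`, `event`.
#' @return A list of class `mirna_survival`: `mirna`, `rule`, `curves`,
#'   `logrank`, `n_analyzed`, `n_excluded`; or `NULL` (with a warning) when
#'   the stratification is degenerate.
#' @export
mirna_survival <- function(mirna, counts, norm, meta, surv,
                           rule = c("median", "tertile")) {
  rule <- match.arg(rule)
  lab <- stratify_by_mirna(mirna, counts, norm, meta, rule)
  if (isTRUE(attr(lab, "degenerate"))) {
    warnf("survival test skipped for '%s'", mirna)
    return(NULL)
  }
  d <- merge(data.frame(sample_id = names(lab), strat = unname(lab),
                        stringsAsFactors = FALSE),
             surv, by = "sample_id")
  ok <- !is.na(d$time) & !is.na(d$event)
  n_excluded <- sum(!ok) + (length(lab) - nrow(d))
  d <- d[ok, ]
  if (length(unique(d$strat)) < 2) {
    warnf("only one stratum with usable survival data for '%s'", mirna)
    return(NULL)
  }
  structure(list(mirna = mirna, rule = rule,
                 curves = km_estimate(d$time, d$event, d$strat),
                 logrank = logrank_test(d$time, d$event, d$strat),
                 n_analyzed = nrow(d), n_excluded = n_excluded),
            class = "mirna_survival")
}

#' @export
print.mirna_survival <- function(x, ...) {
  cat(sprintf("Survival stratification of %s (%s split): n = %d analyzed, %d excluded\n",
              x$mirna, x$rule, x$n_analyzed, x$n_excluded))
  print(x$logrank)
  invisible(x)
}
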