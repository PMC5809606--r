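#' Kaplan-Meier estimate for one patient group
#'
#' Product-limit estimator of the survival function from right-censored
#' event times, with the median defined as the earliest time at which the
#' estimated survival drops to 0.5 or below (undefined if never reached).
#'
#' @param time event or censoring times (days), `> 0`.
#' @param event logical/0-1 vector: was the death observed?
#' @return A `leukdyn_km` list: `table` (data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `median` (days, `NA` if the curve
#'   never reaches 0.5) and `n`.
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))$median  # 2
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one survival record is required")
  stopifnot(length(event) == length(time), all(time > 0))
  event <- as.integer(as.logical(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  below <- tab$time[tab$surv <= 0.5 & tab$n_event > 0]
  med <- if (length(below)) min(below) else NA_real_
  structure(list(table = tab, median = med, n = length(time)),
            class = "leukdyn_km")
}

#' @export
print.leukdyn_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d events, median %s\n",
              x$n, sum(x$table$n_event),
              if (is.na(x$median)) "not reached" else sprintf("%.4g days", x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank chi-square test (1 degree of freedom)
#' comparing the survival distributions of two patient groups, the usual
#' companion of Kaplan-Meier curves.
#'
#' @param time event or censoring times (days).
#' @param event death-observed indicator.
#' @param group two-level group labels.
#' @return A list: `statistic` (chi-square), `df`, `p_value`, `n` per
#'   group, and `medians` (per-group KM medians).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("log-rank comparison needs exactly two groups")
  if (any(tabulate(group) == 0L)) stop("both groups must be non-empty")
  event <- as.integer(as.logical(event))
  for (g in levels(group)) {
    if (sum(event[group == g]) == 0L)
      warning(sprintf("group %s has no observed events", g))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  meds <- vapply(levels(group), function(g)
    km_estimate(time[group == g], event[group == g])$median, numeric(1))
  list(statistic = unname(stat), df = 1L,
       p_value = unname(pchisq(stat, df = 1L, lower.tail = FALSE)),
       n = table(group), medians = meds)
}

#' Compare survival between model-compatibility groups
#'
#' Runs the Kaplan-Meier / log-rank comparison between patients whose
#' blast dynamics are compatible with the cytokine-dependent model
#' (`"group1"`) and patients compatible only with the cytokine-independent
#' model (`"group2"`). Records labelled `"undetermined"` are dropped with
#' a message. The time origin may be overall survival or survival after
#' the first relapse, depending on which times are supplied.
#'
#' @param records data frame with columns `time`, `event`, `group`
#'   (values `"group1"`/`"group2"`).
#' @return A list with the per-group `leukdyn_km` estimates and the
#'   [logrank_test()] result.
#' @export
compare_group_survival <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  keep <- records$group %in% c("group1", "group2")
  if (!all(keep))
    message(sum(!keep), " record(s) with undetermined group dropped")
  records <- records[keep, ]
  km <- lapply(split(records, records$group),
               function(d) km_estimate(d$time, d$event))
  lr <- logrank_test(records$time, records$event, records$group)
  list(km = km, logrank = lr)
}
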