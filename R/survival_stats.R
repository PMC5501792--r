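#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function \eqn{S(t) = \prod_{t_i \le t}
#' (1 - d_i / n_i)} over the distinct event times, with censored-only
#' times reducing the risk set but contributing no factor.  Fitting is done
#' with [survival::survfit()]; this wrapper reduces the result to the event
#' times the estimator actually steps at.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @return object of class `km_curve` with parallel fields `times`
#'   (increasing distinct event times), `survival`, `at_risk`, `n_events`.
#'   If no event occurred at all the curve is constant 1 (empty fields)
#'   and a warning is raised.
#' @export
km_estimate <- function(time, event) {
  .check_surv(time, event)
  if (sum(event) == 0) {
    warning("no events: Kaplan-Meier curve is constant 1", call. = FALSE)
    return(structure(list(times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), n_events = integer(0)),
                     class = "km_curve"))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(
    list(times = fit$time[keep], survival = fit$surv[keep],
         at_risk = as.integer(fit$n.risk[keep]),
         n_events = as.integer(fit$n.event[keep])),
    class = "km_curve")
}

.check_surv <- function(time, event, labels = NULL) {
  if (length(time) != length(event))
    .stop("time and event differ in length")
  if (any(!is.finite(time)) || any(time <= 0))
    .stop("times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    .stop("event must be 0 or 1")
  if (!is.null(labels) && length(labels) != length(time))
    .stop("labels differ in length from time/event")
}

#' Kaplan-Meier curves per subtype
#'
#' @inheritParams km_estimate
#' @param labels group membership vector (subtype labels).
#' @return named list of `km_curve` objects, one per group level.
#' @export
km_by_group <- function(time, event, labels) {
  .check_surv(time, event, labels)
  g <- factor(labels)
  out <- lapply(levels(g), function(lv) {
    i <- g == lv
    suppressWarnings(km_estimate(time[i], event[i]))
  })
  stats::setNames(out, levels(g))
}

#' k-sample log-rank test
#'
#' Mantel-Cox log-rank comparison of survival across `k` groups: at each
#' distinct event time the expected events per group are allocated in
#' proportion to the group's share of the risk set, and the statistic is
#' the quadratic form of observed-minus-expected with the hypergeometric
#' variance-covariance, referred to a chi-square with `k - 1` degrees of
#' freedom.  Computation is delegated to [survival::survdiff()] (with a
#' pseudo-inverse fallback, and a warning, should the variance matrix be
#' singular).
#'
#' @inheritParams km_by_group
#' @return object of class `logrank_result` with fields `statistic`, `df`,
#'   `p_value`, `per_group_observed`, `per_group_expected`, `groups`.
#' @export
logrank_test <- function(time, event, labels) {
  .check_surv(time, event, labels)
  g <- factor(labels)
  if (nlevels(g) < 2L) .stop("need at least 2 groups")
  if (any(table(g) == 0L)) .stop("empty group in labels")
  if (sum(event) == 0) .stop("no events: log-rank test undefined")
  k <- nlevels(g)
  fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ g),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$chisq)) {
    obs <- as.vector(fit$obs)
    expd <- as.vector(fit$exp)
    stat <- unname(fit$chisq)
  } else {
    warning("singular variance matrix; using pseudo-inverse log-rank",
            call. = FALSE)
    oe <- .logrank_oe(time, event, g)
    obs <- oe$obs
    expd <- oe$exp
    d <- (obs - expd)[-k]
    stat <- drop(t(d) %*% .sym_pinv(oe$var[-k, -k, drop = FALSE]) %*% d)
  }
  structure(
    list(statistic = stat, df = k - 1L,
         p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
         per_group_observed = stats::setNames(obs, levels(g)),
         per_group_expected = stats::setNames(expd, levels(g)),
         groups = levels(g)),
    class = "logrank_result")
}

# Observed/expected/variance table of the k-sample log-rank test, assembled
# directly from the pooled event times (used only on the singular-variance
# fallback path).
.logrank_oe <- function(time, event, g) {
  k <- nlevels(g)
  obs <- as.vector(tapply(event, g, sum))
  obs[is.na(obs)] <- 0
  expd <- numeric(k)
  V <- matrix(0, k, k)
  for (t0 in sort(unique(time[event == 1]))) {
    at <- time >= t0
    n_t <- sum(at)
    d_t <- sum(event[time == t0])
    n_g <- as.vector(tapply(at, g, sum))
    n_g[is.na(n_g)] <- 0
    expd <- expd + d_t * n_g / n_t
    if (n_t > 1) {
      f <- d_t * (n_t - d_t) / (n_t - 1) / n_t^2
      V <- V + f * (diag(n_g * n_t, k) - tcrossprod(n_g)) / n_t
    }
  }
  list(obs = obs, exp = expd, var = V)
}

#' Two-group Mantel-Haenszel hazard ratio with 95% confidence interval
#'
#' \eqn{HR = (O_1 / E_1) / (O_2 / E_2)} from the log-rank
#' observed/expected counts, with the confidence interval
#' \eqn{\exp(\log HR \pm 1.96 \sqrt{1/E_1 + 1/E_2})}.  The ratio is
#' reported for the first group level relative to the second; swapping the
#' labels inverts it.
#'
#' @inheritParams km_by_group
#' @param labels binary group vector (exactly two nonempty groups).
#' @return object of class `hazard_ratio` with fields `hr`, `ci_low`,
#'   `ci_high`, `groups`.
#' @export
hazard_ratio_two_group <- function(time, event, labels) {
  .check_surv(time, event, labels)
  g <- factor(labels)
  if (nlevels(g) != 2L) .stop("hazard ratio needs exactly 2 groups")
  lr <- logrank_test(time, event, g)
  O <- lr$per_group_observed
  E <- lr$per_group_expected
  if (any(O == 0)) .stop("HR undefined: a group has zero events")
  hr <- (O[1L] / E[1L]) / (O[2L] / E[2L])
  se <- sqrt(1 / E[1L] + 1 / E[2L])
  structure(
    list(hr = unname(hr),
         ci_low = unname(exp(log(hr) - 1.96 * se)),
         ci_high = unname(exp(log(hr) + 1.96 * se)),
         groups = levels(g)),
    class = "hazard_ratio")
}

#' Write per-group Kaplan-Meier tables as delimited text
#'
#' @param curves named list of `km_curve` objects (see [km_by_group()]).
#' @param path output path; long-format TSV with columns `group`, `time`,
#'   `survival`, `at_risk`, `n_events`.
#' @return `path`, invisibly.
#' @export
write_km_tables <- function(curves, path) {
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    if (length(cv$times) == 0L) return(NULL)
    data.frame(group = nm, time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk, n_events = cv$n_events)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(group = character(0), time = numeric(0),
                     survival = numeric(0), at_risk = integer(0),
                     n_events = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event time(s)\n", length(x$times)))
  if (length(x$times))
    print(data.frame(time = x$times, survival = signif(x$survival, 4),
                     at_risk = x$at_risk, n_events = x$n_events),
          row.names = FALSE)
  invisible(x)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(data.frame(group = x$groups, observed = x$per_group_observed,
                   expected = signif(x$per_group_expected, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("HR (%s vs %s) = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$groups[1L], x$groups[2L], x$hr, x$ci_low, x$ci_high))
  invisible(x)
}
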