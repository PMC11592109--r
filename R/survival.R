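#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival curve `S(t)` from right-censored
#' time-to-event data. Censored subjects leave the risk set just after
#' their censoring time; with no censoring the estimator equals the
#' empirical survival function.
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators (1 = event observed).
#' @return A `km_fit` object: `data.frame`-like list with `time` (distinct
#'   event times), `n_risk`, `n_event`, `survival`, plus the input size `n`.
#'   Has `print` and `plot` methods.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time <= 0)) stop("non-positive survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ts <- sort(unique(time[event == 1]))
  n_risk <- vapply(ts, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ts, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ts, n_risk = n_risk, n_event = n_event,
                 survival = surv, n = length(time)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param fit A `km_fit`.
#' @param t Times at which to evaluate `S(t)` (right-continuous step
#'   function; `S(t) = 1` before the first event).
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(t, function(tt) {
    i <- sum(fit$time <= tt)
    if (i == 0) 1 else fit$survival[i]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, %d event time(s)\n", x$n, length(x$time)))
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   survival = round(x$survival, 4)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ..., xlab = "time (months)", ylab = "survival",
                        col = 1) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[seq_len(2 * length(x$time) - 1)])
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab,
       col = col, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df): at each distinct event
#' time the observed events in group 1 are compared with the expectation
#' under a common hazard, with the hypergeometric variance; the statistic is
#' `(O - E)^2 / V` and is invariant to relabeling the groups.
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param group Two-level grouping vector (e.g. `"high"`/`"low"`).
#' @return List with `chisq`, `p` (upper chi-square tail, 1 df), `observed`
#'   and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  if (sum(event) < 1) stop("need at least one event overall")
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  obs <- c(o1, sum(event) - o1)
  expd <- c(e1, sum(event) - e1)
  names(obs) <- names(expd) <- levels(g)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Cohen's kappa and percent agreement for a square rating table
#'
#' Chance-corrected inter-rater agreement for multi-categorical ratings:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal products. When `p_e == 1` (both raters degenerate on one
#' category) kappa is undefined and returned as `NA` with a flag.
#'
#' @param matrix Square non-negative integer contingency matrix
#'   (rater 1 in rows, rater 2 in columns, categories aligned).
#' @return List with `kappa`, `percent_agreement` (0-100), `undefined`.
#' @export
kappa_agreement <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("rating matrix must be square")
  if (any(m < 0) || sum(m) <= 0) stop("counts must be non-negative with total > 0")
  p <- m / sum(m)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(list(kappa = NA_real_, percent_agreement = 100 * po,
                undefined = TRUE))
  }
  list(kappa = (po - pe) / (1 - pe), percent_agreement = 100 * po,
       undefined = FALSE)
}
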