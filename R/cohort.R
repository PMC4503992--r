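#' Dichotomize expression at the 25th percentile
#'
#' Splits a continuous expression vector into "low" (< 25th percentile)
#' and "high" (>= 25th percentile) labels.  The percentile uses linear
#' interpolation between order statistics (`stats::quantile` type 7) by
#' default; ties at the threshold go to "high" per the strict `<` rule.
#'
#' @param expression Numeric vector, length >= 4.
#' @param probs Percentile cut, default 0.25.
#' @param type Quantile convention passed to [stats::quantile()].
#' @return Factor with levels `low`, `high`; attribute `threshold` is the
#'   cut value.
#' @export
#' @examples
#' quartile_dichotomize(1:8)  # threshold 2.75: low = {1, 2}
quartile_dichotomize <- function(expression, probs = 0.25, type = 7) {
  x <- as.numeric(expression)
  if (length(x) < 4) stop("need at least 4 values to form quartiles")
  if (any(!is.finite(x))) stop("expression values must be finite")
  thr <- unname(stats::quantile(x, probs = probs, type = type))
  if (length(unique(x)) == 1)
    warning("all expression values identical; labelling everything high")
  lab <- factor(ifelse(x < thr, "low", "high"), levels = c("low", "high"))
  attr(lab, "threshold") <- thr
  lab
}

#' Kaplan-Meier product-limit estimator
#'
#' Per-group step-function survival estimate.  At each distinct event time
#' t with d events among n at risk, survival multiplies by `(1 - d/n)`;
#' censored subjects leave the risk set after their time.
#'
#' @param times Positive event/censoring times.
#' @param events Logical (or 0/1): TRUE if the event occurred.
#' @param groups Optional group labels (one curve per level).
#' @return Data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`; rows only at event times, survival right-continuous,
#'   starting implicitly at 1.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (any(times <= 0) || any(!is.finite(times))) stop("times must be > 0")
  if (is.null(groups)) groups <- rep("all", length(times))
  stopifnot(length(times) == length(events), length(times) == length(groups))
  out <- lapply(split(seq_along(times), groups), function(idx) {
    tt <- times[idx]; ev <- events[idx]
    ut <- sort(unique(tt[ev]))
    if (length(ut) == 0) return(NULL)
    s <- 1
    rows <- lapply(ut, function(t0) {
      n_risk <- sum(tt >= t0)
      n_event <- sum(tt == t0 & ev)
      s <<- s * (1 - n_event / n_risk)
      data.frame(time = t0, n_risk = n_risk, n_event = n_event, survival = s)
    })
    do.call(rbind, rows)
  })
  grp <- rep(names(out), vapply(out, function(d) if (is.null(d)) 0L else nrow(d),
                                integer(1)))
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(group = character(), time = numeric(),
                                      n_risk = integer(), n_event = integer(),
                                      survival = numeric()))
  cbind(data.frame(group = grp), res, row.names = NULL)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at each distinct event time the
#' observed minus expected events in group 1 are accumulated, with the
#' hypergeometric variance, giving a 1-df chi-square statistic.  The
#' result is symmetric in group order.
#'
#' @param times Positive times.
#' @param events Logical event indicators.
#' @param groups Labels with exactly two non-empty levels.
#' @return List with `statistic` (chi-square), `p_value`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(times, events, groups) {
  times <- as.numeric(times)
  events <- as.logical(events)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) == 0)) stop("both groups must be non-empty")
  if (!any(events)) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(statistic = 0, p_value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  g1 <- groups == levels(groups)[1]
  ut <- sort(unique(times[events]))
  o_minus_e <- 0; v_sum <- 0; obs1 <- 0; exp1 <- 0
  for (t0 in ut) {
    at_risk <- times >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t0 & events)
    d1 <- sum(times == t0 & events & g1)
    e1 <- d * n1 / n
    obs1 <- obs1 + d1
    exp1 <- exp1 + e1
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v_sum <- v_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v_sum == 0) {
    warning("zero log-rank variance; p = 1")
    return(list(statistic = 0, p_value = 1,
                observed = c(obs1, sum(events) - obs1),
                expected = c(exp1, sum(events) - exp1)))
  }
  stat <- o_minus_e^2 / v_sum
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(obs1, sum(events) - obs1),
       expected = c(exp1, sum(events) - exp1))
}

# conditional MLE of the odds ratio for a 2x2 table (noncentral
# hypergeometric mean matched to the observed cell by root finding)
odds_ratio_cmle <- function(x, m, n, k) {
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  mean_nchg <- function(psi) {
    lp <- lchoose(m, support) + lchoose(n, k - support) +
      support * log(psi)
    w <- exp(lp - max(lp))
    sum(support * w) / sum(w)
  }
  f <- function(lpsi) mean_nchg(exp(lpsi)) - x
  stats::uniroot(f, c(-25, 25), tol = 1e-9)$root |> exp()
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p by full hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.  The conditional maximum
#' likelihood odds ratio is reported.
#'
#' @param table 2x2 matrix of non-negative counts with both margins
#'   nonzero, e.g. response (rows) by expression group (columns).
#' @return List with `p_value`, `odds_ratio`, `table`.
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == 2), all(tb >= 0), all(tb == round(tb)))
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("both margins must be nonzero")
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  x <- tb[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       odds_ratio = odds_ratio_cmle(x, m, n, k),
       table = tb)
}

#' Response-by-expression contingency analysis
#'
#' Cross-tabulates a binary response (e.g. pathologic complete response)
#' against low/high expression labels and applies Fisher's exact test.
#'
#' @param response Logical vector (TRUE = responder).
#' @param expression_group Factor or character, two levels (e.g. from
#'   [quartile_dichotomize()]).
#' @return List with the 2x2 `table`, `p_value`, `odds_ratio`.
#' @export
response_contingency <- function(response, expression_group) {
  response <- as.logical(response)
  g <- factor(expression_group)
  if (nlevels(g) != 2) stop("expression_group must have two levels")
  tb <- table(factor(response, levels = c(TRUE, FALSE)), g)
  tb <- matrix(as.integer(tb), 2, 2,
               dimnames = list(response = c("responder", "non-responder"),
                               expression = levels(g)))
  res <- fisher_exact_2x2(tb)
  list(table = tb, p_value = res$p_value, odds_ratio = res$odds_ratio)
}

#' Wilcoxon rank-sum comparison of expression between outcome groups
#'
#' Same contract and implementation as [compare_groups()] (exact
#' enumeration for small combined n, tie-corrected normal approximation
#' otherwise).
#'
#' @inheritParams compare_groups
#' @return See [compare_groups()].
#' @export
rank_sum_compare <- function(values_a, values_b, exact_limit = 12)
  compare_groups(values_a, values_b, exact_limit = exact_limit)

#' Quartile-split survival analysis of a cohort table
#'
#' The clinical analysis pattern: dichotomize expression at the 25th
#' percentile, estimate per-group Kaplan-Meier curves, and compare the
#' groups with the log-rank test.
#'
#' @param cohort Data frame with columns `expression`, `time` (> 0),
#'   `event` (logical/0-1); optional `subject_id`, `response`, `arm`.
#' @return List with `labels`, `threshold`, `km` (data frame), `logrank`.
#' @export
cohort_survival_analysis <- function(cohort) {
  d <- as.data.frame(cohort)
  req <- c("expression", "time", "event")
  if (!all(req %in% names(d))) stop("cohort needs columns ", paste(req, collapse = ", "))
  if (!is.null(d$subject_id) && anyDuplicated(d$subject_id))
    stop("subject_id must be unique")
  lab <- quartile_dichotomize(d$expression)
  km <- km_estimate(d$time, d$event, lab)
  lr <- logrank_test(d$time, d$event, lab)
  list(labels = lab, threshold = attr(lab, "threshold"), km = km,
       logrank = lr)
}

#' Cox proportional-hazards fit (delegated)
#'
#' Thin pass-through to [survival::coxph()] relating expression (or its
#' low/high dichotomization) to survival; model internals are not
#' reimplemented here.
#'
#' @param cohort Data frame as in [cohort_survival_analysis()].
#' @param dichotomize Use the low/high label (default) rather than the
#'   continuous expression as the covariate.
#' @return The fitted `coxph` object.
#' @export
cox_fit <- function(cohort, dichotomize = TRUE) {
  d <- as.data.frame(cohort)
  x <- if (dichotomize) quartile_dichotomize(d$expression) else d$expression
  df <- data.frame(time = d$time, event = as.integer(d$event), x = x)
  survival::coxph(survival::Surv(time, event) ~ x, data = df)
}
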