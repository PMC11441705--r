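## Centrosome-to-nucleus ratio (CNR) cohort analytics: per-sample CNR from
## field counts, depth-one CART dichotomization against a binary relapse
## outcome, Kaplan-Meier / log-rank survival endpoints and Spearman
## correlates.  Months are the canonical clinical time unit.

#' Per-sample centrosome-to-nucleus ratio
#'
#' Each field contributes the ratio of its centrosome count to its nucleus
#' count; the sample CNR is the unweighted mean of the per-field ratios
#' (typically 10 fields per sample).  The pooled-count variant (total
#' centrosomes / total nuclei) is reported alongside.  Fields with zero
#' nuclei are excluded and counted.
#'
#' @param fields data.frame with `sample_id`, `field_index`,
#'   `n_centrosomes`, `n_nuclei` (non-negative integers).
#' @return data.frame per sample: `sample_id`, `cnr` (mean of per-field
#'   ratios), `cnr_pooled`, `n_fields_used`, `n_fields_excluded`.
#' @export
compute_cnr <- function(fields) {
  stopifnot(all(c("sample_id", "n_centrosomes", "n_nuclei") %in% names(fields)))
  if (any(fields$n_centrosomes < 0 | fields$n_nuclei < 0))
    stop("field counts must be non-negative")
  out <- do.call(rbind, lapply(split(fields, fields$sample_id), function(d) {
    ok <- d$n_nuclei > 0
    if (!any(ok))
      stop("sample ", d$sample_id[1L], ": all fields have zero nuclei")
    data.frame(sample_id = d$sample_id[1L],
               cnr = mean(d$n_centrosomes[ok] / d$n_nuclei[ok]),
               cnr_pooled = sum(d$n_centrosomes[ok]) / sum(d$n_nuclei[ok]),
               n_fields_used = sum(ok), n_fields_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Depth-one CART split of a continuous marker against a binary outcome
#'
#' Exhaustive search over the midpoints between consecutive sorted unique
#' marker values for the binary split minimizing the total (size-weighted)
#' Gini impurity of the two children; ties are broken toward the smaller
#' threshold.  The low group is `value <= threshold`.  This is the single
#' cutoff a depth-1 classification tree produces; no pruning or
#' cross-validation is involved.
#'
#' @param values numeric marker (e.g. CNR per sample).
#' @param outcomes binary outcome (0/1 or logical), same length; both
#'   classes must be present and `n >= 4`.
#' @return list with `threshold`, `impurity` (summed child Gini weighted by
#'   child size, divided by n), `group` (factor `low`/`high`) and the
#'   outcome `table` by group.
#' @export
cart_threshold <- function(values, outcomes) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(values) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  n <- length(values)
  if (n < 4L) stop("need at least 4 observations")
  if (length(unique(outcomes)) < 2L)
    stop("no split possible: a single outcome class is present")
  u <- sort(unique(values))
  if (length(u) < 2L) stop("no split possible: all marker values identical")
  cand <- (u[-length(u)] + u[-1L]) / 2
  gini_total <- vapply(cand, function(thr) {
    left <- values <= thr
    g <- function(y) {
      if (length(y) == 0L) return(0)
      p <- mean(y)
      2 * p * (1 - p)
    }
    (sum(left) * g(outcomes[left]) + sum(!left) * g(outcomes[!left])) / n
  }, numeric(1L))
  best <- which(gini_total <= min(gini_total) + 1e-12)[1L]
  thr <- cand[best]
  group <- factor(ifelse(values <= thr, "low", "high"),
                  levels = c("low", "high"))
  list(threshold = thr, impurity = gini_total[best], group = group,
       table = table(group, outcome = outcomes))
}

#' Classify a CNR against a threshold
#'
#' `low` iff `cnr <= threshold`, `high` otherwise (matching the published
#' convention that the high group is strictly above the cutoff).
#'
#' @param cnr numeric CNR value(s).
#' @param threshold positive cutoff.
#' @return factor with levels `low`, `high`.
#' @export
classify_cnr <- function(cnr, threshold) {
  stopifnot(threshold > 0)
  factor(ifelse(cnr <= threshold, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate of the survival function; censoring occurring at
#' an event time is processed after the events at that time.
#'
#' @param times non-negative event/censoring times (months).
#' @param events 1 = event, 0 = censored.
#' @return data.frame per distinct observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (non-increasing from 1).
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  if (length(times) == 0L) stop("empty input")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance; the statistic is
#' referred to a chi-square distribution with 1 degree of freedom.  With no
#' events in either group the comparison is degenerate and reported as
#' statistic 0, p = 1.
#'
#' @param times_a,events_a,times_b,events_b survival data of the two groups.
#' @return list with `statistic`, `df`, `p_value`, `degenerate`, and the
#'   observed/expected event counts per group.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) == length(events_a),
            length(times_b) == length(events_b),
            length(times_a) > 0L, length(times_b) > 0L)
  if (sum(events_a) + sum(events_b) == 0)
    return(list(statistic = 0, df = 1L, p_value = 1, degenerate = TRUE,
                observed = c(0, 0), expected = c(0, 0)))
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(sd_$chisq)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       degenerate = FALSE,
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Spearman rank correlation
#'
#' Average-rank Spearman rho with the large-sample t approximation for the
#' p-value.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Read cohort and field-count CSV files
#'
#' Field counts: `sample_id, field_index, n_centrosomes, n_nuclei`.  Cohort:
#' `sample_id, cnr (optional when fields are given), relapse_within_6mo,
#' time_to_relapse_months, relapse_event, os_months, os_event, figo_stage`.
#'
#' @param file path to the CSV.
#' @return data.frame.
#' @export
read_field_counts <- function(file) {
  d <- read.csv(file)
  stopifnot(all(c("sample_id", "field_index", "n_centrosomes",
                  "n_nuclei") %in% names(d)))
  d$sample_id <- as.character(d$sample_id)
  d
}

#' @rdname read_field_counts
#' @export
read_cohort <- function(file) {
  d <- read.csv(file)
  need <- c("sample_id", "relapse_within_6mo", "time_to_relapse_months",
            "relapse_event", "os_months", "os_event")
  stopifnot(all(need %in% names(d)))
  d$sample_id <- as.character(d$sample_id)
  if (any(d$time_to_relapse_months < 0) || any(d$os_months < 0))
    stop("survival times must be non-negative")
  d
}
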