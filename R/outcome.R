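#' Treg-normalized marker score
#'
#' Normalizes a marker's bulk-tumor expression by the Treg-abundance gene
#' (FOXP3) to approximate expression per Treg:
#' `log2((marker + pseudocount) / (normalizer + pseudocount))`.
#'
#' @param cohort A `survival_cohort` data.frame with `marker_expr` and
#'   `normalizer_expr` columns.
#' @param pseudocount Positive; prevents division by zero. Default 1.
#' @return Numeric per-subject score, named by subject when available.
#' @export
marker_score <- function(cohort, pseudocount = 1) {
  stopifnot(is.data.frame(cohort),
            all(c("marker_expr", "normalizer_expr") %in% names(cohort)))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  s <- log2((cohort$marker_expr + pseudocount) /
            (cohort$normalizer_expr + pseudocount))
  if ("subject" %in% names(cohort)) names(s) <- cohort$subject
  s
}

#' Quantile stratification into High and Low groups
#'
#' Subjects strictly above the `1 - upper` empirical quantile are High,
#' strictly below the `lower` quantile are Low, everyone else (including
#' ties sitting exactly on a cut) is excluded. The paper's TCGA analysis
#' corresponds to `upper = lower = 0.3`; the Swedish cohort to 0.4.
#'
#' @param scores Numeric per-subject scores (named or not).
#' @param upper,lower Tail proportions; `upper + lower <= 1`.
#' @return Data.frame with `subject`, `score`, `stratum`
#'   (`"High"`/`"Low"`/`"excluded"`); cut values and the number of tied,
#'   excluded subjects are attached as attributes.
#' @export
stratify <- function(scores, upper = 0.3, lower = 0.3) {
  stopifnot(upper > 0, lower > 0, upper + lower <= 1)
  if (length(unique(scores)) < 2)
    stop("degenerate scores: all values equal, cannot stratify")
  hi_cut <- stats::quantile(scores, 1 - upper, names = FALSE)
  lo_cut <- stats::quantile(scores, lower, names = FALSE)
  stratum <- rep("excluded", length(scores))
  stratum[scores > hi_cut] <- "High"
  stratum[scores < lo_cut] <- "Low"
  n_tied <- sum(scores == hi_cut) + sum(scores == lo_cut & lo_cut != hi_cut)
  out <- data.frame(
    subject = if (!is.null(names(scores))) names(scores)
              else as.character(seq_along(scores)),
    score = as.numeric(scores), stratum = stratum)
  attr(out, "cuts") <- c(lower = lo_cut, upper = hi_cut)
  attr(out, "n_tied_at_cut") <- n_tied
  out
}

#' Kaplan-Meier product-limit curve
#'
#' @param cohort Data.frame with `time` and `event` (1 = event observed,
#'   0 = censored) columns, or a numeric `time` vector plus `event`.
#' @param event Used when `cohort` is a numeric vector.
#' @return Data.frame `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   -- the stepwise product-limit estimate at each observed time.
#' @export
km_curve <- function(cohort, event = NULL) {
  if (is.data.frame(cohort)) {
    time <- cohort$time; event <- cohort$event
  } else {
    time <- cohort
  }
  if (length(time) < 1) stop("need at least one subject")
  if (any(time < 0)) stop("negative follow-up times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank: observed-minus-expected events summed over event
#' times with hypergeometric variance, chi-square on one degree of freedom,
#' two-sided p. With no events in either group the statistic is 0 and
#' p = 1, with a warning.
#'
#' @param groupA,groupB Data.frames with `time` and `event` columns.
#' @return List with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(groupA, groupB) {
  stopifnot(nrow(groupA) >= 1, nrow(groupB) >= 1)
  time <- c(groupA$time, groupB$time)
  event <- c(groupA$event, groupB$event)
  grp <- rep(c("A", "B"), c(nrow(groupA), nrow(groupB)))
  if (sum(event) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chisq = 0, df = 1, p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chisq = unname(sd$chisq), df = 1,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Waterfall deltas from the cohort median
#'
#' Each subject's score deviation from the cohort median, sorted
#' descending -- the ordering of a waterfall plot -- paired with response
#' labels when available.
#'
#' @param cohort Data.frame (needs >= 2 rows); `response` column attached
#'   to the output when present.
#' @param scores Numeric per-subject scores; defaults to
#'   `marker_score(cohort)`.
#' @return Data.frame `subject`, `delta`, and `response` if available,
#'   sorted by descending delta.
#' @export
waterfall_deltas <- function(cohort, scores = marker_score(cohort)) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 2)
  delta <- scores - stats::median(scores)
  out <- data.frame(
    subject = if ("subject" %in% names(cohort)) cohort$subject
              else as.character(seq_len(nrow(cohort))),
    delta = delta)
  if ("response" %in% names(cohort)) out$response <- cohort$response
  out <- out[order(-out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U comparison of marker scores between two groups
#'
#' Rank-sum comparison, e.g. of FOXP3-normalized marker scores between
#' tumor stages. The p-value is exact (full enumeration) when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y Numeric scores of the two groups, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `U`, `p_value`, `method`.
#' @export
stage_comparison <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
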