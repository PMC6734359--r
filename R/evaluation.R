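# Assessment statistics: report-level confusion counts per phenotype,
# sensitivity/specificity/PPV with Wilson score intervals, F1, Cohen's
# kappa for label agreement, entity-level precision/recall/F1, and
# Wilson-width sample-size planning.

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval is asymmetric and well behaved for proportions
#' very close to 0 or 1, which is why it is the interval of choice for
#' reporting sensitivity and specificity near 100%. Bounds are clipped
#' to \[0, 1\].
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (n >= 1).
#' @param confidence Confidence level, default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' round(wilson_ci(159, 164), 2)  # c(0.93, 0.99)
wilson_ci <- function(k, n, confidence = 0.95) {
  if (n < 1) stop("undefined metric: n = 0 trials")
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # the closed form collapses exactly at the degenerate counts
  c(low = if (k == 0) 0 else max(0, center - half),
    high = if (k == n) 1 else min(1, center + half))
}

wilson_width <- function(p, n, confidence = 0.95) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  denom <- 1 + z^2 / n
  2 * z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
}

#' F1 score: harmonic mean of precision and recall
#'
#' @param precision,recall Proportions in \[0, 1\].
#' @return F1, or `NA` when undefined.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || (precision + recall) == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Report-level confusion counts for one phenotype
#'
#' A report is a true positive if the phenotype is in both the predicted
#' and gold label sets, a false positive if predicted only, a false
#' negative if gold only, and a true negative otherwise.
#'
#' @param pred,gold Lists of labelled reports (each with `report_id` and
#'   `labels`), covering the same report ids.
#' @param phenotype A phenotype label, or a character vector of labels
#'   treated as a group (positive if any member present).
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gold, phenotype) {
  pid <- vapply(pred, `[[`, character(1), "report_id")
  gid <- vapply(gold, `[[`, character(1), "report_id")
  if (anyDuplicated(pid) || anyDuplicated(gid))
    stop("duplicate report ids")
  missing <- c(setdiff(gid, pid), setdiff(pid, gid))
  if (length(missing))
    stop("pred and gold cover different reports; missing: ",
         paste(missing, collapse = ", "))
  gold <- gold[match(pid, gid)]
  p <- vapply(pred, function(r) any(phenotype %in% r$labels), logical(1))
  g <- vapply(gold, function(r) any(phenotype %in% r$labels), logical(1))
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g)),
            class = "confusion_counts")
}

#' Point metrics with Wilson intervals from confusion counts
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), PPV = tp/(tp+fp),
#' each with a Wilson 95% interval; F1 is the harmonic mean of PPV and
#' sensitivity. A metric with a zero denominator is reported as
#' undefined (`NA`), never as 0.
#'
#' @param counts A `confusion_counts` (or list with tp/fp/fn/tn).
#' @param confidence Confidence level for the intervals.
#' @return Data frame with columns `name`, `estimate`, `ci_low`,
#'   `ci_high`, `numerator`, `denominator`.
#' @export
report_metrics <- function(counts, confidence = 0.95) {
  one <- function(name, k, n) {
    if (n == 0)
      return(data.frame(name = name, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, numerator = k, denominator = n))
    ci <- wilson_ci(k, n, confidence)
    data.frame(name = name, estimate = k / n, ci_low = ci[["low"]],
               ci_high = ci[["high"]], numerator = k, denominator = n)
  }
  sens <- one("sensitivity", counts$tp, counts$tp + counts$fn)
  spec <- one("specificity", counts$tn, counts$tn + counts$fp)
  ppv <- one("ppv", counts$tp, counts$tp + counts$fp)
  f1 <- f1_score(ppv$estimate, sens$estimate)
  out <- rbind(sens, spec, ppv,
               data.frame(name = "f1", estimate = f1, ci_low = NA_real_,
                          ci_high = NA_real_, numerator = counts$tp,
                          denominator = NA_integer_))
  rownames(out) <- NULL
  out
}

#' Cohen's kappa for two annotators' per-report labels
#'
#' Chance-corrected agreement between two boolean vectors (one element
#' per report, TRUE if the annotator assigned the label). Expected
#' agreement uses the product of the marginal proportions. Perfect
#' agreement with degenerate marginals (expected agreement 1) returns 1.
#' Symmetric in its arguments.
#'
#' @param labels_a,labels_b Logical (or 0/1) vectors of equal length.
#' @return Kappa value in \[-1, 1\].
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a <- as.logical(labels_a); b <- as.logical(labels_b)
  stopifnot(length(a) == length(b), length(a) >= 1)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Entity-level precision, recall and F1
#'
#' Matches predicted against gold entities over the same text. `exact`
#' matching requires identical span and type; `overlap` requires span
#' intersection and the same type. Each gold entity is matched at most
#' once (greedy, left to right).
#'
#' @param gold,pred Entity data frames with `start`, `end`, `type`.
#' @param matching `"exact"` or `"overlap"`.
#' @return Named numeric vector `c(precision, recall, f1)`; undefined
#'   components are `NA`.
#' @export
entity_prf <- function(gold, pred, matching = c("exact", "overlap")) {
  matching <- match.arg(matching)
  used <- rep(FALSE, nrow(gold))
  tp <- 0L
  ord <- order(pred$start)
  for (i in ord) {
    cand <- which(!used & gold$type == pred$type[i] &
                    (if (matching == "exact")
                      gold$start == pred$start[i] & gold$end == pred$end[i]
                     else gold$start < pred$end[i] & gold$end > pred$start[i]))
    if (length(cand)) {
      used[cand[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  p <- if (nrow(pred) == 0) NA_real_ else tp / nrow(pred)
  r <- if (nrow(gold) == 0) NA_real_ else tp / nrow(gold)
  f <- if (is.na(p) || is.na(r) || (p + r) == 0) NA_real_ else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Sample size for a target Wilson interval width
#'
#' Finds the smallest positive-case count m whose Wilson interval at
#' observed proportion `p` has total width at most `max_width`, then
#' inflates by the expected prevalence to the report count
#' n = ceiling(m / prevalence), optionally rounded up to a granularity.
#'
#' @param p Expected proportion (e.g. anticipated sensitivity).
#' @param prevalence Expected fraction of positive reports.
#' @param max_width Maximum total CI width (e.g. 0.10).
#' @param round_to Optional granularity to round n up to (e.g. 100).
#' @param confidence Confidence level.
#' @return Integer n, the number of reports to sample.
#' @export
#' @examples
#' min_sample_size(0.95, 0.12, 0.10, round_to = 100)  # 700
min_sample_size <- function(p, prevalence, max_width, round_to = NULL,
                            confidence = 0.95) {
  stopifnot(p > 0, p <= 1, prevalence > 0, prevalence <= 1, max_width > 0)
  # Wilson width is strictly decreasing in n: bracket by doubling, then
  # bisect for the smallest satisfying m
  hi <- 1
  while (wilson_width(p, hi, confidence) > max_width) {
    hi <- hi * 2
    if (hi > 2^40) stop("unattainable interval width: ", max_width)
  }
  lo <- max(1, hi / 2)
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (wilson_width(p, mid, confidence) <= max_width) hi <- mid
    else lo <- mid + 1
  }
  n <- ceiling(hi / prevalence)
  if (!is.null(round_to)) n <- ceiling(n / round_to) * round_to
  as.integer(n)
}

#' Per-phenotype evaluation table
#'
#' Evaluates predicted against gold labelled reports for every phenotype
#' plus the aggregate groups ("Any ischaemic stroke", "Any haemorrhagic
#' stroke", "Any tumour", each positive when any member label matches).
#' Point estimates are kept unrounded; a display filter can suppress
#' rows with fewer than `suppress_below` true positives (counts are
#' never altered, rows are only masked).
#'
#' @param pred,gold Lists of labelled reports over the same report ids.
#' @param suppress_below Optional integer; rows with `tp` below it get
#'   `suppressed = TRUE`.
#' @return Data frame with one row per label/group: `label`, `tp`,
#'   `sensitivity`, `sens_low`, `sens_high`, `ppv`, `ppv_low`,
#'   `ppv_high`, `specificity`, `spec_low`, `spec_high`, `f1`,
#'   `suppressed`.
#' @export
evaluate_labels <- function(pred, gold, suppress_below = NULL) {
  groups <- phenotype_groups()
  rows <- c(as.list(setNames(phenotype_labels(), phenotype_labels())),
            groups)
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    cc <- confusion_counts(pred, gold, rows[[nm]])
    m <- report_metrics(cc)
    g <- function(metric, col) m[m$name == metric, ][[col]]
    data.frame(label = nm, tp = cc$tp,
               sensitivity = g("sensitivity", "estimate"),
               sens_low = g("sensitivity", "ci_low"),
               sens_high = g("sensitivity", "ci_high"),
               ppv = g("ppv", "estimate"),
               ppv_low = g("ppv", "ci_low"), ppv_high = g("ppv", "ci_high"),
               specificity = g("specificity", "estimate"),
               spec_low = g("specificity", "ci_low"),
               spec_high = g("specificity", "ci_high"),
               f1 = g("f1", "estimate"), stringsAsFactors = FALSE)
  }))
  out$suppressed <- if (is.null(suppress_below)) FALSE else
    out$tp < suppress_below
  rownames(out) <- NULL
  out
}

#' Format an evaluation table for display
#'
#' Two-decimal rounding happens only here, at display time; suppressed
#' rows are masked with dashes.
#'
#' @param tab Result of [evaluate_labels()].
#' @return Data frame of formatted strings.
#' @export
format_metrics_table <- function(tab) {
  fmt <- function(est, lo, hi) {
    ifelse(is.na(est), "-",
           sprintf("%.2f (%.2f-%.2f)", est, lo, hi))
  }
  out <- data.frame(
    label = tab$label,
    tp = as.character(tab$tp),
    `sensitivity (95% CI)` = fmt(tab$sensitivity, tab$sens_low, tab$sens_high),
    `ppv (95% CI)` = fmt(tab$ppv, tab$ppv_low, tab$ppv_high),
    `specificity (95% CI)` = fmt(tab$specificity, tab$spec_low, tab$spec_high),
    f1 = ifelse(is.na(tab$f1), "-", sprintf("%.2f", tab$f1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  mask <- which(tab$suppressed)
  for (i in mask) out[i, -1] <- "-"
  out
}
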