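#' Confusion-matrix counts from a diagnostic study
#'
#' Container for the four cells of a 2x2 diagnostic table: true positives,
#' false positives, true negatives and false negatives, counted against a
#' gold standard of reference (histology for positives, follow-up for
#' negatives in the screening setting this package models).
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 76, fp = 48, tn = 971, fn = 0)
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(x) <= 0) {
    stop("at least one confusion count must be positive", call. = FALSE)
  }
  structure(as.list(as.integer(round(x))), names = names(x),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (n =", x$tp + x$fp + x$tn + x$fn, ")\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("test +", "test -"),
                              c("disease +", "disease -")))
  print(m)
  invisible(x)
}

# tp/(tp+fn) etc. with an explicit NA (plus warning) on a zero denominator --
# an undefined metric must never be silently reported as 0.
ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s is undefined (zero denominator); reported as NA", what),
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Diagnostic performance metrics
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, accuracy and prevalence from confusion counts. Metrics are kept
#' as exact fractions; rounding to the customary one-decimal percentage
#' happens only when printing. A metric with a zero denominator is reported
#' as `NA` with a warning, never as zero.
#'
#' @param counts A [confusion_counts()] object.
#' @return An object of class `diagnostic_performance`: a list with
#'   elements `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `prevalence` (all proportions in \[0, 1\] or `NA`) and the `counts`.
#' @examples
#' compute_performance(confusion_counts(76, 48, 971, 0))
#' @export
compute_performance <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- do.call(confusion_counts, as.list(counts))
  }
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  structure(list(
    sensitivity = ratio_or_na(tp, tp + fn, "sensitivity"),
    specificity = ratio_or_na(tn, tn + fp, "specificity"),
    ppv         = ratio_or_na(tp, tp + fp, "positive predictive value"),
    npv         = ratio_or_na(tn, tn + fn, "negative predictive value"),
    accuracy    = (tp + tn) / total,
    prevalence  = (tp + fn) / total,
    counts      = counts
  ), class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, digits = 1, ...) {
  cat("Diagnostic performance (n =",
      with(x$counts, tp + fp + tn + fn), ")\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv",
              "accuracy", "prevalence")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(v)) "undefined" else
                  paste0(formatC(100 * v, format = "f", digits = digits), "%")))
  }
  invisible(x)
}

#' Decision-tree branch probabilities for a diagnostic test
#'
#' Converts disease prevalence (pre-test probability) and the test's
#' sensitivity and specificity into the probabilities of the four
#' decision-tree branches: true positive, false negative, true negative
#' and false positive. The four probabilities sum to one by construction.
#'
#' @param prevalence,sensitivity,specificity Proportions in \[0, 1\].
#' @return An object of class `branch_probabilities`: a named numeric
#'   vector with elements `TP`, `FN`, `TN`, `FP`.
#' @examples
#' branch_probabilities(0.07, 1.00, 0.97)
#' @export
branch_probabilities <- function(prevalence, sensitivity, specificity) {
  args <- c(prevalence = prevalence, sensitivity = sensitivity,
            specificity = specificity)
  bad <- !is.finite(args) | args < 0 | args > 1
  if (any(bad)) {
    stop("arguments must be proportions in [0, 1]; offending: ",
         paste(names(args)[bad], collapse = ", "), call. = FALSE)
  }
  p <- c(TP = prevalence * sensitivity,
         FN = prevalence * (1 - sensitivity),
         TN = (1 - prevalence) * specificity,
         FP = (1 - prevalence) * (1 - specificity))
  structure(p, class = "branch_probabilities")
}

#' @export
print.branch_probabilities <- function(x, ...) {
  cat("Branch probabilities:\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Sample a synthetic confusion table
#'
#' Draws a cohort of `n` patients: disease status is Bernoulli(prevalence),
#' then the test result is Bernoulli(sensitivity) for diseased and
#' Bernoulli(1 - specificity) for disease-free patients. Reproducible under
#' a fixed seed.
#'
#' @param n Number of patients (positive integer).
#' @param prevalence,sensitivity,specificity Proportions in \[0, 1\].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A [confusion_counts()] object.
#' @export
sample_confusion <- function(n, prevalence, sensitivity, specificity,
                             seed = NULL) {
  if (!is.finite(n) || n <= 0 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  branch_probabilities(prevalence, sensitivity, specificity)  # domain check
  with_seed(seed, {
    diseased <- stats::runif(n) < prevalence
    positive <- logical(n)
    positive[diseased] <- stats::runif(sum(diseased)) < sensitivity
    positive[!diseased] <- stats::runif(sum(!diseased)) >= specificity
    confusion_counts(tp = sum(diseased & positive),
                     fp = sum(!diseased & positive),
                     tn = sum(!diseased & !positive),
                     fn = sum(diseased & !positive))
  })
}
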