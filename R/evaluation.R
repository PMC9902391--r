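#' Confusion-matrix evaluation and cascade projection
#'
#' The positive class is DIC throughout. Five metrics summarize a
#' confusion matrix: accuracy ACC = (TP+TN)/(TP+FP+TN+FN), sensitivity
#' TPR = TP/(TP+FN), specificity TNR = TN/(TN+FP), positive predictive
#' value PPV = TP/(TP+FP) and negative predictive value NPV = TN/(TN+FN).
#' Metrics with a zero denominator are reported as `NA` (an explicit
#' undefined marker) rather than silently fabricated.
#'
#' @name evaluation
NULL

#' Tally a confusion matrix
#'
#' @param predicted,truth Character vectors of equal length with values
#'   `"DIC"` / `"nonDIC"`; positive class is DIC.
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  if (length(predicted) != length(truth))
    stop("length mismatch between predicted and truth", call. = FALSE)
  ok <- c("DIC", "nonDIC")
  if (!all(predicted %in% ok) || !all(truth %in% ok))
    stop("labels must be 'DIC' or 'nonDIC'", call. = FALSE)
  structure(list(
    TP = sum(predicted == "DIC" & truth == "DIC"),
    FP = sum(predicted == "DIC" & truth == "nonDIC"),
    FN = sum(predicted == "nonDIC" & truth == "DIC"),
    TN = sum(predicted == "nonDIC" & truth == "nonDIC")),
    class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' @param TP,FP,FN,TN Non-negative counts (at least one positive).
#' @return A `confusion_counts` list.
#' @export
confusion_counts_from <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0, TP + FP + FN + TN >= 1)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Metrics from a confusion matrix
#'
#' @param c A `confusion_counts` or a list/vector with `TP`, `FP`, `FN`,
#'   `TN`.
#' @return A `metrics_report` list of proportions `ACC`, `TPR`, `TNR`,
#'   `PPV`, `NPV` (NA where the denominator is zero).
#' @export
classification_metrics <- function(c) {
  c <- as.list(c)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(c, structure(list(
    ACC = safe(TP + TN, TP + FP + TN + FN),
    TPR = safe(TP, TP + FN),
    TNR = safe(TN, TN + FP),
    PPV = safe(TP, TP + FP),
    NPV = safe(TN, TN + FN)),
    class = "metrics_report"))
}

#' Project the cascade false-positive rate analytically
#'
#' For a population with `ratio` non-DIC per DIC and per-class stage
#' accuracies, the false-positive mass surviving k stages is
#' `ratio * prod(1 - nonDIC_accuracy_i)` and the surviving true-positive
#' mass is `prod(DIC_accuracy_i)`; the projected false-positive rate is
#' FP/(FP+TP).
#'
#' @param ratio_nonDIC_per_DIC Positive population ratio (e.g. 45).
#' @param stages List of 1 or 2 stage-rate pairs, each
#'   `c(nonDIC_accuracy, DIC_accuracy)` as proportions.
#' @return Projected false-positive rate as a proportion (NA if no mass
#'   survives).
#' @export
project_cascade_fpr <- function(ratio_nonDIC_per_DIC, stages) {
  stopifnot(ratio_nonDIC_per_DIC > 0,
            length(stages) >= 1, length(stages) <= 2)
  fp <- ratio_nonDIC_per_DIC
  tp <- 1
  for (s in stages) {
    s <- unlist(s)
    stopifnot(length(s) == 2, all(s >= 0 & s <= 1))
    fp <- fp * (1 - s[1])
    tp <- tp * s[2]
  }
  if (fp + tp <= 0) return(NA_real_)
  unname(fp / (fp + tp))
}

#' Accuracy on an expert-defined subgroup
#'
#' For a subgroup of n objects of which `misidentified` were wrongly
#' labelled, accuracy is (n - misidentified) / n.
#'
#' @param n Subgroup size.
#' @param misidentified Number misidentified.
#' @return Proportion.
#' @export
subgroup_accuracy <- function(n, misidentified) {
  stopifnot(n >= 1, misidentified >= 0, misidentified <= n)
  (n - misidentified) / n
}

#' Format a metrics table
#'
#' Renders counts and percentage metrics (rounded half-up to one decimal)
#' for one or two identification modes side by side.
#'
#' @param ... Named `confusion_counts`, e.g.
#'   `format_metrics_table("first-stage only" = c1, "two-stage" = c2)`.
#' @return Character vector of table lines, invisibly printed with `cat`
#'   when at the console.
#' @export
format_metrics_table <- function(...) {
  modes <- list(...)
  stopifnot(length(modes) >= 1)
  lines <- character(0)
  hdr <- sprintf("%-8s", "")
  for (nm in names(modes)) hdr <- paste0(hdr, sprintf("%-22s", nm))
  lines <- c(lines, hdr)
  cnt <- sprintf("%-8s", "counts")
  for (m in modes)
    cnt <- paste0(cnt, sprintf("TP=%-5d FP=%-6d     ", m$TP, m$FP))
  cnt2 <- sprintf("%-8s", "")
  for (m in modes)
    cnt2 <- paste0(cnt2, sprintf("FN=%-5d TN=%-6d     ", m$FN, m$TN))
  lines <- c(lines, cnt, cnt2)
  mets <- lapply(modes, classification_metrics)
  for (key in c("ACC", "TPR", "TNR", "PPV", "NPV")) {
    row <- sprintf("%-8s", key)
    for (m in mets) {
      v <- m[[key]]
      row <- paste0(row, if (is.na(v)) sprintf("%-22s", "undefined")
                    else sprintf("%-22s",
                                 paste0(round_half_up(100 * v, 1), "%")))
    }
    lines <- c(lines, row)
  }
  lines
}
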