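#' One-vs-rest confusion counts
#'
#' Tallies per-class TP/TN/FP/FN treating each class in turn as positive,
#' plus pooled (micro) counts as their sums. For every class,
#' `TP + TN + FP + FN` equals the number of evaluated items.
#'
#' @param predicted,truth equal-length label vectors.
#' @param classes the class set; labels outside it are an error. Defaults
#'   to the union of observed labels.
#' @return list of class `"confusionCounts"`: `perClass` (data.frame with
#'   rows per class), `pooled` (named numeric), `n`, `classes`.
#' @export
confusionCounts <- function(predicted, truth, classes = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("label vectors must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  if (!all(c(predicted, truth) %in% classes))
    stop("label outside the class set")
  per <- data.frame(class = classes, TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    per$TP[i] <- sum(predicted == cl & truth == cl)
    per$FP[i] <- sum(predicted == cl & truth != cl)
    per$FN[i] <- sum(predicted != cl & truth == cl)
    per$TN[i] <- sum(predicted != cl & truth != cl)
  }
  pooled <- c(TP = sum(per$TP), TN = sum(per$TN),
              FP = sum(per$FP), FN = sum(per$FN))
  structure(list(perClass = per, pooled = pooled, n = length(truth),
                 classes = classes),
            class = "confusionCounts")
}

## Metric formulas on a single TP/TN/FP/FN tally. The default dice
## follows the pipeline's original two-term form without FP;
## `standardDice` switches to 2TP/(2TP+FP+FN).
metricFormulas <- function(TP, TN, FP, FN, standardDice = FALSE) {
  sdiv <- function(num, den) if (den == 0) 0 else num / den
  c(accuracy = sdiv(TP + TN, TP + TN + FP + FN),
    precision = sdiv(TP, TP + FP),
    recall = sdiv(TP, TP + FN),
    dice = if (standardDice) sdiv(2 * TP, 2 * TP + FP + FN)
           else sdiv(2 * TP, 2 * TP + FN),
    jaccard = sdiv(TP, TP + FN + FP))
}

#' The six evaluation metrics from confusion counts
#'
#' Accuracy, precision, recall, F1, Dice and Jaccard. Per-class values use
#' one-vs-rest counts; `macro` averages them over classes; `micro` applies
#' the formulas to the pooled counts (for single-label multiclass data,
#' micro precision = micro recall = accuracy). The default Dice follows
#' the pipeline's original two-term form `2TP/(2TP+FN)` (no FP);
#' `standardDice = TRUE` restores the usual `2TP/(2TP+FP+FN)`. F1 is the
#' standard macro-F1 (mean of per-class `2PR/(P+R)`); the halved-sum
#' variant `sum(PR/(P+R))/2` is also reported as `f1_paper`. Zero
#' denominators yield 0 with a warning.
#'
#' @param counts a `"confusionCounts"` object, or a named vector/list with
#'   `TP`, `TN`, `FP`, `FN` (treated as one binary tally).
#' @param standardDice use the three-term Dice denominator.
#' @return for a single tally: named numeric with `accuracy`, `precision`,
#'   `recall`, `f1`, `dice`, `jaccard`. For multiclass counts: list with
#'   `accuracy`, `perClass` data.frame, `macro`, `micro` and `f1_paper`.
#' @export
metricSuite <- function(counts, standardDice = FALSE) {
  if (!inherits(counts, "confusionCounts")) {
    cc <- as.list(counts)
    if (sum(unlist(cc[c("TP", "TN", "FP", "FN")])) == 0)
      warning("all-zero confusion counts; metrics set to 0")
    m <- metricFormulas(cc$TP, cc$TN, cc$FP, cc$FN, standardDice)
    f1 <- if (m["precision"] + m["recall"] == 0) 0 else
      2 * m["precision"] * m["recall"] / (m["precision"] + m["recall"])
    return(c(m[c("accuracy", "precision", "recall")], f1 = unname(f1),
             m[c("dice", "jaccard")]))
  }
  per <- counts$perClass
  rows <- lapply(seq_len(nrow(per)), function(i)
    metricFormulas(per$TP[i], per$TN[i], per$FP[i], per$FN[i], standardDice))
  pm <- do.call(rbind, rows)
  f1c <- ifelse(pm[, "precision"] + pm[, "recall"] == 0, 0,
                2 * pm[, "precision"] * pm[, "recall"] /
                  (pm[, "precision"] + pm[, "recall"]))
  perClass <- data.frame(class = per$class, pm, f1 = f1c)
  macro <- c(precision = mean(pm[, "precision"]),
             recall = mean(pm[, "recall"]),
             f1 = mean(f1c),
             dice = mean(pm[, "dice"]),
             jaccard = mean(pm[, "jaccard"]))
  p <- counts$pooled
  micro <- metricFormulas(p[["TP"]], p[["TN"]], p[["FP"]], p[["FN"]],
                          standardDice)
  microF1 <- if (micro["precision"] + micro["recall"] == 0) 0 else
    2 * micro["precision"] * micro["recall"] /
      (micro["precision"] + micro["recall"])
  accuracy <- sum(per$TP) / counts$n   # multiclass accuracy = trace/n
  list(accuracy = accuracy, perClass = perClass, macro = macro,
       micro = c(micro[c("accuracy", "precision", "recall")],
                 f1 = unname(microF1), micro[c("dice", "jaccard")]),
       f1_paper = sum(ifelse(pm[, "precision"] + pm[, "recall"] == 0, 0,
                             pm[, "precision"] * pm[, "recall"] /
                               (pm[, "precision"] + pm[, "recall"]))) / 2)
}
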