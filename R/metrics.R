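#' One-vs-rest confusion counts for a class
#'
#' @param pred,truth [LabelMask-class] objects or integer matrices of equal
#'   dimensions.
#' @param classCode the class to count (1 = periderm by default).
#' @return `list(TP =, FP =, FN =)` pixel counts.
#' @export
confusionCounts <- function(pred, truth, classCode = 1L) {
  p <- maskLabels(pred); t <- maskLabels(truth)
  if (!all(dim(p) == dim(t)))
    stop("dimension mismatch: pred is ", paste(dim(p), collapse = "x"),
         ", truth is ", paste(dim(t), collapse = "x"))
  pp <- p == classCode; tp <- t == classCode
  list(TP = sum(pp & tp), FP = sum(pp & !tp), FN = sum(!pp & tp))
}

#' Precision from confusion counts
#'
#' TP / (TP + FP); returns 0 (with a note) when no pixel was predicted
#' positive.
#'
#' @param counts list with TP and FP (from [confusionCounts()]).
#' @return precision in [0, 1].
#' @export
precisionScore <- function(counts) {
  den <- counts$TP + counts$FP
  if (den == 0) {
    .msg("precision: no predicted positives; returning 0 by convention")
    return(0)
  }
  counts$TP / den
}

#' Recall from confusion counts
#'
#' TP / (TP + FN); returns 0 (with a note) when the truth has no positives.
#'
#' @param counts list with TP and FN (from [confusionCounts()]).
#' @return recall in [0, 1].
#' @export
recallScore <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) {
    .msg("recall: no true positives in the reference; returning 0 by convention")
    return(0)
  }
  counts$TP / den
}

#' F1 score: harmonic mean of precision and recall
#'
#' 2PR / (P + R), and 0 when P + R = 0.
#'
#' @param precision,recall values in [0, 1].
#' @return F1 in [0, 1].
#' @export
#' @examples
#' f1Score(0.904, 0.865)   # 0.884 to 3 decimals
f1Score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Pixel-level benchmark of predicted masks against expert annotation
#'
#' Computes per-slide, per-class precision, recall and F1 (one-vs-rest
#' counting) for predictions before and, when given, after postprocessing,
#' plus unweighted averages across slides per class and stage.
#'
#' @param predBefore list of predicted [LabelMask-class], one per slide.
#' @param truth list of ground-truth masks, paired with `predBefore`.
#' @param predAfter optional list of post-processed predictions.
#' @param slideIds slide identifiers (default slide1, slide2, ...).
#' @param classes named integer vector of classes to score (default: the
#'   non-background classes).
#' @return data.frame (slide, class, stage, TP, FP, FN, precision, recall,
#'   f1) with average rows (`slide == "average"`) appended.
#' @export
benchmarkSlides <- function(predBefore, truth, predAfter = NULL,
                            slideIds = paste0("slide", seq_along(predBefore)),
                            classes = peridermClasses()[-1]) {
  if (length(predBefore) != length(truth))
    stop("unpaired slides: ", length(predBefore), " predictions vs ",
         length(truth), " truths")
  if (!is.null(predAfter) && length(predAfter) != length(truth))
    stop("unpaired slides in predAfter")
  stages <- list(before = predBefore)
  if (!is.null(predAfter)) stages$after <- predAfter
  rows <- list()
  for (stage in names(stages)) {
    for (i in seq_along(truth)) {
      for (ci in seq_along(classes)) {
        cc <- confusionCounts(stages[[stage]][[i]], truth[[i]], classes[ci])
        P <- if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP)
        R <- if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN)
        rows[[length(rows) + 1]] <- data.frame(
          slide = slideIds[i], class = names(classes)[ci], stage = stage,
          TP = cc$TP, FP = cc$FP, FN = cc$FN,
          precision = P, recall = R, f1 = f1Score(P, R),
          stringsAsFactors = FALSE)
      }
    }
  }
  rep <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(split(rep, rep[, c("class", "stage")]),
    function(g) data.frame(slide = "average", class = g$class[1],
                           stage = g$stage[1], TP = NA, FP = NA, FN = NA,
                           precision = mean(g$precision),
                           recall = mean(g$recall), f1 = mean(g$f1),
                           stringsAsFactors = FALSE)))
  rownames(avg) <- NULL
  rbind(rep, avg)
}

#' Render a benchmark report as an aligned text table
#'
#' @param report data.frame from [benchmarkSlides()].
#' @param class which class to show (default periderm).
#' @return character vector of lines, invisibly; also printed.
#' @export
renderMetricsTable <- function(report, class = "periderm") {
  rep <- report[report$class == class, ]
  lines <- character(0)
  for (sl in unique(rep$slide)) {
    lines <- c(lines, sprintf("%s\tPrecision\tRecall\tF1 score", sl))
    for (st in unique(rep$stage[rep$slide == sl])) {
      row <- rep[rep$slide == sl & rep$stage == st, ]
      lines <- c(lines, sprintf("%s postprocessing\t%.3f\t%.3f\t%.3f",
                                if (st == "before") "Before" else "After",
                                row$precision, row$recall, row$f1))
    }
    lines <- c(lines, "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a benchmark report CSV
#' @param report data.frame from [benchmarkSlides()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMetricsCSV <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
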