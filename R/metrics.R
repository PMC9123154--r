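# Pixel-wise segmentation evaluation.

#' Pixel-wise confusion counts between a segmentation and ground truth
#'
#' @param seg,gt [BinaryMask-class]s (or binary matrices/arrays) of identical
#'   shape; \code{seg} is the prediction
#' @return a [ConfusionCounts-class]
#' @export
confusionCounts <- function(seg, gt) {
  s <- if (is(seg, "BinaryMask")) seg@data else seg
  g <- if (is(gt, "BinaryMask")) gt@data else gt
  if (!all(dim(s) == dim(g)))
    stop("shape mismatch between segmentation and ground truth", call. = FALSE)
  if (!all(s %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  new("ConfusionCounts",
      TP = sum(s == 1 & g == 1), FP = sum(s == 1 & g == 0),
      TN = sum(s == 0 & g == 0), FN = sum(s == 0 & g == 1))
}

.safeRatio <- function(num, den, name, flags) {
  if (den == 0) {
    flags$v <- c(flags$v, name)
    return(0)
  }
  num / den
}

#' Compute the segmentation metric suite from confusion counts
#'
#' \itemize{
#' \item Acc = (TP+TN)/total, ER = (FP+FN)/total (complementary: Acc+ER = 1)
#' \item Se = TP/(TP+FN), Sp = TN/(TN+FP), P = TP/(TP+FP)
#' \item Vs = 1 - |FN-FP| / (2TP+FP+FN) (volumetric similarity; the absolute
#'   difference of the volumes over their sum)
#' \item DSC = 2TP/(2TP+FP+FN) x 100\%, JC = TP/(TP+FP+FN) x 100\% (the
#'   count forms of the Dice and Jaccard overlap of the two masks)
#' }
#' Ratios with zero denominators are reported as 0 and flagged
#' \code{degenerate} rather than raising.
#'
#' @param cc a [ConfusionCounts-class], or a segmentation mask (then
#'   \code{gt} must be given)
#' @param gt optional ground-truth mask
#' @return a [MetricsReport-class]
#' @examples
#' r <- computeMetrics(new("ConfusionCounts", TP = 90, FP = 10, TN = 890, FN = 10))
#' r@values[["DSC"]]  # 90
#' @export
computeMetrics <- function(cc, gt = NULL) {
  if (!is(cc, "ConfusionCounts")) cc <- confusionCounts(cc, gt)
  TP <- cc@TP; FP <- cc@FP; TN <- cc@TN; FN <- cc@FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  flags <- new.env()
  flags$v <- character()
  vals <- c(
    Acc = (TP + TN) / total,
    Se  = .safeRatio(TP, TP + FN, "Se", flags),
    Sp  = .safeRatio(TN, TN + FP, "Sp", flags),
    P   = .safeRatio(TP, TP + FP, "P", flags),
    ER  = (FP + FN) / total,
    Vs  = if (2 * TP + FP + FN == 0) { flags$v <- c(flags$v, "Vs"); 0 }
          else 1 - abs(FN - FP) / (2 * TP + FP + FN),
    DSC = if (2 * TP + FP + FN == 0) { flags$v <- c(flags$v, "DSC"); 0 }
          else 2 * TP / (2 * TP + FP + FN) * 100,
    JC  = if (TP + FP + FN == 0) { flags$v <- c(flags$v, "JC"); 0 }
          else TP / (TP + FP + FN) * 100
  )
  new("MetricsReport", values = vals, counts = cc, flags = unique(flags$v))
}

#' ROC area under the curve for a soft score map
#'
#' Sweeps thresholds over [0, 1] (\code{nThresholds} evenly spaced levels
#' plus the (0,0)/(1,1) endpoints), classifies \code{score >= t} as lesion,
#' and integrates TPR over FPR by the trapezoidal rule. A constant score map
#' yields 0.5 (chance) by construction.
#'
#' @param score numeric field in [0, 1] (matrix, array, or [VolumeImage-class])
#' @param gt ground-truth [BinaryMask-class] (or binary array) containing
#'   both classes
#' @param nThresholds number of threshold levels (default 256)
#' @return AUC in [0, 1]
#' @export
rocAuc <- function(score, gt, nThresholds = 256) {
  s <- if (is(score, "VolumeImage")) score@data else score
  g <- if (is(gt, "BinaryMask")) gt@data else gt
  if (!all(dim(s) == dim(g))) stop("shape mismatch", call. = FALSE)
  pos <- sum(g == 1); neg <- sum(g == 0)
  if (pos == 0 || neg == 0)
    stop("ground truth must contain both classes", call. = FALSE)
  th <- seq(0, 1, length.out = nThresholds)
  tpr <- fpr <- numeric(nThresholds)
  for (i in seq_along(th)) {
    pred <- s >= th[i]
    tpr[i] <- sum(pred & g == 1) / pos
    fpr[i] <- sum(pred & g == 0) / neg
  }
  fpr <- c(1, fpr, 0); tpr <- c(1, tpr, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Peak signal-to-noise ratio
#'
#' \code{10 log10(peak^2 / MSE)} in dB; identical inputs give \code{Inf}.
#' The default peak of 255 matches the MR gray-level convention.
#'
#' @param reference,test [VolumeImage-class]s (or arrays) of identical shape
#' @param peak peak intensity (default 255)
#' @return PSNR in dB
#' @export
psnr <- function(reference, test, peak = 255) {
  r <- if (is(reference, "VolumeImage")) reference@data else reference
  t <- if (is(test, "VolumeImage")) test@data else test
  if (!all(dim(r) == dim(t))) stop("shape mismatch", call. = FALSE)
  mse <- mean((r - t)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Tabulate metric reports
#'
#' One row per case with the column names Acc, Se, Sp, P, ER, Vs, DSC, JC,
#' AUC, PSNR (AUC/PSNR are NA when not supplied).
#'
#' @param reports list of [MetricsReport-class] (optionally named by case)
#' @param auc,psnr optional numeric vectors aligned with \code{reports}
#' @return data.frame
#' @export
metricsTable <- function(reports, auc = NULL, psnr = NULL) {
  if (is(reports, "MetricsReport")) reports <- list(reports)
  base <- c("Acc", "Se", "Sp", "P", "ER", "Vs", "DSC", "JC")
  rows <- lapply(seq_along(reports), function(i) {
    v <- reports[[i]]@values[base]
    data.frame(t(v),
               AUC = if (is.null(auc)) NA_real_ else auc[i],
               PSNR = if (is.null(psnr)) NA_real_ else psnr[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(reports)
  out
}

#' Write a metrics table to CSV and/or JSON
#'
#' @param tab data.frame from [metricsTable()]
#' @param csv,json optional output paths
#' @return \code{tab}, invisibly
#' @export
writeMetricsReport <- function(tab, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(tab, json, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
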