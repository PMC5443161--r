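# Bundled reference data.

#' Reference pooled confusion matrix (ODCS3-DDAG)
#'
#' The bundled 3x3 count matrix of a ternary readiness-potential classifier
#' (reliability-weighted fusion of the best three algorithms at each DDAG
#' node), pooled over ten test folds and fourteen participants. Rows are the
#' correct class, columns the predicted class, in (R, I, L) order. It serves
#' as a worked example for [cohen_kappa()] and [per_class_accuracy()]:
#' idle epochs are recognized almost perfectly while most left/right errors
#' are lateral confusions between the two movement classes, reflecting the
#' bilateral (if asymmetric) motor-cortical origin of the readiness
#' potential.
#'
#' @return A `confusion_matrix`.
#' @examples
#' cm <- reference_confusion_odcs3_ddag()
#' cohen_kappa(cm)
#' round(100 * per_class_accuracy(cm), 2)
#' @export
reference_confusion_odcs3_ddag <- function() {
  path <- system.file("extdata", "odcs3_ddag_confusion.csv",
                      package = "rpbci", mustWork = TRUE)
  counts <- data.table::fread(path)
  as_confusion_matrix(as.matrix(counts[, -1, with = FALSE]))
}
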