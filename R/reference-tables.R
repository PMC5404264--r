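#' Reference confusion matrices from the original myoepithelial-nucleus study
#'
#' The six published confusion matrices of the four-histotype SVM classifier
#' on real slides, transcribed from the original study's result tables: cell,
#' duct and patient level, for p63 immunohistochemistry and HE staining.
#' They are the benchmark the evaluation layer is checked against — feeding
#' them through \code{\link{accuracy}}, \code{\link{cohen_kappa}} and
#' \code{\link{collapse_classes}} reproduces every published accuracy and
#' kappa value after rounding.
#'
#' @return Named list of six \code{confusion_matrix} objects:
#'   \code{cell_p63}, \code{cell_he}, \code{duct_p63}, \code{duct_he},
#'   \code{patient_p63}, \code{patient_he}.
#' @examples
#' tabs <- reference_tables()
#' accuracy(tabs$patient_p63)                      # 90.9
#' cohen_kappa(collapse_classes(tabs$cell_p63))    # 0.43
#' @export
reference_tables <- function() {
  cls <- histotype_levels()
  mk <- function(v) {
    m <- matrix(as.integer(v), 4, 4, byrow = TRUE,
                dimnames = list(actual = cls, predicted = cls))
    class(m) <- c("confusion_matrix", class(m))
    m
  }
  list(
    cell_p63 = mk(c(625, 150, 31, 18,
                    265, 330, 84, 13,
                    115, 103, 293, 34,
                    145, 91, 84, 40)),
    cell_he = mk(c(263, 85, 30, 8,
                   149, 133, 34, 5,
                   57, 24, 110, 8,
                   52, 35, 61, 18)),
    duct_p63 = mk(c(13, 0, 0, 1,
                    1, 12, 2, 1,
                    0, 3, 13, 5,
                    2, 2, 2, 13)),
    duct_he = mk(c(9, 4, 0, 1,
                   2, 8, 2, 3,
                   1, 1, 18, 1,
                   0, 2, 7, 10)),
    patient_p63 = mk(c(7, 0, 0, 0,
                       0, 5, 0, 0,
                       0, 0, 4, 1,
                       0, 1, 0, 4)),
    patient_he = mk(c(5, 1, 0, 1,
                      0, 4, 1, 0,
                      0, 0, 5, 0,
                      0, 0, 1, 4))
  )
}

#' Recompute all metrics of the reference tables
#'
#' For each reference matrix, computes the four-class accuracy and kappa and
#' the benign-vs-DCIS collapsed two-class accuracy and kappa.
#'
#' @return data.frame with one row per reference table and columns
#'   \code{table}, \code{acc4}, \code{kappa4}, \code{acc2}, \code{kappa2}.
#' @export
reference_metrics <- function() {
  tabs <- reference_tables()
  out <- lapply(names(tabs), function(nm) {
    cm <- tabs[[nm]]
    cm2 <- collapse_classes(cm)
    data.frame(table = nm,
               acc4 = accuracy(cm), kappa4 = cohen_kappa(cm),
               acc2 = accuracy(cm2), kappa2 = cohen_kappa(cm2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
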