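# Readers/writers for the pipeline's tabular and contour artifacts.

#' Write a table with schema metadata
#'
#' Plain CSV with the producing package version and seed embedded as a
#' comment header line.
#'
#' @param records data.frame.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# myomorph %s seed=%s",
                     as.character(utils::packageVersion("myomorph")), seed),
             con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by \code{\link{write_table}}, checking its schema
#'
#' @param path CSV path.
#' @param required_cols column names that must be present; a missing column
#'   raises an error naming it.
#' @return data.frame.
#' @export
read_table <- function(path, required_cols = character(0)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df
}

#' Serialize contours to JSON
#'
#' Per-ROI list of closed vertex arrays ((row, col), 1-based); round-trips
#' losslessly through \code{\link{read_contours}}.
#'
#' @param contours list of \code{nucleus_contour}s.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_contours <- function(contours, path) {
  payload <- lapply(contours, function(con)
    list(vertices = unname(as.matrix(con$vertices)),
         centroid = as.numeric(con$centroid)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read contours written by \code{\link{write_contours}}
#'
#' @param path JSON path.
#' @return List of \code{nucleus_contour}s.
#' @export
read_contours <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                                simplifyDataFrame = FALSE)
  lapply(payload, function(el) {
    v <- el$vertices
    if (!is.matrix(v)) v <- do.call(rbind, v)
    structure(list(vertices = cbind(row = v[, 1], col = v[, 2]),
                   centroid = as.numeric(unlist(el$centroid))),
              class = "nucleus_contour")
  })
}
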