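`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Format numbers in scientific notation with 3 significant digits
#'
#' Serialization helper for p-values and FDRs in result tables, e.g.
#' `1.39e-06` is rendered as `"1.39E-06"`.
#'
#' @param x numeric vector
#' @return character vector; `NA` stays `"NA"`
#' @export
format_sci3 <- function(x) {
  out <- toupper(formatC(x, format = "e", digits = 2))
  out[is.na(x)] <- "NA"
  out
}

#' Intersect sample ids across tables
#'
#' Any operation that joins two tables works on the intersection of their
#' sample ids and reports how many were dropped from each side.
#'
#' @param ... two or more character vectors of sample ids
#' @param context label used in the message
#' @return character vector of shared ids, in the order of the first argument
#' @keywords internal
align_samples <- function(..., context = "join") {
  sets <- list(...)
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0L) stopf("[%s] no samples shared between tables", context)
  dropped <- vapply(sets, function(s) length(setdiff(s, shared)), integer(1))
  if (any(dropped > 0L)) {
    message(sprintf("[%s] dropped %s sample(s) not shared by all tables",
                    context, paste(dropped, collapse = "/")))
  }
  sets[[1L]][sets[[1L]] %in% shared]
}
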