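#' Turn a fitted object into a tidy tibble
#'
#' Generic for one-row-per-term summaries of objects fitted by this package
#' (threshold fits, reliability fits, full analysis reports).
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model-level summary of a fitted object
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
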