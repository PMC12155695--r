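#' Below-LLQ data correction techniques
#'
#' The three substitution rules commonly used for concentration data beneath
#' the assay's lower limit of quantification:
#' \describe{
#'   \item{M5}{replace every below-LLQ value with `LLQ / 2`.}
#'   \item{M6}{within each maximal consecutive run of below-LLQ points,
#'     replace the first with `LLQ / 2` and remove the rest from the
#'     series.}
#'   \item{M7}{replace every below-LLQ value with 0.}
#' }
#' `"none"` is the identity. A series may be corrected at most once;
#' applying a correction to an already-corrected series is an error.
#' Below-LLQ flags are preserved on retained points so downstream code can
#' still see which observations were censored.
#'
#' @param series an [observation_series()] with `correction == "none"`.
#' @param method one of `"none"`, `"M5"`, `"M6"`, `"M7"`.
#' @return The corrected [observation_series()] with its `correction` tag
#'   set.
#' @examples
#' s <- observation_series(1:4, c(0.5, 0.1, 0.05, 0.3), "VEGF", llq = 0.2)
#' apply_correction(s, "M5")$value # 0.5 0.1 0.1 0.3
#' @export
apply_correction <- function(series, method = c("none", "M5", "M6", "M7")) {
  method <- match.arg(method)
  if (!inherits(series, "observation_series"))
    stop("'series' must be an observation_series")
  if (any(series$correction != "none"))
    stop("series already corrected (", series$correction[1],
         "); corrections must not be stacked")
  if (anyNA(series$llq)) stop("series has no LLQ defined")
  out <- series
  below <- series$below_llq == 1
  if (method == "M5") {
    out$value[below] <- out$llq[below] / 2
  } else if (method == "M7") {
    out$value[below] <- 0
  } else if (method == "M6") {
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- rep(TRUE, nrow(out))
    for (i in seq_along(runs$values)) {
      if (runs$values[i]) {
        out$value[starts[i]] <- out$llq[starts[i]] / 2
        if (runs$lengths[i] > 1)
          keep[(starts[i] + 1):ends[i]] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out$correction <- method
  class(out) <- c("observation_series", "data.frame")
  out
}
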