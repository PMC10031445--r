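# Traffic-light status vocabulary shared by every module.

#' Traffic-light status levels
#'
#' The engine classifies every element and parameter into one of four
#' statuses: `"green"` (healthy), `"orange"` (middle, room for improvement),
#' `"red"` (needs improvement) and `"gray"` (undetermined because required
#' inputs are missing). Only the first three are ranked by severity; gray
#' never participates in severity comparison.
#'
#' @format Character vectors of status names.
#' @name traffic_statuses
NULL

#' @rdname traffic_statuses
#' @export
STATUS_LEVELS <- c("green", "orange", "red", "gray")

#' @rdname traffic_statuses
#' @export
RANKED_STATUSES <- c("green", "orange", "red")

#' Severity rank of a traffic-light status
#'
#' @param status character vector of statuses.
#' @return Integer vector: green = 0, orange = 1, red = 2, gray = `NA`
#'   (gray is unranked).
#' @examples
#' status_rank(c("green", "red", "gray"))
#' @export
status_rank <- function(status) {
  bad <- !status %in% STATUS_LEVELS
  if (any(bad)) {
    stop("unknown status value(s): ", paste(unique(status[bad]), collapse = ", "))
  }
  r <- match(status, RANKED_STATUSES) - 1L
  r  # gray -> NA by construction
}

assert_status <- function(status) {
  if (length(status) != 1L || !is.character(status) || !status %in% STATUS_LEVELS) {
    stop("not a valid traffic-light status: ", deparse(status))
  }
  invisible(status)
}
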