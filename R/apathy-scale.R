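#' Score a 14-item Apathy Scale response
#'
#' Each of the 14 questionnaire items is answered on a four-point ordinal
#' scale (No = 0, A little = 1, Yes = 2, Very = 3); the instrument's total
#' is the plain sum of the item points, so totals range from 0 to 42.
#'
#' @param response integer vector of length 14 with values in 0..3.
#' @return Integer total score in `[0, 42]`.
#' @examples
#' scoreResponse(rep(3, 14))  # 42
#' @seealso [classifyScore()]
#' @export
scoreResponse <- function(response) {
  if (length(response) != 14L)
    stop("a questionnaire response must have exactly 14 items, got ",
         length(response))
  response <- as.numeric(response)
  bad <- which(is.na(response) | response != round(response) |
                 response < 0 | response > 3)
  if (length(bad))
    stop(sprintf("item %d has value outside {0, 1, 2, 3}", bad[1]))
  as.integer(sum(response))
}

#' Classify an Apathy Scale total score
#'
#' A total of 16 or more on the Japanese-version Apathy Scale is judged
#' apathetic; 15 or less is non-apathetic.
#'
#' @param score integer total score(s) in `[0, 42]`.
#' @return Factor with levels `apathy`, `non-apathy`, same length as
#'   `score`.
#' @examples
#' classifyScore(c(15, 16))
#' @export
classifyScore <- function(score) {
  score <- as.numeric(score)
  if (any(is.na(score) | score < 0 | score > 42))
    stop("scores must lie in [0, 42]")
  factor(ifelse(score >= 16, "apathy", "non-apathy"), levels = APATHY_LEVELS)
}
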