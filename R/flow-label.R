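#' Binary "full flow" labels from Flow State Scale responses
#'
#' The transformation of time sits at the top of the difficulty hierarchy
#' of the nine flow elements: it is the last element to be endorsed as
#' immersion deepens. A task is therefore labeled a full flow state (1)
#' when its transformation-of-time rating is "agree" or "strongly agree"
#' (>= 3 on the 0..4 coding), and 0 otherwise.
#'
#' @param responses Integer matrix or data frame of ratings in 0..4 with a
#'   `transformation_of_time` column (nine unnamed columns are assigned the
#'   canonical flow-element names).
#' @param agree_threshold Minimum rating counted as endorsement (default 3).
#' @return Integer vector of 0/1 labels, one per row.
#' @export
label_flow <- function(responses, agree_threshold = 3L) {
  X <- as.matrix(responses)
  if (is.null(colnames(X)) && ncol(X) == 9L) colnames(X) <- FSS_ITEMS
  if (!"transformation_of_time" %in% colnames(X)) {
    abort_flowsense("responses lack a transformation_of_time column", "flowsense_validation_error")
  }
  tot <- X[, "transformation_of_time"]
  if (anyNA(tot)) {
    abort_flowsense(
      sprintf("missing transformation_of_time rating in row(s) %s",
              paste(which(is.na(tot)), collapse = ", ")),
      "flowsense_validation_error"
    )
  }
  as.integer(tot >= agree_threshold)
}
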