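#' Canonical condition labels
#'
#' The neural analysis crosses three binary stimulus attributes: elicited
#' aesthetic experience (high/low "moving"), stimulation modality
#' (perception/imagery) and stimulus type (art/face). The eight resulting
#' conditions are always kept in the canonical order HPA, LPA, HPF, LPF,
#' HIA, LIA, HIF, LIF (e.g. "HPA" = high-experience perception artwork).
#'
#' @return Character vector of the 8 condition labels in canonical order.
#' @export
#' @examples
#' condition_labels()
condition_labels <- function() {
  c("HPA", "LPA", "HPF", "LPF", "HIA", "LIA", "HIF", "LIF")
}

#' Condition factor table
#'
#' @return A data.frame with one row per canonical condition and columns
#'   `label`, `experience` ("high"/"low"), `modality`
#'   ("perception"/"imagery") and `type` ("art"/"face").
#' @export
condition_table <- function() {
  lab <- condition_labels()
  data.frame(
    label = lab,
    experience = ifelse(substr(lab, 1, 1) == "H", "high", "low"),
    modality = ifelse(substr(lab, 2, 2) == "P", "perception", "imagery"),
    type = ifelse(substr(lab, 3, 3) == "A", "art", "face"),
    stringsAsFactors = FALSE
  )
}
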