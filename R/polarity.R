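#' Admissible causal-link polarities
#'
#' Every causal link in a causal-loop diagram carries exactly one of two
#' polarities: \code{"positive"} (the target moves the same way as the
#' source) or \code{"negative"} (the target moves the opposite way).
#'
#' @return Character vector \code{c("positive", "negative")}.
#' @export
polarities <- function() c("positive", "negative")

#' The five stakeholder data sources
#'
#' Closed enumeration of the provenance tags a variable or link can carry:
#' rural veterans, non-VA clinic staff, VA health-system informants,
#' veteran service officers (VSOs), and links imputed by the modeling team.
#'
#' @return Character vector of the five source names.
#' @export
stakeholder_sources <- function() {
  c("veteran", "non_va_clinic", "va_system", "vso", "modeler")
}

#' Parse a polarity token
#'
#' Accepts the sign dialects found in coded notes and in web-platform
#' connection tables: \code{"+"}, \code{"-"}, the Unicode minus
#' \code{"−"}, \code{"same"}/\code{"opposite"}, and the canonical
#' \code{"positive"}/\code{"negative"} (case-insensitive).
#'
#' @param token Character vector of polarity tokens.
#' @return Character vector of \code{"positive"}/\code{"negative"}.
#' @export
#' @examples
#' parse_polarity(c("+", "opposite", "Same"))
parse_polarity <- function(token) {
  tok <- tolower(trimws(as.character(token)))
  out <- character(length(tok))
  pos <- tok %in% c("+", "same", "positive", "pos")
  neg <- tok %in% c("-", "−", "–", "opposite", "negative", "neg")
  bad <- !(pos | neg)
  if (any(bad)) {
    cld_stop(sprintf("unrecognized polarity token(s): %s",
                     paste(unique(tok[bad]), collapse = ", ")),
             "cld_parse_error")
  }
  out[pos] <- "positive"
  out[neg] <- "negative"
  out
}

polarity_sign <- function(polarity) ifelse(polarity == "negative", -1L, 1L)
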