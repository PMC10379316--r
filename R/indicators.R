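#' Quality indicators tracked during frozen storage
#'
#' The five biochemical indicators measured on common carp fillets: two lipid
#' markers that rise during storage (TBARS from oxidation, FFA from
#' hydrolysis) and three myofibrillar-protein markers that fall (salt-soluble
#' protein, Ca2+-ATPase activity, total sulfhydryl content).
#'
#' @return A data frame with one row per indicator and columns
#'   \code{indicator} (canonical name), \code{unit_label} (the unit the values
#'   are reported in; labels only, never converted), and \code{direction}
#'   (\code{"increasing"} or \code{"decreasing"} under storage).
#' @examples
#' indicator_table()
#' @export
indicator_table <- function() {
  data.frame(
    indicator = c("TBARS", "FFA", "SSP", "CA_ATPASE", "SH"),
    unit_label = c(
      "mg MDA/kg",
      "g FFA/100 g lipid",
      "mg/g",
      "umol Pi/mg/min",
      "mol/10^5 g"
    ),
    direction = c(
      "increasing", "increasing",
      "decreasing", "decreasing", "decreasing"
    ),
    stringsAsFactors = FALSE
  )
}

#' Canonical indicator names
#' @return Character vector of the five indicator names, in canonical order.
#' @export
indicator_names <- function() indicator_table()$indicator

#' Direction of change of an indicator under frozen storage
#' @param indicator Character vector of indicator names.
#' @return \code{"increasing"} or \code{"decreasing"} per element.
#' @export
indicator_direction <- function(indicator) {
  tab <- indicator_table()
  idx <- match(indicator, tab$indicator)
  if (anyNA(idx)) {
    stop("unknown indicator(s): ",
         paste(unique(indicator[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  tab$direction[idx]
}
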