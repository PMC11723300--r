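#' Published class-1 priority table for the Tianshan survey
#'
#' The 23 wild medicinal plant species placed in the top conservation class
#' by the published 101-species survey of the Tianshan wild fruit forest:
#' species, IUCN red-list label (empty when not listed), family, composite
#' AHP value, local-endemism flag and growth form.
#'
#' @return data.frame with 23 rows.
#' @export
tianshan_class1 <- function() {
  utils::read.csv(system.file("extdata", "tianshan_class1.csv",
                              package = "barcodeval"),
                  stringsAsFactors = FALSE, na.strings = NULL)
}

#' Survey composition tallies for the Tianshan flora
#'
#' IUCN red-list category counts (EN, NT, DD, LC, and NII for species not in
#' the red list) and growth-form counts for the 101 surveyed species.
#'
#' @return data.frame with columns \code{group}, \code{category},
#'   \code{count}.
#' @export
tianshan_survey <- function() {
  utils::read.csv(system.file("extdata", "tianshan_survey.csv",
                              package = "barcodeval"),
                  stringsAsFactors = FALSE)
}
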