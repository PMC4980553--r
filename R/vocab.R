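#' Closed vocabularies and intensity cut points
#'
#' The package works with a fixed six-level food-group coding shared by the
#' momentary instrument and the dietary recall, and a four-level physical
#' activity intensity coding. Accelerometer epochs (counts per minute, CPM)
#' are classified with the Freedson cut points: sedentary below 100 CPM,
#' light 100-1951 CPM, moderate 1952-5724 CPM, vigorous 5725 CPM and above.
#'
#' @name vocab
#' @keywords internal
NULL

#' Food-group vocabulary
#'
#' @return Character vector of the six food-group codes.
#' @export
food_groups <- function() {
  c("sweets", "salty", "fruits_vegetables", "entree", "breads_grains", "other")
}

#' Physical activity intensity levels
#'
#' @return Character vector of the four intensity levels, ordered from
#'   sedentary to vigorous. The instrument label "strenuous" is mapped to
#'   "vigorous" at ingest.
#' @export
pa_levels <- function() {
  c("sedentary", "light", "moderate", "vigorous")
}

#' Freedson intensity cut points
#'
#' Lower band edges in counts per minute. Bands are left-closed: a value
#' equal to an edge belongs to the higher band (100 is light, 1952 moderate,
#' 5725 vigorous); the bands partition the nonnegative reals.
#'
#' @return Named numeric vector of lower band edges.
#' @export
intensity_cutpoints <- function() {
  c(sedentary = 0, light = 100, moderate = 1952, vigorous = 5725)
}

#' Classify counts-per-minute values into intensity levels
#'
#' @param cpm Numeric vector of nonnegative CPM values.
#' @return Factor with levels `pa_levels()`.
#' @examples
#' classify_intensity(c(0, 99, 100, 1951, 1952, 5724, 5725))
#' @export
classify_intensity <- function(cpm) {
  if (!is.numeric(cpm)) stop("`cpm` must be numeric", call. = FALSE)
  bad <- !is.na(cpm) & cpm < 0
  if (any(bad)) {
    stop("negative CPM value(s): ", paste(utils::head(cpm[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  edges <- intensity_cutpoints()
  idx <- findInterval(cpm, edges)
  factor(pa_levels()[idx], levels = pa_levels())
}

# internal: semicolon-joined set columns used in the delimited-text schemas
fg_join <- function(x) vapply(x, paste, character(1), collapse = ";")

fg_split <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# internal: does the joined set column contain `group`?
fg_has <- function(x, group) {
  vapply(fg_split(x), function(v) group %in% v, logical(1))
}
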