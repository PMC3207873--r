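# Icon-array pictographs: 100 person-icons, the expected number affected
# highlighted. Denominator 100 matches the integer-percent display; fill
# order is left-to-right, top-to-bottom, so output is byte-deterministic.

ICON_COLOURS <- c(stroke = "#b2182b", major_bleed = "#2166ac")
ICON_UNAFFECTED <- "#cccccc"

#' Build an icon array from a risk estimate
#'
#' The affected count equals the estimate's rounded integer percent for the
#' chosen outcome, out of a fixed denominator of 100.
#'
#' @param estimate A `risk_estimate`.
#' @param outcome `"stroke"` or `"major_bleed"`.
#' @return An object of class `icon_array`: list with `denominator` (100),
#'   `affected`, `outcome`, `option`.
#' @export
build_icon_array <- function(estimate, outcome = c("stroke", "major_bleed")) {
  stopifnot(inherits(estimate, "risk_estimate"))
  outcome <- match.arg(outcome)
  affected <- if (outcome == "stroke") estimate$stroke_pct else estimate$bleed_pct
  structure(
    list(
      denominator = 100L,
      affected = as.integer(affected),
      outcome = outcome,
      option = estimate$option
    ),
    class = "icon_array"
  )
}

#' Render an icon array
#'
#' Text format gives ten rows of glyphs, affected `●` and unaffected
#' `○`, filled left-to-right, top-to-bottom. SVG format gives a 10 x 10
#' grid of circles with the affected icons in the outcome's colour (dark red
#' for stroke, dark blue for major bleed). Both renderings are
#' byte-deterministic for a fixed array.
#'
#' @param array An `icon_array`.
#' @param format `"text"` or `"svg"`.
#' @return A single character string containing the document.
#' @export
render_icon_array <- function(array, format = c("text", "svg")) {
  stopifnot(inherits(array, "icon_array"))
  format <- match.arg(format)
  if (array$affected < 0L || array$affected > array$denominator) {
    stop("affected count must lie in [0, 100]", call. = FALSE)
  }
  if (format == "text") {
    glyphs <- c(rep("●", array$affected),
                rep("○", array$denominator - array$affected))
    rows <- vapply(0:9, function(r) {
      paste0(glyphs[(r * 10 + 1):(r * 10 + 10)], collapse = "")
    }, character(1))
    paste0(rows, collapse = "\n")
  } else {
    fill_on <- ICON_COLOURS[[array$outcome]]
    circles <- vapply(seq_len(100L), function(i) {
      row <- (i - 1L) %/% 10L
      col <- (i - 1L) %% 10L
      fill <- if (i <= array$affected) fill_on else ICON_UNAFFECTED
      sprintf('<circle cx="%d" cy="%d" r="8" fill="%s"/>',
              12L + 20L * col, 12L + 20L * row, fill)
    }, character(1))
    paste0(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
      'width="204" height="204" viewBox="0 0 204 204">\n',
      paste0(circles, collapse = "\n"),
      "\n</svg>"
    )
  }
}

#' @export
print.icon_array <- function(x, ...) {
  cat(sprintf(
    "%s with %s: %d of %d affected\n",
    gsub("_", " ", x$outcome), option_label(x$option), x$affected,
    x$denominator
  ))
  cat(render_icon_array(x, "text"), "\n")
  invisible(x)
}
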