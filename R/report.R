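# Assembly and rendering of the full decision report, in the presentation
# order of the original tool: communication opener, education, per-option
# screens shown one at a time, sequelae, the combined all-options screen,
# value clarification, the worksheet, and the physician prompt.

#' Load the facilitator script passages
#'
#' The spoken-script text is an editable asset file, not hard-coded, so
#' locale variants can be swapped in; the shipped default is the tool's
#' original wording.
#'
#' @param path Optional path to an alternative passages JSON file; `NULL`
#'   loads the shipped default.
#' @return Named list of character strings.
#' @export
load_script_passages <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "script_passages.json", package = "afdecide")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("script passages file not found: %s", path), call. = FALSE)
  }
  passages <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c(
    "communication_intro", "education_intro", "education_anatomy",
    "sequelae_stroke", "sequelae_bleed", "no_perfect_medication",
    "think_one_at_a_time", "importance_to_doctor", "talking_helps",
    "worksheet_prompt", "physician_prompt"
  )
  missing <- setdiff(required, names(passages))
  if (length(missing) > 0L) {
    stop(
      sprintf("script passages file is missing: %s",
              paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  lapply(passages, as.character)
}

#' Assemble a decision report
#'
#' Builds the structured report for one patient: the education script, one
#' screen per available treatment option (risk estimate, stroke and bleed
#' icon arrays, practical issues), the combined all-options screen, the
#' worksheet, and the physician prompt. Screen order follows the option
#' menu; every number on a screen is taken from the corresponding
#' `risk_estimate`, never recomputed.
#'
#' @param profile A `patient_profile`.
#' @param years Horizon in years (default 5).
#' @param passages Script passages, as from [load_script_passages()].
#' @return An object of class `decision_report`.
#' @export
build_report <- function(profile, years = 5,
                         passages = load_script_passages()) {
  stopifnot(inherits(profile, "patient_profile"))
  menu <- available_options(profile)
  screens <- lapply(menu$options, function(opt) {
    est <- risk_estimate(profile, opt, years)
    list(
      option = opt,
      estimate = est,
      stroke_array = build_icon_array(est, "stroke"),
      bleed_array = build_icon_array(est, "major_bleed"),
      issues = practical_issues(opt)
    )
  })
  combined <- data.frame(
    option = menu$options,
    label = vapply(menu$options, option_label, character(1)),
    stroke_pct = vapply(screens, function(s) s$estimate$stroke_pct, integer(1)),
    bleed_pct = vapply(screens, function(s) s$estimate$bleed_pct, integer(1)),
    row.names = NULL
  )
  structure(
    list(
      profile = profile,
      years = years,
      menu = menu,
      passages = passages,
      option_screens = screens,
      combined = combined,
      worksheet_slots = 5L
    ),
    class = "decision_report"
  )
}

wrap_text <- function(text, width = 72L, indent = "") {
  paste0(strwrap(text, width = width, prefix = indent), collapse = "\n")
}

heading <- function(title) {
  paste0(title, "\n", strrep("=", nchar(title)))
}

report_text <- function(report) {
  p <- report$passages
  yrs <- report$years
  parts <- c(
    heading("TREATMENT DECISIONS FOR ATRIAL FIBRILLATION"),
    "",
    "[photograph screen: patients and physicians talking together]",
    "",
    wrap_text(p$communication_intro),
    "",
    heading("UNDERSTANDING AFIB"),
    "",
    wrap_text(p$education_intro),
    "",
    "[illustration: the heart and its connection to the brain]",
    "",
    wrap_text(p$education_anatomy),
    "",
    heading("YOUR TREATMENT OPTIONS"),
    "",
    wrap_text(report$menu$context_note),
    ""
  )
  for (screen in report$option_screens) {
    est <- screen$estimate
    parts <- c(
      parts,
      sprintf("--- %s ---", option_label(screen$option)),
      "",
      sprintf("Out of 100 people like you, over %g years:", yrs),
      "",
      sprintf("  Stroke: %d out of 100", est$stroke_pct),
      paste0("  ", gsub("\n", "\n  ",
                        render_icon_array(screen$stroke_array, "text"))),
      "",
      sprintf("  Major bleed: %d out of 100", est$bleed_pct),
      paste0("  ", gsub("\n", "\n  ",
                        render_icon_array(screen$bleed_array, "text"))),
      "",
      "Practical issues:",
      paste0("  - ", screen$issues),
      ""
    )
  }
  combined_rows <- sprintf(
    "  %-20s %19d %19d",
    report$combined$label, report$combined$stroke_pct,
    report$combined$bleed_pct
  )
  parts <- c(
    parts,
    heading("WHAT A STROKE OR A MAJOR BLEED MEANS"),
    "",
    wrap_text(p$sequelae_stroke),
    "",
    wrap_text(p$sequelae_bleed),
    "",
    heading("ALL OPTIONS TOGETHER"),
    "",
    sprintf("  %-20s %19s %19s", "Option",
            "Strokes per 100", "Major bleeds per 100"),
    combined_rows,
    "",
    heading("WEIGHING YOUR OPTIONS"),
    "",
    wrap_text(p$no_perfect_medication),
    "",
    wrap_text(p$think_one_at_a_time),
    "",
    wrap_text(p$importance_to_doctor),
    "",
    wrap_text(p$talking_helps),
    "",
    heading("YOUR WORKSHEET"),
    "",
    wrap_text(p$worksheet_prompt),
    "",
    paste0("  ", seq_len(report$worksheet_slots), ". ",
           strrep("_", 60)),
    "",
    heading("PROMPT FOR YOUR DOCTOR"),
    "",
    wrap_text(p$physician_prompt),
    ""
  )
  paste0(paste0(parts, collapse = "\n"), "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

report_html <- function(report) {
  p <- lapply(report$passages, html_escape)
  yrs <- report$years
  parts <- c(
    "<!DOCTYPE html>",
    '<html lang="en"><head><meta charset="utf-8"/>',
    "<title>Treatment decisions for atrial fibrillation</title>",
    "<style>",
    "body{font-family:sans-serif;max-width:48em;margin:2em auto;}",
    "h2{border-bottom:2px solid #444;}",
    ".array{display:inline-block;margin:0.5em 2em 0.5em 0;}",
    ".slot{border-bottom:1px solid #999;height:1.6em;}",
    "table{border-collapse:collapse;}",
    "td,th{border:1px solid #999;padding:0.3em 0.8em;text-align:right;}",
    "td:first-child,th:first-child{text-align:left;}",
    "</style></head><body>",
    "<h1>Treatment decisions for atrial fibrillation</h1>",
    "<p><em>[photograph screen: patients and physicians talking together]</em></p>",
    sprintf("<p>%s</p>", p$communication_intro),
    "<h2>Understanding AFib</h2>",
    sprintf("<p>%s</p>", p$education_intro),
    "<p><em>[illustration: the heart and its connection to the brain]</em></p>",
    sprintf("<p>%s</p>", p$education_anatomy),
    "<h2>Your treatment options</h2>",
    sprintf("<p>%s</p>", html_escape(report$menu$context_note))
  )
  for (screen in report$option_screens) {
    est <- screen$estimate
    parts <- c(
      parts,
      sprintf("<h3>%s</h3>", html_escape(option_label(screen$option))),
      sprintf("<p>Out of 100 people like you, over %g years:</p>", yrs),
      '<div class="array">',
      sprintf("<p>Stroke: <strong>%d out of 100</strong></p>", est$stroke_pct),
      render_icon_array(screen$stroke_array, "svg"),
      "</div>",
      '<div class="array">',
      sprintf("<p>Major bleed: <strong>%d out of 100</strong></p>",
              est$bleed_pct),
      render_icon_array(screen$bleed_array, "svg"),
      "</div>",
      "<p>Practical issues:</p><ul>",
      sprintf("<li>%s</li>", html_escape(screen$issues)),
      "</ul>"
    )
  }
  combined_rows <- sprintf(
    "<tr><td>%s</td><td>%d</td><td>%d</td></tr>",
    html_escape(report$combined$label), report$combined$stroke_pct,
    report$combined$bleed_pct
  )
  parts <- c(
    parts,
    "<h2>What a stroke or a major bleed means</h2>",
    sprintf("<p>%s</p>", p$sequelae_stroke),
    sprintf("<p>%s</p>", p$sequelae_bleed),
    "<h2>All options together</h2>",
    "<table><tr><th>Option</th><th>Strokes per 100</th>",
    "<th>Major bleeds per 100</th></tr>",
    combined_rows,
    "</table>",
    "<h2>Weighing your options</h2>",
    sprintf("<p>%s</p>", p$no_perfect_medication),
    sprintf("<p>%s</p>", p$think_one_at_a_time),
    sprintf("<p>%s</p>", p$importance_to_doctor),
    sprintf("<p>%s</p>", p$talking_helps),
    "<h2>Your worksheet</h2>",
    sprintf("<p>%s</p>", p$worksheet_prompt),
    rep('<div class="slot"></div>', report$worksheet_slots),
    "<h2>Prompt for your doctor</h2>",
    sprintf("<p>%s</p>", p$physician_prompt),
    "</body></html>"
  )
  paste0(paste0(parts, collapse = "\n"), "\n")
}

#' Render a decision report
#'
#' Builds the report with [build_report()] and renders it as plain text
#' (terminal-friendly, glyph icon arrays) or a self-contained HTML document
#' with inline SVG pictographs. Rendering is byte-deterministic: the same
#' profile, horizon and format always give the same output.
#'
#' @param profile A `patient_profile`.
#' @param years Horizon in years (default 5).
#' @param format `"text"` or `"html"`.
#' @param passages Script passages, as from [load_script_passages()].
#' @return A single character string containing the document.
#' @export
render_report <- function(profile, years = 5, format = c("text", "html"),
                          passages = load_script_passages()) {
  format <- match.arg(format)
  report <- build_report(profile, years, passages)
  if (format == "text") report_text(report) else report_html(report)
}

#' @export
print.decision_report <- function(x, ...) {
  cat(sprintf(
    "Decision report: %d option screen(s) over %g years (%s)\n",
    length(x$option_screens), x$years,
    paste(vapply(x$menu$options, option_label, character(1)), collapse = ", ")
  ))
  invisible(x)
}
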