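# Human-readable views of a spec: ASCII read diagram, markdown table, and a
# minimal standalone HTML page. The ASCII glyph set ("|", ":", "-") is fixed
# so diagrams are deterministic and machine-parseable — scanning a diagram
# and accumulating the max lengths reproduces index_read intervals, which
# doubles as a visual-vs-positional consistency check.

#' ASCII read diagram
#'
#' One line per top-level construct; atomic Regions rendered left to right
#' as `|id:min-max|`, collapsed to `|id:len|` when `min == max`.
#'
#' @param assay A formatted [assay()].
#' @return An object of class `"read_diagram"`: list with `lines` (one
#'   string per top-level region) and `legend` (data.frame mapping
#'   region_id to region_type and a length-range label).
#' @export
render_ascii <- function(assay) {
  seg <- function(r) {
    if (r$min_len == r$max_len) sprintf("%s:%d", r$region_id, r$max_len)
    else sprintf("%s:%d-%d", r$region_id, r$min_len, r$max_len)
  }
  lines <- vapply(assay$regions, function(top) {
    lv <- leaves(top)
    paste0("|", paste(vapply(lv, seg, character(1)), collapse = "|"), "|")
  }, character(1))
  lv <- leaves(assay)
  legend <- data.frame(
    region_id = vapply(lv, `[[`, character(1), "region_id"),
    region_type = vapply(lv, `[[`, character(1), "region_type"),
    length = vapply(lv, function(r)
      if (r$min_len == r$max_len) sprintf("%d nt", r$max_len)
      else sprintf("%d-%d nt", r$min_len, r$max_len), character(1)),
    stringsAsFactors = FALSE)
  structure(list(lines = lines, legend = legend), class = "read_diagram")
}

#' @export
print.read_diagram <- function(x, ...) {
  for (l in x$lines) cat(l, "\n")
  invisible(x)
}

#' Parse an ASCII diagram line back to intervals
#'
#' The scanner companion of [render_ascii()]: splits a diagram line on its
#' glyphs and accumulates max lengths into 0-based half-open intervals.
#'
#' @param line One element of a diagram's `lines`.
#' @return data.frame with columns `region_id`, `start`, `end`, `variable`.
#' @export
scan_diagram_line <- function(line) {
  body <- gsub("^\\||\\|$", "", line)
  segs <- strsplit(body, "|", fixed = TRUE)[[1L]]
  m <- regmatches(segs, regexec("^(.+):([0-9]+)(-([0-9]+))?$", segs))
  ids <- vapply(m, `[[`, character(1), 2L)
  lo <- as.integer(vapply(m, `[[`, character(1), 3L))
  hi <- vapply(m, function(x) x[5L], character(1))
  mx <- ifelse(nzchar(hi), suppressWarnings(as.integer(hi)), lo)
  ends <- cumsum(mx)
  data.frame(region_id = ids,
             start = as.integer(c(0L, ends[-length(ends)])),
             end = as.integer(ends),
             variable = nzchar(hi),
             stringsAsFactors = FALSE)
}

md_cell <- function(x) gsub("|", "\\|", x, fixed = TRUE)

#' Markdown table of a spec's atomic Regions
#'
#' Rows follow the pre-order of leaves (5'-to-3' document order); output is
#' deterministic.
#'
#' @param assay A formatted [assay()].
#' @return A single markdown string.
#' @export
render_markdown <- function(assay) {
  lv <- leaves(assay)
  header <- c("order", "region_id", "region_type", "sequence_type",
              "sequence", "min_len", "max_len", "onlist")
  rows <- vapply(seq_along(lv), function(i) {
    r <- lv[[i]]
    cells <- c(i, r$region_id, r$region_type, r$sequence_type, r$sequence,
               r$min_len, r$max_len,
               if (is.null(r$onlist)) "" else r$onlist$filename)
    paste0("| ", paste(md_cell(as.character(cells)), collapse = " | "), " |")
  }, character(1))
  paste(c(
    sprintf("# %s", assay$name),
    "",
    paste0("| ", paste(header, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
    rows, ""), collapse = "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Minimal standalone HTML page for a spec
#'
#' Wraps the [render_markdown()] table into a self-contained HTML document;
#' stripping the tags recovers the markdown cell contents.
#'
#' @param assay A formatted [assay()].
#' @return A single HTML string.
#' @export
render_html <- function(assay) {
  md <- render_markdown(assay)
  lines <- strsplit(md, "\n", fixed = TRUE)[[1L]]
  out <- c("<!DOCTYPE html>", "<html>", "<head>",
           sprintf("<title>%s</title>", html_escape(assay$name)),
           "<meta charset=\"utf-8\"/>", "</head>", "<body>")
  for (l in lines) {
    if (grepl("^# ", l)) {
      out <- c(out, sprintf("<h1>%s</h1>", html_escape(sub("^# ", "", l))))
    } else if (grepl("^\\|---", l) || !nzchar(l)) {
      next
    } else if (grepl("^\\| ", l)) {
      cells <- strsplit(gsub("^\\| | \\|$", "", l), " | ", fixed = TRUE)[[1L]]
      tag <- if (identical(cells[1L], "order")) "th" else "td"
      if (identical(cells[1L], "order")) out <- c(out, "<table>")
      out <- c(out, paste0(
        "<tr>",
        paste(sprintf("<%s>%s</%s>", tag, html_escape(cells), tag),
              collapse = ""),
        "</tr>"))
    }
  }
  out <- c(out, "</table>", "</body>", "</html>")
  paste(out, collapse = "\n")
}
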