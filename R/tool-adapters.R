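# Technology-string emitters: render a set of read indices in the argument
# dialect of a single-cell preprocessing tool, plus a parser used to verify
# every emitted string by round-tripping.
#
# Dialect grammars (defined by this module; verified by parse_tool_string):
#   kb       — colon-separated triples "<file>,<start>,<end>", 0-based files
#              and positions: barcode triple(s) 5'->3', then the UMI triple,
#              then the biological-sequence triple; "<file>,0,0" means the
#              sequence spans that whole file/read.
#   starsolo — "--soloCBstart <s> --soloCBlen <l> --soloUMIstart <s'>
#              --soloUMIlen <l'>", 1-based starts; exactly one barcode and
#              one UMI, fixed-length, in the same read.
#   simpleaf — read geometry "1{...}2{...}" with descriptors b[len] (barcode),
#              u[len] (UMI), x[len] (other fixed elements), r[len] or r[:]
#              (biological sequence; ":" = the remainder of the read).

tool_dialects <- function() c("kb", "starsolo", "simpleaf")

tool_string <- function(tool, text, intervals_used) {
  structure(list(tool = tool, text = text, intervals_used = intervals_used),
            class = "tool_string")
}

#' @export
print.tool_string <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

# Flatten a list of region_index objects into one table with 0-based read
# (file) numbers following input order, which follows top-level 5'->3'
# document order.
gather_intervals <- function(indices) {
  if (length(indices) == 0L)
    stop_readspec("no read indices supplied", "readspec_missing_element")
  rows <- lapply(seq_along(indices), function(i) {
    ix <- indices[[i]]
    iv <- ix$intervals
    iv$file <- i - 1L
    iv$fixed_prefix_ok <- ix$fixed_prefix_ok
    iv$read_len <- max(iv$end)
    iv
  })
  do.call(rbind, rows)
}

check_fixed_positions <- function(tab, kinds = c("barcode", "umi")) {
  # a read without a fixed prefix makes every downstream position
  # unreliable, so fixed-position dialects refuse the whole layout
  if (any(!tab$fixed_prefix_ok))
    stop_readspec(
      paste0("cannot emit fixed positions: a supplied read contains a ",
             "variable-length region upstream of other regions ",
             "(fixed_prefix_ok = FALSE)"),
      "readspec_refusal")
  bad <- tab$region_type %in% kinds & tab$variable
  if (any(bad))
    stop_readspec(
      sprintf(paste0("cannot emit fixed positions: region(s) %s lie in a ",
                     "read without a fixed prefix (fixed_prefix_ok = FALSE) ",
                     "or are variable-length"),
              paste(tab$region_id[bad], collapse = ", ")),
      "readspec_refusal")
}

seq_rows <- function(tab) which(tab$region_type %in% c("cdna", "gdna"))

#' Emit a kallisto bustools technology string
#'
#' @param indices List of `region_index` objects (from [index_read()]), in
#'   read order; file numbers in the output follow this order, 0-based.
#' @return A `tool_string` with the triple-group text, e.g.
#'   `"0,0,16:0,16,28:1,0,0"` for a 16-nt barcode and 12-nt UMI on read 1
#'   and the cDNA spanning read 2.
#' @export
emit_kb <- function(indices) {
  tab <- gather_intervals(indices)
  check_fixed_positions(tab)
  bc <- tab[tab$region_type == "barcode", , drop = FALSE]
  umi <- tab[tab$region_type == "umi", , drop = FALSE]
  sq <- tab[seq_rows(tab), , drop = FALSE]
  if (nrow(sq) == 0L)
    stop_readspec("no cdna/gdna region found in the supplied reads",
                  "readspec_missing_element")
  if (nrow(umi) == 0L)
    stop_readspec("no umi region found in the supplied reads",
                  "readspec_missing_element")
  # a sequence region spanning a whole read is written "<file>,0,0"
  sq <- sq[nrow(sq), , drop = FALSE]
  triple <- function(row) {
    if (row$region_type %in% c("cdna", "gdna") &&
        row$start == 0L && row$end == row$read_len)
      sprintf("%d,0,0", row$file)
    else sprintf("%d,%d,%d", row$file, row$start, row$end)
  }
  parts <- c(
    vapply(seq_len(nrow(bc)), function(i) triple(bc[i, ]), character(1)),
    triple(umi[1L, ]),
    triple(sq[1L, ])
  )
  used <- rbind(bc, umi[1L, ], sq[1L, ])
  tool_string("kb", paste(parts, collapse = ":"), used)
}

#' Emit STARsolo barcode/UMI arguments
#'
#' Converts the 0-based half-open barcode and UMI intervals to STARsolo's
#' 1-based start/length flags. The dialect cannot express split barcodes or
#' variable lengths; such layouts are refused.
#'
#' @inheritParams emit_kb
#' @return A `tool_string`, e.g.
#'   `"--soloCBstart 1 --soloCBlen 16 --soloUMIstart 17 --soloUMIlen 12"`.
#' @export
emit_starsolo <- function(indices) {
  tab <- gather_intervals(indices)
  check_fixed_positions(tab)
  bc <- tab[tab$region_type == "barcode", , drop = FALSE]
  umi <- tab[tab$region_type == "umi", , drop = FALSE]
  if (nrow(bc) != 1L)
    stop_readspec(
      sprintf("starsolo flags express exactly one barcode region, found %d",
              nrow(bc)),
      if (nrow(bc) > 1L) "readspec_unsupported_layout"
      else "readspec_missing_element")
  if (nrow(umi) != 1L)
    stop_readspec(
      sprintf("starsolo flags express exactly one umi region, found %d",
              nrow(umi)), "readspec_unsupported_layout")
  if (bc$file != umi$file)
    stop_readspec("barcode and umi must lie in the same read for starsolo",
                  "readspec_unsupported_layout")
  text <- sprintf(
    "--soloCBstart %d --soloCBlen %d --soloUMIstart %d --soloUMIlen %d",
    bc$start + 1L, bc$end - bc$start, umi$start + 1L, umi$end - umi$start)
  tool_string("starsolo", text, rbind(bc, umi))
}

#' Emit a simpleaf/alevin-fry read-geometry string
#'
#' Each read is rendered as a concatenation of element descriptors —
#' `b[len]` barcode, `u[len]` UMI, `x[len]` other fixed elements, `r[len]`
#' or `r[:]` biological sequence (`:` = remainder of the read) — grouped as
#' `1{...}2{...}` in read order.
#'
#' @inheritParams emit_kb
#' @return A `tool_string`, e.g. `"1{b[16]u[12]}2{r[:]}"`.
#' @export
emit_simpleaf <- function(indices) {
  tab <- gather_intervals(indices)
  check_fixed_positions(tab)
  if (length(seq_rows(tab)) == 0L)
    stop_readspec("no cdna/gdna region found in the supplied reads",
                  "readspec_missing_element")
  descr <- function(row, is_last) {
    len <- row$end - row$start
    if (row$region_type == "barcode") sprintf("b[%d]", len)
    else if (row$region_type == "umi") sprintf("u[%d]", len)
    else if (row$region_type %in% c("cdna", "gdna")) {
      if (is_last && (row$variable || row$start == 0L)) "r[:]"
      else sprintf("r[%d]", len)
    } else sprintf("x[%d]", len)
  }
  groups <- vapply(seq_along(indices), function(i) {
    rows <- tab[tab$file == i - 1L, , drop = FALSE]
    body <- vapply(seq_len(nrow(rows)), function(j)
      descr(rows[j, ], j == nrow(rows)), character(1))
    sprintf("%d{%s}", i, paste(body, collapse = ""))
  }, character(1))
  tool_string("simpleaf", paste(groups, collapse = ""), tab)
}

# ---- dialect parsers --------------------------------------------------------

parse_fail <- function(text, offset, msg) {
  stop_readspec(
    sprintf("%s at offset %d in \"%s\"", msg, offset, text),
    "readspec_parse_error")
}

parse_kb <- function(text, read_lengths) {
  groups <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(groups) < 3L)
    parse_fail(text, nchar(text), "kb string needs >= 3 triples")
  offset <- 0L
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    parts <- strsplit(g, ",", fixed = TRUE)[[1L]]
    if (length(parts) != 3L || anyNA(suppressWarnings(as.integer(parts))))
      parse_fail(text, offset, sprintf("malformed triple '%s'", g))
    v <- as.integer(parts)
    kind <- if (i == length(groups)) "sequence"
      else if (i == length(groups) - 1L) "umi" else "barcode"
    if (kind == "sequence" && v[2L] == 0L && v[3L] == 0L) {
      if (v[1L] + 1L > length(read_lengths))
        parse_fail(text, offset, sprintf("file %d beyond read_lengths", v[1L]))
      v[3L] <- read_lengths[v[1L] + 1L]
    }
    if (v[3L] < v[2L])
      parse_fail(text, offset, sprintf("end %d < start %d", v[3L], v[2L]))
    offset <<- offset + nchar(g) + 1L
    data.frame(read = v[1L], kind = kind, start = v[2L], end = v[3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_starsolo <- function(text, read_lengths) {
  grab <- function(flag) {
    m <- regmatches(text,
                    regexpr(sprintf("%s ([0-9]+)", flag), text))
    if (length(m) == 0L)
      parse_fail(text, 0L, sprintf("missing flag %s", flag))
    as.integer(sub(".* ", "", m))
  }
  cbs <- grab("--soloCBstart"); cbl <- grab("--soloCBlen")
  us <- grab("--soloUMIstart"); ul <- grab("--soloUMIlen")
  data.frame(
    read = c(0L, 0L), kind = c("barcode", "umi"),
    start = c(cbs - 1L, us - 1L),
    end = c(cbs - 1L + cbl, us - 1L + ul),
    stringsAsFactors = FALSE)
}

parse_simpleaf <- function(text, read_lengths) {
  rows <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regmatches(substr(text, pos, n),
                    regexec("^([0-9]+)\\{([^}]*)\\}", substr(text, pos, n)))[[1L]]
    if (length(m) == 0L)
      parse_fail(text, pos, "expected '<read>{...}' group")
    read1 <- as.integer(m[2L])
    body <- m[3L]
    cursor <- 0L
    bpos <- 1L
    bn <- nchar(body)
    while (bpos <= bn) {
      em <- regmatches(substr(body, bpos, bn),
                       regexec("^([buxr])\\[([0-9]+|:)\\]",
                               substr(body, bpos, bn)))[[1L]]
      if (length(em) == 0L)
        parse_fail(text, pos + bpos, "malformed element descriptor")
      kind <- c(b = "barcode", u = "umi", x = "other",
                r = "sequence")[[em[2L]]]
      len <- if (em[3L] == ":") {
        if (read1 > length(read_lengths))
          parse_fail(text, pos, sprintf("read %d beyond read_lengths", read1))
        read_lengths[read1] - cursor
      } else as.integer(em[3L])
      rows[[length(rows) + 1L]] <- data.frame(
        read = read1 - 1L, kind = kind,
        start = cursor, end = cursor + len, stringsAsFactors = FALSE)
      cursor <- cursor + len
      bpos <- bpos + nchar(em[1L])
    }
    pos <- pos + nchar(m[1L])
  }
  if (length(rows) == 0L) parse_fail(text, 1L, "empty geometry")
  do.call(rbind, rows)
}

#' Parse a technology string back to intervals
#'
#' Inverse of the emitters; used to verify every emitted string by
#' round-tripping. Positions in the result are 0-based half-open regardless
#' of the dialect's own convention.
#'
#' @param tool One of `"kb"`, `"starsolo"`, `"simpleaf"`.
#' @param text A string in that dialect.
#' @param read_lengths Integer vector of read lengths (needed to resolve
#'   whole-read/remainder tokens).
#' @return data.frame with columns `read` (0-based), `kind` (barcode, umi,
#'   sequence, other), `start`, `end`.
#' @export
parse_tool_string <- function(tool, text, read_lengths = integer(0)) {
  tool <- match.arg(tool, tool_dialects())
  switch(tool,
         kb = parse_kb(text, read_lengths),
         starsolo = parse_starsolo(text, read_lengths),
         simpleaf = parse_simpleaf(text, read_lengths))
}
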