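# Core computations over a spec: bottom-up metadata population, positional
# indexing of reads, onlist retrieval, and newick-based initialization.

#' Auto-populate meta-Region metadata
#'
#' Processes the tree bottom-up: every meta Region receives
#' `sequence_type = "joined"`, `min_len`/`max_len` equal to the sums over its
#' children, and `sequence` equal to the concatenation of child sequences.
#' Atomic Regions are returned unchanged. The input is not mutated; a new
#' assay is returned. Applying the operation twice equals applying it once.
#'
#' @param assay An [assay()] whose atomic regions have their own fields
#'   populated (`sequence_type` one of fixed/onlist/random).
#' @return A new, formatted [assay()].
#' @export
format_spec <- function(assay) {
  fmt <- function(r) {
    if (!is_meta(r)) {
      if (r$sequence_type == "joined")
        stop_readspec(
          sprintf("atomic region '%s' has sequence_type 'joined'",
                  r$region_id),
          "readspec_structural_error")
      return(r)
    }
    kids <- lapply(r$regions, fmt)
    r$regions <- kids
    r$sequence_type <- "joined"
    r$min_len <- sum(vapply(kids, `[[`, integer(1), "min_len"))
    r$max_len <- sum(vapply(kids, `[[`, integer(1), "max_len"))
    r$sequence <- paste(vapply(kids, `[[`, character(1), "sequence"),
                        collapse = "")
    r
  }
  assay$regions <- lapply(assay$regions, fmt)
  assay
}

#' Positional index of a read
#'
#' Lays out the atomic Regions of a read (a meta Region, commonly of
#' region_type `"fastq"`) as contiguous 0-based half-open intervals using
#' cumulative `max_len` offsets. An interval is flagged `variable` when
#' `min_len != max_len`; `fixed_prefix_ok` is `TRUE` iff every interval that
#' precedes a variable-length interval is itself fixed-length, which is what
#' fixed-position consumers (tool adapters, FASTQ splitting) require.
#' Zero-length regions yield empty intervals (`start == end`).
#'
#' @param assay A formatted [assay()].
#' @param read_id region_id of the meta Region denoting the read. An atomic
#'   id yields a single self-interval (degenerate, not an error).
#' @return An object of class `"region_index"`: a list with `read_id`,
#'   `intervals` (data.frame with columns region_id, region_type, start,
#'   end, min_len, max_len, variable) and `fixed_prefix_ok`.
#' @export
index_read <- function(assay, read_id) {
  read <- get_region(assay, read_id)
  lv <- leaves(read)
  maxs <- vapply(lv, `[[`, integer(1), "max_len")
  mins <- vapply(lv, `[[`, integer(1), "min_len")
  ends <- cumsum(maxs)
  starts <- c(0L, ends[-length(ends)])
  intervals <- data.frame(
    region_id = vapply(lv, `[[`, character(1), "region_id"),
    region_type = vapply(lv, `[[`, character(1), "region_type"),
    start = as.integer(starts),
    end = as.integer(ends),
    min_len = mins,
    max_len = maxs,
    variable = mins != maxs,
    stringsAsFactors = FALSE
  )
  # every interval preceding a variable-length one must itself be fixed, so
  # the only admissible variable interval is the final one
  fixed_prefix_ok <- !any(intervals$variable[-nrow(intervals)])
  structure(list(read_id = read_id, intervals = intervals,
                 fixed_prefix_ok = fixed_prefix_ok),
            class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  cat(sprintf("<region_index> read '%s', %d interval(s), fixed_prefix_ok=%s\n",
              x$read_id, nrow(x$intervals), x$fixed_prefix_ok))
  print(x$intervals[, c("region_id", "region_type", "start", "end",
                        "variable")], row.names = FALSE)
  invisible(x)
}

#' Resolve onlists for a region type
#'
#' Finds every Region of the given type that carries an onlist, in 5'-to-3'
#' (pre-order) order — several in the split-pool case — and resolves their
#' paths and sequence counts.
#'
#' @param assay An [assay()].
#' @param region_type One of [region_types()].
#' @param base_dir Directory against which onlist filenames resolve.
#' @return data.frame with columns `region_id`, `path`, `n`.
#' @export
get_onlist <- function(assay, region_type, base_dir = ".") {
  hits <- Filter(function(r) !is.null(r$onlist),
                 find_by_type(assay, region_type))
  if (length(hits) == 0L)
    stop_readspec(
      sprintf("no region of type '%s' carries an onlist", region_type),
      "readspec_not_found")
  paths <- vapply(hits, function(r)
    resolve_onlist_path(r$onlist$filename, base_dir), character(1))
  n <- vapply(paths, function(p) length(read_onlist(p)), integer(1))
  data.frame(
    region_id = vapply(hits, `[[`, character(1), "region_id"),
    path = unname(paths), n = unname(n), stringsAsFactors = FALSE)
}

# ---- newick initialization --------------------------------------------------
#
# Grammar: leaf label "<region_id>:<length>" (atomic, random, min = max =
# length); internal node label "<region_id>"; standard parentheses/commas;
# trailing semicolon optional. Hand-rolled recursive descent so that
# single-child internal nodes are accepted and errors carry character
# offsets.

parse_newick <- function(text) {
  s <- trimws(text)
  s <- sub(";\\s*$", "", s)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  fail <- function(msg, class = "readspec_parse_error")
    stop_readspec(sprintf("%s at character %d of newick string", msg, pos),
                  class)
  read_label <- function() {
    start <- pos
    while (pos <= n && !peek() %in% c("(", ")", ",", ":")) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      children <- list(node())
      while (peek() == ",") {
        pos <<- pos + 1L
        children[[length(children) + 1L]] <- node()
      }
      if (peek() != ")") fail("expected ')' or ','")
      pos <<- pos + 1L
      label <- read_label()
      if (!nzchar(label)) fail("internal node without a label",
                               "readspec_grammar_error")
      if (peek() == ":") fail("internal node must not carry ':<length>'",
                              "readspec_grammar_error")
      list(label = label, length = NA_integer_, children = children)
    } else {
      label <- read_label()
      if (!nzchar(label)) fail("expected a node label")
      if (peek() != ":")
        fail(sprintf("leaf '%s' lacks ':<length>'", label),
             "readspec_grammar_error")
      pos <<- pos + 1L
      start <- pos
      while (pos <= n && grepl("[0-9]", peek())) pos <<- pos + 1L
      if (pos == start) fail("expected an integer length after ':'",
                             "readspec_grammar_error")
      list(label = label,
           length = as.integer(substr(s, start, pos - 1L)),
           children = list())
    }
  }
  root <- node()
  if (pos <= n) fail(sprintf("unexpected character '%s'", peek()))
  root
}

newick_to_region <- function(nd) {
  if (length(nd$children) == 0L) {
    region(nd$label, region_type = "other", sequence_type = "random",
           sequence = strrep("X", nd$length),
           min_len = nd$length, max_len = nd$length)
  } else {
    region(nd$label, region_type = "named_region", sequence_type = "joined",
           regions = lapply(nd$children, newick_to_region))
  }
}

#' Initialize a skeleton assay from a newick string
#'
#' Builds an assay whose region tree mirrors the newick topology, sibling
#' order preserved. Leaves (`"id:length"`) become atomic random Regions of
#' fixed length; internal nodes (`"(...)id"`) become meta Regions of type
#' `"named_region"`; leaves default to type `"other"` — both are meant to be
#' edited afterwards. The outermost node supplies the assay_id and becomes
#' the single top-level Region. `format_spec()` then [check_spec()] on the
#' result yield no errors.
#'
#' @param tree Newick string, e.g. `"((bc:16,umi:12,cdna:98)R1)rna;"`.
#' @return A formatted skeleton [assay()].
#' @export
init_from_newick <- function(tree) {
  root <- parse_newick(tree)
  if (length(root$children) == 0L)
    stop_readspec("newick root must be an internal node",
                  "readspec_grammar_error")
  labels <- character(0)
  walk <- function(nd) {
    labels <<- c(labels, nd$label)
    for (ch in nd$children) walk(ch)
  }
  walk(root)
  dups <- unique(labels[duplicated(labels)])
  if (length(dups))
    stop_readspec(sprintf("duplicate region id(s) in newick string: %s",
                          paste(dups, collapse = ", ")),
                  "readspec_duplicate_id")
  a <- assay(assay_id = root$label, regions = list(newick_to_region(root)))
  format_spec(a)
}

#' Render an assay's topology as a newick string
#'
#' Inverse companion of [init_from_newick()]: leaves are written as
#' `"id:max_len"`, meta Regions as parenthesized groups. Re-initializing the
#' result yields an order-isomorphic tree with identical lengths.
#'
#' @param assay An [assay()].
#' @return A newick string terminated by `";"`.
#' @export
to_newick <- function(assay) {
  render <- function(r) {
    if (!is_meta(r)) sprintf("%s:%d", r$region_id, r$max_len)
    else sprintf("(%s)%s",
                 paste(vapply(r$regions, render, character(1)),
                       collapse = ","),
                 r$region_id)
  }
  if (length(assay$regions) == 1L && is_meta(assay$regions[[1L]]))
    paste0(render(assay$regions[[1L]]), ";")
  else
    sprintf("(%s)%s;",
            paste(vapply(assay$regions, render, character(1)),
                  collapse = ","),
            assay$assay_id)
}
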