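# Region/Assay data model: an ordered tree of annotated library segments.

#' Controlled vocabulary of region types
#'
#' The closed set of biological/technical element types a [region()] may carry.
#' `"other"` is the extensibility catch-all; `"named_region"` is the default
#' for meta Regions created by [init_from_newick()].
#'
#' @return Character vector of permitted `region_type` values.
#' @export
region_types <- function() {
  c("barcode", "umi", "cdna", "gdna", "adapter", "primer", "linker",
    "fastq", "illumina_p5", "illumina_p7", "index5", "index7", "poly_a",
    "named_region", "other")
}

#' Controlled vocabulary of sequence types
#'
#' `fixed` regions carry a literal sequence; `onlist` regions draw their
#' sequence from a file of permissible sequences; `random` regions are
#' unconstrained (represented as `X` padding); `joined` marks a meta Region
#' whose sequence is the concatenation of its children.
#'
#' @return Character vector of permitted `sequence_type` values.
#' @export
sequence_types <- function() {
  c("fixed", "onlist", "random", "joined")
}

seq_alphabet <- function() c("A", "C", "G", "T", "N", "X")

stop_readspec <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "readspec_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Reference to an onlist file
#'
#' An onlist is a plain-text file of permissible sequences (one per line,
#' optionally gzip-compressed) constraining a Region whose
#' `sequence_type == "onlist"` — e.g. a cell-barcode whitelist.
#'
#' @param filename Path of the onlist file, relative to the directory holding
#'   the spec document.
#' @param md5 Optional 32-hex-character checksum of the uncompressed content.
#' @return An object of class `"onlist"`.
#' @export
onlist_ref <- function(filename, md5 = NULL) {
  if (!is.character(filename) || length(filename) != 1L || !nzchar(filename))
    stop_readspec("onlist filename must be a non-empty string", "readspec_value_error")
  ol <- list(filename = filename)
  if (!is.null(md5)) ol$md5 <- as.character(md5)
  structure(ol, class = "onlist")
}

#' Construct a Region
#'
#' A Region annotates one contiguous segment of a library molecule. Regions
#' form an ordered tree: a Region with children (`regions`) is a *meta
#' Region* whose sequence is the 5'-to-3' join of its children; a childless
#' Region is *atomic*. Construction is deliberately permissive (lengths and
#' vocabulary are enforced by [check_spec()]) so that partially built trees
#' are representable during incremental construction.
#'
#' @param region_id Identifier, unique across the whole document.
#' @param region_type One of [region_types()].
#' @param sequence_type One of [sequence_types()].
#' @param name Human-readable label; defaults to `region_id`.
#' @param sequence Literal sequence for `fixed` regions; `X`-padding of
#'   length `max_len` for `random` regions; the child concatenation (filled
#'   by [format_spec()]) for `joined` regions.
#' @param min_len,max_len Length bounds in nucleotides.
#' @param onlist An [onlist_ref()], or `NULL`.
#' @param regions Ordered list of child [region()]s; empty for atomic Regions.
#' @param extra Named list of unrecognized keys preserved from a document.
#' @return An object of class `"region"`.
#' @export
region <- function(region_id, region_type, sequence_type,
                   name = region_id, sequence = "",
                   min_len = 0L, max_len = 0L,
                   onlist = NULL, regions = list(), extra = NULL) {
  if (!is.character(region_id) || length(region_id) != 1L || !nzchar(region_id))
    stop_readspec("region_id must be a non-empty string", "readspec_value_error")
  r <- list(
    region_id = region_id,
    region_type = as.character(region_type),
    name = as.character(name),
    sequence_type = as.character(sequence_type),
    sequence = as.character(sequence),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    onlist = onlist,
    regions = regions
  )
  if (!is.null(extra) && length(extra)) r$extra <- extra
  structure(r, class = "region")
}

#' @export
print.region <- function(x, ...) {
  kind <- if (length(x$regions)) "meta region" else "region"
  cat(sprintf("<%s> %s [%s/%s] %d-%d nt", kind, x$region_id,
              x$region_type, x$sequence_type, x$min_len, x$max_len))
  if (!is.null(x$onlist)) cat(sprintf(" onlist=%s", x$onlist$filename))
  cat("\n")
  invisible(x)
}

is_meta <- function(r) length(r$regions) > 0L

#' Construct an Assay
#'
#' The root document: assay-level metadata plus the ordered list of
#' top-level [region()]s, one per sequenced read or library element, in
#' 5'-to-3' order. Sibling order is significant everywhere and preserved by
#' serialization round-trips.
#'
#' @param assay_id Assay identifier.
#' @param regions Non-empty ordered list of top-level [region()]s.
#' @param name Human-readable assay name.
#' @param doi,description Optional metadata strings.
#' @param modalities Character vector of modalities (e.g. `"rna"`, `"atac"`).
#' @param spec_version Optional format-version string, preserved verbatim.
#' @param extra Named list of unrecognized keys preserved from a document.
#' @return An object of class `"assay"`.
#' @export
assay <- function(assay_id, regions, name = assay_id, doi = NULL,
                  description = NULL, modalities = "rna",
                  spec_version = NULL, extra = NULL) {
  if (!is.list(regions) || length(regions) == 0L)
    stop_readspec("an assay needs at least one top-level region",
                  "readspec_value_error")
  a <- list(
    assay_id = as.character(assay_id),
    name = as.character(name),
    doi = doi,
    description = description,
    modalities = as.character(modalities),
    spec_version = spec_version,
    regions = regions
  )
  if (!is.null(extra) && length(extra)) a$extra <- extra
  structure(a, class = "assay")
}

#' @export
print.assay <- function(x, ...) {
  cat(sprintf("<assay> %s (%s), %d top-level region(s), %d leaves\n",
              x$assay_id, paste(x$modalities, collapse = "+"),
              length(x$regions), length(leaves_of(x))))
  for (r in x$regions) print(r)
  invisible(x)
}

#' Pre-order traversal of an assay's region tree
#'
#' Visits every Region exactly once: parent before children, siblings in
#' stored (5'-to-3') order. Top-level regions are traversed left to right.
#'
#' @param x An [assay()] or a single [region()].
#' @return Ordered list of `region` objects.
#' @export
pre_order <- function(x) {
  roots <- if (inherits(x, "assay")) x$regions else list(x)
  out <- list()
  walk <- function(r) {
    out[[length(out) + 1L]] <<- r
    for (child in r$regions) walk(child)
  }
  for (r in roots) walk(r)
  out
}

#' Atomic (leaf) Regions in left-to-right order
#'
#' @param x An [assay()] or [region()]. A childless region returns itself.
#' @return Ordered list of atomic `region` objects.
#' @export
leaves <- function(x) {
  Filter(function(r) !is_meta(r), pre_order(x))
}

# internal alias used where `leaves` would shadow a local
leaves_of <- function(x) leaves(x)

region_ids <- function(x) vapply(pre_order(x), `[[`, character(1), "region_id")

#' Look up a Region by id
#'
#' @param assay An [assay()].
#' @param region_id Identifier to find.
#' @return The unique matching `region`.
#' @details An unknown id raises a not-found error that names the id and
#'   lists the nearest matches (by edit distance) to help catch typos.
#' @export
get_region <- function(assay, region_id) {
  for (r in pre_order(assay)) {
    if (r$region_id == region_id) return(r)
  }
  ids <- region_ids(assay)
  d <- utils::adist(region_id, ids)[1L, ]
  near <- ids[order(d)][seq_len(min(3L, length(ids)))]
  stop_readspec(
    sprintf("no region with id '%s'; nearest matches: %s",
            region_id, paste(near, collapse = ", ")),
    "readspec_not_found")
}

#' All Regions of a given type, in pre-order
#'
#' @param assay An [assay()].
#' @param region_type One of [region_types()].
#' @return Ordered list of matching `region`s (possibly empty).
#' @export
find_by_type <- function(assay, region_type) {
  if (!region_type %in% region_types())
    stop_readspec(
      sprintf("unknown region_type '%s'; permitted: %s", region_type,
              paste(region_types(), collapse = ", ")),
      "readspec_vocab_error")
  Filter(function(r) r$region_type == region_type, pre_order(assay))
}
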