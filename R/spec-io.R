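# YAML serialization and schema validation of assay specifications.
#
# Documents are UTF-8 YAML with 2-space indentation. Key order in output is
# fixed (region_id, region_type, name, sequence_type, sequence, min_len,
# max_len, onlist, regions) so that dumps are byte-deterministic; sibling
# order is preserved exactly in both directions.

REQUIRED_REGION_KEYS <- c("region_id", "region_type", "sequence_type",
                          "min_len", "max_len")
KNOWN_REGION_KEYS <- c("region_id", "region_type", "name", "sequence_type",
                       "sequence", "min_len", "max_len", "onlist", "regions")
KNOWN_ASSAY_KEYS <- c("assay_id", "name", "doi", "description", "modalities",
                      "spec_version", "regions")

# Closed set of validation issue codes (see check_spec for their meaning).
issue_codes <- function() {
  c("E_DUP_ID", "E_LEN_ORDER", "E_SEQ_LEN", "E_SEQ_CHARS",
    "E_ONLIST_MISSING", "E_ONLIST_FORBIDDEN", "E_ONLIST_FILE",
    "E_ONLIST_ENTRY", "E_MD5", "E_VOCAB", "E_JOINED_CHILDLESS",
    "E_ATOMIC_CHILDREN", "E_EMPTY", "W_UNKNOWN_KEY")
}

region_from_list <- function(x, path) {
  if (!is.list(x))
    stop_readspec(sprintf("region at %s is not a mapping", path),
                  "readspec_schema_error")
  missing <- setdiff(REQUIRED_REGION_KEYS, names(x))
  if (length(missing))
    stop_readspec(
      sprintf("missing required field(s) %s at %s",
              paste(missing, collapse = ", "), path),
      "readspec_schema_error")
  kids <- list()
  if (!is.null(x$regions)) {
    kids <- lapply(seq_along(x$regions), function(i) {
      child <- x$regions[[i]]
      cid <- if (is.list(child) && !is.null(child$region_id))
        child$region_id else sprintf("[%d]", i)
      region_from_list(child, paste(path, cid, sep = "/"))
    })
  }
  ol <- NULL
  if (!is.null(x$onlist)) {
    if (!is.list(x$onlist) || is.null(x$onlist$filename))
      stop_readspec(sprintf("onlist at %s must be a mapping with a filename",
                            path), "readspec_schema_error")
    ol <- onlist_ref(x$onlist$filename, md5 = x$onlist$md5)
  }
  extra <- x[setdiff(names(x), KNOWN_REGION_KEYS)]
  region(
    region_id = as.character(x$region_id),
    region_type = as.character(x$region_type),
    name = if (is.null(x$name)) as.character(x$region_id) else as.character(x$name),
    sequence_type = as.character(x$sequence_type),
    sequence = if (is.null(x$sequence)) "" else as.character(x$sequence),
    min_len = x$min_len, max_len = x$max_len,
    onlist = ol, regions = kids,
    extra = if (length(extra)) extra else NULL
  )
}

#' Load an assay specification from YAML
#'
#' @param file Path to a YAML document, or `NULL` when `text` is given.
#' @param text YAML text given directly (takes precedence over `file`).
#' @param strict If `TRUE`, unrecognized keys are an error; by default they
#'   are preserved (for round-tripping) and reported with a warning.
#' @return An [assay()] whose child order matches the document exactly.
#' @export
load_spec <- function(file = NULL, text = NULL, strict = FALSE) {
  doc <- tryCatch(
    if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(file),
    error = function(e) stop_readspec(
      sprintf("YAML parse error: %s", conditionMessage(e)),
      "readspec_parse_error"))
  if (!is.list(doc) || is.null(doc$regions) || length(doc$regions) == 0L)
    stop_readspec("document must define a non-empty 'regions' list at the root",
                  "readspec_schema_error")
  if (is.null(doc$assay_id))
    stop_readspec("missing required field assay_id at document root",
                  "readspec_schema_error")
  regions <- lapply(seq_along(doc$regions), function(i) {
    x <- doc$regions[[i]]
    rid <- if (is.list(x) && !is.null(x$region_id)) x$region_id
      else sprintf("[%d]", i)
    region_from_list(x, rid)
  })
  extra <- doc[setdiff(names(doc), KNOWN_ASSAY_KEYS)]
  a <- assay(
    assay_id = doc$assay_id,
    name = if (is.null(doc$name)) doc$assay_id else doc$name,
    doi = doc$doi, description = doc$description,
    modalities = if (is.null(doc$modalities)) "rna"
      else as.character(unlist(doc$modalities)),
    spec_version = doc$spec_version,
    regions = regions,
    extra = if (length(extra)) extra else NULL
  )
  unknown <- collect_unknown_keys(a)
  if (length(unknown)) {
    if (strict)
      stop_readspec(sprintf("unrecognized key(s): %s",
                            paste(unknown, collapse = ", ")),
                    "readspec_schema_error")
    warning(sprintf("preserving unrecognized key(s): %s",
                    paste(unique(unknown), collapse = ", ")),
            call. = FALSE)
  }
  a
}

collect_unknown_keys <- function(a) {
  out <- character(0)
  if (!is.null(a$extra)) out <- names(a$extra)
  for (r in pre_order(a))
    if (!is.null(r$extra))
      out <- c(out, paste0(r$region_id, ":", names(r$extra)))
  out
}

region_to_list <- function(r) {
  out <- list(
    region_id = r$region_id,
    region_type = r$region_type,
    name = r$name,
    sequence_type = r$sequence_type,
    sequence = r$sequence,
    min_len = r$min_len,
    max_len = r$max_len
  )
  if (!is.null(r$onlist)) {
    ol <- list(filename = r$onlist$filename)
    if (!is.null(r$onlist$md5)) ol$md5 <- r$onlist$md5
    out$onlist <- ol
  }
  if (length(r$regions)) out$regions <- lapply(r$regions, region_to_list)
  if (!is.null(r$extra)) out <- c(out, r$extra)
  out
}

assay_to_list <- function(a) {
  out <- list(assay_id = a$assay_id, name = a$name)
  if (!is.null(a$doi)) out$doi <- a$doi
  if (!is.null(a$description)) out$description <- a$description
  out$modalities <- as.list(a$modalities)
  if (!is.null(a$spec_version)) out$spec_version <- a$spec_version
  out$regions <- lapply(a$regions, region_to_list)
  if (!is.null(a$extra)) out <- c(out, a$extra)
  out
}

#' Serialize an assay to YAML
#'
#' Output is deterministic: fixed key order, 2-space indentation, children in
#' stored order, so two dumps of the same assay are byte-identical and
#' `load_spec(text = dump_spec(a))` reproduces `a`.
#'
#' @param assay An [assay()].
#' @param file Optional path; when given the text is also written there.
#' @return The YAML text, invisibly when `file` is given.
#' @export
dump_spec <- function(assay, file = NULL) {
  txt <- yaml::as.yaml(assay_to_list(assay), indent = 2,
                       indent.mapping.sequence = TRUE)
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Structural equality of two assays
#'
#' Compares the canonical serialized forms, so key order, sibling order and
#' every field (including preserved unknown keys) participate.
#'
#' @param a,b [assay()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
assay_equal <- function(a, b) {
  identical(assay_to_list(a), assay_to_list(b))
}

issue <- function(code, path, message) {
  data.frame(code = code, path = path, message = message,
             stringsAsFactors = FALSE)
}

resolve_onlist_path <- function(filename, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", filename)) filename
  else file.path(base_dir, filename)
}

#' Read an onlist file
#'
#' @param path Path to a text file with one sequence per line; gzip input is
#'   detected transparently.
#' @return Character vector of sequences.
#' @export
read_onlist <- function(path) {
  if (!file.exists(path))
    stop_readspec(sprintf("cannot read onlist file '%s'", path),
                  "readspec_io_error")
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  x <- readLines(con)
  x[nzchar(x)]
}

# md5 of the *uncompressed* content, so the checksum is stable across
# compression settings.
onlist_md5 <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(readLines(gzfile(path, open = "rt")), tmp)
    unname(tools::md5sum(tmp))
  } else {
    unname(tools::md5sum(path))
  }
}

#' Validate an assay against the schema
#'
#' Returns *all* violations rather than stopping at the first; an empty
#' result means the assay satisfies every model invariant. Issue codes form
#' a documented closed set:
#'
#' * `E_DUP_ID` — duplicated region_id in the tree
#' * `E_LEN_ORDER` — min_len > max_len
#' * `E_SEQ_LEN` — sequence length inconsistent with the length bounds
#'   (fixed: outside `[min_len, max_len]`; random: not `max_len` X's)
#' * `E_SEQ_CHARS` — sequence uses characters outside `{A,C,G,T,N,X}`, or a
#'   fixed sequence contains `X`
#' * `E_ONLIST_MISSING` — `sequence_type == "onlist"` without an onlist
#' * `E_ONLIST_FORBIDDEN` — onlist present on a non-onlist region
#' * `E_ONLIST_FILE` — onlist file absent/unreadable (`resolve_files = TRUE`)
#' * `E_ONLIST_ENTRY` — onlist entry length outside `[min_len, max_len]`
#' * `E_MD5` — malformed md5 field, or checksum mismatch against the file
#' * `E_VOCAB` — region_type or sequence_type outside the vocabulary
#' * `E_JOINED_CHILDLESS` — `sequence_type == "joined"` on an atomic region
#' * `E_ATOMIC_CHILDREN` — children present but `sequence_type != "joined"`
#' * `E_EMPTY` — assay has no top-level regions
#' * `W_UNKNOWN_KEY` — unrecognized key preserved from the document (warning)
#'
#' @param assay An [assay()] (possibly invalid).
#' @param base_dir Directory against which onlist filenames resolve.
#' @param resolve_files If `TRUE`, onlist files are opened and their entries
#'   and checksums verified.
#' @return A data.frame with columns `code`, `path` (slash-delimited
#'   region_id path from the root) and `message`; zero rows when clean.
#' @export
check_spec <- function(assay, base_dir = ".", resolve_files = FALSE) {
  issues <- list()
  add <- function(code, path, msg)
    issues[[length(issues) + 1L]] <<- issue(code, path, msg)

  if (length(assay$regions) == 0L)
    add("E_EMPTY", "/", "assay has no top-level regions")

  ids <- region_ids(assay)
  for (dup in unique(ids[duplicated(ids)]))
    add("E_DUP_ID", dup, sprintf("region_id '%s' occurs %d times",
                                 dup, sum(ids == dup)))

  if (!is.null(assay$extra))
    for (k in names(assay$extra))
      add("W_UNKNOWN_KEY", "/", sprintf("unrecognized key '%s' at root", k))

  walk <- function(r, path) {
    if (!r$region_type %in% region_types())
      add("E_VOCAB", path, sprintf("unknown region_type '%s'", r$region_type))
    if (!r$sequence_type %in% sequence_types())
      add("E_VOCAB", path,
          sprintf("unknown sequence_type '%s'", r$sequence_type))
    if (!is.na(r$min_len) && !is.na(r$max_len) && r$min_len > r$max_len)
      add("E_LEN_ORDER", path,
          sprintf("min_len %d > max_len %d", r$min_len, r$max_len))
    if (nzchar(r$sequence) &&
        !grepl("^[ACGTNX]*$", r$sequence))
      add("E_SEQ_CHARS", path,
          "sequence contains characters outside {A,C,G,T,N,X}")
    if (r$sequence_type == "fixed") {
      n <- nchar(r$sequence)
      if (n < r$min_len || n > r$max_len)
        add("E_SEQ_LEN", path,
            sprintf("fixed sequence length %d outside [%d, %d]",
                    n, r$min_len, r$max_len))
      if (grepl("X", r$sequence, fixed = TRUE))
        add("E_SEQ_CHARS", path, "fixed sequence must not contain X")
    }
    if (r$sequence_type == "random" &&
        r$sequence != strrep("X", r$max_len))
      add("E_SEQ_LEN", path,
          sprintf("random sequence must be 'X' repeated max_len (%d) times",
                  r$max_len))
    if (r$sequence_type == "onlist" && is.null(r$onlist))
      add("E_ONLIST_MISSING", path,
          "sequence_type is 'onlist' but no onlist is given")
    if (r$sequence_type != "onlist" && !is.null(r$onlist))
      add("E_ONLIST_FORBIDDEN", path,
          sprintf("onlist present on a '%s' region", r$sequence_type))
    if (r$sequence_type == "joined" && !is_meta(r))
      add("E_JOINED_CHILDLESS", path,
          "sequence_type 'joined' requires child regions")
    if (r$sequence_type != "joined" && is_meta(r))
      add("E_ATOMIC_CHILDREN", path,
          sprintf("region with children must have sequence_type 'joined', not '%s'",
                  r$sequence_type))
    if (!is.null(r$onlist)) {
      if (!is.null(r$onlist$md5) && !grepl("^[0-9a-f]{32}$", r$onlist$md5))
        add("E_MD5", path, sprintf("malformed md5 '%s'", r$onlist$md5))
      if (resolve_files) {
        p <- resolve_onlist_path(r$onlist$filename, base_dir)
        if (!file.exists(p)) {
          add("E_ONLIST_FILE", path,
              sprintf("onlist file '%s' does not exist", p))
        } else {
          seqs <- read_onlist(p)
          bad <- nchar(seqs) < r$min_len | nchar(seqs) > r$max_len
          if (any(bad))
            add("E_ONLIST_ENTRY", path,
                sprintf("%d onlist entr(ies) with length outside [%d, %d]",
                        sum(bad), r$min_len, r$max_len))
          if (!is.null(r$onlist$md5) &&
              grepl("^[0-9a-f]{32}$", r$onlist$md5) &&
              onlist_md5(p) != r$onlist$md5)
            add("E_MD5", path,
                sprintf("md5 mismatch for '%s'", r$onlist$filename))
        }
      }
    }
    if (!is.null(r$extra))
      for (k in names(r$extra))
        add("W_UNKNOWN_KEY", path, sprintf("unrecognized key '%s'", k))
    for (child in r$regions)
      walk(child, paste(path, child$region_id, sep = "/"))
  }
  for (r in assay$regions) walk(r, r$region_id)

  if (length(issues)) do.call(rbind, issues)
  else issue(character(0), character(0), character(0))
}
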