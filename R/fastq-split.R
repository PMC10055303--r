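# Split FASTQ records at Region boundaries and verify reads against a spec.
#
# Records are the plain 4-line discipline: "@header", sequence, "+",
# quality, with len(quality) == len(sequence). Gzip input/output is detected
# by the .gz suffix; output compression mirrors input. Splitting is purely
# positional — variable-length regions are only allowed in final position,
# where they take the remainder of each read; no in-read anchoring or
# pattern search is attempted.

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path; `.gz` input is decompressed transparently.
#' @return data.frame with columns `header` (without the leading `@`),
#'   `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  x <- readLines(con)
  if (length(x) %% 4L != 0L)
    stop_readspec(sprintf("'%s' is not 4-line FASTQ (%d lines)",
                          path, length(x)), "readspec_parse_error")
  h <- x[seq(1L, length(x), by = 4L)]
  if (length(h) && !all(startsWith(h, "@")))
    stop_readspec(sprintf("malformed FASTQ header in '%s'", path),
                  "readspec_parse_error")
  data.frame(header = sub("^@", "", h),
             sequence = x[seq(2L, length(x), by = 4L)],
             quality = x[seq(4L, length(x), by = 4L)],
             stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' @param records data.frame with columns `header`, `sequence`, `quality`.
#' @param path Output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "wt")
    else file(path, open = "wt")
  on.exit(close(con))
  if (nrow(records))
    writeLines(as.vector(rbind(paste0("@", records$header),
                               records$sequence, "+", records$quality)),
               con)
  invisible(path)
}

split_layout <- function(assay, read_id) {
  ix <- index_read(assay, read_id)
  iv <- ix$intervals
  if (any(iv$variable[-nrow(iv)]))
    stop_readspec(
      sprintf(paste0("read '%s' has a variable-length region before the ",
                     "final position; positional splitting is refused"),
              read_id),
      "readspec_refusal")
  iv
}

#' Split FASTQ records into per-Region records
#'
#' Each record's sequence and quality strings are sliced identically at the
#' read's interval boundaries; a variable-length *final* region takes the
#' remainder of the record. Headers gain a `/<region_id>` suffix. Records
#' shorter than the fixed prefix are skipped and counted; a residual length
#' outside the final region's `[min_len, max_len]` is counted as a length
#' violation (the record is still split, so rejoin stays exact).
#'
#' @param assay A formatted [assay()].
#' @param read_id The read's meta-Region id.
#' @param records data.frame as returned by [read_fastq()].
#' @return Named list (one element per atomic region, in order) of record
#'   data.frames, with attributes `skipped` (count of too-short records),
#'   `length_violations`, and `skipped_idx`.
#' @export
split_fastq <- function(assay, read_id, records) {
  iv <- split_layout(assay, read_id)
  nreg <- nrow(iv)
  final_var <- iv$variable[nreg]
  fixed_prefix <- if (final_var) iv$start[nreg] else iv$end[nreg]
  len <- nchar(records$sequence)
  ok <- len >= fixed_prefix
  skipped <- sum(!ok)
  kept <- records[ok, , drop = FALSE]
  residual <- nchar(kept$sequence) - fixed_prefix
  length_violations <- 0L
  if (final_var) {
    length_violations <- sum(residual < iv$min_len[nreg] |
                             residual > iv$max_len[nreg])
  } else {
    length_violations <- sum(nchar(kept$sequence) != iv$end[nreg])
  }
  out <- vector("list", nreg)
  names(out) <- iv$region_id
  for (i in seq_len(nreg)) {
    from <- iv$start[i] + 1L
    to <- if (i == nreg && final_var) nchar(kept$sequence) else iv$end[i]
    out[[i]] <- data.frame(
      header = paste0(kept$header, "/", iv$region_id[i]),
      sequence = substr(kept$sequence, from, to),
      quality = substr(kept$quality, from, to),
      stringsAsFactors = FALSE)
  }
  attr(out, "skipped") <- skipped
  attr(out, "skipped_idx") <- which(!ok)
  attr(out, "length_violations") <- length_violations
  out
}

#' Split a FASTQ file by Regions
#'
#' File-level wrapper around [split_fastq()]: writes one output file per
#' atomic region, `<out_prefix>.<region_id>.fastq[.gz]`, mirroring the
#' input's compression.
#'
#' @inheritParams split_fastq
#' @param fastq Input FASTQ path.
#' @param out_prefix Output path prefix.
#' @return Named character vector of output paths, with the same attributes
#'   as [split_fastq()].
#' @export
split_fastq_files <- function(assay, read_id, fastq, out_prefix) {
  gz <- grepl("\\.gz$", fastq)
  parts <- split_fastq(assay, read_id, read_fastq(fastq))
  paths <- vapply(names(parts), function(rid) {
    p <- sprintf("%s.%s.fastq%s", out_prefix, rid, if (gz) ".gz" else "")
    write_fastq(parts[[rid]], p)
    p
  }, character(1))
  attributes(paths) <- c(attributes(paths),
                         attributes(parts)[c("skipped", "length_violations")])
  paths
}

#' Verify FASTQ records against a spec
#'
#' Counts, per region: fixed-sequence mismatches (exact comparison, with `N`
#' in the read matching any base), onlist misses (exact membership), and
#' length violations (short records, plus residuals outside the final
#' region's bounds). All counts are deterministic.
#'
#' @inheritParams split_fastq
#' @param onlists Optional named list mapping region_id to a character
#'   vector of permissible sequences; by default every onlist referenced by
#'   the read's regions is loaded relative to `base_dir`.
#' @param base_dir Directory against which onlist filenames resolve.
#' @return A list of class `"verify_report"` with `total`, `skipped`,
#'   `length_violations`, and `per_region` (data.frame with columns
#'   region_id, fixed_mismatch, onlist_miss).
#' @export
verify_reads <- function(assay, read_id, records, onlists = NULL,
                         base_dir = ".") {
  iv <- split_layout(assay, read_id)
  parts <- split_fastq(assay, read_id, records)
  lv <- leaves(get_region(assay, read_id))
  per <- data.frame(region_id = iv$region_id,
                    fixed_mismatch = 0L, onlist_miss = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    r <- lv[[i]]
    obs <- parts[[r$region_id]]$sequence
    if (r$sequence_type == "fixed") {
      per$fixed_mismatch[i] <- sum(!matches_with_n(obs, r$sequence))
    } else if (r$sequence_type == "onlist") {
      allowed <- if (!is.null(onlists) && !is.null(onlists[[r$region_id]]))
        onlists[[r$region_id]]
      else read_onlist(resolve_onlist_path(r$onlist$filename, base_dir))
      per$onlist_miss[i] <- sum(!obs %in% allowed)
    }
  }
  structure(list(
    total = nrow(records),
    skipped = attr(parts, "skipped"),
    length_violations = attr(parts, "length_violations"),
    per_region = per
  ), class = "verify_report")
}

# exact match where N in the observed read matches any reference base
matches_with_n <- function(obs, ref) {
  if (length(obs) == 0L) return(logical(0))
  exact <- obs == ref
  if (all(exact) || !any(grepl("N", obs[!exact], fixed = TRUE)))
    return(exact & nchar(obs) == nchar(ref))
  vapply(seq_along(obs), function(i) {
    if (nchar(obs[i]) != nchar(ref)) return(FALSE)
    o <- strsplit(obs[i], "")[[1L]]
    r <- strsplit(ref, "")[[1L]]
    all(o == r | o == "N")
  }, logical(1))
}

#' @export
print.verify_report <- function(x, ...) {
  cat(sprintf("verified %d record(s): %d skipped, %d length violation(s)\n",
              x$total, x$skipped, x$length_violations))
  print(x$per_region, row.names = FALSE)
  invisible(x)
}
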