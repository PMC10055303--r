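# Synthetic fixtures: specs, onlists and FASTQ reads with known ground
# truth, so every operation is testable without external downloads. All
# generation is deterministic under a seed.
#
# Canonical layouts:
#   tenx_like              — droplet scRNA-seq geometry: R1 = 16-nt onlist
#                            barcode + 12-nt random UMI; R2 = cDNA (1..read_len).
#   splitpool_like         — three 8-nt barcode rounds, each with its own
#                            onlist, separated by fixed 6-nt linkers, then a
#                            10-nt UMI on R1; cDNA on R2.
#   adapter_insert_adapter — a single construct: fixed adapter, variable
#                            insert, fixed adapter (the variable insert sits
#                            upstream of a fixed element, so fixed-position
#                            consumers must refuse this layout).
#   random_tree            — a random nested tree of fixed-length regions,
#                            for structural property tests.
#
# An unbounded cDNA region is modeled with max_len equal to the sequencer
# read-length remainder (read_len), so intervals stay finite.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

distinct_random_seqs <- function(n, len) {
  out <- unique(random_seqs(n, len))
  while (length(out) < n)
    out <- unique(c(out, random_seqs(n - length(out), len)))
  out
}

#' Simulation configuration
#'
#' @param n_reads Number of records to simulate.
#' @param seed RNG seed; identical configurations give byte-identical output.
#' @param barcode_corruption_rate Per-record probability that one onlist
#'   (barcode) region is replaced by a sequence not on its onlist.
#' @param fixed_corruption_rate Per-record probability that one
#'   fixed-sequence region is replaced by a different random sequence.
#' @param onlist_size Number of distinct sequences per generated onlist.
#' @param layout One of `"tenx_like"`, `"splitpool_like"`,
#'   `"adapter_insert_adapter"`, `"random_tree"`.
#' @param read_len Maximum length for otherwise unbounded cDNA regions.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_reads = 1000L, seed = 1L,
                       barcode_corruption_rate = 0,
                       fixed_corruption_rate = 0,
                       onlist_size = 100L, layout = "tenx_like",
                       read_len = 98L) {
  layout <- match.arg(layout, c("tenx_like", "splitpool_like",
                                "adapter_insert_adapter", "random_tree"))
  structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                 barcode_corruption_rate = barcode_corruption_rate,
                 fixed_corruption_rate = fixed_corruption_rate,
                 onlist_size = as.integer(onlist_size), layout = layout,
                 read_len = as.integer(read_len)),
            class = "sim_config")
}

write_onlist_file <- function(seqs, path) {
  writeLines(seqs, path)
  path
}

onlist_region <- function(rid, type, len, filename, seqs, dir) {
  p <- file.path(dir, filename)
  write_onlist_file(seqs, p)
  region(rid, region_type = type, sequence_type = "onlist",
         sequence = strrep("X", len), min_len = len, max_len = len,
         onlist = onlist_ref(filename, md5 = onlist_md5(p)))
}

make_tenx <- function(seed, dir, onlist_size, read_len) {
  bcs <- distinct_random_seqs(onlist_size, 16L)
  bc <- onlist_region("bc", "barcode", 16L, "bc_onlist.txt", bcs, dir)
  umi <- region("umi", "umi", "random", sequence = strrep("X", 12L),
                min_len = 12L, max_len = 12L)
  cdna <- region("cdna", "cdna", "random",
                 sequence = strrep("X", read_len),
                 min_len = 1L, max_len = read_len)
  a <- assay("tenx_like",
             name = "droplet scRNA-seq style fixture",
             modalities = "rna",
             regions = list(
               region("R1", "fastq", "joined", regions = list(bc, umi)),
               region("R2", "fastq", "joined", regions = list(cdna))))
  ledger <- list(
    reads = c("R1", "R2"),
    intervals = list(
      R1 = data.frame(region_id = c("bc", "umi"),
                      start = c(0L, 16L), end = c(16L, 28L),
                      stringsAsFactors = FALSE),
      R2 = data.frame(region_id = "cdna", start = 0L,
                      end = as.integer(read_len), stringsAsFactors = FALSE)),
    onlists = list(bc = bcs),
    onlist_paths = file.path(dir, "bc_onlist.txt"))
  list(assay = a, ledger = ledger)
}

make_splitpool <- function(seed, dir, onlist_size, read_len) {
  kids <- list()
  onlists <- list()
  paths <- character(0)
  starts <- integer(0)
  cursor <- 0L
  ids <- character(0)
  for (i in 1:3) {
    seqs <- distinct_random_seqs(onlist_size, 8L)
    rid <- sprintf("bc%d", i)
    fn <- sprintf("bc%d_onlist.txt", i)
    kids[[length(kids) + 1L]] <-
      onlist_region(rid, "barcode", 8L, fn, seqs, dir)
    onlists[[rid]] <- seqs
    paths <- c(paths, file.path(dir, fn))
    ids <- c(ids, rid); starts <- c(starts, cursor); cursor <- cursor + 8L
    if (i < 3) {
      lid <- sprintf("linker%d", i)
      lseq <- random_seqs(1L, 6L)
      kids[[length(kids) + 1L]] <-
        region(lid, "linker", "fixed", sequence = lseq,
               min_len = 6L, max_len = 6L)
      ids <- c(ids, lid); starts <- c(starts, cursor); cursor <- cursor + 6L
    }
  }
  kids[[length(kids) + 1L]] <-
    region("umi", "umi", "random", sequence = strrep("X", 10L),
           min_len = 10L, max_len = 10L)
  ids <- c(ids, "umi"); starts <- c(starts, cursor); cursor <- cursor + 10L
  cdna <- region("cdna", "cdna", "random", sequence = strrep("X", read_len),
                 min_len = 1L, max_len = read_len)
  a <- assay("splitpool_like",
             name = "split-pool barcoding fixture",
             modalities = "rna",
             regions = list(
               region("R1", "fastq", "joined", regions = kids),
               region("R2", "fastq", "joined", regions = list(cdna))))
  widths <- diff(c(starts, cursor))
  ledger <- list(
    reads = c("R1", "R2"),
    intervals = list(
      R1 = data.frame(region_id = ids, start = starts,
                      end = as.integer(starts + widths),
                      stringsAsFactors = FALSE),
      R2 = data.frame(region_id = "cdna", start = 0L,
                      end = as.integer(read_len), stringsAsFactors = FALSE)),
    onlists = onlists,
    onlist_paths = paths)
  list(assay = a, ledger = ledger)
}

make_adapter_insert <- function(seed, dir, onlist_size, read_len) {
  a5 <- random_seqs(1L, 12L)
  a3 <- random_seqs(1L, 12L)
  insert_max <- 50L
  a <- assay("adapter_insert_adapter",
             name = "adapter-insert-adapter construct fixture",
             modalities = "rna",
             regions = list(
               region("construct", "named_region", "joined", regions = list(
                 region("adapter5", "adapter", "fixed", sequence = a5,
                        min_len = 12L, max_len = 12L),
                 region("insert", "cdna", "random",
                        sequence = strrep("X", insert_max),
                        min_len = 1L, max_len = insert_max),
                 region("adapter3", "adapter", "fixed", sequence = a3,
                        min_len = 12L, max_len = 12L)))))
  ledger <- list(
    reads = "construct",
    intervals = list(
      construct = data.frame(
        region_id = c("adapter5", "insert", "adapter3"),
        start = c(0L, 12L, 62L), end = c(12L, 62L, 74L),
        stringsAsFactors = FALSE)),
    onlists = list(), onlist_paths = character(0))
  list(assay = a, ledger = ledger)
}

make_random_tree <- function(seed, dir, onlist_size, read_len) {
  counter <- 0L
  new_id <- function(prefix) {
    counter <<- counter + 1L
    sprintf("%s%d", prefix, counter)
  }
  leaf_types <- c("barcode", "umi", "cdna", "adapter", "linker", "other")
  gen <- function(depth) {
    if (depth >= 3L || stats::runif(1) < 0.4) {
      len <- sample(1:12, 1L)
      if (stats::runif(1) < 0.5)
        region(new_id("leaf"), sample(leaf_types, 1L), "fixed",
               sequence = random_seqs(1L, len),
               min_len = len, max_len = len)
      else
        region(new_id("leaf"), sample(leaf_types, 1L), "random",
               sequence = strrep("X", len), min_len = len, max_len = len)
    } else {
      n <- sample(1:3, 1L)
      region(new_id("meta"), "named_region", "joined",
             regions = lapply(seq_len(n), function(i) gen(depth + 1L)))
    }
  }
  n_top <- sample(1:3, 1L)
  tops <- lapply(seq_len(n_top), function(i) {
    r <- gen(1L)
    # a top-level construct is always a meta region
    if (length(r$regions)) r
    else region(new_id("read"), "fastq", "joined", regions = list(r))
  })
  a <- assay("random_tree", name = "random nested fixture",
             regions = tops)
  read_ids <- vapply(tops, `[[`, character(1), "region_id")
  intervals <- lapply(tops, function(top) {
    lv <- leaves(top)
    w <- vapply(lv, `[[`, integer(1), "max_len")
    ends <- cumsum(w)
    data.frame(region_id = vapply(lv, `[[`, character(1), "region_id"),
               start = as.integer(c(0L, ends[-length(ends)])),
               end = as.integer(ends), stringsAsFactors = FALSE)
  })
  names(intervals) <- read_ids
  list(assay = a,
       ledger = list(reads = read_ids, intervals = intervals,
                     onlists = list(), onlist_paths = character(0)))
}

#' Generate a synthetic spec with a ground-truth ledger
#'
#' Builds a valid, formatted assay for one of the canonical layouts, writes
#' any onlist files (with md5 checksums) under `dir`, and returns a ledger
#' of expected index intervals, onlist paths and onlist contents. The
#' result passes [check_spec()] with `resolve_files = TRUE`.
#'
#' @param layout One of `"tenx_like"`, `"splitpool_like"`,
#'   `"adapter_insert_adapter"`, `"random_tree"`.
#' @param seed RNG seed; a fixed seed gives an identical assay across runs.
#' @param dir Directory for onlist files (created if needed).
#' @param onlist_size Sequences per onlist.
#' @param read_len Maximum cDNA length (sequencer read-length remainder).
#' @return List with elements `assay` (formatted), `ledger` and `dir`.
#' @export
make_spec <- function(layout = c("tenx_like", "splitpool_like",
                                 "adapter_insert_adapter", "random_tree"),
                      seed = 1L, dir = tempfile("fixture"),
                      onlist_size = 100L, read_len = 98L) {
  layout <- match.arg(layout)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- with_seed(seed, switch(
    layout,
    tenx_like = make_tenx(seed, dir, onlist_size, read_len),
    splitpool_like = make_splitpool(seed, dir, onlist_size, read_len),
    adapter_insert_adapter = make_adapter_insert(seed, dir, onlist_size,
                                                 read_len),
    random_tree = make_random_tree(seed, dir, onlist_size, read_len)))
  out$assay <- format_spec(out$assay)
  out$dir <- dir
  out
}

#' Simulate FASTQ reads from a spec
#'
#' Draws each record by concatenating per-region sequences: `fixed` regions
#' contribute their literal sequence; `onlist` regions a uniform draw from
#' the onlist; `random` regions uniform A/C/G/T bases (of length uniform in
#' `[min_len, max_len]` for a final variable region, `max_len` otherwise).
#' Corruptions are applied per the configuration and logged per record, so
#' verification counts can be compared against an exact ledger. Output is
#' deterministic under `cfg$seed`.
#'
#' @param assay A formatted [assay()].
#' @param read_id The read's meta-Region id.
#' @param cfg A [sim_config()].
#' @param onlists Named list region_id -> permissible sequences (e.g. the
#'   fixture ledger's `onlists`); required for onlist regions.
#' @return List with `records` (data.frame header/sequence/quality) and
#'   `ledger` (data.frame record/region_id/kind of seeded corruptions).
#' @export
simulate_reads <- function(assay, read_id, cfg, onlists = list()) {
  iv <- split_layout(assay, read_id)  # same refusal rule as split_fastq
  lv <- leaves(get_region(assay, read_id))
  with_seed(cfg$seed, {
    n <- cfg$n_reads
    cols <- lapply(seq_along(lv), function(i) {
      r <- lv[[i]]
      final <- i == length(lv)
      switch(r$sequence_type,
        fixed = rep(r$sequence, n),
        onlist = {
          allowed <- onlists[[r$region_id]]
          if (is.null(allowed))
            stop_readspec(
              sprintf("no onlist sequences supplied for region '%s'",
                      r$region_id), "readspec_value_error")
          sample(allowed, n, replace = TRUE)
        },
        random = {
          lens <- if (final && r$min_len != r$max_len)
            sample(seq(r$min_len, r$max_len), n, replace = TRUE)
          else rep(r$max_len, n)
          vapply(lens, function(L)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""), character(1))
        },
        stop_readspec(
          sprintf("cannot simulate sequence_type '%s'", r$sequence_type),
          "readspec_structural_error"))
    })
    names(cols) <- vapply(lv, `[[`, character(1), "region_id")

    ledger <- list()
    onlist_idx <- which(vapply(lv, function(r)
      r$sequence_type == "onlist", logical(1)))
    fixed_idx <- which(vapply(lv, function(r)
      r$sequence_type == "fixed", logical(1)))
    for (rec in seq_len(n)) {
      if (length(onlist_idx) &&
          stats::runif(1) < cfg$barcode_corruption_rate) {
        j <- if (length(onlist_idx) == 1L) onlist_idx
          else sample(onlist_idx, 1L)
        r <- lv[[j]]
        allowed <- onlists[[r$region_id]]
        repeat {
          corrupt <- random_seqs(1L, r$max_len)
          if (!corrupt %in% allowed) break
        }
        cols[[j]][rec] <- corrupt
        ledger[[length(ledger) + 1L]] <-
          data.frame(record = rec, region_id = r$region_id,
                     kind = "onlist", stringsAsFactors = FALSE)
      }
      if (length(fixed_idx) &&
          stats::runif(1) < cfg$fixed_corruption_rate) {
        j <- if (length(fixed_idx) == 1L) fixed_idx
          else sample(fixed_idx, 1L)
        r <- lv[[j]]
        repeat {
          corrupt <- random_seqs(1L, r$max_len)
          if (corrupt != r$sequence) break
        }
        cols[[j]][rec] <- corrupt
        ledger[[length(ledger) + 1L]] <-
          data.frame(record = rec, region_id = r$region_id,
                     kind = "fixed", stringsAsFactors = FALSE)
      }
    }
    seqs <- do.call(paste0, cols)
    records <- data.frame(
      header = sprintf("sim_%s_%d", read_id, seq_len(n)),
      sequence = seqs,
      quality = strrep("I", nchar(seqs)),
      stringsAsFactors = FALSE)
    ledger <- if (length(ledger)) do.call(rbind, ledger)
      else data.frame(record = integer(0), region_id = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
    list(records = records, ledger = ledger)
  })
}
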