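# Independent oracles and small in-code fixtures shared across the suite.
# The oracles deliberately use different algorithms from the implementation
# (iterative stack traversal, explicit accumulation loops) so agreement is
# informative.

# Pre-order traversal via an explicit stack (vs the recursive implementation).
oracle_pre_order <- function(x) {
  roots <- if (inherits(x, "assay")) x$regions else list(x)
  out <- list()
  stack <- rev(roots)
  while (length(stack)) {
    r <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    out[[length(out) + 1L]] <- r
    if (length(r$regions))
      for (ch in rev(r$regions)) stack[[length(stack) + 1L]] <- ch
  }
  out
}

oracle_leaf_ids <- function(x) {
  flat <- oracle_pre_order(x)
  ids <- vapply(flat, `[[`, character(1), "region_id")
  ids[vapply(flat, function(r) length(r$regions) == 0L, logical(1))]
}

# Cumulative-sum layout oracle: explicit loop over childless descendants.
oracle_intervals <- function(read_region) {
  flat <- oracle_pre_order(read_region)
  atoms <- flat[vapply(flat, function(r) length(r$regions) == 0L, logical(1))]
  start <- 0L
  rows <- lapply(atoms, function(r) {
    row <- data.frame(region_id = r$region_id, start = start,
                      end = start + r$max_len, stringsAsFactors = FALSE)
    start <<- start + r$max_len
    row
  })
  do.call(rbind, rows)
}

ids_of <- function(regions) vapply(regions, `[[`, character(1), "region_id")

# A minimal clean single-read assay with one fixed, one onlist and one
# random region; the onlist file is written under `dir` with a correct md5.
clean_read_assay <- function(dir) {
  seqs <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT")
  writeLines(seqs, file.path(dir, "bc8.txt"))
  a <- assay("mini", regions = list(
    region("R1", "fastq", "joined", regions = list(
      region("link", "linker", "fixed", sequence = "ACGT",
             min_len = 4L, max_len = 4L),
      region("bc", "barcode", "onlist", sequence = strrep("X", 8L),
             min_len = 8L, max_len = 8L,
             onlist = onlist_ref("bc8.txt",
                                 md5 = unname(tools::md5sum(file.path(dir, "bc8.txt"))))),
      region("umi", "umi", "random", sequence = strrep("X", 8L),
             min_len = 8L, max_len = 8L)))))
  format_spec(a)
}

# One seeded mutation per validation issue code, each constructed so that
# exactly that issue (and no other) is reported. Returns a list of
# list(code, assay, resolve) entries.
seeded_mutations <- function(dir) {
  base <- clean_read_assay(dir)
  mod <- function(f) {
    a <- base
    a$regions[[1]]$regions <- f(a$regions[[1]]$regions)
    a
  }
  short_file <- file.path(dir, "bc_short.txt")
  writeLines(c("AAAAAAAA", "AC"), short_file)
  short_md5 <- unname(tools::md5sum(short_file))

  list(
    list(code = "E_DUP_ID", resolve = FALSE, assay = mod(function(k) {
      k[[3]]$region_id <- "link"; k })),
    list(code = "E_LEN_ORDER", resolve = FALSE, assay = mod(function(k) {
      k[[3]]$min_len <- 10L; k })),
    list(code = "E_SEQ_LEN", resolve = FALSE, assay = mod(function(k) {
      k[[1]]$sequence <- "ACGTA"; k })),
    list(code = "E_SEQ_CHARS", resolve = FALSE, assay = mod(function(k) {
      k[[1]]$sequence <- "ACBT"; k })),
    list(code = "E_ONLIST_MISSING", resolve = FALSE, assay = mod(function(k) {
      k[[2]]$onlist <- NULL; k })),
    list(code = "E_ONLIST_FORBIDDEN", resolve = FALSE, assay = mod(function(k) {
      k[[1]]$onlist <- onlist_ref("bc8.txt"); k })),
    list(code = "E_ONLIST_FILE", resolve = TRUE, assay = mod(function(k) {
      k[[2]]$onlist$filename <- "missing.txt"; k })),
    list(code = "E_ONLIST_ENTRY", resolve = TRUE, assay = mod(function(k) {
      k[[2]]$onlist <- onlist_ref("bc_short.txt", md5 = short_md5); k })),
    list(code = "E_MD5", resolve = TRUE, assay = mod(function(k) {
      k[[2]]$onlist$md5 <- strrep("0", 32L); k })),
    list(code = "E_VOCAB", resolve = FALSE, assay = mod(function(k) {
      k[[2]]$region_type <- "bogus"; k })),
    list(code = "E_JOINED_CHILDLESS", resolve = FALSE, assay = mod(function(k) {
      k[[3]]$sequence_type <- "joined"; k })),
    list(code = "E_ATOMIC_CHILDREN", resolve = FALSE, assay = {
      a <- base
      a$regions[[1]]$sequence_type <- "random"
      # keep the random-sequence convention satisfied so only the
      # children/sequence_type contradiction is reported
      a$regions[[1]]$sequence <- strrep("X", a$regions[[1]]$max_len)
      a }),
    list(code = "E_EMPTY", resolve = FALSE, assay = {
      a <- base
      a$regions <- list()
      a }),
    list(code = "W_UNKNOWN_KEY", resolve = FALSE, assay = mod(function(k) {
      k[[2]]$extra <- list(color = "blue"); k }))
  )
}

# Random newick generator over the init grammar: unique labels, integer
# lengths, internal root.
random_newick <- function(seed) {
  counter <- 0L
  gen <- function(depth) {
    counter <<- counter + 1L
    my <- counter
    if (depth >= 3L || stats::runif(1) < 0.45) {
      sprintf("n%d:%d", my, sample(1:99, 1L))
    } else {
      kids <- vapply(seq_len(sample(1:3, 1L)), function(i)
        gen(depth + 1L), character(1))
      sprintf("(%s)n%d", paste(kids, collapse = ","), my)
    }
  }
  set.seed(seed)
  kids <- vapply(seq_len(sample(1:3, 1L)), function(i) gen(1L),
                 character(1))
  counter <- counter + 1L
  sprintf("(%s)root;", paste(kids, collapse = ","))
}

# Geometry a dialect string must encode: barcode/umi/sequence intervals with
# 0-based file numbers in input order.
expected_geometry <- function(indices) {
  rows <- lapply(seq_along(indices), function(i) {
    iv <- indices[[i]]$intervals
    iv <- iv[iv$region_type %in% c("barcode", "umi", "cdna", "gdna"), ,
             drop = FALSE]
    if (nrow(iv) == 0L) return(NULL)
    data.frame(read = i - 1L,
               kind = ifelse(iv$region_type %in% c("cdna", "gdna"),
                             "sequence", iv$region_type),
               start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sorted_geometry <- function(g) {
  g <- g[g$kind %in% c("barcode", "umi", "sequence"), , drop = FALSE]
  g <- g[order(g$read, g$start, g$kind), ]
  rownames(g) <- NULL
  g
}
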