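test_that("a minimal document loads into one top-level region", {
  txt <- paste(
    "assay_id: mini",
    "regions:",
    "  - region_id: probe",
    "    region_type: other",
    "    sequence_type: fixed",
    "    sequence: ACGT",
    "    min_len: 4",
    "    max_len: 4",
    sep = "\n")
  a <- load_spec(text = txt)
  expect_s3_class(a, "assay")
  expect_length(a$regions, 1L)
  expect_identical(a$regions[[1]]$sequence, "ACGT")
})

test_that("missing required fields raise schema errors naming the path", {
  txt <- paste(
    "assay_id: mini",
    "regions:",
    "  - region_id: probe",
    "    region_type: other",
    "    min_len: 4",
    "    max_len: 4",
    sep = "\n")
  err <- expect_error(load_spec(text = txt), class = "readspec_schema_error")
  expect_match(conditionMessage(err), "sequence_type")
  expect_match(conditionMessage(err), "probe")
  expect_error(load_spec(text = "regions: ["), class = "readspec_parse_error")
})

test_that("child order survives a load and matches the raw text", {
  fx <- make_spec("tenx_like", seed = 4)
  txt <- dump_spec(fx$assay)
  a <- load_spec(text = txt)
  expect_identical(ids_of(leaves(a)), c("bc", "umi", "cdna"))
  # order in the parsed object matches textual occurrence order
  occurrence <- regmatches(txt, gregexpr("region_id: [A-Za-z0-9]+", txt))[[1]]
  expect_identical(sub("region_id: ", "", occurrence),
                   ids_of(pre_order(a)))
})

test_that("dump/load round-trips preserve structure; dumps are deterministic", {
  for (seed in 1:20) {
    fx <- make_spec("random_tree", seed = seed)
    t1 <- dump_spec(fx$assay)
    t2 <- dump_spec(fx$assay)
    expect_identical(t1, t2)
    expect_true(assay_equal(load_spec(text = t1), fx$assay))
  }
  # all named layouts, including onlist metadata
  for (layout in c("tenx_like", "splitpool_like", "adapter_insert_adapter")) {
    fx <- make_spec(layout, seed = 7)
    expect_true(assay_equal(load_spec(text = dump_spec(fx$assay)), fx$assay))
  }
})

test_that("nesting depth maps to indentation units in the dump", {
  a <- format_spec(assay("deep", regions = list(
    region("L1", "named_region", "joined", regions = list(
      region("L2", "named_region", "joined", regions = list(
        region("L3", "other", "fixed", sequence = "AC",
               min_len = 2L, max_len = 2L))))))))
  lines <- strsplit(dump_spec(a), "\n")[[1]]
  grandchild <- grep("region_id: L3", lines, value = TRUE)
  # each nesting level adds one 4-space unit (2 for the mapping indent plus
  # 2 for the sequence-item marker); L3 sits at depth 3
  expect_identical(sub("region_id.*", "", grandchild),
                   paste0(strrep(" ", 2L + 4L * 2L), "- "))
})

test_that("unknown keys warn, are preserved, and error under strict", {
  txt <- paste(
    "assay_id: mini",
    "vendor: acme",
    "regions:",
    "  - region_id: probe",
    "    region_type: other",
    "    sequence_type: fixed",
    "    sequence: ACGT",
    "    min_len: 4",
    "    max_len: 4",
    "    color: blue",
    sep = "\n")
  expect_warning(a <- load_spec(text = txt), "unrecognized")
  expect_identical(a$extra$vendor, "acme")
  expect_identical(a$regions[[1]]$extra$color, "blue")
  redumped <- dump_spec(a)
  expect_match(redumped, "vendor: acme")
  expect_match(redumped, "color: blue")
  expect_error(load_spec(text = txt, strict = TRUE),
               class = "readspec_schema_error")
  issues <- check_spec(a)
  expect_setequal(issues$code, "W_UNKNOWN_KEY")
  expect_equal(nrow(issues), 2L)
})

test_that("check_spec is sound on clean fixtures", {
  for (layout in c("tenx_like", "splitpool_like", "adapter_insert_adapter")) {
    fx <- make_spec(layout, seed = 5)
    expect_identical(nrow(check_spec(fx$assay, base_dir = fx$dir,
                                     resolve_files = TRUE)), 0L)
  }
  for (seed in 1:10)
    expect_identical(nrow(check_spec(make_spec("random_tree",
                                               seed = seed)$assay)), 0L)
})

test_that("each seeded mutation triggers exactly its issue code", {
  dir <- withr::local_tempdir()
  for (m in seeded_mutations(dir)) {
    issues <- check_spec(m$assay, base_dir = dir, resolve_files = m$resolve)
    expect_identical(issues$code, m$code)
  }
})

test_that("independent mutations are all reported together", {
  dir <- withr::local_tempdir()
  fx <- make_spec("splitpool_like", seed = 3, dir = dir)
  a <- fx$assay
  k <- a$regions[[1]]$regions
  k[[1]]$onlist$filename <- "missing.txt"        # bc1 -> E_ONLIST_FILE
  k[[3]]$onlist$md5 <- strrep("0", 32L)          # bc2 -> E_MD5
  k[[5]]$region_type <- "bogus"                  # bc3 -> E_VOCAB
  k[[2]]$sequence <- "ACBTAA"                    # linker1 -> E_SEQ_CHARS
  k[[4]]$sequence <- paste0(k[[4]]$sequence, "A") # linker2 -> E_SEQ_LEN
  k[[6]]$min_len <- 99L                          # umi -> E_LEN_ORDER
  k[[6]]$region_id <- "bc1"                      # umi -> E_DUP_ID
  a$regions[[1]]$regions <- k
  a$regions[[2]]$regions[[1]]$extra <- list(note = "x") # cdna -> W_UNKNOWN_KEY
  issues <- check_spec(a, base_dir = dir, resolve_files = TRUE)
  expect_equal(nrow(issues), 8L)
  expect_setequal(issues$code,
                  c("E_ONLIST_FILE", "E_MD5", "E_VOCAB", "E_SEQ_CHARS",
                    "E_SEQ_LEN", "E_LEN_ORDER", "E_DUP_ID", "W_UNKNOWN_KEY"))
})

test_that("issue paths point at the offending node", {
  dir <- withr::local_tempdir()
  a <- clean_read_assay(dir)
  a$regions[[1]]$regions[[2]]$min_len <- 20L
  issues <- check_spec(a)
  expect_identical(issues$code, "E_LEN_ORDER")
  expect_identical(issues$path, "R1/bc")
})
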