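tenx_r1_assay <- function() {
  format_spec(assay("x", regions = list(
    region("R1", "fastq", "joined", regions = list(
      region("bc", "barcode", "random", sequence = strrep("X", 16L),
             min_len = 16L, max_len = 16L),
      region("umi", "umi", "random", sequence = strrep("X", 12L),
             min_len = 12L, max_len = 12L),
      region("cdna", "cdna", "random", sequence = strrep("X", 98L),
             min_len = 0L, max_len = 98L))))))
}

fq_record <- function(len, header = "rec1") {
  s <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  data.frame(header = header, sequence = s,
             quality = strrep("F", len), stringsAsFactors = FALSE)
}

test_that("records are sliced at interval boundaries with headers suffixed", {
  a <- tenx_r1_assay()
  rec <- fq_record(100L)
  parts <- split_fastq(a, "R1", rec)
  expect_identical(names(parts), c("bc", "umi", "cdna"))
  expect_identical(nchar(parts$bc$sequence), 16L)
  expect_identical(nchar(parts$umi$sequence), 12L)
  expect_identical(nchar(parts$cdna$sequence), 72L)
  expect_identical(parts$bc$header, "rec1/bc")
  expect_identical(nchar(parts$cdna$quality), 72L)
  expect_identical(attr(parts, "skipped"), 0L)
  expect_identical(attr(parts, "length_violations"), 0L)

  # exactly the fixed prefix: empty final slice, no violation
  parts28 <- split_fastq(a, "R1", fq_record(28L))
  expect_identical(parts28$cdna$sequence, "")
  expect_identical(attr(parts28, "length_violations"), 0L)

  # shorter than the fixed prefix: skipped and counted
  parts20 <- split_fastq(a, "R1", rbind(fq_record(20L, "short"),
                                        fq_record(100L, "ok")))
  expect_identical(attr(parts20, "skipped"), 1L)
  expect_identical(parts20$bc$header, "ok/bc")
})

test_that("split refuses variable-length regions before the final position", {
  fx <- make_spec("adapter_insert_adapter", seed = 2)
  expect_error(split_fastq(fx$assay, "construct", fq_record(74L)),
               class = "readspec_refusal")
})

test_that("per-region slices rejoin to the original records exactly", {
  fx <- make_spec("splitpool_like", seed = 9)
  sim <- simulate_reads(fx$assay, "R1", sim_config(n_reads = 500, seed = 11),
                        onlists = fx$ledger$onlists)
  parts <- split_fastq(fx$assay, "R1", sim$records)
  rejoined_seq <- do.call(paste0, lapply(parts, `[[`, "sequence"))
  rejoined_qual <- do.call(paste0, lapply(parts, `[[`, "quality"))
  expect_identical(rejoined_seq, sim$records$sequence)
  expect_identical(rejoined_qual, sim$records$quality)
  # conservation of record counts per region
  for (p in parts)
    expect_identical(nrow(p), nrow(sim$records) - attr(parts, "skipped"))
})

test_that("file round trip mirrors gzip and preserves bytes", {
  dir <- withr::local_tempdir()
  fx <- make_spec("tenx_like", seed = 12)
  sim <- simulate_reads(fx$assay, "R1", sim_config(n_reads = 40, seed = 5),
                        onlists = fx$ledger$onlists)
  gz <- file.path(dir, "r1.fastq.gz")
  write_fastq(sim$records, gz)
  expect_identical(read_fastq(gz), sim$records)

  paths <- split_fastq_files(fx$assay, "R1", gz, file.path(dir, "out"))
  expect_true(all(grepl("\\.fastq\\.gz$", paths)))
  expect_true(all(file.exists(paths)))
  bc <- read_fastq(paths[["bc"]])
  expect_identical(bc$sequence, substr(sim$records$sequence, 1L, 16L))
})

test_that("verify_reads counts nothing on faithful reads", {
  fx <- make_spec("splitpool_like", seed = 13)
  sim <- simulate_reads(fx$assay, "R1", sim_config(n_reads = 300, seed = 3),
                        onlists = fx$ledger$onlists)
  rep <- verify_reads(fx$assay, "R1", sim$records,
                      onlists = fx$ledger$onlists)
  expect_identical(rep$skipped, 0L)
  expect_identical(rep$length_violations, 0L)
  expect_identical(sum(rep$per_region$fixed_mismatch), 0L)
  expect_identical(sum(rep$per_region$onlist_miss), 0L)
})

test_that("verify_reads counts match the simulator's corruption ledger", {
  fx <- make_spec("splitpool_like", seed = 14)
  cfg <- sim_config(n_reads = 1000, seed = 7,
                    barcode_corruption_rate = 0.1,
                    fixed_corruption_rate = 0.05)
  sim <- simulate_reads(fx$assay, "R1", cfg, onlists = fx$ledger$onlists)
  rep <- verify_reads(fx$assay, "R1", sim$records,
                      onlists = fx$ledger$onlists)
  led <- sim$ledger
  expect_gt(nrow(led), 0L)
  for (rid in rep$per_region$region_id) {
    expect_identical(
      rep$per_region$onlist_miss[rep$per_region$region_id == rid],
      nrow(led[led$region_id == rid & led$kind == "onlist", ]))
    expect_identical(
      rep$per_region$fixed_mismatch[rep$per_region$region_id == rid],
      nrow(led[led$region_id == rid & led$kind == "fixed", ]))
  }
})

test_that("N bases in reads match any fixed base", {
  a <- format_spec(assay("n", regions = list(
    region("R", "fastq", "joined", regions = list(
      region("ad", "adapter", "fixed", sequence = "ACGTACGT",
             min_len = 8L, max_len = 8L))))))
  recs <- data.frame(header = c("a", "b", "c"),
                     sequence = c("ACGTACGT", "ANGTACGT", "AAGTACGT"),
                     quality = rep(strrep("I", 8L), 3),
                     stringsAsFactors = FALSE)
  rep <- verify_reads(a, "R", recs)
  expect_identical(rep$per_region$fixed_mismatch, 1L)
})
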