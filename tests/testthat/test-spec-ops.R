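test_that("format_spec joins sequences and sums lengths bottom-up", {
  a <- assay("x", regions = list(
    region("R1", "fastq", "joined", regions = list(
      region("bc", "barcode", "fixed", sequence = "ACGT",
             min_len = 4L, max_len = 4L),
      region("umi", "umi", "random", sequence = "XXX",
             min_len = 3L, max_len = 3L)))))
  f <- format_spec(a)
  r1 <- f$regions[[1]]
  expect_identical(r1$sequence, "ACGTXXX")
  expect_identical(r1$min_len, 7L)
  expect_identical(r1$max_len, 7L)
  expect_identical(r1$sequence_type, "joined")
  # input untouched
  expect_identical(a$regions[[1]]$sequence, "")

  single <- format_spec(assay("y", regions = list(
    region("m", "named_region", "joined", regions = list(
      region("c", "cdna", "fixed", sequence = "AC",
             min_len = 2L, max_len = 2L))))))
  m <- single$regions[[1]]
  expect_identical(m$sequence, "AC")
  expect_identical(m$min_len, 2L)

  two_level <- format_spec(assay("z", regions = list(
    region("R", "named_region", "joined", regions = list(
      region("A", "named_region", "joined", regions = list(
        region("b1", "barcode", "fixed", sequence = "AC",
               min_len = 2L, max_len = 2L),
        region("b2", "barcode", "fixed", sequence = "GGG",
               min_len = 3L, max_len = 3L))),
      region("c", "cdna", "fixed", sequence = "TTTTT",
             min_len = 5L, max_len = 5L))))))
  expect_identical(two_level$regions[[1]]$min_len, 10L)
  expect_identical(two_level$regions[[1]]$max_len, 10L)

  bad <- assay("w", regions = list(
    region("solo", "other", "joined")))
  expect_error(format_spec(bad), class = "readspec_structural_error")
})

test_that("format_spec is idempotent and conserves lengths over leaves", {
  for (seed in 1:20) {
    a <- make_spec("random_tree", seed = seed)$assay
    once <- format_spec(a)
    expect_true(assay_equal(format_spec(once), once))
    for (r in pre_order(once)) {
      if (length(r$regions)) {
        lv <- leaves(r)
        expect_identical(r$max_len,
                         sum(vapply(lv, `[[`, integer(1), "max_len")))
        expect_identical(r$min_len,
                         sum(vapply(lv, `[[`, integer(1), "min_len")))
      }
    }
  }
})

test_that("index_read matches the cumulative-sum oracle", {
  a <- format_spec(assay("x", regions = list(
    region("R1", "fastq", "joined", regions = list(
      region("bc", "barcode", "random", sequence = strrep("X", 16L),
             min_len = 16L, max_len = 16L),
      region("umi", "umi", "random", sequence = strrep("X", 12L),
             min_len = 12L, max_len = 12L),
      region("cdna", "cdna", "random", sequence = strrep("X", 98L),
             min_len = 1L, max_len = 98L))))))
  ix <- index_read(a, "R1")
  expect_identical(ix$intervals$start, c(0L, 16L, 28L))
  expect_identical(ix$intervals$end, c(16L, 28L, 126L))
  expect_identical(ix$intervals$variable, c(FALSE, FALSE, TRUE))
  expect_true(ix$fixed_prefix_ok)

  # degenerate: an atomic id yields a single self-interval
  solo <- index_read(a, "umi")
  expect_identical(solo$intervals$start, 0L)
  expect_identical(solo$intervals$end, 12L)

  expect_error(index_read(a, "R9"), class = "readspec_not_found")

  # zero-length middle region yields an empty interval
  z <- format_spec(assay("z", regions = list(
    region("R", "fastq", "joined", regions = list(
      region("a", "barcode", "random", sequence = strrep("X", 16L),
             min_len = 16L, max_len = 16L),
      region("gap", "other", "random", sequence = "",
             min_len = 0L, max_len = 0L),
      region("b", "cdna", "random", sequence = strrep("X", 10L),
             min_len = 10L, max_len = 10L))))))
  ixz <- index_read(z, "R")
  expect_identical(ixz$intervals$start, c(0L, 16L, 16L))
  expect_identical(ixz$intervals$end, c(16L, 16L, 26L))
})

test_that("index intervals agree with the oracle and fixture ledgers", {
  for (layout in c("tenx_like", "splitpool_like", "adapter_insert_adapter")) {
    fx <- make_spec(layout, seed = 6)
    for (rid in fx$ledger$reads) {
      ix <- index_read(fx$assay, rid)
      got <- ix$intervals[, c("region_id", "start", "end")]
      rownames(got) <- NULL
      expect_identical(got, oracle_intervals(get_region(fx$assay, rid)))
      expect_identical(got, fx$ledger$intervals[[rid]])
      expect_identical(max(ix$intervals$end),
                       sum(ix$intervals$max_len))
    }
  }
})

test_that("variable-length regions upstream of fixed ones clear the flag", {
  fx <- make_spec("adapter_insert_adapter", seed = 1)
  ix <- index_read(fx$assay, "construct")
  expect_false(ix$fixed_prefix_ok)
})

test_that("get_onlist resolves paths and counts, split-pool included", {
  fx <- make_spec("tenx_like", seed = 8)
  res <- get_onlist(fx$assay, "barcode", base_dir = fx$dir)
  expect_identical(res$region_id, "bc")
  expect_identical(res$n, 100L)
  expect_true(file.exists(res$path))

  expect_error(get_onlist(fx$assay, "umi", base_dir = fx$dir),
               class = "readspec_not_found")

  sp <- make_spec("splitpool_like", seed = 8)
  res3 <- get_onlist(sp$assay, "barcode", base_dir = sp$dir)
  expect_identical(res3$region_id, c("bc1", "bc2", "bc3"))
  expect_identical(res3$n, rep(100L, 3))
})

test_that("init_from_newick builds the documented skeleton", {
  a <- init_from_newick("((bc:16,umi:12,cdna:98)R1)rna;")
  expect_identical(a$assay_id, "rna")
  root <- a$regions[[1]]
  expect_identical(root$region_id, "rna")
  expect_identical(ids_of(root$regions), "R1")
  lv <- leaves(a)
  expect_identical(ids_of(lv), c("bc", "umi", "cdna"))
  expect_identical(vapply(lv, `[[`, integer(1), "max_len"),
                   c(16L, 12L, 98L))
  expect_identical(lv[[1]]$sequence, strrep("X", 16L))
  expect_identical(root$regions[[1]]$region_type, "named_region")
  expect_identical(lv[[1]]$region_type, "other")
  expect_identical(nrow(check_spec(format_spec(a))), 0L)

  mini <- init_from_newick("(a:5)r;")
  expect_length(pre_order(mini), 2L)
  expect_identical(leaves(mini)[[1]]$max_len, 5L)

  expect_error(init_from_newick("((a:1,a:2)r)s;"),
               class = "readspec_duplicate_id")
  expect_error(init_from_newick("(a:5"), class = "readspec_parse_error")
  err <- expect_error(init_from_newick("(a)r;"),
                      class = "readspec_grammar_error")
  expect_match(conditionMessage(err), "character [0-9]+")
})

test_that("init -> format -> check is clean and topology round-trips", {
  for (seed in 1:25) {
    nw <- random_newick(seed)
    a <- init_from_newick(nw)
    expect_identical(nrow(check_spec(format_spec(a))), 0L)
    expect_identical(to_newick(a), nw)
  }
})
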