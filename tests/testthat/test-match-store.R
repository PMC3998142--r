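run_on <- function(fx, base, ...) {
  run_pipeline(pipeline_config(fx, base, ...))
}

test_that("partitioning splits hits from misses and guards on versions", {
  fx <- shared_fixture()
  base <- file.path(tempfile("msa"), "run")
  dir.create(dirname(base))
  run_on(fx, base)
  store <- load_store(paste0(base, ".xml"))
  analyses <- data.frame(name = "toylib", version = "1.0")

  prots <- fx$proteins[1:3]
  part <- partition_by_store(prots, store, analyses)
  expect_length(part$hits, 3L)
  expect_length(part$misses, 0L)

  novel <- random_protein("novel", 40)
  part2 <- partition_by_store(c(prots[1:2], list(novel)), store, analyses)
  expect_length(part2$hits, 2L)
  expect_equal(part2$misses[[1]]$id, "novel")

  stale <- data.frame(name = "toylib", version = "2.0")
  part3 <- partition_by_store(prots, store, stale)
  expect_length(part3$hits, 0L)
  expect_length(part3$misses, 3L)

  empty <- structure(list(version = "toylib:1.0", records = list()),
                     class = "match_store")
  part4 <- partition_by_store(prots, empty, analyses)
  expect_length(part4$misses, 3L)
  # partition never mutates the store
  expect_length(store$records, length(load_store(paste0(base, ".xml"))$records))
})

test_that("loading is idempotent and rejects broken XML", {
  fx <- shared_fixture()
  base <- file.path(tempfile("msb"), "run")
  dir.create(dirname(base))
  run_on(fx, base)
  xml <- paste0(base, ".xml")
  once <- load_store(xml)
  twice <- load_store(c(xml, xml))
  expect_identical(twice$records, once$records)

  trunc <- tempfile(fileext = ".xml")
  full <- readLines(xml)
  writeLines(full[1:(length(full) %/% 2)], trunc)
  expect_error(load_store(trunc), "malformed|schema")

  wrong <- tempfile(fileext = ".xml")
  writeLines("<not-results/>", wrong)
  expect_error(load_store(wrong), "schema violation")
})

test_that("a store round-trips through its single-file form", {
  fx <- shared_fixture()
  base <- file.path(tempfile("msc"), "run")
  dir.create(dirname(base))
  run_on(fx, base)
  store <- load_store(paste0(base, ".xml"))
  f <- tempfile(fileext = ".xml")
  save_match_store(store, f)
  back <- read_match_store(f)
  expect_equal(back$version, store$version)
  expect_equal(sort(names(back$records)), sort(names(store$records)))
  md5 <- names(store$records)[[1]]
  expect_equal(back$records[[md5]], store$records[[md5]])
})

test_that("cache hits reproduce recomputed output byte for byte", {
  fx <- shared_fixture()
  base_a <- file.path(tempfile("msd"), "a")
  base_b <- file.path(dirname(base_a), "b")
  dir.create(dirname(base_a))
  run_on(fx, base_a)

  res_b <- run_on(fx, base_b, disable_precalc = FALSE,
                  lookup = paste0(base_a, ".xml"))
  expect_equal(res_b$n_hits, 12L)
  expect_equal(res_b$n_misses, 0L)
  expect_null(res_b$report)  # nothing was launched on the engine
  for (fmt in c("tsv", "xml", "gff3", "json")) {
    expect_identical(readLines(paste0(base_b, ".", fmt)),
                     readLines(paste0(base_a, ".", fmt)),
                     label = fmt)
  }

  # an unusable store degrades to recomputation, not failure
  bad <- tempfile(fileext = ".xml"); writeLines("<broken", bad)
  expect_warning(res_c <- run_on(fx, file.path(dirname(base_a), "c"),
                                 disable_precalc = FALSE, lookup = bad),
                 "unusable")
  expect_equal(res_c$n_misses, 12L)
  expect_identical(readLines(paste0(dirname(base_a), "/c.xml")),
                   readLines(paste0(base_a, ".xml")))
})
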