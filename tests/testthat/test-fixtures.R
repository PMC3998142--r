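test_that("fixture generation is a pure function of the spec", {
  spec <- default_fixture_spec(303, n_proteins = 6L, n_placements = 3L)
  d1 <- tempfile("fxa"); d2 <- tempfile("fxb")
  generate_fixture(spec, d1)
  generate_fixture(spec, d2)
  for (f in c("proteins.fasta", "ground_truth.tsv",
              "libraries/toylib/signatures.tsv",
              "libraries/toylib/patterns.tsv",
              "integration/protein_pathway.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and it restores the caller's RNG stream
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(generate_fixture(spec, tempfile()))
  expect_identical(stats::runif(3), before)
})

test_that("planted placements are realizable and recorded exactly once", {
  fx <- shared_fixture()
  gt <- fx$ground_truth
  expect_equal(nrow(gt), 6L)
  expect_equal(anyDuplicated(gt$protein_id), 0L)  # one plant per protein
  prot_by_id <- stats::setNames(
    fx$proteins, vapply(fx$proteins, `[[`, character(1), "id"))
  sigs <- fx$library$signatures
  for (r in seq_len(nrow(gt))) {
    p <- prot_by_id[[gt$protein_id[r]]]
    window <- substr(p$residues, gt$start[r], gt$stop[r])
    sig <- sigs[[gt$signature_accession[r]]]
    if (sig$model_kind == "pattern") {
      expect_length(oracle_scan_pattern(
        canonicalize_and_checksum("w", window), sig$model_payload), 1L)
    } else {
      expect_gte(oracle_scan_profile(
        canonicalize_and_checksum("w", window),
        sig$model_payload)[[1]][["score"]], sig$model_payload$threshold)
    }
  }
})

test_that("the library bundle on disk reproduces the in-memory signatures", {
  fx <- shared_fixture()
  lib <- read_signature_library(file.path(fx$data_dir, "libraries",
                                          "toylib"))
  expect_equal(lib$name, "toylib")
  expect_equal(lib$version, "1.0")
  expect_setequal(names(lib$signatures), names(fx$library$signatures))
  for (acc in names(lib$signatures)) {
    a <- lib$signatures[[acc]]; b <- fx$library$signatures[[acc]]
    expect_equal(a$model_kind, b$model_kind)
    expect_equal(a$clan, b$clan)
    if (a$model_kind == "pattern") {
      expect_equal(a$model_payload$elements, b$model_payload$elements)
    } else {
      expect_equal(a$model_payload$matrix, b$model_payload$matrix)
      expect_equal(a$model_payload$threshold, b$model_payload$threshold)
    }
  }
})

test_that("annotation fractions around the boundary drive associations", {
  spec81 <- default_fixture_spec(404, n_proteins = 4L, n_placements = 2L,
                                 pathway_fractions = c(ENT00001 = 0.81,
                                                       ENT00002 = 0.80),
                                 n_reference = 100L)
  fx <- generate_fixture(spec81, tempfile("fxp"))
  expect_equal(nrow(fx$bundle$entries[["ENT00001"]]$pathway_xrefs), 1L)
  expect_equal(nrow(fx$bundle$entries[["ENT00002"]]$pathway_xrefs), 0L)
})

test_that("nucleotide fixtures embed each planted protein on the stated strand", {
  if (is.null(.fixture_cache$nt)) {
    .fixture_cache$nt <- generate_nucleotide_fixture(
      default_fixture_spec(202, n_proteins = 6L, n_placements = 3L),
      tempfile("ntfx"))
  }
  fxn <- .fixture_cache$nt
  gt <- fxn$ground_truth
  contigs <- stats::setNames(
    fxn$contigs, vapply(fxn$contigs, `[[`, character(1), "id"))
  for (r in seq_len(nrow(gt))) {
    nt <- contigs[[gt$parent_id[r]]]
    bases <- substr(nt$residues, gt$nt_start[r], gt$nt_end[r])
    if (gt$strand[r] == "-") bases <- revcomp(bases)
    # the projected bases translate to a window matching the signature
    aa <- translate_codons(bases)
    expect_equal(nchar(aa), gt$stop[r] - gt$start[r] + 1L)
    expect_false(grepl("\\*", aa))
  }
})
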