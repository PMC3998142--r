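ref_md5 <- function(i) sprintf("%032x", i)

make_bundle <- function(n_matched = 10L, n_annotated = 9L) {
  ents <- list(
    sig_entry("ENT1", "entry one", "family",
              signature_accessions = c("S1", "S2"),
              go_terms = data.frame(go_id = c("GO:1", "GO:2"),
                                    category = c("MF", "BP"),
                                    term = c("t1", "t2"),
                                    stringsAsFactors = FALSE)),
    sig_entry("ENT2", "entry two", "domain",
              signature_accessions = "S3"))
  ann <- if (n_annotated > 0L) {
    data.frame(protein_md5 = vapply(seq_len(n_annotated), ref_md5, ""),
               database = "KEGG", pathway_id = "K9", name = "pw",
               stringsAsFactors = FALSE)
  } else NULL
  ep <- data.frame(entry_accession = "ENT1",
                   protein_md5 = vapply(seq_len(n_matched), ref_md5, ""),
                   stringsAsFactors = FALSE)
  integration_bundle(ents, c(S1 = "ENT1", S2 = "ENT1", S3 = "ENT2"),
                     ann, ep)
}

test_that("annotation is a pure lookup that conserves matches", {
  b <- make_bundle()
  ms <- list(
    sig_match(ref_md5(1), "S1", list(sig_location(1, 5)), "filtered_in"),
    sig_match(ref_md5(1), "S2", list(sig_location(8, 12)), "filtered_in"),
    sig_match(ref_md5(2), "SX", list(sig_location(2, 4)), "filtered_in"))
  ann <- annotate(ms, b)
  expect_length(ann, 3L)
  expect_equal(ann[[1]]$entry$accession, "ENT1")
  expect_equal(nrow(ann[[1]]$go_terms), 2L)
  # two signatures in the same entry share it
  expect_equal(ann[[2]]$entry$accession, "ENT1")
  # unintegrated signature: no entry, empty annotation
  expect_null(ann[[3]]$entry)
  expect_equal(nrow(ann[[3]]$go_terms), 0L)
  expect_equal(nrow(ann[[3]]$pathways), 0L)
  # original matches untouched
  expect_identical(ann[[1]]$match, ms[[1]])
})

test_that("the pathway rule is strict at the 80% boundary", {
  b9 <- make_bundle(10L, 9L)   # 0.9 > 0.8: associated
  expect_equal(b9$entries[["ENT1"]]$pathway_xrefs$pathway_id, "K9")
  b8 <- make_bundle(10L, 8L)   # 0.8 is not > 0.8: not associated
  expect_equal(nrow(b8$entries[["ENT1"]]$pathway_xrefs), 0L)
  # entry with no matched proteins: vacuously empty
  expect_equal(nrow(b9$entries[["ENT2"]]$pathway_xrefs), 0L)
  # runtime recomputation agrees with build-time association
  expect_equal(associate_pathways(b9$entries[["ENT1"]],
                                  vapply(1:10, ref_md5, ""), b9)$pathway_id,
               "K9")
  expect_equal(nrow(associate_pathways(b9$entries[["ENT1"]],
                                       character(), b9)), 0L)
})

test_that("the pathway fraction collapses duplicate checksums", {
  b <- make_bundle(10L, 8L)
  matched_dup <- c(vapply(1:10, ref_md5, ""), ref_md5(1), ref_md5(2))
  expect_equal(nrow(associate_pathways(b$entries[["ENT1"]], matched_dup, b)),
               0L)  # still 8/10, duplicates do not inflate the numerator
})

test_that("adding an annotated protein never removes an association", {
  set.seed(41)
  b <- make_bundle(10L, 9L)
  e <- b$entries[["ENT1"]]
  for (rep in 1:20) {
    base_set <- vapply(sample(9, sample(3:9, 1)), ref_md5, "")
    before <- associate_pathways(e, base_set, b)
    after <- associate_pathways(e, c(base_set, ref_md5(9)), b)  # annotated
    expect_true(all(before$pathway_id %in% after$pathway_id))
  }
})

test_that("integration bundles survive the plain-text round trip", {
  b <- make_bundle()
  dir <- tempfile("ib")
  write_integration_bundle(b, dir)
  expect_setequal(list.files(dir),
                  c("entries.tsv", "signature_entry.tsv", "entry_go.tsv",
                    "protein_pathway.tsv", "entry_proteins.tsv"))
  b2 <- read_integration_bundle(dir)
  expect_equal(names(b2$entries), names(b$entries))
  expect_equal(b2$entries[["ENT1"]]$pathway_xrefs,
               b$entries[["ENT1"]]$pathway_xrefs)
  expect_equal(sort(names(b2$signature_to_entry)),
               sort(names(b$signature_to_entry)))
  expect_equal(b2$entries[["ENT1"]]$go_terms, b$entries[["ENT1"]]$go_terms)
})

test_that("malformed bundles are rejected", {
  ents <- list(sig_entry("ENT1", "e", "family"))
  expect_error(integration_bundle(ents, c(S1 = "NOPE")),
               "unknown entries")
  expect_error(
    sig_entry("E", "n", "family",
              pathway_xrefs = data.frame(database = c("KEGG", "KEGG"),
                                         pathway_id = c("K1", "K1"),
                                         name = c("a", "b"))),
    "duplicate")
})
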