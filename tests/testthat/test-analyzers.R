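prot <- function(res) canonicalize_and_checksum("t", res)

test_that("pattern scanning handles wildcards, anchors and repeats", {
  expect_equal(loc_table(scan_pattern(prot("ACKLCA"), "C-x(2)-C")),
               rbind(c(2L, 5L)))
  expect_equal(loc_table(scan_pattern(prot("MKV"), "<M")), rbind(c(1L, 1L)))
  expect_equal(nrow(loc_table(scan_pattern(prot("KMV"), "<M"))), 0L)
  expect_equal(loc_table(scan_pattern(prot("DAKEAK"), "[DE]-x-K")),
               rbind(c(1L, 3L), c(4L, 6L)))
  expect_equal(loc_table(scan_pattern(prot("ACDC"), "C>")), rbind(c(4L, 4L)))
  expect_error(parse_prosite("C-x(2,1)-C"), "repeat max < min")
  expect_error(parse_prosite("C--C"), "empty element at position")
  expect_error(parse_prosite("C-#-C"), "cannot parse element")
})

test_that("pattern scanner agrees with the regex-expansion oracle", {
  set.seed(23)
  for (rep in 1:300) {
    pat <- random_pattern()
    p <- random_protein(len = sample(8:30, 1))
    expect_identical(loc_table(scan_pattern(p, pat)),
                     oracle_loc_table(oracle_scan_pattern(p, pat)),
                     label = sprintf("pattern %s on %s", pat, p$residues))
  }
})

test_that("profile scanning reports every window meeting the threshold", {
  m <- matrix(0, 2, 20, dimnames = list(NULL,
       strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  m[1, "M"] <- 5; m[2, "A"] <- 5
  mod <- profile_model(m, 10)
  locs <- scan_profile(prot("MAMA"), mod)
  expect_equal(loc_table(locs), rbind(c(1L, 2L), c(3L, 4L)))
  expect_equal(vapply(locs, `[[`, numeric(1), "score"), c(10, 10))

  expect_length(scan_profile(prot("MAMA"), profile_model(m, 11)), 0L)

  zero <- profile_model(matrix(0, 2, 20, dimnames = dimnames(m)), 0)
  expect_equal(loc_table(scan_profile(prot("MAV"), zero)),
               rbind(c(1L, 2L), c(2L, 3L)))
  # shorter than the model: empty, not an error
  expect_length(scan_profile(prot("M"), zero), 0L)
})

test_that("profile scanner agrees with the exhaustive window-sum oracle", {
  set.seed(29)
  for (rep in 1:100) {
    L <- sample(2:5, 1)
    m <- matrix(round(stats::rnorm(20 * L, 0, 3), 2), L, 20,
                dimnames = list(NULL,
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    mod <- profile_model(m, stats::runif(1, -2, 6))
    p <- random_protein(len = sample(4:25, 1))
    got <- scan_profile(p, mod)
    want <- oracle_scan_profile(p, mod)
    expect_equal(loc_table(got), oracle_loc_table(want))
    expect_equal(vapply(got, `[[`, numeric(1), "score"),
                 oracle_scores(want))
  }
})

test_that("raising a profile threshold never adds windows", {
  set.seed(31)
  m <- matrix(round(stats::rnorm(60, 0, 3), 2), 3, 20,
              dimnames = list(NULL,
                strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  p <- random_protein(len = 30)
  lo <- scan_profile(p, profile_model(m, 0))
  hi <- scan_profile(p, profile_model(m, 2))
  lo_starts <- vapply(lo, `[[`, integer(1), "start")
  hi_starts <- vapply(hi, `[[`, integer(1), "start")
  expect_true(all(hi_starts %in% lo_starts))
})

test_that("clan overlap resolution keeps the best location and restatuses only", {
  sigs <- list(
    sig_signature("PF001", "a", "lib", "1", "pattern",
                  parse_prosite("A"), clan = "CL1"),
    sig_signature("PF002", "b", "lib", "1", "pattern",
                  parse_prosite("A"), clan = "CL1"),
    sig_signature("PF009", "c", "lib", "1", "pattern",
                  parse_prosite("A"), clan = NA))
  md5 <- "00000000000000000000000000000000"
  m <- function(acc, s, e, score = NA_real_)
    sig_match(md5, acc, list(sig_location(s, e, score)))

  r <- resolve_overlaps(list(m("PF001", 1, 10, 8), m("PF002", 5, 15, 3)),
                        sigs)
  expect_equal(vapply(r, `[[`, character(1), "status"),
               c("filtered_in", "filtered_out"))

  r2 <- resolve_overlaps(list(m("PF001", 1, 10, 2), m("PF002", 20, 30, 2)),
                         sigs)
  expect_true(all(vapply(r2, `[[`, character(1), "status") == "filtered_in"))

  # tie-break chain: equal score, equal start -> smaller accession wins
  r3 <- resolve_overlaps(list(m("PF002", 3, 9, 5), m("PF001", 3, 9, 5)),
                         sigs)
  st <- stats::setNames(vapply(r3, `[[`, character(1), "status"),
                        vapply(r3, `[[`, character(1), "signature_accession"))
  expect_equal(st[["PF001"]], "filtered_in")
  expect_equal(st[["PF002"]], "filtered_out")

  # clanless matches never compete
  r4 <- resolve_overlaps(list(m("PF009", 1, 10), m("PF001", 1, 10, 1)), sigs)
  expect_true(all(vapply(r4, `[[`, character(1), "status") == "filtered_in"))
})

test_that("overlap resolution conserves matches and is idempotent", {
  set.seed(37)
  sigs <- lapply(1:4, function(i) {
    sig_signature(sprintf("PF%03d", i), "s", "lib", "1", "pattern",
                  parse_prosite("A"),
                  clan = if (i <= 3) "CL1" else NA_character_)
  })
  for (rep in 1:20) {
    ms <- lapply(seq_len(sample(2:6, 1)), function(j) {
      s <- sample(50, 1)
      sig_match("0be5c08db39d8e6ccd7c8dd85ccdbca1",
                sprintf("PF%03d", sample(4, 1)),
                list(sig_location(s, s + sample(3:10, 1),
                                  sample(c(NA, 1:9), 1))))
    })
    once <- resolve_overlaps(ms, sigs)
    twice <- resolve_overlaps(once, sigs)
    expect_length(once, length(ms))
    expect_identical(twice, once)
    expect_true(all(vapply(once, `[[`, character(1), "status") %in%
                      c("filtered_in", "filtered_out")))
  }
})

test_that("run_analysis recovers planted motifs exactly, and modalities differ", {
  fx <- shared_fixture()
  sigs <- fx$library$signatures
  got <- list()
  for (p in fx$proteins) {
    for (m in run_analysis(list(p), sigs)) {
      if (m$status != "filtered_in") next
      for (l in m$locations) {
        got[[length(got) + 1L]] <- data.frame(
          protein_id = p$id, signature_accession = m$signature_accession,
          start = l$start, stop = l$stop, stringsAsFactors = FALSE)
      }
    }
  }
  got <- do.call(rbind, got)
  gt <- fx$ground_truth[, c("protein_id", "signature_accession",
                            "start", "stop")]
  expect_equal(got[order(got$protein_id, got$signature_accession), ],
               gt[order(gt$protein_id, gt$signature_accession), ],
               ignore_attr = TRUE)

  expect_length(run_analysis(list(), sigs), 0L)

  # single-pass modality: raw matches pass straight through as filtered_in
  p <- fx$proteins[[1]]
  sp <- run_analysis(list(p), sigs, single_pass_analyzer())
  raw <- builtin_analyzer()$scan(list(p), sigs)
  expect_length(sp, length(raw))
  expect_true(all(vapply(sp, `[[`, character(1), "status") == "filtered_in"))
})
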