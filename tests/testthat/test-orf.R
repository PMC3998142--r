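test_that("a simple coding sequence yields one plus-strand ORF", {
  nt <- nucleotide_sequence("n", "ATGGCCTAA")
  orfs <- find_orfs(nt, min_protein_length = 1L)
  plus <- Filter(function(o) o$strand == "+", orfs)
  expect_length(plus, 1L)
  expect_equal(plus[[1]]$protein$residues, "MA")
  expect_equal(plus[[1]]$nt_start, 1L)
  expect_equal(plus[[1]]$nt_end, 9L)  # terminating TAA included in the span
})

test_that("the length filter suppresses short translations", {
  nt <- nucleotide_sequence("n", strrep("A", 9))
  expect_length(find_orfs(nt, min_protein_length = 4L), 0L)
})

test_that("reverse-complement input mirrors ORFs onto the minus strand", {
  nt <- nucleotide_sequence("n", revcomp("ATGGCCTAA"))
  orfs <- Filter(function(o) o$strand == "-", find_orfs(nt, 1L))
  expect_length(orfs, 1L)
  expect_equal(orfs[[1]]$protein$residues, "MA")
  expect_equal(c(orfs[[1]]$nt_start, orfs[[1]]$nt_end), c(1L, 9L))
})

test_that("strand-flip oracle holds on random sequences", {
  set.seed(11)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(60:150, 1),
                      replace = TRUE), collapse = "")
    fwd <- find_orfs(nucleotide_sequence("f", s), 10L)
    rev <- find_orfs(nucleotide_sequence("r", revcomp(s)), 10L)
    key <- function(o, L) {
      # reflect coordinates so both runs describe the same physical ORF
      sort(vapply(o, function(x) {
        sprintf("%s|%d|%d|%s",
                if (x$strand == "+") "-" else "+",
                L - x$nt_end + 1L, L - x$nt_start + 1L,
                x$protein$residues)
      }, character(1)))
    }
    direct <- sort(vapply(fwd, function(x) {
      sprintf("%s|%d|%d|%s", x$strand, x$nt_start, x$nt_end,
              x$protein$residues)
    }, character(1)))
    expect_identical(direct, key(rev, nchar(s)))
  }
})

test_that("coordinate back-mapping follows codon arithmetic", {
  mk <- function(strand, nt_start, nt_end, plen) {
    structure(list(parent_id = "n", strand = strand, nt_start = nt_start,
                   nt_end = nt_end, protein = list(length = plen)),
              class = "open_reading_frame")
  }
  expect_equal(map_to_nucleotide(mk("+", 1L, 9L, 3L), 1, 2),
               list(nt_start = 1L, nt_end = 6L, strand = "+"))
  expect_equal(map_to_nucleotide(mk("+", 10L, 18L, 3L), 2, 2),
               list(nt_start = 13L, nt_end = 15L, strand = "+"))
  expect_equal(map_to_nucleotide(mk("-", 1L, 9L, 3L), 1, 1),
               list(nt_start = 7L, nt_end = 9L, strand = "-"))
  expect_error(map_to_nucleotide(mk("+", 1L, 9L, 3L), 2, 4),
               "outside protein")
})

test_that("minus-strand mapping points at bases whose reverse complement translates back", {
  # the example ORF: residue 1 of a '-' ORF at nt 1..9 lives at bases 7..9
  s <- revcomp("ATGGCCTAA")
  orf <- Filter(function(o) o$strand == "-",
                find_orfs(nucleotide_sequence("n", s), 1L))[[1]]
  m <- map_to_nucleotide(orf, 1, 1)
  codon <- revcomp(substr(s, m$nt_start, m$nt_end))
  expect_equal(oracle_translate(codon), substr(orf$protein$residues, 1, 1))
})

test_that("round trip and span law hold over random ORFs and intervals", {
  set.seed(13)
  checked <- 0L
  while (checked < 200L) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(120:240, 1),
                      replace = TRUE), collapse = "")
    nt <- nucleotide_sequence("n", s)
    for (orf in find_orfs(nt, 10L)) {
      a <- sample(orf$protein$length, 1)
      b <- sample_between(a, orf$protein$length)
      m <- map_to_nucleotide(orf, a, b)
      expect_equal(m$nt_end - m$nt_start + 1L, 3L * (b - a + 1L))
      bases <- substr(s, m$nt_start, m$nt_end)
      if (m$strand == "-") bases <- revcomp(bases)
      expect_equal(oracle_translate(bases),
                   substr(orf$protein$residues, a, b))
      checked <- checked + 1L
    }
  }
})

test_that("translation matches the standard-code oracle including N codons", {
  set.seed(17)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 3 * sample(5:30, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    expect_equal(translate_codons(s), oracle_translate(s))
  }
})
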