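# Independent oracles used across tests. These deliberately take naive
# routes (regex expansion, exhaustive window sums, Biostrings translation)
# so that agreement with the package's scanners and coordinate arithmetic
# is a genuine cross-check, not a tautology.

# Expand a parsed pattern into a regular expression (greedy; the oracle
# enumerates window lengths explicitly, so greediness is irrelevant).
pattern_to_regex <- function(model) {
  paste(vapply(model$elements, function(el) {
    core <- switch(el$type,
                   literal = el$residues,
                   any = ".",
                   set = paste0("[", paste(el$residues, collapse = ""), "]"),
                   negset = paste0("[^", paste(el$residues, collapse = ""), "]"))
    rep_suffix <- if (el$min == 1L && el$max == 1L) ""
                  else sprintf("{%d,%d}", el$min, el$max)
    paste0(core, rep_suffix)
  }, character(1)), collapse = "")
}

# Brute-force pattern scan: try every start and every window length.
oracle_scan_pattern <- function(protein, model) {
  if (is.character(model)) model <- parse_prosite(model)
  re <- paste0("^", pattern_to_regex(model), "$")
  L <- protein$length
  starts <- if (model$n_anchor) 1L else seq_len(L)
  out <- list()
  for (s in starts) {
    lens <- seq_len(L - s + 1L)
    if (model$c_anchor) lens <- lens[s + lens - 1L == L]
    hit <- NA_integer_
    for (len in lens) {
      if (grepl(re, substr(protein$residues, s, s + len - 1L))) {
        hit <- len; break
      }
    }
    if (!is.na(hit)) out[[length(out) + 1L]] <- c(start = s,
                                                  stop = s + hit - 1L)
  }
  out
}

# Exhaustive window-sum profile scan.
oracle_scan_profile <- function(protein, model) {
  chars <- strsplit(protein$residues, "")[[1]]
  Lm <- nrow(model$matrix)
  out <- list()
  if (length(chars) < Lm) return(out)
  for (s in seq_len(length(chars) - Lm + 1L)) {
    sc <- 0
    for (j in seq_len(Lm)) {
      ch <- chars[s + j - 1L]
      if (ch %in% colnames(model$matrix)) {
        sc <- sc + unname(model$matrix[j, ch])
      }
    }
    if (sc >= model$threshold) {
      out[[length(out) + 1L]] <- c(start = s, stop = s + Lm - 1L, score = sc)
    }
  }
  out
}

# Biostrings-based translation oracle for coordinate round trips.
oracle_translate <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# sample() treats a scalar first argument as 1:n; this keeps b in [a, n].
sample_between <- function(a, n) if (a == n) a else sample(a:n, 1)

# Random pattern generator for property tests.
random_pattern <- function() {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_el <- sample(2:5, 1)
  els <- vapply(seq_len(n_el), function(i) {
    core <- switch(sample(4, 1),
                   sample(aas, 1),
                   "x",
                   paste0("[", paste(sample(aas, sample(2:4, 1)), collapse = ""), "]"),
                   paste0("{", paste(sample(aas, sample(1:3, 1)), collapse = ""), "}"))
    rep_suffix <- switch(sample(3, 1), "",
                         sprintf("(%d)", sample(1:3, 1)),
                         sprintf("(%d,%d)", sample(0:2, 1), sample(2:4, 1)))
    paste0(core, rep_suffix)
  }, character(1))
  pat <- paste(els, collapse = "-")
  if (stats::runif(1) < 0.15) pat <- paste0("<", pat)
  if (stats::runif(1) < 0.15) pat <- paste0(pat, ">")
  pat
}

random_protein <- function(id = "r", len = sample(10:40, 1)) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  canonicalize_and_checksum(id, paste(sample(aas, len, replace = TRUE),
                                      collapse = ""))
}

loc_table <- function(locs) {
  if (length(locs) == 0L) return(matrix(integer(), ncol = 2))
  unname(t(vapply(locs, function(l) c(l$start, l$stop), integer(2))))
}

# Same shape for oracle output (lists of named start/stop[/score] vectors).
oracle_loc_table <- function(want) {
  if (length(want) == 0L) return(matrix(integer(), ncol = 2))
  unname(t(vapply(want, function(w) as.integer(w[1:2]), integer(2))))
}

oracle_scores <- function(want) {
  vapply(want, function(w) unname(w[["score"]]), numeric(1))
}
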