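# Session-cached fixtures: generated once per test run and shared by the
# tests that only read them.

.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function(seed = 101, n_proteins = 12L, n_placements = 6L) {
  key <- sprintf("fx_%d_%d_%d", seed, n_proteins, n_placements)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_fixture(
      default_fixture_spec(seed, n_proteins = n_proteins,
                           n_placements = n_placements),
      tempfile("sigscan_fx_"))
  }
  .fixture_cache[[key]]
}

pipeline_config <- function(fx, base, ...) {
  utils::modifyList(
    list(input = fx$fasta, data_dir = fx$data_dir, seq_type = "p",
         output_base = base, date = "2000-01-01", chunk_size = 4L,
         mode = "serial", disable_precalc = TRUE),
    list(...))
}

# Small random result documents for serialization round-trip properties.
random_document <- function() {
  n_prot <- sample(1:3, 1)
  proteins <- lapply(seq_len(n_prot), function(i) {
    p <- random_protein(sprintf("p%02d", i), len = sample(20:40, 1))
    n_match <- sample(0:2, 1)
    matches <- lapply(seq_len(n_match), function(j) {
      n_loc <- sample(1:2, 1)
      starts <- sort(sample(seq_len(p$length - 5L), n_loc))
      list(analysis = "toylib",
           signature_accession = sprintf("TOY%05d", sample(1:99, 1)),
           signature_name = "random signature",
           status = "filtered_in",
           entry = if (stats::runif(1) < 0.5)
             list(accession = "ENT00001", name = "an entry",
                  type = "family") else NULL,
           go_terms = if (stats::runif(1) < 0.5)
             data.frame(go_id = "GO:0003824",
                        category = "molecular_function",
                        term = "catalytic activity",
                        stringsAsFactors = FALSE)
             else empty_go_terms(),
           pathways = empty_pathway_xrefs(),
           locations = lapply(starts, function(s) {
             list(start = s, stop = s + sample(2:5, 1),
                  score = if (stats::runif(1) < 0.5) NA_real_
                          else round(stats::runif(1, 0, 50), 3),
                  evalue = NA_real_)
           }))
    })
    list(md5 = p$md5, length = p$length, residues = p$residues,
         ids = sprintf("p%02d", i), matches = matches)
  })
  result_document(
    analyses = data.frame(name = "toylib", version = "1.0",
                          stringsAsFactors = FALSE),
    proteins = proteins, date = "2000-01-01")
}
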