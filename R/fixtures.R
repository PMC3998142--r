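# Synthetic fixture generator.
#
# Produces, from a seed, everything the pipeline consumes: a protein (or
# nucleotide) FASTA with motifs planted at known coordinates, a toy
# signature library bundle, an integration bundle with entries/GO/pathway
# tables, and an exact ground-truth table. Background sequences are
# rejection-sampled against the whole library so that the planted matches
# are provably the only filtered-in matches — precision and recall against
# ground truth are exact by construction, not probabilistically.
# Generation restores the caller's RNG state on exit.

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# The default toy signature library: two clanned models competing for
# overlaps, one clanless pattern, one unintegrated pattern.
default_toy_library <- function() {
  prof_len <- 6L
  prof_target <- strsplit("MDEWKH", "")[[1]]
  mat <- matrix(-1, nrow = prof_len, ncol = 20L,
                dimnames = list(NULL, PROFILE_RESIDUES))
  for (i in seq_len(prof_len)) mat[i, prof_target[i]] <- 5
  sigs <- list(
    sig_signature("TOY00001", "tryptophan sandwich motif", "toylib", "1.0",
                  "pattern", parse_prosite("W-H-x(2)-C-C"), clan = "CL0001"),
    sig_signature("TOY00002", "acidic linker pattern", "toylib", "1.0",
                  "pattern", parse_prosite("[DE]-x-K-[DE]-W"),
                  clan = NA_character_),
    sig_signature("TOY00003", "MDEWKH profile block", "toylib", "1.0",
                  "profile", profile_model(mat, threshold = 25),
                  clan = "CL0001"),
    sig_signature("TOY00004", "orphan histidine triad", "toylib", "1.0",
                  "pattern", parse_prosite("H-x-H-x-H-Q"),
                  clan = NA_character_))
  list(name = "toylib", version = "1.0",
       signatures = stats::setNames(sigs, vapply(sigs, `[[`, character(1),
                                                 "accession")))
}

# Realize a concrete string guaranteed to match a signature at its full
# planted window (patterns: minimal repeat counts, first allowed residue;
# profiles: the argmax residue per position).
realize_signature <- function(sig) {
  if (sig$model_kind == "profile") {
    m <- sig$model_payload$matrix
    return(paste(PROFILE_RESIDUES[apply(m, 1L, which.max)], collapse = ""))
  }
  els <- sig$model_payload$elements
  paste(vapply(els, function(el) {
    ch <- switch(el$type,
                 literal = el$residues,
                 any = "A",
                 set = el$residues[1L],
                 negset = setdiff(STANDARD_AA, el$residues)[1L])
    paste(rep(ch, el$min), collapse = "")
  }, character(1)), collapse = "")
}

#' Describe a synthetic fixture
#'
#' The default emulates a small screening run: 50 background proteins of
#' 100-300 residues, 10 planted motif occurrences (one per protein, chosen
#' signatures cycling through the library), the toy signature library, two
#' curated entries with GO terms, and a 10-protein reference annotation
#' table in which 90% of the proteins matched by the first entry carry a
#' KEGG pathway (so the strict >80% rule associates it).
#'
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param n_proteins Number of background proteins.
#' @param n_placements Number of planted motif occurrences (at most one
#'   per protein).
#' @param length_range Protein length range (uniform).
#' @param library Signature library (as from [default_toy_library()]).
#' @param pathway_fractions Named vector, entry accession -> fraction of
#'   reference proteins annotated with that entry's candidate pathway.
#' @param n_reference Reference proteins per entry for the pathway rule.
#' @return A `fixture_spec`.
#' @export
default_fixture_spec <- function(seed, n_proteins = 50L,
                                 n_placements = 10L,
                                 length_range = c(100L, 300L),
                                 library = default_toy_library(),
                                 pathway_fractions = c(ENT00001 = 0.9,
                                                       ENT00002 = 0.5),
                                 n_reference = 10L) {
  stopifnot(n_placements <= n_proteins)
  structure(list(seed = seed, n_proteins = n_proteins,
                 n_placements = n_placements, length_range = length_range,
                 library = library,
                 pathway_fractions = pathway_fractions,
                 n_reference = n_reference),
            class = "fixture_spec")
}

# Entries + GO wiring for the toy library. TOY00004 stays unintegrated.
default_entries <- function() {
  list(
    sig_entry("ENT00001", "Tryptophan sandwich superfamily", "family",
              signature_accessions = c("TOY00001", "TOY00003"),
              go_terms = data.frame(
                go_id = c("GO:0003824", "GO:0008152"),
                category = c("molecular_function", "biological_process"),
                term = c("catalytic activity", "metabolic process"),
                stringsAsFactors = FALSE)),
    sig_entry("ENT00002", "Acidic linker domain", "domain",
              signature_accessions = "TOY00002",
              go_terms = data.frame(
                go_id = "GO:0005515", category = "molecular_function",
                term = "protein binding", stringsAsFactors = FALSE)))
}

# Reference annotation tables probing the >80% pathway rule. Each entry
# gets n_reference synthetic reference proteins; a fraction of them is
# annotated with one candidate pathway.
reference_tables <- function(spec) {
  ep <- list(); pp <- list()
  pw <- list(ENT00001 = c("KEGG", "K00001", "toy glycolysis"),
             ENT00002 = c("MetaCyc", "PWY-0001", "toy degradation"))
  for (acc in names(spec$pathway_fractions)) {
    md5s <- vapply(seq_len(spec$n_reference), function(i) {
      digest::digest(sprintf("%s_ref%04d", acc, i), algo = "md5",
                     serialize = FALSE)
    }, character(1))
    ep[[acc]] <- data.frame(entry_accession = acc, protein_md5 = md5s,
                            stringsAsFactors = FALSE)
    n_ann <- round(spec$pathway_fractions[[acc]] * spec$n_reference)
    if (n_ann > 0L) {
      info <- pw[[acc]]
      pp[[acc]] <- data.frame(protein_md5 = md5s[seq_len(n_ann)],
                              database = info[1L], pathway_id = info[2L],
                              name = info[3L], stringsAsFactors = FALSE)
    }
  }
  list(entry_proteins = do.call(rbind, c(ep, list(
         data.frame(entry_accession = character(),
                    protein_md5 = character())))),
       protein_pathway = do.call(rbind, c(pp, list(
         data.frame(protein_md5 = character(), database = character(),
                    pathway_id = character(), name = character())))))
}

# Expected filtered-in match set for one protein carrying one plant.
expected_for_plant <- function(sig, pos) {
  realization <- realize_signature(sig)
  data.frame(signature_accession = sig$accession, start = pos,
             stop = pos + nchar(realization) - 1L,
             stringsAsFactors = FALSE)
}

observed_matches <- function(protein, signatures) {
  ms <- run_analysis(list(protein), signatures)
  rows <- lapply(ms, function(m) {
    if (m$status != "filtered_in") return(NULL)
    do.call(rbind, lapply(m$locations, function(l) {
      data.frame(signature_accession = m$signature_accession,
                 start = l$start, stop = l$stop, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    signature_accession = character(), start = integer(),
    stop = integer()))))
  out[order(out$signature_accession, out$start), , drop = FALSE]
}

matches_equal <- function(a, b) {
  rownames(a) <- NULL; rownames(b) <- NULL
  isTRUE(all.equal(a[order(a$signature_accession, a$start), , drop = FALSE],
                   b[order(b$signature_accession, b$start), , drop = FALSE],
                   check.attributes = FALSE))
}

# Sample one background protein, optionally with a plant, rejecting any
# draw whose filtered-in matches differ from the expectation.
sample_protein <- function(id, len, plant_sig, signatures,
                           max_attempts = 500L) {
  for (attempt in seq_len(max_attempts)) {
    chars <- sample(STANDARD_AA, len, replace = TRUE)
    expected <- data.frame(signature_accession = character(),
                           start = integer(), stop = integer(),
                           stringsAsFactors = FALSE)
    pos <- NA_integer_
    if (!is.null(plant_sig)) {
      realization <- realize_signature(plant_sig)
      w <- nchar(realization)
      if (w > len) stop("unrealizable placement: motif longer than protein",
                        call. = FALSE)
      pos <- sample.int(len - w + 1L, 1L)
      chars[pos:(pos + w - 1L)] <- strsplit(realization, "")[[1]]
      expected <- expected_for_plant(plant_sig, pos)
    }
    protein <- canonicalize_and_checksum(id, paste(chars, collapse = ""))
    if (matches_equal(observed_matches(protein, signatures), expected)) {
      return(list(protein = protein, plant_pos = pos,
                  expected = expected))
    }
  }
  stop(sprintf("could not realize background for '%s' within %d attempts",
               id, max_attempts), call. = FALSE)
}

#' Generate a protein fixture with planted motifs
#'
#' Writes `proteins.fasta`, the signature library bundle under
#' `libraries/toylib/`, the integration bundle under `integration/`, and
#' `ground_truth.tsv` (one row per expected filtered-in match:
#' `protein_id`, `signature_accession`, `start`, `stop`,
#' `entry_accession`). Identical specs produce byte-identical files.
#'
#' @param spec A [default_fixture_spec()].
#' @param dir Output directory (becomes a pipeline `data_dir` with the
#'   FASTA alongside).
#' @return List with `fasta`, `data_dir`, `ground_truth`, `proteins`,
#'   `library`, `bundle`.
#' @export
generate_fixture <- function(spec, dir) {
  with_fixture_seed(spec$seed, {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sigs <- spec$library$signatures
    lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]),
                   spec$n_proteins, replace = TRUE)
    planted_idx <- sort(sample.int(spec$n_proteins, spec$n_placements))
    plant_sig_of <- stats::setNames(
      rep(names(sigs), length.out = spec$n_placements), NULL)
    proteins <- list(); gt_rows <- list()
    sig_cursor <- 0L
    for (i in seq_len(spec$n_proteins)) {
      id <- sprintf("prot%03d", i)
      plant <- NULL
      if (i %in% planted_idx) {
        sig_cursor <- sig_cursor + 1L
        plant <- sigs[[plant_sig_of[sig_cursor]]]
      }
      drawn <- sample_protein(id, lens[i], plant, sigs)
      proteins[[i]] <- drawn$protein
      if (nrow(drawn$expected) > 0L) {
        gt_rows[[length(gt_rows) + 1L]] <-
          cbind(data.frame(protein_id = id, stringsAsFactors = FALSE),
                drawn$expected)
      }
    }
    ground_truth <- do.call(rbind, gt_rows)
    rownames(ground_truth) <- NULL
    refs <- reference_tables(spec)
    bundle <- integration_bundle(default_entries(),
                                 sig_to_entry_map(default_entries()),
                                 refs$protein_pathway, refs$entry_proteins)
    s2e <- bundle$signature_to_entry
    ground_truth$entry_accession <- ifelse(
      ground_truth$signature_accession %in% names(s2e),
      unname(s2e[ground_truth$signature_accession]), "-")

    fasta <- file.path(dir, "proteins.fasta")
    write_fasta(proteins, fasta)
    write_signature_library(spec$library,
                            file.path(dir, "libraries", spec$library$name))
    write_integration_bundle(bundle, file.path(dir, "integration"))
    utils::write.table(ground_truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(fasta = fasta, data_dir = dir, ground_truth = ground_truth,
         proteins = proteins, library = spec$library, bundle = bundle)
  })
}

sig_to_entry_map <- function(entries) {
  pairs <- lapply(entries, function(e) {
    stats::setNames(rep(e$accession, length(e$signature_accessions)),
                    e$signature_accessions)
  })
  do.call(c, pairs)
}

# Reverse translation with random synonymous codon choice (drawn from the
# fixture's seeded stream). Randomizing codons lets the rejection sampler
# escape spurious cross-frame/cross-strand matches that arise inside the
# coding region itself and that no amount of flank resampling could remove.
reverse_translate <- function(protein_str) {
  tab <- codon_table()
  paste(vapply(strsplit(protein_str, "")[[1]], function(aa) {
    codons <- sort(names(tab)[tab == aa])
    codons[sample.int(length(codons), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a nucleotide fixture with planted, strand-randomized ORFs
#'
#' Each planted protein from the underlying protein fixture is
#' reverse-translated, flanked by in-frame stop codons, embedded on a
#' random strand inside random nucleotide background, and written as
#' `contigs.fasta`. The ground truth additionally carries the expected
#' nucleotide-projected coordinates of every planted match, computed
#' arithmetically from the construction (independent of the ORF finder).
#'
#' @param spec A [default_fixture_spec()]; only planted proteins are
#'   embedded (one contig per plant).
#' @param dir Output directory.
#' @param flank Background bases on each side of the embedded cassette.
#' @param min_orf_length ORF length the pipeline should use on this
#'   fixture (background is rejection-sampled so that no spurious ORF
#'   protein matches any signature).
#' @return List with `fasta`, `data_dir`, `ground_truth`, `contigs`.
#' @export
generate_nucleotide_fixture <- function(spec, dir, flank = 60L,
                                        min_orf_length = 30L) {
  base <- generate_fixture(spec, dir)
  with_fixture_seed(spec$seed + 1L, {
    gt <- base$ground_truth
    planted_ids <- unique(gt$protein_id)
    prot_by_id <- stats::setNames(base$proteins,
                                  vapply(base$proteins, `[[`, character(1),
                                         "id"))
    sigs <- spec$library$signatures
    contigs <- list(); nt_rows <- list()
    for (j in seq_along(planted_ids)) {
      pid <- planted_ids[j]
      prot <- prot_by_id[[pid]]
      strand <- sample(c("+", "-"), 1L)
      cid <- sprintf("contig%03d", j)
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > 500L) {
          stop(sprintf("could not realize contig background for '%s'", pid),
               call. = FALSE)
        }
        cds <- reverse_translate(prot$residues)
        bg1 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                     collapse = "")
        bg2 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                     collapse = "")
        cassette <- paste0("TAA", cds, "TAA")
        if (strand == "-") cassette <- revcomp(cassette)
        nt <- nucleotide_sequence(cid, paste0(bg1, cassette, bg2))
        # verify construction: the pipeline on this contig must produce
        # exactly the planted matches (no spurious ORF hits)
        orfs <- find_orfs(nt, min_protein_length = min_orf_length)
        orf_prots <- lapply(orfs, `[[`, "protein")
        obs <- do.call(rbind, c(lapply(orf_prots, observed_matches, sigs),
                                list(data.frame(
                                  signature_accession = character(),
                                  start = integer(), stop = integer()))))
        exp_rows <- gt[gt$protein_id == pid,
                       c("signature_accession", "start", "stop"),
                       drop = FALSE]
        if (matches_equal(obs, exp_rows)) break
      }
      contigs[[j]] <- nt
      # expected forward-strand projection, from the construction itself:
      # '+': cds starts at flank + 4; '-': residue 1 ends at
      # flank + 3 + 3 * protein_length (the reverse-complemented cassette
      # places the cds end-first).
      for (r in which(gt$protein_id == pid)) {
        s <- gt$start[r]; e <- gt$stop[r]
        if (strand == "+") {
          cds_start <- flank + 3L + 1L
          nt_rows[[length(nt_rows) + 1L]] <- data.frame(
            parent_id = cid, protein_id = pid,
            signature_accession = gt$signature_accession[r],
            start = s, stop = e,
            nt_start = cds_start + 3L * (s - 1L),
            nt_end = cds_start + 3L * e - 1L,
            strand = "+", stringsAsFactors = FALSE)
        } else {
          res1_end <- flank + 3L + 3L * prot$length
          nt_rows[[length(nt_rows) + 1L]] <- data.frame(
            parent_id = cid, protein_id = pid,
            signature_accession = gt$signature_accession[r],
            start = s, stop = e,
            nt_start = res1_end - 3L * e + 1L,
            nt_end = res1_end - 3L * (s - 1L),
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
    nt_gt <- do.call(rbind, nt_rows)
    fasta <- file.path(dir, "contigs.fasta")
    write_fasta(contigs, fasta)
    utils::write.table(nt_gt, file.path(dir, "ground_truth_nt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(fasta = fasta, data_dir = dir, ground_truth = nt_gt,
         contigs = contigs, min_orf_length = min_orf_length)
  })
}
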