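#' @importFrom digest digest
NULL

# Canonical residue alphabets. Proteins accept the 20 standard amino acids
# plus ambiguity/rare codes B, Z, X, U, O; '*' is legal only as a trailing
# stop (stripped during canonicalization).
PROTEIN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      "B", "Z", "X", "U", "O")
NUCLEOTIDE_ALPHABET <- c("A", "C", "G", "T", "N")

#' Canonicalize a raw protein sequence and compute its checksum
#'
#' Strips whitespace, uppercases, removes a single trailing stop ('*'),
#' validates the residue alphabet and computes the lowercase hex MD5 digest
#' of the canonical residue string. The digest is a pure function of the
#' canonical residues: identical residues give identical checksums
#' regardless of identifier or input case.
#'
#' @param raw_id User-supplied sequence identifier.
#' @param raw_residues Amino-acid string; may contain whitespace and a
#'   trailing '*'.
#' @return A `protein_sequence` object with fields `id`, `residues`, `md5`
#'   and `length`.
#' @export
canonicalize_and_checksum <- function(raw_id, raw_residues) {
  stopifnot(is.character(raw_id), length(raw_id) == 1L,
            is.character(raw_residues), length(raw_residues) == 1L)
  res <- gsub("[[:space:]]+", "", raw_residues)
  res <- toupper(res)
  res <- sub("\\*$", "", res)
  if (!nzchar(res)) {
    stop(sprintf("empty sequence for id '%s'", raw_id), call. = FALSE)
  }
  chars <- strsplit(res, "")[[1]]
  bad <- which(!(chars %in% PROTEIN_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf(
      "illegal character '%s' at position %d in sequence '%s'",
      chars[bad[1L]], bad[1L], raw_id), call. = FALSE)
  }
  structure(
    list(id = raw_id, residues = res,
         md5 = digest::digest(res, algo = "md5", serialize = FALSE),
         length = nchar(res)),
    class = "protein_sequence")
}

#' Construct a validated nucleotide sequence
#'
#' @param id Identifier.
#' @param residues Nucleotide string over A, C, G, T, N (case-insensitive;
#'   canonical form is uppercase).
#' @return A `nucleotide_sequence` object with `id`, `residues`, `length`.
#' @export
nucleotide_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[[:space:]]+", "", residues))
  if (!nzchar(res)) {
    stop(sprintf("empty sequence for id '%s'", id), call. = FALSE)
  }
  chars <- strsplit(res, "")[[1]]
  bad <- which(!(chars %in% NUCLEOTIDE_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf(
      "illegal character '%s' at position %d in sequence '%s'",
      chars[bad[1L]], bad[1L], id), call. = FALSE)
  }
  structure(list(id = id, residues = res, length = nchar(res)),
            class = "nucleotide_sequence")
}

#' Collapse duplicate protein sequences by checksum
#'
#' Downstream analysis runs once per distinct checksum; results are fanned
#' back out to every submitted identifier through the alias map.
#'
#' @param sequences List of `protein_sequence` objects.
#' @return List with `unique` (one `protein_sequence` per distinct md5, in
#'   first-seen order) and `alias_map` (named list, md5 -> character vector
#'   of all ids sharing that md5, in input order).
#' @export
deduplicate <- function(sequences) {
  unique_seqs <- list()
  alias_map <- list()
  for (s in sequences) {
    stopifnot(inherits(s, "protein_sequence"))
    if (is.null(alias_map[[s$md5]])) {
      alias_map[[s$md5]] <- s$id
      unique_seqs[[length(unique_seqs) + 1L]] <- s
    } else {
      alias_map[[s$md5]] <- c(alias_map[[s$md5]], s$id)
    }
  }
  list(unique = unique_seqs, alias_map = alias_map)
}

#' Construct a located region of a signature hit
#'
#' Coordinates are 1-based inclusive residue positions on the protein.
#'
#' @param start,stop Residue coordinates, `1 <= start <= stop`.
#' @param score Optional window/bit score.
#' @param evalue Optional e-value.
#' @return A `sig_location` object.
#' @export
sig_location <- function(start, stop, score = NA_real_, evalue = NA_real_) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1L || start > stop) {
    stop("invalid location coordinates", call. = FALSE)
  }
  structure(list(start = start, stop = stop,
                 score = as.numeric(score), evalue = as.numeric(evalue)),
            class = "sig_location")
}

#' Construct a signature match on a protein
#'
#' @param protein_md5 Checksum of the matched protein.
#' @param signature_accession Accession of the matching signature.
#' @param locations Nonempty list of [sig_location()] regions.
#' @param status One of `raw`, `filtered_in`, `filtered_out`. Only
#'   `filtered_in` matches appear in user-facing output.
#' @return A `sig_match` object.
#' @export
sig_match <- function(protein_md5, signature_accession, locations,
                      status = c("raw", "filtered_in", "filtered_out")) {
  status <- match.arg(status)
  if (length(locations) == 0L) stop("match needs at least one location",
                                    call. = FALSE)
  stopifnot(all(vapply(locations, inherits, logical(1), "sig_location")))
  structure(list(protein_md5 = protein_md5,
                 signature_accession = signature_accession,
                 locations = locations, status = status),
            class = "sig_match")
}

#' Construct a signature (predictive model) record
#'
#' @param accession Accession, unique within `(library, library_version)`.
#' @param name Human-readable name.
#' @param library Signature-library name.
#' @param library_version Release version string.
#' @param model_kind `"pattern"` or `"profile"`.
#' @param model_payload For patterns, the pattern string; for profiles, a
#'   list with `matrix` (L x 20 numeric, columns named by residue) and
#'   `threshold`.
#' @param clan Optional group label used during overlap resolution; `NA`
#'   means clanless.
#' @return A `sig_signature` object.
#' @export
sig_signature <- function(accession, name, library, library_version,
                          model_kind = c("pattern", "profile"),
                          model_payload, clan = NA_character_) {
  model_kind <- match.arg(model_kind)
  structure(list(accession = accession, name = name, library = library,
                 library_version = library_version, model_kind = model_kind,
                 model_payload = model_payload, clan = clan),
            class = "sig_signature")
}

#' Construct a curated entry grouping signatures
#'
#' An entry groups signatures that describe the same family, domain, site
#' or repeat, and carries Gene Ontology and pathway cross-references. A
#' signature accession maps to at most one entry.
#'
#' @param accession Entry accession.
#' @param name Entry name.
#' @param type One of `family`, `domain`, `site`, `repeat`.
#' @param signature_accessions Character vector of member signatures.
#' @param go_terms Data frame with columns `go_id`, `category`, `term`.
#' @param pathway_xrefs Data frame with columns `database`, `pathway_id`,
#'   `name`; `(database, pathway_id)` unique within the entry.
#' @return A `sig_entry` object.
#' @export
sig_entry <- function(accession, name,
                      type = c("family", "domain", "site", "repeat"),
                      signature_accessions = character(),
                      go_terms = empty_go_terms(),
                      pathway_xrefs = empty_pathway_xrefs()) {
  type <- match.arg(type)
  if (anyDuplicated(paste(pathway_xrefs$database, pathway_xrefs$pathway_id))) {
    stop("duplicate (database, pathway_id) in entry pathway xrefs",
         call. = FALSE)
  }
  structure(list(accession = accession, name = name, type = type,
                 signature_accessions = signature_accessions,
                 go_terms = go_terms, pathway_xrefs = pathway_xrefs),
            class = "sig_entry")
}

#' @rdname sig_entry
#' @export
empty_go_terms <- function() {
  data.frame(go_id = character(), category = character(),
             term = character(), stringsAsFactors = FALSE)
}

#' @rdname sig_entry
#' @export
empty_pathway_xrefs <- function() {
  data.frame(database = character(), pathway_id = character(),
             name = character(), stringsAsFactors = FALSE)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein %s: %d aa, md5 %s>\n", x$id, x$length, x$md5))
  invisible(x)
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  cat(sprintf("<nucleotide %s: %d bp>\n", x$id, x$length))
  invisible(x)
}
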