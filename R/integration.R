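# Entry/GO/pathway integration.
#
# An integration bundle maps signatures to curated entries carrying GO
# cross-references, and holds a reference protein->pathway annotation table
# together with the reference matched-protein sets per entry. Pathway
# cross-references are attached to an entry when a significant proportion
# (strictly more than 80%) of the proteins matched by the entry in the
# reference table are annotated with that pathway.

#' Build an integration bundle
#'
#' Computes each entry's pathway cross-references from the reference
#' annotation table via [associate_pathways()] (strict >80% rule) at
#' build time, mirroring release-time precomputation.
#'
#' @param entries List of [sig_entry()] objects (pathway xrefs may be
#'   empty; they are filled in here).
#' @param signature_to_entry Named character vector, signature accession ->
#'   entry accession. Must be functional (one entry per signature) and every
#'   mapped entry must exist.
#' @param protein_pathway_annotations Data frame with columns
#'   `protein_md5`, `database`, `pathway_id`, `name`: the reference
#'   proteome's pathway annotation.
#' @param entry_proteins Data frame with columns `entry_accession`,
#'   `protein_md5`: which reference proteins each entry matches.
#' @return An `integration_bundle` object.
#' @export
integration_bundle <- function(entries, signature_to_entry,
                               protein_pathway_annotations = NULL,
                               entry_proteins = NULL) {
  if (is.null(protein_pathway_annotations)) {
    protein_pathway_annotations <- data.frame(
      protein_md5 = character(), database = character(),
      pathway_id = character(), name = character(), stringsAsFactors = FALSE)
  }
  if (is.null(entry_proteins)) {
    entry_proteins <- data.frame(entry_accession = character(),
                                 protein_md5 = character(),
                                 stringsAsFactors = FALSE)
  }
  entry_accs <- vapply(entries, function(e) e$accession, character(1))
  names(entries) <- entry_accs
  if (!all(signature_to_entry %in% entry_accs)) {
    stop("signature_to_entry references unknown entries", call. = FALSE)
  }
  if (anyDuplicated(names(signature_to_entry))) {
    stop("a signature accession maps to more than one entry", call. = FALSE)
  }
  bundle <- structure(
    list(entries = entries, signature_to_entry = signature_to_entry,
         protein_pathway_annotations = protein_pathway_annotations,
         entry_proteins = entry_proteins),
    class = "integration_bundle")
  for (acc in entry_accs) {
    matched <- entry_proteins$protein_md5[
      entry_proteins$entry_accession == acc]
    bundle$entries[[acc]]$pathway_xrefs <-
      associate_pathways(bundle$entries[[acc]], matched, bundle)
  }
  bundle
}

#' Associate pathways with an entry by the >80% rule
#'
#' A pathway cross-reference present among the annotations of an entry's
#' matched proteins is associated with the entry iff strictly more than 80%
#' of the distinct matched proteins carry that annotation. An empty matched
#' set yields no associations.
#'
#' @param entry A [sig_entry()].
#' @param matched_proteins Character vector of protein checksums matched by
#'   the entry (duplicates collapsed before computing the fraction).
#' @param bundle An [integration_bundle()] providing the reference
#'   annotation table.
#' @return Data frame of associated pathway xrefs (`database`,
#'   `pathway_id`, `name`), sorted by (database, pathway_id).
#' @export
associate_pathways <- function(entry, matched_proteins, bundle) {
  matched <- unique(matched_proteins)
  if (length(matched) == 0L) return(empty_pathway_xrefs())
  ann <- bundle$protein_pathway_annotations
  ann <- ann[ann$protein_md5 %in% matched, , drop = FALSE]
  if (nrow(ann) == 0L) return(empty_pathway_xrefs())
  key <- paste(ann$database, ann$pathway_id, sep = "\r")
  counts <- tapply(ann$protein_md5, key, function(x) length(unique(x)))
  frac <- counts / length(matched)
  keep <- names(frac)[frac > 0.80]          # strict: 80% exactly fails
  out <- unique(ann[key %in% keep,
                    c("database", "pathway_id", "name"), drop = FALSE])
  out <- out[order(out$database, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate filtered matches with entry, GO and pathway information
#'
#' A pure lookup: every match is annotated, none is filtered or altered.
#' Matches to signatures not integrated into any entry carry no entry and
#' empty GO/pathway sets.
#'
#' @param matches List of `filtered_in` matches.
#' @param bundle An [integration_bundle()].
#' @return List of `annotated_match` objects (`match`, `entry` or `NULL`,
#'   `go_terms`, `pathways`).
#' @export
annotate <- function(matches, bundle) {
  lapply(matches, function(m) {
    entry_acc <- unname(bundle$signature_to_entry[m$signature_accession])
    entry <- if (length(entry_acc) == 0L || is.na(entry_acc)) NULL
             else bundle$entries[[entry_acc]]
    structure(
      list(match = m, entry = entry,
           go_terms = if (is.null(entry)) empty_go_terms() else entry$go_terms,
           pathways = if (is.null(entry)) empty_pathway_xrefs()
                      else entry$pathway_xrefs),
      class = "annotated_match")
  })
}

#' Write an integration bundle as plain-text tables
#'
#' Emits five TSVs: `entries.tsv`, `signature_entry.tsv`, `entry_go.tsv`,
#' `protein_pathway.tsv` and `entry_proteins.tsv`.
#'
#' @param bundle An [integration_bundle()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_integration_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ents <- bundle$entries
  w(data.frame(accession = vapply(ents, `[[`, character(1), "accession"),
               name = vapply(ents, `[[`, character(1), "name"),
               type = vapply(ents, `[[`, character(1), "type"),
               stringsAsFactors = FALSE),
    "entries.tsv")
  w(data.frame(signature_accession = names(bundle$signature_to_entry),
               entry_accession = unname(bundle$signature_to_entry),
               stringsAsFactors = FALSE),
    "signature_entry.tsv")
  go_rows <- lapply(ents, function(e) {
    if (nrow(e$go_terms) == 0L) return(NULL)
    cbind(data.frame(entry_accession = e$accession,
                     stringsAsFactors = FALSE), e$go_terms)
  })
  go_df <- do.call(rbind, c(go_rows, list(
    cbind(data.frame(entry_accession = character()), empty_go_terms()))))
  w(go_df, "entry_go.tsv")
  w(bundle$protein_pathway_annotations, "protein_pathway.tsv")
  w(bundle$entry_proteins, "entry_proteins.tsv")
  invisible(dir)
}

#' Read an integration bundle written by [write_integration_bundle()]
#'
#' Entry pathway associations are recomputed at load time from the
#' reference tables, so a bundle on disk never carries stale associations.
#'
#' @param dir Bundle directory.
#' @return An [integration_bundle()].
#' @export
read_integration_bundle <- function(dir) {
  r <- function(name) {
    # every column in these tables is textual; never let read.table sniff
    # an all-digit checksum into an integer
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = character(),
                      colClasses = "character")
  }
  ents_df <- r("entries.tsv")
  sig_df <- r("signature_entry.tsv")
  go_df <- r("entry_go.tsv")
  pp_df <- r("protein_pathway.tsv")
  ep_df <- r("entry_proteins.tsv")
  s2e <- stats::setNames(sig_df$entry_accession, sig_df$signature_accession)
  entries <- lapply(seq_len(nrow(ents_df)), function(i) {
    acc <- ents_df$accession[i]
    gos <- go_df[go_df$entry_accession == acc,
                 c("go_id", "category", "term"), drop = FALSE]
    rownames(gos) <- NULL
    sig_entry(acc, ents_df$name[i], ents_df$type[i],
              signature_accessions = sig_df$signature_accession[
                sig_df$entry_accession == acc],
              go_terms = gos)
  })
  integration_bundle(entries, s2e, pp_df, ep_df)
}
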