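# Analyzer contract and built-in analyzers.
#
# Two modalities are supported behind one contract: single-pass predictors
# whose post-processing is the identity, and multi-model scan + post-process
# pipelines whose raw hits are filtered (here: clan overlap resolution)
# before reporting. scan() is pure per (protein, signature); postprocess()
# never invents locations, it only sets match status.

#' Build an analyzer contract
#'
#' @param name Analyzer name.
#' @param scan `function(proteins, signatures)` returning raw matches.
#' @param postprocess `function(matches, signatures)` returning the same
#'   matches with `status` set to `filtered_in`/`filtered_out`.
#' @return An `analyzer_contract` object.
#' @export
analyzer_contract <- function(name, scan, postprocess) {
  stopifnot(is.function(scan), is.function(postprocess))
  structure(list(name = name, scan = scan, postprocess = postprocess),
            class = "analyzer_contract")
}

# Raw scan shared by the built-in analyzers: dispatch on model kind, group
# all of a signature's locations on one protein into a single match.
builtin_scan <- function(proteins, signatures) {
  matches <- list()
  for (p in proteins) {
    for (sig in signatures) {
      locs <- switch(sig$model_kind,
                     pattern = scan_pattern(p, sig$model_payload),
                     profile = scan_profile(p, sig$model_payload))
      if (length(locs) > 0L) {
        matches[[length(matches) + 1L]] <-
          sig_match(p$md5, sig$accession, locs, status = "raw")
      }
    }
  }
  matches
}

#' The built-in scan + post-process analyzer
#'
#' Scans each protein with every pattern and profile signature, then
#' resolves clan overlaps. Use [single_pass_analyzer()] for the
#' predictor-style modality whose raw output is reported as-is.
#'
#' @param name Analyzer name (defaults to "builtin").
#' @return An [analyzer_contract()].
#' @export
builtin_analyzer <- function(name = "builtin") {
  analyzer_contract(name, builtin_scan,
                    function(matches, signatures) {
                      resolve_overlaps(matches, signatures)
                    })
}

#' @rdname builtin_analyzer
#' @export
single_pass_analyzer <- function(name = "singlepass") {
  analyzer_contract(name, builtin_scan,
                    function(matches, signatures) {
                      lapply(matches, function(m) { m$status <- "filtered_in"; m })
                    })
}

#' Resolve overlapping same-clan matches
#'
#' Within each clan, locations that overlap by at least one residue compete;
#' the best survives (highest location score, ties broken by smaller start,
#' then lexicographically smaller signature accession; a missing score ranks
#' below any number). A multi-location match competes location-wise and is
#' `filtered_in` if any of its locations survives. Clanless matches are
#' always `filtered_in`. No match is removed — statuses only — so the
#' operation conserves match count and is idempotent.
#'
#' @param matches List of raw matches, all on the same protein (matches on
#'   several proteins are grouped internally by checksum).
#' @param signatures Named list (or list) of [sig_signature()] objects
#'   indexed by accession, used to look up clans.
#' @return The matches with `status` set.
#' @export
resolve_overlaps <- function(matches, signatures) {
  if (length(matches) == 0L) return(matches)
  sig_index <- signature_index(signatures)
  by_prot <- split(seq_along(matches),
                   vapply(matches, function(m) m$protein_md5, character(1)))
  for (idxs in by_prot) {
    clans <- vapply(idxs, function(i) {
      sig <- sig_index[[matches[[i]]$signature_accession]]
      if (is.null(sig) || is.na(sig$clan)) NA_character_ else sig$clan
    }, character(1))
    for (i in idxs[is.na(clans)]) matches[[i]]$status <- "filtered_in"
    for (cl in unique(clans[!is.na(clans)])) {
      members <- idxs[!is.na(clans) & clans == cl]
      # flatten locations of all clan members
      tab <- do.call(rbind, lapply(members, function(i) {
        m <- matches[[i]]
        do.call(rbind, lapply(m$locations, function(l) {
          data.frame(match = i, acc = m$signature_accession,
                     start = l$start, stop = l$stop,
                     score = if (is.na(l$score)) -Inf else l$score,
                     stringsAsFactors = FALSE)
        }))
      }))
      ord <- order(-tab$score, tab$start, tab$acc)
      kept <- logical(nrow(tab))
      for (r in ord) {
        ov <- kept & tab$start <= tab$stop[r] & tab$stop >= tab$start[r]
        if (!any(ov)) kept[r] <- TRUE
      }
      surviving <- unique(tab$match[kept])
      for (i in members) {
        matches[[i]]$status <-
          if (i %in% surviving) "filtered_in" else "filtered_out"
      }
    }
  }
  matches
}

# Index signatures by accession (accepts a list or an already-named list).
signature_index <- function(signatures) {
  if (inherits(signatures, "sig_signature")) signatures <- list(signatures)
  nm <- vapply(signatures, function(s) s$accession, character(1))
  stats::setNames(signatures, nm)
}

#' Run one analyzer over a protein set
#'
#' Applies the analyzer's scan then post-process stages. Output is
#' deterministic given the inputs and keyed by protein checksum.
#'
#' @param proteins List of protein sequences (typically deduplicated).
#' @param signatures Signatures from one library release.
#' @param contract An [analyzer_contract()] (default: the built-in
#'   scan + post-process analyzer).
#' @return List of matches with status set.
#' @export
run_analysis <- function(proteins, signatures, contract = builtin_analyzer()) {
  raw <- contract$scan(proteins, signatures)
  contract$postprocess(raw, signatures)
}
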