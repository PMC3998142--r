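# Checksum-keyed store of precomputed matches.
#
# A store built from prior result XML short-circuits recomputation: before
# launching analysis jobs, the protein set is partitioned into hits
# (returned verbatim from the store) and misses (analyzed from scratch).
# The store is valid only for exactly matching signature-library release
# versions; any mismatch makes the whole set a miss. Lookup is an
# optimization, never a correctness dependency: an unreadable or corrupt
# store degrades to all-miss with a warning.

# Version stamp: sorted "name:version" pairs joined by ';'.
version_stamp <- function(analyses) {
  paste(sort(paste0(analyses$name, ":", analyses$version)), collapse = ";")
}

#' Build a match store from result XML files
#'
#' One record per distinct checksum; annotated matches in the XML are
#' reduced back to raw match sets (signature accession, locations, status).
#' Loading the same file twice is idempotent.
#'
#' @param xml_paths Character vector of result XML files produced by
#'   [write_result_xml()].
#' @return A `match_store` with a `version` stamp and `records`
#'   (md5 -> list of [sig_match()]).
#' @export
load_store <- function(xml_paths) {
  records <- list()
  stamp <- NULL
  for (path in xml_paths) {
    doc <- read_result_xml(path)
    this_stamp <- version_stamp(doc$metadata$analyses)
    if (is.null(stamp)) stamp <- this_stamp
    else if (!identical(stamp, this_stamp)) {
      stop(sprintf("store load error: %s carries analysis versions '%s', store has '%s'",
                   path, this_stamp, stamp), call. = FALSE)
    }
    for (p in doc$proteins) {
      records[[p$md5]] <- lapply(p$matches, function(m) {
        sig_match(p$md5, m$signature_accession,
                  lapply(m$locations, function(l) {
                    sig_location(l$start, l$stop, l$score, l$evalue)
                  }),
                  status = m$status)
      })
    }
  }
  structure(list(version = stamp, records = records),
            class = "match_store")
}

#' Save / reload a match store as a single XML file
#'
#' The on-disk form is a minimal XML dialect: a `match-store` root stamped
#' with the release versions, one `protein` element per checksum, `match`
#' and `location` children.
#'
#' @param store A `match_store`.
#' @param path Target file.
#' @return `path` (save) or the reloaded `match_store` (read).
#' @export
save_match_store <- function(store, path) {
  root <- xml2::xml_new_root("match-store", version = store$version)
  for (md5 in sort(names(store$records))) {
    pn <- xml2::xml_add_child(root, "protein", md5 = md5)
    for (m in store$records[[md5]]) {
      mn <- xml2::xml_add_child(pn, "match",
                                "signature-ac" = m$signature_accession,
                                status = m$status)
      for (l in m$locations) {
        xml2::xml_add_child(mn, "location",
                            start = as.character(l$start),
                            stop = as.character(l$stop),
                            score = fmt_num(l$score),
                            evalue = fmt_num(l$evalue))
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' @rdname save_match_store
#' @export
read_match_store <- function(path) {
  x <- xml2::read_xml(path)
  if (xml2::xml_name(x) != "match-store") {
    stop(sprintf("schema violation in %s: root '%s', expected 'match-store'",
                 path, xml2::xml_name(x)), call. = FALSE)
  }
  records <- list()
  for (pn in xml2::xml_find_all(x, "./protein")) {
    md5 <- xml2::xml_attr(pn, "md5")
    records[[md5]] <- lapply(xml2::xml_find_all(pn, "./match"), function(mn) {
      sig_match(md5, xml2::xml_attr(mn, "signature-ac"),
                lapply(xml2::xml_find_all(mn, "./location"), function(ln) {
                  sig_location(as.integer(xml2::xml_attr(ln, "start")),
                               as.integer(xml2::xml_attr(ln, "stop")),
                               parse_num(xml2::xml_attr(ln, "score")),
                               parse_num(xml2::xml_attr(ln, "evalue")))
                }),
                status = xml2::xml_attr(mn, "status"))
    })
  }
  structure(list(version = xml2::xml_attr(x, "version"), records = records),
            class = "match_store")
}

#' Partition proteins into store hits and misses
#'
#' Hits are returned verbatim from the store; the union of hits and misses
#' covers the input exactly once. A version-stamp mismatch between the
#' store and the configured analyses makes the entire input a miss
#' (staleness guard); a `NULL`/corrupt store likewise degrades to all-miss
#' with a warning. The store is never mutated.
#'
#' @param proteins List of protein sequences.
#' @param store A `match_store`, or `NULL` for no lookup.
#' @param analyses Data frame `name`/`version` of the configured analyses.
#' @return List with `hits` (md5 -> list of matches) and `misses` (list of
#'   proteins).
#' @export
partition_by_store <- function(proteins, store, analyses) {
  all_miss <- list(hits = list(), misses = proteins)
  if (is.null(store)) return(all_miss)
  if (!inherits(store, "match_store") || is.null(store$records)) {
    warning("match store unreadable; treating all sequences as misses")
    return(all_miss)
  }
  if (!identical(store$version, version_stamp(analyses))) {
    return(all_miss)
  }
  hits <- list()
  misses <- list()
  for (p in proteins) {
    rec <- store$records[[p$md5]]
    if (is.null(rec)) {
      misses[[length(misses) + 1L]] <- p
    } else {
      hits[[p$md5]] <- rec
    }
  }
  list(hits = hits, misses = misses)
}
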