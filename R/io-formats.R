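# Result document and the output format family.
#
# The XML serialization is canonical and lossless: read_result_xml() of
# write_result_xml() reproduces the document field-wise, and every other
# format (TSV, GFF3, JSON) is a deterministic projection of the same
# in-memory document, so converting from XML byte-equals writing directly.
# Element ordering is stable everywhere: proteins by first id, matches by
# (analysis, signature accession, first location start), locations by
# (start, stop), rows in TSV by (id, analysis, signature accession, start).

#' Read a FASTA file of protein or nucleotide sequences
#'
#' Headers are split at the first whitespace to obtain identifiers;
#' duplicate identifiers are rejected; line wrapping and blank lines are
#' tolerated. Residue validation (and, for proteins, canonicalization and
#' checksumming) is delegated to the sequence constructors.
#'
#' @param path FASTA file.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return List of sequence objects.
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id '%s' in %s", dup[1L], path),
         call. = FALSE)
  }
  res <- unname(as.character(set))
  lapply(seq_along(ids), function(i) {
    if (kind == "protein") canonicalize_and_checksum(ids[i], res[i])
    else nucleotide_sequence(ids[i], res[i])
  })
}

#' Write sequences as FASTA
#'
#' @param sequences List of sequence objects (protein or nucleotide).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  lines <- unlist(lapply(sequences, function(s) {
    body <- substring(s$residues,
                      seq(1L, s$length, by = width),
                      pmin(seq(width, s$length + width - 1L, by = width),
                           s$length))
    c(paste0(">", s$id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- result document ------------------------------------------------------

num_or_na <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)

# canonical per-match record used inside a result document
doc_match <- function(analysis, signature_accession, signature_name,
                      status, entry, go_terms, pathways, locations) {
  locs <- locations[order(vapply(locations, `[[`, integer(1), "start"),
                          vapply(locations, `[[`, integer(1), "stop"))]
  list(analysis = analysis,
       signature_accession = signature_accession,
       signature_name = signature_name,
       status = status,
       entry = entry,  # NULL or list(accession, name, type)
       go_terms = go_terms, pathways = pathways,
       locations = locs)
}

#' Assemble a result document
#'
#' @param analyses Data frame with columns `name`, `version` (one row per
#'   analysis run).
#' @param proteins List of per-protein records: `md5`, `length`,
#'   `residues`, `ids` (all aliases), `matches` (list as built by
#'   [document_from_results()]).
#' @param nucleotides Optional list of per-nucleotide records: `id`,
#'   `length`, `orfs` (list of `id`, `strand`, `nt_start`, `nt_end`,
#'   `protein_md5`).
#' @param date Run date string (injectable so output is reproducible).
#' @param tool_version Tool version stamp.
#' @return A `result_document`, canonically sorted.
#' @export
result_document <- function(analyses, proteins, nucleotides = list(),
                            date = as.character(Sys.Date()),
                            tool_version = "0.1.0") {
  analyses <- analyses[order(analyses$name), , drop = FALSE]
  rownames(analyses) <- NULL
  proteins <- lapply(proteins, function(p) {
    p$ids <- sort(p$ids)
    ord <- order(vapply(p$matches, `[[`, character(1), "analysis"),
                 vapply(p$matches, `[[`, character(1), "signature_accession"),
                 vapply(p$matches, function(m) m$locations[[1L]]$start,
                        integer(1)))
    p$matches <- p$matches[ord]
    p
  })
  proteins <- proteins[order(vapply(proteins, function(p) p$ids[1L],
                                    character(1)))]
  nucleotides <- lapply(nucleotides, function(nt) {
    nt$orfs <- nt$orfs[order(vapply(nt$orfs, `[[`, character(1), "id"))]
    nt
  })
  nucleotides <- nucleotides[order(vapply(nucleotides, `[[`, character(1),
                                          "id"))]
  structure(list(metadata = list(tool = "sigscan",
                                 tool_version = tool_version,
                                 date = date, analyses = analyses),
                 proteins = proteins, nucleotides = nucleotides),
            class = "result_document")
}

#' Build a result document from annotated pipeline results
#'
#' Fans analysis results (one per distinct checksum) back out to every
#' submitted identifier via the alias map. Only `filtered_in` matches enter
#' the document.
#'
#' @param annotated List of `annotated_match` objects.
#' @param dedup Output of [deduplicate()] on the analyzed proteins.
#' @param analyses Data frame `name`/`version`.
#' @param signatures Signature index (for signature names).
#' @param nucleotides,orfs Optional: list of [nucleotide_sequence()] and of
#'   `open_reading_frame`s for nucleotide runs.
#' @param date Run date string.
#' @return A [result_document()].
#' @export
document_from_results <- function(annotated, dedup, analyses, signatures,
                                  nucleotides = list(), orfs = list(),
                                  date = as.character(Sys.Date())) {
  sig_index <- signature_index(signatures)
  by_md5 <- split(annotated, vapply(annotated, function(a) a$match$protein_md5,
                                    character(1)))
  proteins <- lapply(dedup$unique, function(p) {
    ann <- by_md5[[p$md5]]
    matches <- lapply(ann, function(a) {
      if (a$match$status != "filtered_in") return(NULL)
      sig <- sig_index[[a$match$signature_accession]]
      entry <- if (is.null(a$entry)) NULL else
        list(accession = a$entry$accession, name = a$entry$name,
             type = a$entry$type)
      doc_match(analysis = sig$library,
                signature_accession = sig$accession,
                signature_name = sig$name,
                status = a$match$status, entry = entry,
                go_terms = a$go_terms, pathways = a$pathways,
                locations = lapply(a$match$locations, function(l) {
                  list(start = l$start, stop = l$stop,
                       score = num_or_na(l$score),
                       evalue = num_or_na(l$evalue))
                }))
    })
    list(md5 = p$md5, length = p$length, residues = p$residues,
         ids = dedup$alias_map[[p$md5]],
         matches = Filter(Negate(is.null), matches))
  })
  nts <- lapply(nucleotides, function(nt) {
    my_orfs <- Filter(function(o) o$parent_id == nt$id, orfs)
    list(id = nt$id, length = nt$length,
         orfs = lapply(my_orfs, function(o) {
           list(id = o$protein$id, strand = o$strand,
                nt_start = o$nt_start, nt_end = o$nt_end,
                protein_md5 = o$protein$md5)
         }))
  })
  result_document(analyses, proteins, nts, date = date)
}

# ---- XML (canonical form) -------------------------------------------------

fmt_num <- function(x) if (is.na(x)) "-" else sprintf("%.17g", x)
parse_num <- function(s) if (s == "-") NA_real_ else as.numeric(s)

#' Write / read the canonical XML result format
#'
#' The XML round trip is lossless: `read_result_xml(write_result_xml(doc))`
#' equals `doc` field-wise. Schema (informal): a `protein-matches` root with
#' `analyses`, optional `nucleotide-sequence` elements (with `orf`
#' children), and `protein` elements carrying `xref`, `sequence` and
#' `match` children; each `match` holds optional `entry`, `go-xref`,
#' `pathway-xref` and one or more `location` children.
#'
#' @param doc A [result_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_xml <- function(doc, path) {
  root <- xml2::xml_new_root("protein-matches",
                             tool = doc$metadata$tool,
                             "tool-version" = doc$metadata$tool_version,
                             date = doc$metadata$date)
  an <- xml2::xml_add_child(root, "analyses")
  for (i in seq_len(nrow(doc$metadata$analyses))) {
    xml2::xml_add_child(an, "analysis",
                        name = doc$metadata$analyses$name[i],
                        version = doc$metadata$analyses$version[i])
  }
  for (nt in doc$nucleotides) {
    nn <- xml2::xml_add_child(root, "nucleotide-sequence", id = nt$id,
                              length = as.character(nt$length))
    for (o in nt$orfs) {
      xml2::xml_add_child(nn, "orf", id = o$id, strand = o$strand,
                          "nt-start" = as.character(o$nt_start),
                          "nt-end" = as.character(o$nt_end),
                          "protein-md5" = o$protein_md5)
    }
  }
  for (p in doc$proteins) {
    pn <- xml2::xml_add_child(root, "protein", md5 = p$md5,
                              length = as.character(p$length))
    for (id in p$ids) xml2::xml_add_child(pn, "xref", id = id)
    xml2::xml_add_child(pn, "sequence", p$residues)
    for (m in p$matches) {
      mn <- xml2::xml_add_child(pn, "match", analysis = m$analysis,
                                "signature-ac" = m$signature_accession,
                                "signature-name" = m$signature_name,
                                status = m$status)
      if (!is.null(m$entry)) {
        xml2::xml_add_child(mn, "entry", ac = m$entry$accession,
                            name = m$entry$name, type = m$entry$type)
      }
      if (nrow(m$go_terms) > 0L) {
        for (i in seq_len(nrow(m$go_terms))) {
          xml2::xml_add_child(mn, "go-xref", id = m$go_terms$go_id[i],
                              category = m$go_terms$category[i],
                              term = m$go_terms$term[i])
        }
      }
      if (nrow(m$pathways) > 0L) {
        for (i in seq_len(nrow(m$pathways))) {
          xml2::xml_add_child(mn, "pathway-xref",
                              database = m$pathways$database[i],
                              id = m$pathways$pathway_id[i],
                              name = m$pathways$name[i])
        }
      }
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

#' @rdname write_result_xml
#' @param path Path of an XML file produced by [write_result_xml()].
#' @return For `read_result_xml`: the reconstructed [result_document()].
#' @export
read_result_xml <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) {
    stop(sprintf("cannot read result XML: %s is missing or empty", path),
         call. = FALSE)
  }
  x <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed result XML %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (xml2::xml_name(x) != "protein-matches") {
    stop(sprintf("schema violation in %s: root element '%s', expected 'protein-matches'",
                 path, xml2::xml_name(x)), call. = FALSE)
  }
  att <- function(node, a) xml2::xml_attr(node, a)
  analyses_nodes <- xml2::xml_find_all(x, "./analyses/analysis")
  analyses <- data.frame(name = att(analyses_nodes, "name"),
                         version = att(analyses_nodes, "version"),
                         stringsAsFactors = FALSE)
  nucleotides <- lapply(xml2::xml_find_all(x, "./nucleotide-sequence"),
                        function(nn) {
    list(id = att(nn, "id"), length = as.integer(att(nn, "length")),
         orfs = lapply(xml2::xml_find_all(nn, "./orf"), function(o) {
           list(id = att(o, "id"), strand = att(o, "strand"),
                nt_start = as.integer(att(o, "nt-start")),
                nt_end = as.integer(att(o, "nt-end")),
                protein_md5 = att(o, "protein-md5"))
         }))
  })
  proteins <- lapply(xml2::xml_find_all(x, "./protein"), function(pn) {
    seq_node <- xml2::xml_find_first(pn, "./sequence")
    if (inherits(seq_node, "xml_missing")) {
      stop(sprintf("schema violation in %s: protein %s lacks a sequence element",
                   path, att(pn, "md5")), call. = FALSE)
    }
    matches <- lapply(xml2::xml_find_all(pn, "./match"), function(mn) {
      entry_node <- xml2::xml_find_first(mn, "./entry")
      entry <- if (inherits(entry_node, "xml_missing")) NULL else
        list(accession = att(entry_node, "ac"),
             name = att(entry_node, "name"),
             type = att(entry_node, "type"))
      go_nodes <- xml2::xml_find_all(mn, "./go-xref")
      gos <- data.frame(go_id = att(go_nodes, "id"),
                        category = att(go_nodes, "category"),
                        term = att(go_nodes, "term"),
                        stringsAsFactors = FALSE)
      pw_nodes <- xml2::xml_find_all(mn, "./pathway-xref")
      pws <- data.frame(database = att(pw_nodes, "database"),
                        pathway_id = att(pw_nodes, "id"),
                        name = att(pw_nodes, "name"),
                        stringsAsFactors = FALSE)
      locs <- lapply(xml2::xml_find_all(mn, "./location"), function(ln) {
        list(start = as.integer(att(ln, "start")),
             stop = as.integer(att(ln, "stop")),
             score = parse_num(att(ln, "score")),
             evalue = parse_num(att(ln, "evalue")))
      })
      if (length(locs) == 0L) {
        stop(sprintf("schema violation in %s: match %s has no location",
                     path, att(mn, "signature-ac")), call. = FALSE)
      }
      doc_match(att(mn, "analysis"), att(mn, "signature-ac"),
                att(mn, "signature-name"), att(mn, "status"),
                entry, gos, pws, locs)
    })
    list(md5 = att(pn, "md5"), length = as.integer(att(pn, "length")),
         residues = xml2::xml_text(seq_node),
         ids = vapply(xml2::xml_find_all(pn, "./xref"),
                      function(n) att(n, "id"), character(1)),
         matches = matches)
  })
  result_document(analyses, proteins, nucleotides,
                  date = att(x, "date"),
                  tool_version = att(x, "tool-version"))
}

# ---- TSV ------------------------------------------------------------------

fmt_score_tsv <- function(x) if (is.na(x)) "-" else sprintf("%.1f", x)

#' Write the 15-column tab-delimited projection
#'
#' One row per (protein id, match location). Columns: id, md5, length,
#' analysis, signature accession, signature description, start, stop,
#' score, status, date, entry accession, entry description, GO terms
#' (pipe-joined ids), pathways (pipe-joined `db:id`). Missing values are
#' "-"; scores use one fixed decimal. Rows sorted by (id, analysis,
#' signature accession, start).
#'
#' @param doc A [result_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(doc, path) {
  rows <- list()
  for (p in doc$proteins) {
    for (id in p$ids) {
      for (m in p$matches) {
        gos <- if (nrow(m$go_terms) > 0L)
          paste(m$go_terms$go_id, collapse = "|") else "-"
        pws <- if (nrow(m$pathways) > 0L)
          paste(paste0(m$pathways$database, ":", m$pathways$pathway_id),
                collapse = "|") else "-"
        for (l in m$locations) {
          rows[[length(rows) + 1L]] <- c(
            id, p$md5, as.character(p$length), m$analysis,
            m$signature_accession, m$signature_name,
            as.character(l$start), as.character(l$stop),
            fmt_score_tsv(l$score), m$status, doc$metadata$date,
            if (is.null(m$entry)) "-" else m$entry$accession,
            if (is.null(m$entry)) "-" else m$entry$name,
            gos, pws)
        }
      }
    }
  }
  if (length(rows) > 0L) {
    tab <- do.call(rbind, rows)
    ord <- order(tab[, 1L], tab[, 4L], tab[, 5L], as.integer(tab[, 7L]))
    lines <- apply(tab[ord, , drop = FALSE], 1L, paste, collapse = "\t")
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- GFF3 -----------------------------------------------------------------

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

#' Write the GFF3 projection
#'
#' Protein runs: one `protein_match` feature per (protein id, location)
#' with 1-based inclusive coordinates and strand ".". Nucleotide runs
#' additionally emit one `ORF` feature per translated ORF with matches and
#' one projected `protein_match` feature per location on the parent
#' nucleotide seqid (coordinates via [map_to_nucleotide()], the ORF's
#' strand). A `##FASTA` section with the analyzed proteins follows the
#' features.
#'
#' @param doc A [result_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_gff3 <- function(doc, path) {
  lines <- c("##gff-version 3",
             sprintf("##date %s", doc$metadata$date))
  src <- doc$metadata$tool
  feature_rows <- character()
  k <- 0L
  for (p in doc$proteins) {
    for (id in p$ids) {
      for (m in p$matches) {
        for (l in m$locations) {
          k <- k + 1L
          attrs <- c(sprintf("ID=match%05d", k),
                     sprintf("Name=%s", gff3_escape(m$signature_accession)),
                     sprintf("signature_desc=%s", gff3_escape(m$signature_name)))
          if (!is.null(m$entry)) {
            attrs <- c(attrs, sprintf("entry=%s", gff3_escape(m$entry$accession)))
          }
          feature_rows <- c(feature_rows, paste(
            gff3_escape(id), src, "protein_match",
            l$start, l$stop,
            if (is.na(l$score)) "." else sprintf("%.1f", l$score),
            ".", ".", paste(attrs, collapse = ";"), sep = "\t"))
        }
      }
    }
  }
  # nucleotide projection
  if (length(doc$nucleotides) > 0L) {
    md5_proteins <- stats::setNames(
      doc$proteins, vapply(doc$proteins, `[[`, character(1), "md5"))
    for (nt in doc$nucleotides) {
      for (o in nt$orfs) {
        prot <- md5_proteins[[o$protein_md5]]
        ms <- prot$matches
        if (is.null(ms) || length(ms) == 0L) next
        orf_obj <- structure(
          list(parent_id = nt$id, strand = o$strand, nt_start = o$nt_start,
               nt_end = o$nt_end, protein = list(length = prot$length)),
          class = "open_reading_frame")
        feature_rows <- c(feature_rows, paste(
          gff3_escape(nt$id), src, "ORF", o$nt_start, o$nt_end, ".",
          o$strand, ".",
          sprintf("ID=%s;md5=%s", gff3_escape(o$id), o$protein_md5),
          sep = "\t"))
        for (m in ms) {
          for (l in m$locations) {
            k <- k + 1L
            proj <- map_to_nucleotide(orf_obj, l$start, l$stop)
            attrs <- c(sprintf("ID=match%05d", k),
                       sprintf("Name=%s", gff3_escape(m$signature_accession)),
                       sprintf("Parent=%s", gff3_escape(o$id)))
            if (!is.null(m$entry)) {
              attrs <- c(attrs,
                         sprintf("entry=%s", gff3_escape(m$entry$accession)))
            }
            feature_rows <- c(feature_rows, paste(
              gff3_escape(nt$id), src, "protein_match",
              proj$nt_start, proj$nt_end,
              if (is.na(l$score)) "." else sprintf("%.1f", l$score),
              proj$strand, ".", paste(attrs, collapse = ";"), sep = "\t"))
          }
        }
      }
    }
  }
  lines <- c(lines, feature_rows, "##FASTA")
  for (p in doc$proteins) {
    for (id in p$ids) {
      body <- substring(p$residues,
                        seq(1L, p$length, by = 60L),
                        pmin(seq(60L, p$length + 59L, by = 60L), p$length))
      lines <- c(lines, paste0(">", id), body)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- JSON -----------------------------------------------------------------

#' Write the JSON projection
#'
#' A direct structural mirror of the canonical XML document.
#'
#' @param doc A [result_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(doc, path) {
  mirror <- list(
    tool = doc$metadata$tool,
    `tool-version` = doc$metadata$tool_version,
    date = doc$metadata$date,
    analyses = lapply(seq_len(nrow(doc$metadata$analyses)), function(i) {
      list(name = doc$metadata$analyses$name[i],
           version = doc$metadata$analyses$version[i])
    }),
    `nucleotide-sequences` = lapply(doc$nucleotides, function(nt) {
      list(id = nt$id, length = nt$length, orfs = nt$orfs)
    }),
    proteins = lapply(doc$proteins, function(p) {
      list(md5 = p$md5, length = p$length, xref = as.list(p$ids),
           sequence = p$residues,
           matches = lapply(p$matches, function(m) {
             list(analysis = m$analysis,
                  `signature-ac` = m$signature_accession,
                  `signature-name` = m$signature_name,
                  status = m$status,
                  entry = m$entry,
                  `go-xrefs` = lapply(seq_len(nrow(m$go_terms)), function(i) {
                    list(id = m$go_terms$go_id[i],
                         category = m$go_terms$category[i],
                         term = m$go_terms$term[i])
                  }),
                  `pathway-xrefs` = lapply(seq_len(nrow(m$pathways)),
                                           function(i) {
                    list(database = m$pathways$database[i],
                         id = m$pathways$pathway_id[i],
                         name = m$pathways$name[i])
                  }),
                  locations = lapply(m$locations, function(l) {
                    list(start = l$start, stop = l$stop,
                         score = if (is.na(l$score)) NULL else l$score,
                         evalue = if (is.na(l$evalue)) NULL else l$evalue)
                  }))
           }))
    }))
  json <- jsonlite::toJSON(mirror, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

# ---- convert --------------------------------------------------------------

#' Convert canonical XML output to another format
#'
#' Output is byte-identical to writing the target format directly from the
#' in-memory document that produced the XML.
#'
#' @param xml_path Path to a result XML file.
#' @param target One of `"tsv"`, `"gff3"`, `"json"`.
#' @param out_path Output path.
#' @return `out_path`, invisibly.
#' @export
convert_results <- function(xml_path, target, out_path) {
  target <- tolower(target)
  if (!target %in% c("tsv", "gff3", "json")) {
    stop(sprintf(
      "unsupported conversion target '%s' (supported: tsv, gff3, json)",
      target), call. = FALSE)
  }
  doc <- read_result_xml(xml_path)
  switch(target,
         tsv = write_result_tsv(doc, out_path),
         gff3 = write_result_gff3(doc, out_path),
         json = write_result_json(doc, out_path))
  invisible(out_path)
}
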