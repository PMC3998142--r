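# PROSITE-style pattern models: parser and scanner.
#
# Grammar: elements separated by '-'; an element is a literal residue, the
# wildcard 'x', a set '[ACD]' or a negated set '{ACD}', optionally followed
# by a repeat '(n)' or '(n,max)'. '<' anchors the pattern to the N terminus,
# '>' to the C terminus. No nested groups. Matching reports, for every
# distinct start position, the shortest accepting window.

#' Parse a PROSITE-style pattern
#'
#' @param pattern Pattern string, e.g. `"C-x(2)-C"`, `"<M"`, `"[DE]-x-K>"`.
#' @return A `pattern_model` object: list of elements (each with `type`,
#'   `residues`, `min`, `max`) plus `n_anchor`/`c_anchor` flags.
#' @export
parse_prosite <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  src <- pattern
  n_anchor <- FALSE; c_anchor <- FALSE
  if (startsWith(pattern, "<")) { n_anchor <- TRUE; pattern <- substr(pattern, 2L, nchar(pattern)) }
  if (endsWith(pattern, ">")) { c_anchor <- TRUE; pattern <- substr(pattern, 1L, nchar(pattern) - 1L) }
  if (!nzchar(pattern)) stop("malformed pattern: no elements", call. = FALSE)
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(parts))
  offset <- if (n_anchor) 1L else 0L  # for error positions in the source
  pos <- offset
  for (i in seq_along(parts)) {
    p <- parts[i]
    pos <- pos + 1L  # 1-based position of this element in src (approximate: start)
    if (!nzchar(p)) {
      stop(sprintf("malformed pattern '%s': empty element at position %d",
                   src, pos), call. = FALSE)
    }
    min_rep <- 1L; max_rep <- 1L
    rep_m <- regmatches(p, regexec("\\((\\d+)(,(\\d+))?\\)$", p))[[1]]
    if (length(rep_m) > 0L) {
      min_rep <- as.integer(rep_m[2L])
      max_rep <- if (nzchar(rep_m[4L])) as.integer(rep_m[4L]) else min_rep
      if (max_rep < min_rep) {
        stop(sprintf("malformed pattern '%s': repeat max < min at position %d",
                     src, pos), call. = FALSE)
      }
      p <- sub("\\(\\d+(,\\d+)?\\)$", "", p)
    }
    if (grepl("^\\[[A-Z]+\\]$", p)) {
      el <- list(type = "set", residues = strsplit(substr(p, 2L, nchar(p) - 1L), "")[[1]])
    } else if (grepl("^\\{[A-Z]+\\}$", p)) {
      el <- list(type = "negset", residues = strsplit(substr(p, 2L, nchar(p) - 1L), "")[[1]])
    } else if (p == "x") {
      el <- list(type = "any", residues = character())
    } else if (grepl("^[A-Z]$", p)) {
      el <- list(type = "literal", residues = p)
    } else {
      stop(sprintf("malformed pattern '%s': cannot parse element '%s' at position %d",
                   src, p, pos), call. = FALSE)
    }
    el$min <- min_rep; el$max <- max_rep
    elements[[i]] <- el
    pos <- pos + nchar(parts[i])
  }
  structure(list(elements = elements, n_anchor = n_anchor,
                 c_anchor = c_anchor, source = src),
            class = "pattern_model")
}

# Does residue ch satisfy a single pattern element?
element_matches <- function(el, ch) {
  switch(el$type,
         literal = ch == el$residues,
         any = TRUE,
         set = ch %in% el$residues,
         negset = !(ch %in% el$residues))
}

#' Scan a protein with a pattern model
#'
#' Reports every distinct start position at which the pattern accepts, each
#' with its shortest accepting window, in leftmost order. Overlapping
#' occurrences at distinct starts are all reported. Pattern matches carry no
#' score.
#'
#' @param protein A [canonicalize_and_checksum()] protein.
#' @param model A [parse_prosite()] model (or a pattern string).
#' @return List of [sig_location()] objects.
#' @export
scan_pattern <- function(protein, model) {
  if (is.character(model)) model <- parse_prosite(model)
  stopifnot(inherits(model, "pattern_model"))
  chars <- strsplit(protein$residues, "")[[1]]
  L <- length(chars)
  els <- model$elements
  n_el <- length(els)

  # Memoized set of exclusive end positions reachable by matching elements
  # i..n starting at pos.
  memo <- new.env(parent = emptyenv())
  match_ends <- function(i, pos) {
    key <- paste0(i, ":", pos)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- integer()
    if (i > n_el) {
      out <- pos
    } else {
      el <- els[[i]]
      for (cnt in el$min:el$max) {
        if (pos + cnt - 1L > L) break
        ok <- cnt == 0L ||
          all(vapply(chars[pos:(pos + cnt - 1L)][seq_len(cnt)],
                     function(ch) element_matches(el, ch), logical(1)))
        if (!ok) next
        out <- c(out, match_ends(i + 1L, pos + cnt))
      }
      out <- sort(unique(out))
    }
    memo[[key]] <- out
    out
  }

  starts <- if (model$n_anchor) 1L else seq_len(L)
  locs <- list()
  for (s in starts) {
    ends <- match_ends(1L, s)
    if (model$c_anchor) ends <- ends[ends == L + 1L]
    ends <- ends[ends > s]  # require a nonempty window
    if (length(ends) == 0L) next
    locs[[length(locs) + 1L]] <- sig_location(s, min(ends) - 1L)
  }
  locs
}
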