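# Signature library release bundle: a directory holding
#   release.yml       name + version of the release
#   signatures.tsv    accession, name, model_kind, clan, threshold
#   patterns.tsv      accession, pattern          (pattern models)
#   profiles.tsv      accession, position, A..Y   (profile score matrices)
# The fixture generator emits exactly this layout.

#' Write a signature library release bundle
#'
#' @param lib List with `name`, `version` and `signatures` (list of
#'   [sig_signature()]).
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_signature_library <- function(lib, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(name = lib$name, version = lib$version),
                   file.path(dir, "release.yml"))
  sigs <- lib$signatures
  meta <- data.frame(
    accession = vapply(sigs, function(s) s$accession, character(1)),
    name = vapply(sigs, function(s) s$name, character(1)),
    model_kind = vapply(sigs, function(s) s$model_kind, character(1)),
    clan = vapply(sigs, function(s) ifelse(is.na(s$clan), "-", s$clan),
                  character(1)),
    threshold = vapply(sigs, function(s) {
      if (s$model_kind == "profile") s$model_payload$threshold else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  meta <- meta[order(meta$accession), , drop = FALSE]
  utils::write.table(meta, file.path(dir, "signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  pats <- Filter(function(s) s$model_kind == "pattern", sigs)
  pat_df <- data.frame(
    accession = vapply(pats, function(s) s$accession, character(1)),
    pattern = vapply(pats, function(s) {
      m <- s$model_payload
      if (inherits(m, "pattern_model")) m$source else m
    }, character(1)),
    stringsAsFactors = FALSE)
  pat_df <- pat_df[order(pat_df$accession), , drop = FALSE]
  utils::write.table(pat_df, file.path(dir, "patterns.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  profs <- Filter(function(s) s$model_kind == "profile", sigs)
  prof_rows <- lapply(profs, function(s) {
    m <- s$model_payload$matrix
    cbind(data.frame(accession = s$accession,
                     position = seq_len(nrow(m)),
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  prof_df <- if (length(prof_rows) > 0L) do.call(rbind, prof_rows) else {
    cbind(data.frame(accession = character(), position = integer()),
          stats::setNames(as.data.frame(matrix(numeric(), ncol = 20L)),
                          PROFILE_RESIDUES))
  }
  prof_df <- prof_df[order(prof_df$accession, prof_df$position), ,
                     drop = FALSE]
  utils::write.table(prof_df, file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a signature library release bundle
#'
#' @param dir Bundle directory written by [write_signature_library()].
#' @return List with `name`, `version`, `signatures` (named by accession).
#' @export
read_signature_library <- function(dir) {
  rel <- yaml::read_yaml(file.path(dir, "release.yml"))
  meta <- utils::read.table(file.path(dir, "signatures.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            na.strings = character(),
                            colClasses = "character")
  pats <- utils::read.table(file.path(dir, "patterns.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            na.strings = character(),
                            colClasses = "character")
  profs <- utils::read.table(file.path(dir, "profiles.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             na.strings = character())
  sigs <- list()
  for (i in seq_len(nrow(meta))) {
    acc <- meta$accession[i]
    clan <- if (meta$clan[i] == "-") NA_character_ else meta$clan[i]
    if (meta$model_kind[i] == "pattern") {
      pat <- pats$pattern[pats$accession == acc]
      stopifnot(length(pat) == 1L)
      payload <- parse_prosite(pat)
    } else {
      rows <- profs[profs$accession == acc, , drop = FALSE]
      rows <- rows[order(rows$position), , drop = FALSE]
      m <- as.matrix(rows[, PROFILE_RESIDUES, drop = FALSE])
      rownames(m) <- NULL
      payload <- profile_model(m, as.numeric(meta$threshold[i]))
    }
    sigs[[acc]] <- sig_signature(acc, meta$name[i], rel$name, rel$version,
                                 meta$model_kind[i], payload, clan)
  }
  list(name = rel$name, version = rel$version, signatures = sigs)
}
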