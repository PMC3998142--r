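# End-to-end pipeline: FASTA in -> (ORF translation) -> deduplication ->
# match lookup -> planned jobs on the engine -> overlap resolution ->
# entry/GO/pathway annotation -> TSV/XML/GFF3/JSON out.
#
# Per analysis (one signature library) the job is:
#   write_fasta (chunkable) -> scan (chunkable) -> postprocess (chunkable)
#   -> persist (fan-in). Intermediate artifacts pass by path under a
# run-scoped work directory (shared-filesystem assumption); every step
# writes to an instance-scoped temp path and renames atomically, making
# re-execution idempotent.

atomic_write_rds <- function(obj, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  saveRDS(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Step functions -------------------------------------------------------------

step_write_fasta <- function(context, inst) {
  dir.create(file.path(context$workdir, "fasta"), showWarnings = FALSE,
             recursive = TRUE)
  out <- file.path(context$workdir, "fasta",
                   sprintf("%s_%03d.fasta", inst$job, inst$chunk_index))
  tmp <- paste0(out, ".tmp", Sys.getpid())
  write_fasta(context$proteins[inst$md5_list], tmp)
  file.rename(tmp, out)
}

step_scan <- function(context, inst) {
  fasta <- file.path(context$workdir, "fasta",
                     sprintf("%s_%03d.fasta", inst$job, inst$chunk_index))
  chunk_proteins <- read_fasta(fasta, "protein")
  # analysis is keyed by checksum; re-key ids back to canonical md5 ids
  lib <- context$libraries[[inst$job]]
  raw <- context$analyzer$scan(chunk_proteins, lib$signatures)
  dir.create(file.path(context$workdir, "raw"), showWarnings = FALSE,
             recursive = TRUE)
  atomic_write_rds(raw, file.path(
    context$workdir, "raw",
    sprintf("%s_%03d.rds", inst$job, inst$chunk_index)))
}

step_postprocess <- function(context, inst) {
  raw <- readRDS(file.path(context$workdir, "raw",
                           sprintf("%s_%03d.rds", inst$job,
                                   inst$chunk_index)))
  lib <- context$libraries[[inst$job]]
  post <- context$analyzer$postprocess(raw, lib$signatures)
  dir.create(file.path(context$workdir, "post"), showWarnings = FALSE,
             recursive = TRUE)
  atomic_write_rds(post, file.path(
    context$workdir, "post",
    sprintf("%s_%03d.rds", inst$job, inst$chunk_index)))
}

step_persist <- function(context, inst) {
  files <- sort(list.files(file.path(context$workdir, "post"),
                           pattern = sprintf("^%s_\\d+\\.rds$", inst$job),
                           full.names = TRUE))
  all_matches <- do.call(c, c(list(list()), lapply(files, readRDS)))
  atomic_write_rds(all_matches,
                   file.path(context$workdir,
                             sprintf("matches_%s.rds", inst$job)))
}

#' Build the standard per-library analysis job
#'
#' @param library_name Signature library (job) name.
#' @return A [job_def()] with the write-fasta, scan, post-process and
#'   fan-in persist stages.
#' @export
analysis_job <- function(library_name) {
  job_def(library_name, list(
    step_def("write_fasta", "write_fasta", chunkable = TRUE,
             fn = step_write_fasta),
    step_def("scan", "run_analyzer_scan", depends_on = "write_fasta",
             chunkable = TRUE, fn = step_scan),
    step_def("postprocess", "run_postprocess", depends_on = "scan",
             chunkable = TRUE, fn = step_postprocess),
    step_def("persist", "persist_matches", depends_on = "postprocess",
             fn = step_persist)))
}

#' Run the full analysis pipeline
#'
#' @param config A configuration list as produced by [load_config()] /
#'   [default_config()]; see that help page for the keys.
#' @return List with `doc` (the [result_document()]), `report` (the
#'   engine's execution report, `NULL` if everything was served from the
#'   lookup store), `outputs` (named vector of written files), `n_hits`,
#'   `n_misses`.
#' @export
run_pipeline <- function(config) {
  config <- merge_config(config)
  seq_kind <- if (config$seq_type == "n") "nucleotide" else "protein"
  input_seqs <- read_fasta(config$input, seq_kind)

  nucleotides <- list(); orfs <- list()
  if (seq_kind == "nucleotide") {
    nucleotides <- input_seqs
    orfs <- do.call(c, c(list(list()),
                         lapply(nucleotides, find_orfs,
                                min_protein_length = config$min_orf_length)))
    proteins <- lapply(orfs, `[[`, "protein")
  } else {
    proteins <- input_seqs
  }

  # signature libraries ------------------------------------------------------
  lib_root <- file.path(config$data_dir, "libraries")
  available <- sort(list.dirs(lib_root, recursive = FALSE,
                              full.names = FALSE))
  selected <- if (is.null(config$analyses)) available else config$analyses
  unknown <- setdiff(selected, available)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown analysis '%s'; available analyses: %s",
                 unknown[1L], paste(available, collapse = ", ")),
         call. = FALSE)
  }
  libraries <- stats::setNames(
    lapply(selected, function(nm) {
      read_signature_library(file.path(lib_root, nm))
    }), selected)
  analyses <- data.frame(
    name = selected,
    version = vapply(libraries, `[[`, character(1), "version"),
    stringsAsFactors = FALSE)
  bundle <- read_integration_bundle(file.path(config$data_dir,
                                              "integration"))

  dedup <- deduplicate(proteins)

  # lookup -------------------------------------------------------------------
  store <- NULL
  if (!isTRUE(config$disable_precalc) && !is.null(config$lookup)) {
    store <- tryCatch({
      root_name <- xml2::xml_name(xml2::read_xml(config$lookup))
      if (root_name == "match-store") read_match_store(config$lookup)
      else load_store(config$lookup)
    }, error = function(e) {
      warning(sprintf("lookup store %s unusable (%s); recomputing all",
                      config$lookup, conditionMessage(e)))
      NULL
    })
  }
  part <- partition_by_store(dedup$unique, store, analyses)

  # analysis of misses over the engine ---------------------------------------
  report <- NULL
  computed <- list()
  if (length(part$misses) > 0L) {
    workdir <- tempfile("sigscan_run_")
    dir.create(workdir, recursive = TRUE)
    on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
    miss_md5 <- vapply(part$misses, `[[`, character(1), "md5")
    context <- list(
      workdir = workdir,
      proteins = stats::setNames(part$misses, miss_md5),
      libraries = libraries,
      analyzer = config$analyzer %||% builtin_analyzer())
    jobs <- lapply(selected, analysis_job)
    instances <- plan_instances(jobs, miss_md5, config$chunk_size)
    policy <- config$policy %||% worker_policy(
      max_direct_workers = config$max_direct_workers,
      retry_limit = config$retry_limit)
    report <- run_master(instances, policy, mode = config$mode,
                         context = context,
                         max_workers = config$max_workers)
    if (!report$success) {
      stop(sprintf("run aborted: instance %s failed after %d attempts: %s",
                   report$aborted$instance, policy$retry_limit,
                   report$aborted$diagnostics), call. = FALSE)
    }
    computed <- do.call(c, c(list(list()), lapply(selected, function(nm) {
      readRDS(file.path(workdir, sprintf("matches_%s.rds", nm)))
    })))
  }

  all_matches <- c(do.call(c, c(list(list()), unname(part$hits))), computed)
  filtered <- Filter(function(m) m$status == "filtered_in", all_matches)
  annotated <- annotate(filtered, bundle)
  doc <- document_from_results(annotated, dedup, analyses,
                               do.call(c, lapply(libraries, `[[`,
                                                 "signatures")),
                               nucleotides = nucleotides, orfs = orfs,
                               date = config$date)

  outputs <- character()
  for (fmt in tolower(config$formats)) {
    out <- paste0(config$output_base, ".", fmt)
    switch(fmt,
           tsv = write_result_tsv(doc, out),
           xml = write_result_xml(doc, out),
           gff3 = write_result_gff3(doc, out),
           json = write_result_json(doc, out),
           stop(sprintf("unknown output format '%s'", fmt), call. = FALSE))
    outputs[fmt] <- out
  }
  list(doc = doc, report = report, outputs = outputs,
       n_hits = length(part$hits), n_misses = length(part$misses))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
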