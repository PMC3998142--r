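# Position-specific scoring profiles: an L x 20 score matrix plus a
# threshold on the summed window score. A stand-in for profile/HMM model
# classes that keeps the framework exercisable without external binaries.

PROFILE_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a profile model
#'
#' @param matrix Numeric matrix, one row per model position, 20 columns
#'   named by the standard amino acids. Residues outside the 20 (ambiguity
#'   codes) score 0 at every position.
#' @param threshold Minimum summed window score for a hit.
#' @return A `profile_model` object.
#' @export
profile_model <- function(matrix, threshold) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 20L, nrow(matrix) >= 1L,
            all(is.finite(matrix)), is.finite(threshold))
  if (is.null(colnames(matrix)) ||
      !identical(sort(colnames(matrix)), sort(PROFILE_RESIDUES))) {
    stop("profile matrix needs the 20 standard residues as column names",
         call. = FALSE)
  }
  matrix <- matrix[, PROFILE_RESIDUES, drop = FALSE]
  structure(list(matrix = matrix, threshold = as.numeric(threshold)),
            class = "profile_model")
}

#' Scan a protein with a profile model
#'
#' Slides the profile over the protein and reports every window whose
#' summed per-position score meets the threshold, with its score.
#' Overlapping and non-maximal windows are all retained at this raw stage;
#' filtering is post-processing's job. A protein shorter than the model
#' yields an empty result.
#'
#' @param protein A protein sequence object.
#' @param model A [profile_model()].
#' @return List of [sig_location()] objects carrying window scores.
#' @export
scan_profile <- function(protein, model) {
  stopifnot(inherits(model, "profile_model"))
  chars <- strsplit(protein$residues, "")[[1]]
  L_model <- nrow(model$matrix)
  L <- length(chars)
  if (L < L_model) return(list())
  col_idx <- match(chars, PROFILE_RESIDUES)  # NA for ambiguity codes -> 0
  locs <- list()
  for (s in seq_len(L - L_model + 1L)) {
    idx <- col_idx[s:(s + L_model - 1L)]
    sc <- sum(model$matrix[cbind(which(!is.na(idx)), idx[!is.na(idx)])])
    if (sc >= model$threshold) {
      locs[[length(locs) + 1L]] <- sig_location(s, s + L_model - 1L,
                                                score = sc)
    }
  }
  locs
}
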