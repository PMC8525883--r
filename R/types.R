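# Domain types: connectome matrices, subject records, outcome labels.

#' Construct a validated connectome adjacency matrix
#'
#' A connectome is a square symmetric adjacency matrix over a brain
#' parcellation. Functional connectomes hold Pearson correlations of ROI
#' BOLD time series (entries in `[-1, 1]`, unit diagonal; 223 nodes in the
#' neonatal functional parcellation). Structural connectomes hold mean
#' fractional anisotropy along tracts (entries in `[0, 1]`, zero diagonal;
#' 90 nodes in the anatomical parcellation).
#'
#' @param values Square numeric matrix.
#' @param kind `"functional"` or `"structural"`.
#' @param expected_n Expected node count; defaults to 223 (functional) or
#'   90 (structural). Override for reduced-size simulated cohorts.
#' @return A `connectome_matrix` object (matrix with `kind` attribute).
#' @export
connectome_matrix <- function(values, kind = c("functional", "structural"),
                              expected_n = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(expected_n)) {
    expected_n <- if (kind == "functional") 223L else 90L
  }
  if (nrow(values) != ncol(values)) {
    stop("connectome matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  if (nrow(values) != expected_n) {
    stop(sprintf("%s connectome must be %dx%d, observed n = %d",
                 kind, expected_n, expected_n, nrow(values)))
  }
  if (any(!is.finite(values))) stop("connectome matrix contains non-finite entries")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-6) {
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance 1e-6", asym))
  }
  if (asym > 0) values <- (values + t(values)) / 2
  if (kind == "functional") {
    bad <- which(values < -1 - 1e-9 | values > 1 + 1e-9, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("functional entries outside [-1,1] at cells: ",
           paste(utils::head(apply(bad, 1, paste, collapse = ","), 5), collapse = "; "))
    }
    if (max(abs(diag(values) - 1)) > 1e-6) {
      stop("functional connectome must have unit diagonal")
    }
    diag(values) <- 1
    values <- pmin(pmax(values, -1), 1)
  } else {
    bad <- which(values < -1e-9 | values > 1 + 1e-9, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("structural (FA) entries outside [0,1] at cells: ",
           paste(utils::head(apply(bad, 1, paste, collapse = ","), 5), collapse = "; "))
    }
    if (max(abs(diag(values))) > 1e-6) {
      stop("structural connectome must have zero diagonal")
    }
    diag(values) <- 0
    values <- pmin(pmax(values, 0), 1)
  }
  structure(values, kind = kind, class = c("connectome_matrix", "matrix", "array"))
}

#' @export
print.connectome_matrix <- function(x, ...) {
  cat(sprintf("<connectome_matrix> kind=%s n=%d range=[%.3f, %.3f]\n",
              attr(x, "kind"), nrow(x), min(x), max(x)))
  invisible(x)
}

#' Construct a subject record
#'
#' Bundles one subject's four modality inputs (functional connectome,
#' structural connectome, DWMA feature vector, clinical feature vector),
#' the optional Bayley-III outcome score and the acquisition batch label.
#' At least one modality must be present; a score, when present, must lie
#' on the Bayley-III scale `[40, 160]`.
#'
#' @param subject_id Unique subject identifier.
#' @param functional,structural `connectome_matrix` objects or `NULL`.
#' @param dwma Numeric DWMA feature vector (length 11) or `NULL`.
#' @param clinical Numeric clinical feature vector (length 72) or `NULL`.
#' @param score Bayley-III scale score in `[40, 160]` or `NULL`.
#' @param batch Site/batch label or `NULL`.
#' @param dwma_length,clinical_length Expected vector lengths; override for
#'   reduced-size simulated cohorts.
#' @return A `subject_record` object.
#' @export
subject_record <- function(subject_id, functional = NULL, structural = NULL,
                           dwma = NULL, clinical = NULL, score = NULL,
                           batch = NULL, dwma_length = 11L, clinical_length = 72L) {
  if (is.null(functional) && is.null(structural) && is.null(dwma) && is.null(clinical)) {
    stop("subject ", subject_id, ": at least one modality must be present")
  }
  if (!is.null(dwma)) {
    if (length(dwma) != dwma_length) {
      stop("subject ", subject_id, ": DWMA vector length ", length(dwma),
           " != ", dwma_length)
    }
    if (any(!is.finite(dwma))) stop("subject ", subject_id, ": non-finite DWMA entries")
  }
  if (!is.null(clinical)) {
    if (length(clinical) != clinical_length) {
      stop("subject ", subject_id, ": clinical vector length ", length(clinical),
           " != ", clinical_length)
    }
    if (any(!is.finite(clinical))) stop("subject ", subject_id, ": non-finite clinical entries")
  }
  if (!is.null(score)) {
    if (!is.finite(score) || score < 40 || score > 160) {
      stop("subject ", subject_id, ": score ", score, " outside Bayley-III range [40,160]")
    }
  }
  structure(list(subject_id = as.character(subject_id), functional = functional,
                 structural = structural, dwma = dwma, clinical = clinical,
                 score = score, batch = batch, synthetic = FALSE,
                 provenance = NULL),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  mods <- c("functional", "structural", "dwma", "clinical")
  have <- mods[!vapply(x[mods], is.null, logical(1))]
  cat(sprintf("<subject_record> %s%s | modalities: %s | score: %s | batch: %s\n",
              x$subject_id, if (isTRUE(x$synthetic)) " (synthetic)" else "",
              paste(have, collapse = ","),
              if (is.null(x$score)) "NA" else format(x$score),
              if (is.null(x$batch)) "NA" else as.character(x$batch)))
  invisible(x)
}

#' Dichotomize a Bayley-III score into the risk classes
#'
#' High risk is a score of 90 or below; low risk is above 90.
#'
#' @param score Numeric vector of Bayley-III scores.
#' @return Factor with levels `c("high", "low")`.
#' @export
risk_class <- function(score) {
  factor(ifelse(score <= 90, "high", "low"), levels = c("high", "low"))
}
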