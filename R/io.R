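# On-disk artifacts: delimited connectome matrices, DWMA vectors, cohort
# manifests with clinical columns, NIfTI volumes. All tabular artifacts are
# plain CSV/TSV so they stay inspectable.

#' Read a connectome adjacency matrix from a delimited file
#'
#' The file must parse as a square numeric table (no header, no row names).
#' Mild numeric asymmetry (at most 1e-6) is repaired by averaging with the
#' transpose; larger asymmetry is rejected.
#'
#' @param path CSV/TSV file holding an n x n numeric matrix.
#' @param kind `"functional"` or `"structural"`.
#' @param expected_n Node-count override for reduced-size matrices.
#' @return A [connectome_matrix()].
#' @export
read_connectome <- function(path, kind = c("functional", "structural"),
                            expected_n = NULL) {
  kind <- match.arg(kind)
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("file ", path, " does not parse as a numeric matrix")
  connectome_matrix(m, kind = kind, expected_n = expected_n)
}

#' Write a connectome matrix as CSV
#'
#' Values are written at full double precision so a write/read round trip
#' reproduces the matrix to better than 1e-12.
#' @param m Matrix to write.
#' @param path Output file.
#' @export
write_connectome <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a DWMA feature vector (one-column or one-row CSV)
#' @param path CSV file with 11 numeric values (optionally named).
#' @param expected_length Expected vector length (11).
#' @return Named numeric vector.
#' @export
read_dwma_vector <- function(path, expected_length = 11L) {
  d <- data.table::fread(path, header = TRUE)
  v <- as.numeric(as.matrix(d))
  if (length(v) != expected_length) {
    stop("DWMA vector in ", path, " has length ", length(v), ", expected ",
         expected_length)
  }
  stats::setNames(v, colnames(d))
}

#' Declare a clinical feature schema
#'
#' The perinatal clinical vector has a fixed length (72 by default). The
#' schema declares, per feature, whether it is continuous (z-scored against
#' the cohort) or categorical (encoded as numeric level codes starting at 0;
#' binary features therefore become 0/1 indicators). The encoded vector
#' length is pinned to the declared total and checked.
#'
#' @param names Character vector of feature (column) names.
#' @param types Character vector, each `"continuous"` or `"categorical"`.
#' @return A `clinical_schema` data.frame.
#' @export
clinical_schema <- function(names, types) {
  stopifnot(length(names) == length(types))
  types <- match.arg(types, c("continuous", "categorical"), several.ok = TRUE)
  structure(data.frame(name = names, type = types, stringsAsFactors = FALSE),
            class = c("clinical_schema", "data.frame"))
}

#' Default 72-feature clinical schema for simulated cohorts
#'
#' Mirrors the five perinatal domains (maternal demographics, pregnancy
#' complications, labor and delivery, neonatal information at birth, medical
#' history) as 40 continuous and 32 categorical features.
#' @return A [clinical_schema()].
#' @export
default_clinical_schema <- function() {
  n_cont <- 40L; n_cat <- 32L
  clinical_schema(
    names = c(sprintf("clin_cont_%02d", seq_len(n_cont)),
              sprintf("clin_cat_%02d", seq_len(n_cat))),
    types = c(rep("continuous", n_cont), rep("categorical", n_cat))
  )
}

# Encode the clinical columns of a manifest-like data.frame to an
# n x length(schema) numeric matrix. Missing values are imputed (median for
# continuous, mode for categorical) before z-scoring; every imputation is
# logged.
encode_clinical <- function(df, schema) {
  missing_cols <- setdiff(schema$name, colnames(df))
  if (length(missing_cols)) {
    stop("unknown/missing clinical columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow(df), nrow(schema),
                dimnames = list(NULL, schema$name))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- df[[nm]]
    if (all(is.na(v))) stop("clinical feature '", nm, "' is missing for every subject")
    if (schema$type[i] == "continuous") {
      v <- as.numeric(v)
      if (anyNA(v)) {
        imp <- stats::median(v, na.rm = TRUE)
        np_log("imputing %d missing value(s) of continuous feature '%s' with median %g",
               sum(is.na(v)), nm, imp)
        v[is.na(v)] <- imp
      }
      s <- stats::sd(v)
      out[, i] <- if (s > 0) (v - mean(v)) / s else 0
    } else {
      v <- as.character(v)
      if (anyNA(v)) {
        tab <- table(v)
        imp <- names(tab)[which.max(tab)]
        np_log("imputing %d missing value(s) of categorical feature '%s' with mode '%s'",
               sum(is.na(v)), nm, imp)
        v[is.na(v)] <- imp
      }
      out[, i] <- as.numeric(factor(v, levels = sort(unique(v)))) - 1
    }
  }
  if (any(!is.finite(out))) stop("clinical encoding produced non-finite entries")
  out
}

#' Read and validate a cohort manifest
#'
#' A manifest is a CSV with one row per subject: a `subject_id` column,
#' optional per-modality file-path columns (`functional`, `structural`,
#' `dwma`), optional `score` and `batch` columns, and the clinical feature
#' columns named by the schema.
#'
#' @param path Manifest CSV.
#' @return data.frame with uniqueness and file-existence validated.
#' @export
read_manifest <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"subject_id" %in% colnames(df)) stop("manifest lacks a subject_id column")
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  for (col in intersect(c("functional", "structural", "dwma"), colnames(df))) {
    p <- df[[col]]
    p <- p[!is.na(p) & nzchar(p)]
    miss <- p[!file.exists(p)]
    if (length(miss)) {
      stop("manifest references missing ", col, " file(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    }
  }
  df
}

#' Load a cohort of subject records from a manifest
#'
#' Reads each referenced modality file, encodes the clinical columns against
#' the schema (z-scoring continuous features against this cohort, so the
#' encoding is deterministic given schema + cohort), and attaches scores and
#' batch labels.
#'
#' @param manifest Path to a manifest CSV or a validated manifest data.frame.
#' @param schema A [clinical_schema()], or `NULL` for no clinical channel.
#' @param functional_n,structural_n Node-count overrides for reduced-size data.
#' @param dwma_length Expected DWMA vector length.
#' @return List of [subject_record()]s.
#' @export
load_cohort <- function(manifest, schema = NULL, functional_n = NULL,
                        structural_n = NULL, dwma_length = 11L) {
  df <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in manifest")
  clin <- if (!is.null(schema)) encode_clinical(df, schema) else NULL
  n <- nrow(df)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    fc <- sc <- dw <- NULL
    if ("functional" %in% colnames(df) && nzchar_na(df$functional[i])) {
      fc <- read_connectome(df$functional[i], "functional", expected_n = functional_n)
    }
    if ("structural" %in% colnames(df) && nzchar_na(df$structural[i])) {
      sc <- read_connectome(df$structural[i], "structural", expected_n = structural_n)
    }
    if ("dwma" %in% colnames(df) && nzchar_na(df$dwma[i])) {
      dw <- read_dwma_vector(df$dwma[i], expected_length = dwma_length)
    }
    score <- if ("score" %in% colnames(df) && is.finite(suppressWarnings(as.numeric(df$score[i]))))
      as.numeric(df$score[i]) else NULL
    batch <- if ("batch" %in% colnames(df) && nzchar_na(df$batch[i]))
      as.character(df$batch[i]) else NULL
    records[[i]] <- subject_record(
      df$subject_id[i], functional = fc, structural = sc, dwma = dw,
      clinical = if (!is.null(clin)) clin[i, ] else NULL,
      score = score, batch = batch,
      dwma_length = dwma_length,
      clinical_length = if (!is.null(schema)) nrow(schema) else 72L)
  }
  records
}

nzchar_na <- function(x) !is.na(x) & nzchar(as.character(x))

#' Read a NIfTI volume as a numeric array
#'
#' Thin wrapper over RNifti that also returns the voxel volume in cubic
#' millimetres (product of the spatial pixdims).
#' @param path NIfTI file.
#' @return List with `data` (array) and `voxel_volume` (mm^3).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  list(data = as.array(img), voxel_volume = prod(abs(pd)))
}
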