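# Readers and writers for the pipeline's file formats: NRRD / NIfTI
# volumes, GMT gene-set collections, and the one-row-per-patient cohort
# spreadsheet.

#' Read a GMT gene-set collection
#'
#' Tab-delimited, one set per line: set id, description, then gene ids.
#'
#' @param path File path.
#' @return Named list of gene id vectors, with the descriptions in the
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  stop_if_not(!any(bad), "malformed GMT: every line needs id, description, genes")
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a volume (NRRD or NIfTI)
#'
#' Dispatches on the file extension: `.nrrd` uses the package's NRRD
#' reader (ascii/text encodings), `.nii`/`.nii.gz` uses RNifti with
#' spacing taken from the header. `as_mask = TRUE` binarizes at 0.5.
#'
#' @param path File path.
#' @param as_mask Return a logical array instead of intensities.
#' @return List with `data` (3D array) and `spacing` (mm).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  out <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    list(data = array(as.numeric(img), dim = dim(img)),
         spacing = RNifti::pixdim(img)[1:3])
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  if (as_mask) out$data <- out$data >= 0.5
  out
}

#' Read an NRRD volume (text encodings)
#'
#' Minimal NRRD reader for 3D volumes with `ascii`/`text`/`txt` encoding,
#' as written by [write_nrrd()]. Spacing is taken from `spacings` or from
#' diagonal `space directions`.
#'
#' @param path File path.
#' @return List with `data` and `spacing`.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stop_if_not(grepl("^NRRD", lines[1]), "not an NRRD file")
  blank <- which(lines == "")[1]
  stop_if_not(is.finite(blank), "NRRD header must end with a blank line")
  header <- lines[2:(blank - 1)]
  header <- header[!grepl("^#", header)]
  kv <- strsplit(header, ": ", fixed = TRUE)
  keys <- tolower(vapply(kv, `[[`, character(1), 1))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1))
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  stop_if_not(as.integer(get("dimension")) == 3, "only 3D NRRD supported")
  sizes <- as.integer(strsplit(get("sizes"), " ")[[1]])
  enc <- get("encoding")
  stop_if_not(enc %in% c("ascii", "text", "txt"),
              "only text-encoded NRRD supported")
  spacing <- if (!is.null(get("spacings"))) {
    as.numeric(strsplit(get("spacings"), " ")[[1]])
  } else if (!is.null(get("space directions"))) {
    dirs <- gsub("[()]", "", strsplit(get("space directions"), " ")[[1]])
    m <- vapply(strsplit(dirs, ","), as.numeric, numeric(3))
    sqrt(colSums(m^2))
  } else {
    c(1, 1, 1)
  }
  vals_num <- as.numeric(scan(text = paste(lines[-(1:blank)],
                                           collapse = " "),
                              what = "character", quiet = TRUE))
  stop_if_not(length(vals_num) == prod(sizes),
              "NRRD data length does not match sizes")
  list(data = array(vals_num, dim = sizes), spacing = spacing)
}

#' Write an NRRD volume (text encoding)
#'
#' @param data Numeric or logical 3D array.
#' @param path Output path.
#' @param spacing Voxel spacing in mm.
#' @export
write_nrrd <- function(data, path, spacing = c(1, 1, 1)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               "type: double",
               "dimension: 3",
               paste("sizes:", paste(dim(data), collapse = " ")),
               paste("spacings:", paste(spacing, collapse = " ")),
               "encoding: ascii",
               ""), con)
  writeLines(paste(as.numeric(data), collapse = " "), con)
}

#' Write a cohort bundle as a one-row-per-patient spreadsheet
#'
#' Layout mirrors the cohort supplements the pipeline consumes: one row
#' per patient with radiomic columns prefixed `radiomic_`, expression
#' columns named by gene symbol, and clinical columns `os_time`,
#' `os_event`, `stage`, `histology`. Gene sets are written next to the
#' spreadsheet as `<stem>_sets.gmt`.
#'
#' @param bundle A [cohort_bundle()].
#' @param path Output CSV path.
#' @export
write_cohort <- function(bundle, path) {
  df <- data.frame(patient_id = bundle$patients,
                   stringsAsFactors = FALSE)
  feats <- as.data.frame(bundle$features)
  names(feats) <- paste0("radiomic_", colnames(bundle$features))
  expr <- as.data.frame(t(bundle$expr))
  cl <- bundle$clinical[, c("os_time", "os_event", "stage", "histology")]
  out <- cbind(df, feats, expr, cl)
  utils::write.csv(out, path, row.names = FALSE)
  write_gmt(bundle$gene_sets, sub("\\.csv$", "_sets.gmt", path))
  invisible(path)
}

#' Load a cohort
#'
#' `layout = "bundle_spreadsheet"` reads the CSV written by
#' [write_cohort()] (gene sets from the sibling `_sets.gmt` file);
#' `layout = "split_files"` expects a directory with `features.csv`,
#' `expression.csv` (genes x patients), `clinical.csv`, and `sets.gmt`.
#' Patients missing from any block are dropped with a logged count;
#' duplicated patient ids are an error.
#'
#' @param path CSV path or directory, per `layout`.
#' @param layout One of `"bundle_spreadsheet"`, `"split_files"`.
#' @param cohort_id Identifier for the loaded cohort.
#' @return A [cohort_bundle()].
#' @export
load_cohort <- function(path, layout = c("bundle_spreadsheet",
                                         "split_files"),
                        cohort_id = basename(path)) {
  layout <- match.arg(layout)
  if (layout == "bundle_spreadsheet") {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    stop_if_not("patient_id" %in% names(df), "missing patient_id column")
    if (anyDuplicated(df$patient_id)) {
      stop("duplicated patient ids in ", path, call. = FALSE)
    }
    rad_cols <- grep("^radiomic_", names(df), value = TRUE)
    clin_cols <- c("os_time", "os_event", "stage", "histology")
    stop_if_not(all(clin_cols %in% names(df)),
                "missing clinical columns in spreadsheet")
    gene_cols <- setdiff(names(df), c("patient_id", rad_cols, clin_cols))
    num_block <- df[, c(rad_cols, gene_cols)]
    bad <- !vapply(num_block, is.numeric, logical(1))
    if (any(bad)) {
      stop("malformed numeric cell(s) in column(s): ",
           paste(names(num_block)[bad], collapse = ", "), call. = FALSE)
    }
    features <- as.matrix(df[, rad_cols, drop = FALSE])
    colnames(features) <- sub("^radiomic_", "", rad_cols)
    rownames(features) <- df$patient_id
    expr <- t(as.matrix(df[, gene_cols, drop = FALSE]))
    colnames(expr) <- df$patient_id
    sets <- read_gmt(sub("\\.csv$", "_sets.gmt", path))
    clinical <- cbind(data.frame(patient_id = df$patient_id,
                                 stringsAsFactors = FALSE),
                      df[, clin_cols])
    cohort_bundle(features, expr, sets, clinical, cohort_id = cohort_id)
  } else {
    feats <- utils::read.csv(file.path(path, "features.csv"),
                             row.names = 1, check.names = FALSE)
    expr <- as.matrix(utils::read.csv(file.path(path, "expression.csv"),
                                      row.names = 1, check.names = FALSE))
    clinical <- utils::read.csv(file.path(path, "clinical.csv"),
                                stringsAsFactors = FALSE)
    sets <- read_gmt(file.path(path, "sets.gmt"))
    cohort_bundle(as.matrix(feats), expr, sets, clinical,
                  cohort_id = cohort_id)
  }
}
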