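#' Construct a view matrix
#'
#' A "view" is one modality's cells-by-features matrix of already-normalized
#' values (log-normalized expression, accessibility or protein abundance),
#' together with unique cell barcodes and feature names. The package consumes
#' normalized values as-is; quality control, normalization and feature
#' selection are the caller's job.
#'
#' @param values Numeric matrix, cells in rows, features in columns.
#' @param cell_ids Character vector of unique cell barcodes (default
#'   `cell_1..cell_I`).
#' @param feature_ids Character vector of unique feature names (default
#'   `feat_1..feat_J`).
#' @param view_name Single string naming the modality.
#' @return An object of class `"view_matrix"`.
#' @export
view_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                        view_name = "view") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feat_", seq_len(ncol(values)))
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length does not match nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match ncol(values)")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (any(!is.finite(values)))
    stop("view '", view_name, "' contains non-finite values")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 feature_ids = as.character(feature_ids),
                 view_name = as.character(view_name)[1]),
            class = "view_matrix")
}

#' @export
print.view_matrix <- function(x, ...) {
  cat("<view_matrix> '", x$view_name, "': ", nrow(x$values), " cells x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' @export
dim.view_matrix <- function(x) dim(x$values)

#' Read a view from disk
#'
#' Supports two on-disk layouts:
#' \describe{
#'   \item{`mtx_dir`}{a directory in the CellRanger dialect: `matrix.mtx`
#'     (MatrixMarket, optionally `.gz`) plus `features.tsv` (or `genes.tsv`)
#'     and `barcodes.tsv` sidecars. CellRanger stores features x cells; the
#'     orientation is inferred by matching sidecar lengths to the matrix
#'     dimensions and the result is always returned cells x features.}
#'   \item{`csv`}{a dense comma-separated file, one header row of feature
#'     names, first column of cell ids.}
#' }
#' Values are passed through unchanged.
#'
#' @param path Directory (for `mtx_dir`) or file (for `csv`).
#' @param format One of `"auto"`, `"mtx_dir"`, `"csv"`. `"auto"` picks
#'   `mtx_dir` for directories.
#' @param view_name Modality name; defaults to the file/directory base name.
#' @return A [view_matrix()].
#' @export
read_view <- function(path, format = c("auto", "mtx_dir", "csv"),
                      view_name = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "mtx_dir" else "csv"
  if (is.null(view_name))
    view_name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "mtx_dir") .read_view_mtx(path, view_name)
  else .read_view_csv(path, view_name)
}

.find_sidecar <- function(dir, stems) {
  for (stem in stems)
    for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  stop("missing sidecar file in '", dir, "': looked for ",
       paste(stems, collapse = ", "), " (optionally .gz)")
}

.read_view_mtx <- function(dir, view_name) {
  if (!dir.exists(dir)) stop("no such directory: '", dir, "'")
  mtx <- .find_sidecar(dir, c("matrix.mtx"))
  feat_file <- .find_sidecar(dir, c("features.tsv", "genes.tsv"))
  bc_file <- .find_sidecar(dir, c("barcodes.tsv"))
  M <- tryCatch(as.matrix(Matrix::readMM(mtx)), error = function(e)
    stop("failed to parse MatrixMarket file '", mtx, "': ",
         conditionMessage(e)))
  feats <- utils::read.table(feat_file, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  bcs <- utils::read.table(bc_file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  dm <- dim(M)
  if (dm[1] == length(feats) && dm[2] == length(bcs)) {
    M <- t(M)                       # features x cells on disk (CellRanger)
  } else if (dm[1] == length(bcs) && dm[2] == length(feats)) {
    # already cells x features
  } else {
    stop("dimension mismatch in '", dir, "': matrix is ", dm[1], " x ", dm[2],
         " but features.tsv has ", length(feats), " rows and barcodes.tsv has ",
         length(bcs), " rows")
  }
  view_matrix(M, cell_ids = bcs, feature_ids = feats, view_name = view_name)
}

.read_view_csv <- function(file, view_name) {
  if (!file.exists(file)) stop("no such file: '", file, "'")
  df <- utils::read.csv(file, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("CSV '", file, "' needs a cell-id column plus ",
                         "at least one feature column")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop("non-numeric entries in CSV '", file, "', column '",
         names(df)[-1][bad], "'")
  }
  view_matrix(vals, cell_ids = ids, feature_ids = colnames(df)[-1],
              view_name = view_name)
}

#' Write a view to disk
#'
#' Inverse of [read_view()]: `csv` writes the dense layout, `mtx_dir` writes
#' `matrix.mtx` (features x cells, CellRanger orientation) with
#' `features.tsv`/`barcodes.tsv` sidecars.
#'
#' @param view A [view_matrix()].
#' @param path Output file (`csv`) or directory (`mtx_dir`).
#' @param format `"csv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_view <- function(view, path, format = c("csv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(cell_id = view$cell_ids, view$values,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    M <- Matrix::Matrix(t(view$values), sparse = TRUE)
    Matrix::writeMM(M, file.path(path, "matrix.mtx"))
    writeLines(view$feature_ids, file.path(path, "features.tsv"))
    writeLines(view$cell_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Triple-store representation of a view
#'
#' The model trains on the vectorized matrix: each retained entry becomes a
#' triple `(i, j, y_ij)` of cell index, feature index and value, in cell-major
#' order (`t = (i - 1) * J + j`), matching the row ordering of
#' [coreg_kernel_full()].
#'
#' @param view A [view_matrix()].
#' @param keep_zeros Keep entries equal to zero (default `TRUE`: the model is
#'   a dense factorization and zeros are observations).
#' @return An object of class `"triple_store"`: list with integer vectors
#'   `i`, `j`, numeric `y`, counts `I`, `J`, and `view_name`.
#' @export
build_triple_store <- function(view, keep_zeros = TRUE) {
  Y <- view$values
  I <- nrow(Y); J <- ncol(Y)
  # cell-major: iterate rows of Y
  i <- rep(seq_len(I), each = J)
  j <- rep(seq_len(J), times = I)
  y <- as.vector(t(Y))
  if (!keep_zeros) {
    keep <- y != 0
    i <- i[keep]; j <- j[keep]; y <- y[keep]
  }
  structure(list(i = i, j = j, y = y, I = I, J = J,
                 view_name = view$view_name),
            class = "triple_store")
}

#' @export
print.triple_store <- function(x, ...) {
  cat("<triple_store> '", x$view_name, "': ", length(x$y), " triples on a ",
      x$I, " x ", x$J, " grid\n", sep = "")
  invisible(x)
}

#' Reconstruct the dense matrix from a triple store
#'
#' Entries absent from the store are filled with `fill` (default 0), so the
#' round trip through [build_triple_store()] with `keep_zeros = TRUE` is
#' lossless.
#'
#' @param store A `triple_store`.
#' @param fill Value for absent entries.
#' @return An `I x J` numeric matrix.
#' @export
triples_to_matrix <- function(store, fill = 0) {
  Y <- matrix(fill, store$I, store$J)
  Y[cbind(store$i, store$j)] <- store$y
  Y
}

#' Restrict views to their common cells
#'
#' Multimodal integration needs the same cells in every view; this keeps only
#' barcodes present in all views, in the order of the first view.
#'
#' @param views List of two or more [view_matrix()] objects.
#' @return List of views sharing identical `cell_ids` in identical order.
#' @export
intersect_cells <- function(views) {
  if (length(views) < 2) stop("need at least two views to intersect")
  common <- views[[1]]$cell_ids
  for (v in views[-1]) common <- common[common %in% v$cell_ids]
  if (length(common) == 0) stop("no cells are shared across all views")
  lapply(views, function(v) {
    idx <- match(common, v$cell_ids)
    view_matrix(v$values[idx, , drop = FALSE], cell_ids = common,
                feature_ids = v$feature_ids, view_name = v$view_name)
  })
}

#' Read cell-type labels
#'
#' Tab-separated file with columns `cell_id` and `cell_type` (header
#' required). Labels are used only for evaluation and interpretation, never
#' for fitting.
#'
#' @param path TSV file path.
#' @return A data.frame with character columns `cell_id`, `cell_type`.
#' @export
read_cell_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% names(df)))
    stop("labels TSV must have columns 'cell_id' and 'cell_type'")
  df[c("cell_id", "cell_type")]
}

# Align a labels data.frame (or named character vector) to a vector of cell
# ids; errors on missing ids.
.align_labels <- function(labels, cell_ids) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$cell_type),
                           as.character(labels$cell_id))
  } else if (!is.null(names(labels))) {
    lab <- as.character(labels); names(lab) <- names(labels)
  } else {
    if (length(labels) != length(cell_ids))
      stop("unnamed label vector must match the number of cells")
    return(as.character(labels))
  }
  miss <- setdiff(cell_ids, names(lab))
  if (length(miss))
    stop("no label for cell id(s): ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  unname(lab[cell_ids])
}
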