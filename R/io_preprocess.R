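#' Read an expression dataset from ARFF or delimited text
#'
#' Reads a samples-by-genes expression table together with one categorical
#' label column. Numeric attributes become gene columns in file order; the
#' label column is encoded as a factor whose levels are the lexicographically
#' sorted class names (see [encode_labels()]). Missing-value markers (`?` in
#' ARFF; empty string, `NA` or `NaN` in delimited files) become `NA`, never
#' zero. Any other non-numeric token in a gene column is a parse error.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (default, from the file extension), `"arff"`, or
#'   `"delimited"` (CSV or TSV with a header row).
#' @param label Name (or integer position) of the label column.
#'   Defaults to `"label"`; for ARFF files a column named `class` is also
#'   recognised when `label` is absent.
#' @return A tibble with one row per sample: gene columns (double, possibly
#'   containing `NA`) followed by a factor column `label`. Attribute
#'   `meta` records the source path and format.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(g1 = c(1, 2), g2 = c(3, NA), label = c("a", "b")), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, format = c("auto", "arff", "delimited"),
                            label = "label") {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "arff") "arff" else "delimited"
  }
  raw <- if (format == "arff") {
    tryCatch(foreign::read.arff(path),
      error = function(e) stop("failed to parse ARFF file: ", conditionMessage(e),
        call. = FALSE
      )
    )
  } else {
    read_delimited_strict(path)
  }
  as_expr_dataset(raw, label = label, meta = list(source = path, format = format))
}

# Delimited reader that refuses silent coercion: every gene cell must be
# numeric or one of the recognised missing markers ("", "NA", "NaN", "?").
read_delimited_strict <- function(path) {
  delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab", "txt")) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  if (nrow(raw) == 0) stop("delimited file has no data rows: ", path, call. = FALSE)
  raw
}

#' Coerce a data frame to the expression-dataset layout
#'
#' Validates and normalises a data frame into the layout the rest of the
#' pipeline expects: all-double gene columns plus one factor `label` column
#' (moved last and renamed `label`). Character gene cells are converted with
#' strict missing-marker handling.
#'
#' @param data A data frame of samples by genes plus a label column.
#' @param label Name or integer position of the label column.
#' @param meta Optional named list of provenance notes, stored as the `meta`
#'   attribute.
#' @return A tibble of gene columns plus factor column `label`.
#' @export
as_expr_dataset <- function(data, label = "label", meta = list()) {
  data <- tibble::as_tibble(data)
  if (is.numeric(label)) {
    if (label < 1 || label > ncol(data)) {
      stop("label column index out of range: ", label, call. = FALSE)
    }
    label <- names(data)[label]
  }
  if (!label %in% names(data) && "class" %in% names(data)) label <- "class"
  if (!label %in% names(data)) {
    stop("label column '", label, "' not found; columns are: ",
      paste(utils::head(names(data), 10), collapse = ", "),
      call. = FALSE
    )
  }
  labs_raw <- as.character(data[[label]])
  labs_raw[labs_raw %in% c("", "?")] <- NA_character_
  if (anyNA(labs_raw)) stop("label column contains missing values", call. = FALSE)
  enc <- encode_labels(labs_raw)

  genes <- data[setdiff(names(data), label)]
  genes[] <- lapply(genes, parse_expression_column)
  if (ncol(genes) < 1) stop("no gene columns found", call. = FALSE)
  if (nrow(genes) < 2) stop("fewer than 2 samples", call. = FALSE)

  out <- genes
  out$label <- factor(enc$class_names[enc$codes + 1L], levels = enc$class_names)
  attr(out, "meta") <- meta
  out
}

parse_expression_column <- function(x) {
  if (is.numeric(x)) {
    return(as.double(x))
  }
  x <- as.character(x)
  x[x %in% c("", "NA", "NaN", "?")] <- NA_character_
  out <- suppressWarnings(as.double(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("non-numeric token in expression column: '", x[which(bad)[1]],
      "' (recognised missing markers: \"\", NA, NaN, ?)",
      call. = FALSE
    )
  }
  out
}

#' Encode class labels as dense integer codes
#'
#' Distinct labels are sorted lexicographically and assigned codes
#' `0..m-1` in that order, so the encoding is deterministic across runs and
#' platforms. Numeric labels are encoded by the sort order of their distinct
#' values.
#'
#' @param raw_labels Character (or coercible) vector of per-sample labels.
#' @return A list with `codes` (integer vector in `0..m-1`) and
#'   `class_names` (ordered character vector of length `m`).
#' @examples
#' encode_labels(c("AML", "ALL", "AML"))
#' @export
encode_labels <- function(raw_labels) {
  raw <- as.character(raw_labels)
  if (length(raw) == 0 || anyNA(raw)) {
    stop("labels must be non-empty and complete", call. = FALSE)
  }
  nms <- sort(unique(raw))
  if (length(nms) < 2) stop("need at least 2 distinct classes, got 1", call. = FALSE)
  list(codes = match(raw, nms) - 1L, class_names = nms)
}

#' Replace missing expression values by per-gene means
#'
#' Each `NA` entry is replaced by the mean of the observed entries of its
#' gene column. Observed entries are never altered, so the operation is
#' idempotent. The number of imputed cells is recorded in the `n_imputed`
#' attribute of the result.
#'
#' @param data An expression tibble (gene columns + `label`), as returned by
#'   [read_expression()] or [simulate_expression()].
#' @return The tibble with no missing gene entries.
#' @export
impute_mean <- function(data) {
  ed <- check_expr(data)
  n_imp <- 0L
  for (j in ed$gene_cols) {
    x <- data[[j]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) {
      stop("gene column '", j, "' is entirely missing; no mean exists", call. = FALSE)
    }
    x[miss] <- mean(x[!miss])
    data[[j]] <- x
    n_imp <- n_imp + sum(miss)
  }
  attr(data, "n_imputed") <- n_imp
  data
}

#' Z-score normalize each gene column
#'
#' Transforms every gene column to `(x - mu) / sigma`, with the mean and the
#' population standard deviation (divide by `n`) computed over all samples of
#' that column. Constant columns cannot be standardized; they are set to zero
#' and listed in the `constant_genes` attribute rather than dropped, so gene
#' indices stay stable across pipeline stages. Idempotent to within floating
#' point on already-normalized input.
#'
#' @inheritParams impute_mean
#' @return The tibble with per-gene mean 0 and population standard deviation
#'   1 (constant columns exempt and flagged via `attr(., "constant_genes")`).
#' @export
zscore_normalize <- function(data) {
  ed <- check_expr(data)
  x <- ed$x
  if (anyNA(x)) {
    stop("missing entries present; run impute_mean() before zscore_normalize()",
      call. = FALSE
    )
  }
  n <- nrow(x)
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2) # population sd
  const <- sigma <= .Machine$double.eps * 10 * pmax(1, abs(mu))
  z <- sweep(x, 2, mu, "-")
  z <- sweep(z, 2, ifelse(const, 1, sigma), "/")
  z[, const] <- 0
  for (k in seq_along(ed$gene_cols)) data[[ed$gene_cols[k]]] <- z[, k]
  attr(data, "constant_genes") <- ed$gene_cols[const]
  data
}

#' Full preprocessing chain
#'
#' Convenience wrapper: [impute_mean()] then [zscore_normalize()].
#'
#' @inheritParams impute_mean
#' @return Preprocessed tibble.
#' @export
preprocess_expression <- function(data) {
  zscore_normalize(impute_mean(data))
}

#' Write an expression dataset back to CSV
#'
#' Writes gene columns plus a `label` column, round-trippable through
#' [read_expression()].
#'
#' @inheritParams impute_mean
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  check_expr(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# Internal: validate the expression layout and expose matrix/label views.
# Returns list(x = numeric matrix, labels = factor, codes = 0-based integer,
# gene_cols = character).
check_expr <- function(data) {
  if (!is.data.frame(data)) stop("expected a data frame of expression values", call. = FALSE)
  if (!"label" %in% names(data)) {
    stop("no 'label' column; use as_expr_dataset() to designate one", call. = FALSE)
  }
  gene_cols <- setdiff(names(data), "label")
  if (length(gene_cols) == 0) stop("no gene columns", call. = FALSE)
  labels <- data$label
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes, got ", nlevels(labels), call. = FALSE)
  if (nrow(data) < 2) stop("need at least 2 samples", call. = FALSE)
  x <- as.matrix(data[gene_cols])
  if (!is.numeric(x)) stop("gene columns must be numeric", call. = FALSE)
  list(x = x, labels = labels, codes = as.integer(labels) - 1L, gene_cols = gene_cols)
}
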