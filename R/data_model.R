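#' Expression dataset
#'
#' Container for a log2-scale gene-by-sample expression matrix with optional
#' case/control group labels. Gene and sample identifiers are the matrix
#' dimnames and must be unique; values must be finite (missing values are
#' rejected, never imputed).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param groups Optional named character vector mapping every sample id to
#'   `"case"` or `"control"`. When present, each group must contain at least
#'   two samples.
#' @return An object of class `expression_dataset` with elements `values`
#'   and `groups`.
#' @seealso [read_expression_matrix()], [attach_groups()]
#' @export
expression_dataset <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    validation_error("`values` must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    validation_error("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(genes)) {
    validation_error(sprintf(
      "duplicate gene identifier(s): %s",
      paste(unique(genes[duplicated(genes)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(samples)) {
    validation_error(sprintf(
      "duplicate sample identifier(s): %s",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")
    ))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    validation_error(sprintf(
      "non-finite expression value at gene '%s', sample '%s' (missing values are not allowed)",
      genes[bad[1]], samples[bad[2]]
    ))
  }
  if (!is.null(groups)) {
    groups <- normalize_groups(groups)
    if (is.null(names(groups)) || !setequal(names(groups), samples) ||
        length(groups) != length(samples)) {
      validation_error("`groups` must name every sample exactly once")
    }
    groups <- groups[samples]
    counts <- table(factor(groups, levels = c("case", "control")))
    if (any(counts < 2)) {
      validation_error(sprintf(
        "each group needs >= 2 samples (case: %d, control: %d)",
        counts[["case"]], counts[["control"]]
      ))
    }
  }
  structure(list(values = values, groups = groups),
            class = "expression_dataset")
}

# Synonym normalization for group labels ("patient" -> case etc.).
normalize_groups <- function(groups) {
  g <- tolower(trimws(as.character(groups)))
  case_syn <- c("case", "patient", "patients", "experimental", "disease",
                "affected", "treatment")
  ctrl_syn <- c("control", "controls", "ctrl", "healthy", "normal",
                "reference")
  out <- ifelse(g %in% case_syn, "case",
                ifelse(g %in% ctrl_syn, "control", NA_character_))
  if (anyNA(out)) {
    validation_error(sprintf(
      "unrecognized group label(s): %s (expected case/control or a synonym)",
      paste(unique(g[is.na(out)]), collapse = ", ")
    ))
  }
  names(out) <- names(groups)
  out
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$groups)) {
    cat("  groups: <none attached>\n")
  } else {
    cat(sprintf("  groups: %d case / %d control\n",
                sum(x$groups == "case"), sum(x$groups == "control")))
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset an expression dataset to a set of genes
#'
#' @param ds An [expression_dataset()].
#' @param genes Character vector of gene ids to keep (order preserved).
#' @return An `expression_dataset` restricted to `genes`.
#' @export
subset_genes <- function(ds, genes) {
  stopifnot(inherits(ds, "expression_dataset"))
  missing <- setdiff(genes, rownames(ds$values))
  if (length(missing)) {
    validation_error(sprintf("unknown gene id(s): %s",
                             paste(utils::head(missing, 5), collapse = ", ")))
  }
  expression_dataset(ds$values[genes, , drop = FALSE], ds$groups)
}

group_matrix <- function(ds, group) {
  if (is.null(ds$groups)) validation_error("dataset has no group labels attached")
  ds$values[, names(ds$groups)[ds$groups == group], drop = FALSE]
}

#' Read a tab-separated expression matrix
#'
#' Expects a TSV file with a header row of sample identifiers and gene
#' identifiers in the first column. All body cells must be numeric; any
#' unparsable cell or missing value raises an error naming the offending
#' gene and sample. Input is assumed to already be on the log2 scale (e.g.
#' RMA output); set `log2_transform = TRUE` for raw non-negative
#' intensities, which are stored as `log2(x + 1)`.
#'
#' @param path Path to the TSV file.
#' @param log2_transform Apply `log2(x + 1)` to the values on read.
#' @return An [expression_dataset()] without group labels.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) parse_error("expected gene id column plus >= 1 sample column")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    parse_error(sprintf(
      "cannot parse numeric value '%s' at gene '%s', sample '%s'",
      body[bad[1], bad[2]], genes[bad[1]], samples[bad[2]]
    ))
  }
  if (log2_transform) {
    if (any(num < 0)) {
      validation_error("negative intensities are incompatible with log2(x + 1)")
    }
    num <- log2(num + 1)
  }
  dimnames(num) <- list(genes, samples)
  expression_dataset(num)
}

#' Write an expression dataset as TSV
#'
#' Inverse of [read_expression_matrix()]: genes in rows, samples in columns,
#' values rendered with 10 significant digits so that a read/write round
#' trip agrees to better than 1e-9 relative error.
#'
#' @param ds An [expression_dataset()].
#' @param path Output file path.
#' @param id_column Name for the gene-id column header.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(ds, path, id_column = "gene_id") {
  stopifnot(inherits(ds, "expression_dataset"))
  body <- apply(ds$values, 2, formatC, format = "g", digits = 10)
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(ds$values))
  out <- cbind(rownames(ds$values), body)
  colnames(out) <- c(id_column, colnames(ds$values))
  write_tsv_safely(out, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Two-column TSV/CSV mapping sample id to group label. The delimiter is
#' sniffed from the header line (tab preferred over comma).
#'
#' @param path Path to the sheet.
#' @return A data frame with columns `sample_id` and `group` (raw labels,
#'   not yet normalized).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  sheet <- utils::read.delim(path, header = TRUE, sep = sep, quote = "",
                             colClasses = "character", check.names = FALSE)
  if (ncol(sheet) < 2) parse_error("sample sheet needs columns (sample_id, group)")
  data.frame(sample_id = sheet[[1]], group = sheet[[2]],
             stringsAsFactors = FALSE)
}

#' Attach case/control labels to a dataset
#'
#' Every sample in the dataset must appear exactly once in the sheet.
#' Group labels are normalized ("patient" and similar synonyms map to
#' `case`; "healthy" and similar to `control`), and each group must end up
#' with at least two samples so that control statistics and group variances
#' are defined.
#'
#' @param ds An [expression_dataset()].
#' @param sheet Data frame with columns `sample_id` and `group`, e.g. from
#'   [read_sample_sheet()].
#' @return The dataset with `groups` attached.
#' @export
attach_groups <- function(ds, sheet) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    validation_error("sheet must have columns `sample_id` and `group`")
  }
  if (anyDuplicated(sheet$sample_id)) {
    validation_error("duplicate sample id(s) in sample sheet")
  }
  samples <- colnames(ds$values)
  unknown <- setdiff(sheet$sample_id, samples)
  if (length(unknown)) {
    validation_error(sprintf("sheet sample(s) not in dataset: %s",
                             paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(samples, sheet$sample_id)
  if (length(missing)) {
    validation_error(sprintf("dataset sample(s) missing from sheet: %s",
                             paste(missing, collapse = ", ")))
  }
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  expression_dataset(ds$values, groups)
}

#' Write the sample sheet of a dataset
#'
#' @param ds An [expression_dataset()] with groups attached.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$groups)) validation_error("dataset has no group labels attached")
  out <- cbind(sample_id = names(ds$groups), group = unname(ds$groups))
  write_tsv_safely(out, path)
  invisible(path)
}

write_tsv_safely <- function(x, path) {
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) io_error(sprintf("cannot write '%s': %s", path,
                                    conditionMessage(ok)))
}

deg_table_columns <- c("gene", "method", "p", "q", "fold_change",
                       "direction", "sig_raw_01", "sig_raw_05", "sig_fdr_05")

#' Construct a DEG result table
#'
#' A tidy per-gene, per-method table of differential-expression calls:
#' raw p, BH q, signed fold change, direction (`up`/`down`, empty unless
#' the gene is flagged by at least one criterion), and significance flags
#' at the two stringency levels (raw p < 0.01, raw p < 0.05) plus BH
#' q < 0.05.
#'
#' @param gene,method Character vectors.
#' @param p,q,fold_change Numeric vectors (`p`, `q` in (0, 1]).
#' @param direction Character, `"up"`, `"down"`, or `""`.
#' @param sig_raw_01,sig_raw_05,sig_fdr_05 Logical flags.
#' @return A data frame of class `deg_table`.
#' @export
deg_table <- function(gene, method, p, q, fold_change, direction,
                      sig_raw_01, sig_raw_05, sig_fdr_05) {
  tab <- data.frame(gene = as.character(gene), method = as.character(method),
                    p = as.numeric(p), q = as.numeric(q),
                    fold_change = as.numeric(fold_change),
                    direction = as.character(direction),
                    sig_raw_01 = as.logical(sig_raw_01),
                    sig_raw_05 = as.logical(sig_raw_05),
                    sig_fdr_05 = as.logical(sig_fdr_05),
                    stringsAsFactors = FALSE)
  validate_deg_table(tab)
  tab <- tab[order(tab$gene, tab$method), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("deg_table", "data.frame")
  tab
}

validate_deg_table <- function(tab) {
  if (!all(deg_table_columns %in% names(tab))) {
    validation_error("DEG table is missing required columns")
  }
  if (nrow(tab) == 0) return(invisible(tab))
  if (any(tab$p <= 0 | tab$p > 1) || any(tab$q <= 0 | tab$q > 1)) {
    validation_error("p and q must lie in (0, 1]")
  }
  any_flag <- tab$sig_raw_01 | tab$sig_raw_05 | tab$sig_fdr_05
  if (any(any_flag & !(tab$direction %in% c("up", "down")))) {
    validation_error("flagged genes must carry a direction")
  }
  if (any(!any_flag & tab$direction != "")) {
    validation_error("direction must be empty for unflagged genes")
  }
  invisible(tab)
}

#' Write a DEG table as TSV
#'
#' Fixed column order, floats rendered with 6 significant digits, rows
#' sorted by gene id then method, so identical analyses produce
#' byte-identical files.
#'
#' @param tab A [deg_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(tab, path) {
  validate_deg_table(tab)
  tab <- tab[order(tab$gene, tab$method), deg_table_columns, drop = FALSE]
  out <- tab
  for (col in c("p", "q", "fold_change")) {
    out[[col]] <- formatC(tab[[col]], format = "g", digits = 6)
  }
  for (col in c("sig_raw_01", "sig_raw_05", "sig_fdr_05")) {
    out[[col]] <- ifelse(tab[[col]], "TRUE", "FALSE")
  }
  write_tsv_safely(as.matrix(out), path)
  invisible(path)
}

#' Read a DEG table written by [write_deg_table()]
#'
#' @param path Path to the TSV file.
#' @return A [deg_table()].
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) {
    return(deg_table(character(), character(), numeric(), numeric(),
                     numeric(), character(), logical(), logical(), logical()))
  }
  deg_table(raw$gene, raw$method,
            as.numeric(raw$p), as.numeric(raw$q), as.numeric(raw$fold_change),
            ifelse(is.na(raw$direction), "", raw$direction),
            raw$sig_raw_01 == "TRUE", raw$sig_raw_05 == "TRUE",
            raw$sig_fdr_05 == "TRUE")
}
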