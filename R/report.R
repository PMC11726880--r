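#' Per-dataset DEG count summary
#'
#' Re-derives the headline count matrix from stored per-gene flags: for
#' one dataset, the number of genes called by each conventional criterion
#' (Welch BH q < 0.05, moderated-t BH q < 0.01 and < 0.05) and by the
#' Shapley pipeline at its two stringencies (raw p < 0.01, raw p < 0.05)
#' plus the FDR-corrected 0.05 variant, with up/down breakdowns for the
#' Shapley columns.
#'
#' @param label Free-text dataset label.
#' @param classical A `classical_result` for the full gene universe.
#' @param cash01,cash05 `cash_result` objects run at preselection alpha
#'   0.01 and 0.05 on the same dataset.
#' @param fdr_alpha FDR level for the corrected columns.
#' @return A one-row data frame of class `method_count_row`.
#' @export
summarize_counts <- function(label, classical, cash01, cash05,
                             fdr_alpha = 0.05) {
  stopifnot(inherits(classical, "classical_result"),
            inherits(cash01, "cash_result"),
            inherits(cash05, "cash_result"))
  for (cr in list(cash01, cash05)) {
    if (!all(cr$gene %in% classical$gene)) {
      validation_error("CASh results contain genes outside the classical universe")
    }
  }
  updown <- function(res, flag) {
    sel <- res[flag, , drop = FALSE]
    c(total = nrow(sel), up = sum(sel$direction == "up"),
      down = sum(sel$direction == "down"))
  }
  c01 <- updown(cash01, cash01$sig_raw)
  c05 <- updown(cash05, cash05$sig_raw)
  cf <- updown(cash05, cash05$sig_fdr)
  row <- data.frame(
    dataset = label,
    welch_fdr05 = sum(classical$q_welch < fdr_alpha),
    ebayes_fdr01 = sum(classical$q_ebayes < 0.01),
    ebayes_fdr05 = sum(classical$q_ebayes < fdr_alpha),
    cash05_fdr05 = cf[["total"]], cash05_fdr05_up = cf[["up"]],
    cash05_fdr05_down = cf[["down"]],
    cash01_raw = c01[["total"]], cash01_raw_up = c01[["up"]],
    cash01_raw_down = c01[["down"]],
    cash05_raw = c05[["total"]], cash05_raw_up = c05[["up"]],
    cash05_raw_down = c05[["down"]],
    stringsAsFactors = FALSE)
  class(row) <- c("method_count_row", "data.frame")
  row
}

#' Format a DEG count cell with its up/down breakdown
#'
#' Renders `"5 (3 up, 2 down)"` (ASCII, default) or with arrows when
#' `ascii = FALSE`; a zero count renders as `"0"`.
#'
#' @param total,up,down Non-negative counts with `up + down = total`.
#' @param ascii Use `up`/`down` words instead of arrow glyphs.
#' @return A character scalar.
#' @export
format_count_cell <- function(total, up, down, ascii = TRUE) {
  if (up + down != total) validation_error("up + down must equal total")
  if (total == 0) return("0")
  if (ascii) {
    sprintf("%d (%d up, %d down)", total, up, down)
  } else {
    sprintf("%d (%d ↑, %d ↓)", total, up, down)
  }
}

#' Render count rows as a display table
#'
#' @param rows One or more [summarize_counts()] rows (rbind-ed).
#' @param ascii Passed to [format_count_cell()].
#' @return A character data frame, one formatted column per method.
#' @export
render_count_table <- function(rows, ascii = TRUE) {
  cell <- function(prefix) {
    vapply(seq_len(nrow(rows)), function(i) {
      format_count_cell(rows[[prefix]][i], rows[[paste0(prefix, "_up")]][i],
                        rows[[paste0(prefix, "_down")]][i], ascii)
    }, "")
  }
  data.frame(dataset = rows$dataset,
             welch_fdr05 = as.character(rows$welch_fdr05),
             ebayes_fdr01 = as.character(rows$ebayes_fdr01),
             ebayes_fdr05 = as.character(rows$ebayes_fdr05),
             cash05_fdr05 = cell("cash05_fdr05"),
             cash01 = cell("cash01_raw"),
             cash05 = cell("cash05_raw"),
             stringsAsFactors = FALSE)
}

#' Cross-dataset DEG overlap
#'
#' Exact set intersections of named DEG lists for every combination of two
#' or more sets, with deterministic (alphabetical) ordering of both the
#' combinations and the shared gene ids.
#'
#' @param deg_lists Named list of character vectors (>= 2 sets, unique
#'   names).
#' @return A data frame of class `overlap_report` with columns `sets`
#'   (names joined by `+`), `n_sets`, `size`, and list-column `genes`.
#' @export
deg_overlap <- function(deg_lists) {
  if (length(deg_lists) < 2) validation_error("need >= 2 named DEG sets")
  nms <- names(deg_lists)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    validation_error("DEG sets must have unique non-empty names")
  }
  deg_lists <- lapply(deg_lists, unique)
  combos <- list()
  for (k in 2:length(deg_lists)) {
    combos <- c(combos, utils::combn(sort(nms), k, simplify = FALSE))
  }
  shared <- lapply(combos, function(cmb) {
    sort(Reduce(intersect, deg_lists[cmb]))
  })
  out <- data.frame(sets = vapply(combos, paste, "", collapse = "+"),
                    n_sets = lengths(combos), size = lengths(shared),
                    stringsAsFactors = FALSE)
  out$genes <- shared
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Reproducibility manifest for a run
#'
#' Records the configuration, seed, package and R versions, and MD5
#' digests of the input and output files, sufficient to verify that a
#' rerun reproduced a result bit-for-bit.
#'
#' @param config A configuration list (e.g. a [cash_config()]).
#' @param seed Integer seed used for the run.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, inputs = character(),
                         outputs = character()) {
  digest <- function(paths) {
    if (length(paths) == 0) return(stats::setNames(list(), character()))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      io_error(sprintf("cannot digest missing file(s): %s",
                       paste(missing, collapse = ", ")))
    }
    as.list(tools::md5sum(paths))
  }
  structure(list(
    tool = "cashr",
    version = as.character(utils::packageVersion("cashr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    config = unclass(config),
    inputs = digest(inputs),
    outputs = digest(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
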