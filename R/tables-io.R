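## Readers and writers for the tabular and image inputs. TSV is the
## canonical dialect (UTF-8, "." decimal); CSV is accepted via `csv = TRUE`.

.readTable <- function(path, required, csv = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- utils::read.table(path, header = TRUE,
                         sep = if (csv) "," else "\t",
                         quote = "", comment.char = "",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L) {
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(sprintf("\"%s\"", missing_cols), collapse = ", ")))
  }
  d
}

#' Read a spectral-index quantification table
#'
#' Loads a long-format TSV/CSV of per-protein spectral indices (columns
#' `protein_id`, `condition`, `fraction`, `replicate`, `spectral_index`,
#' `psm_count`) and validates it as a [QuantTable-class]. Missing
#' (protein, condition, fraction) combinations are *not* materialized on
#' load; absence is distinct from a measured spectral index of 0 and is
#' handled by each downstream operation's stated NA policy.
#'
#' @param path file path.
#' @param bait_id identifier of the bait protein; must be measured in every
#'   condition present.
#' @param condition_labels,fraction_mode see [QuantTable()].
#' @param csv set `TRUE` for comma-separated input.
#' @return A validated [QuantTable-class].
#' @export
loadQuantTable <- function(path, bait_id, condition_labels = NULL,
                           fraction_mode = NULL, csv = FALSE) {
  d <- .readTable(path, .QUANT_COLUMNS, csv = csv)
  QuantTable(d, bait_id = bait_id, condition_labels = condition_labels,
             fraction_mode = fraction_mode)
}

#' Read a differential-expression table
#'
#' @param path TSV/CSV with columns `gene_id`, `log2fc`, `p_value`.
#' @param dataset_label name for the contrast; defaults to the file name.
#' @param csv set `TRUE` for comma-separated input.
#' @return A validated [DETable-class].
#' @export
loadDETable <- function(path, dataset_label = basename(path), csv = FALSE) {
  d <- .readTable(path, c("gene_id", "log2fc", "p_value"), csv = csv)
  DETable(d, dataset_label = dataset_label)
}

#' Read gene sets in GMT format
#'
#' One set per line: tab-separated `name`, `description`, then member
#' identifiers. Duplicate members within a set are removed. Lines with fewer
#' than three fields raise a parse error naming the line.
#'
#' @param path GMT file path.
#' @param universe optional background identifiers; defaults to the union of
#'   all set members (see [GeneSetCollection()]).
#' @return A [GeneSetCollection-class].
#' @export
loadGMT <- function(path, universe = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: %d field(s), need >= 3",
                   i, length(fields)))
    }
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
  }
  GeneSetCollection(sets, universe = universe)
}

#' Read a flow-cytometry event table
#'
#' @param path TSV/CSV with columns `event_id`, `tof`, `fluor_integral`.
#' @param group_label group name (e.g. `"control"`).
#' @param csv set `TRUE` for comma-separated input.
#' @return A validated [EventTable-class].
#' @export
loadEventTable <- function(path, group_label, csv = FALSE) {
  d <- .readTable(path, c("event_id", "tof", "fluor_integral"), csv = csv)
  EventTable(d, group_label = group_label)
}

#' Read a per-cell intensity table
#'
#' @param path TSV/CSV with columns `animal_id`, `cell_id`,
#'   `nucleus_intensity`, `cytosol_intensity`.
#' @param csv set `TRUE` for comma-separated input.
#' @return A validated [CellTable-class].
#' @export
loadCellTable <- function(path, csv = FALSE) {
  d <- .readTable(path, c("animal_id", "cell_id", "nucleus_intensity",
                          "cytosol_intensity"), csv = csv)
  CellTable(d)
}

#' Read a qPCR Ct table
#'
#' @param path TSV/CSV with columns `sample_label`, `gene_id`, `ct`,
#'   `replicate`.
#' @param housekeeping_ids housekeeping gene identifiers (length >= 1).
#' @param csv set `TRUE` for comma-separated input.
#' @return A validated [CtTable-class].
#' @export
loadCtTable <- function(path, housekeeping_ids, csv = FALSE) {
  d <- .readTable(path, c("sample_label", "gene_id", "ct", "replicate"),
                  csv = csv)
  CtTable(d, housekeeping_ids = housekeeping_ids)
}

#' Read an 8-bit grayscale image
#'
#' Accepts PNG or single-plane TIFF. Multi-channel images are collapsed only
#' when all channels are identical (i.e. gray stored as RGB); otherwise an
#' error is raised. Returned as an integer matrix with values in 0..255.
#'
#' @param path PNG or TIFF file path.
#' @return integer matrix in \[0, 255\].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format: '%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    first <- img[, , 1L]
    for (k in seq_len(ch)[-1L]) {
      if (k <= 3L && any(abs(img[, , k] - first) > 1e-9)) {
        stop("image is not grayscale: color channels differ")
      }
    }
    img <- first
  }
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

.assertGrayImage <- function(image) {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("image must be a non-empty matrix")
  }
  if (any(is.na(image)) || any(image < 0) || any(image > 255)) {
    stop("image intensities must lie in [0, 255]")
  }
  invisible(TRUE)
}

#' Write a result table as TSV
#'
#' Writes any result data.frame with a stable column order (the order of the
#' input), floating-point values at 6 significant digits and missing values
#' as `NA`, so that a write/reload cycle reproduces values within 1e-6.
#'
#' @param table a data.frame of results.
#' @param path destination file path.
#' @param csv set `TRUE` to write comma-separated output.
#' @return `path`, invisibly.
#' @export
writeResults <- function(table, path, csv = FALSE) {
  stopifnot(is.data.frame(table))
  out <- table
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- signif(out[[col]], 6L)
      v[is.nan(v)] <- NA_real_
      out[[col]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = if (csv) "," else "\t",
                       quote = FALSE, row.names = FALSE, na = "NA",
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write results to '%s': %s", path,
                 conditionMessage(e)))
  })
  invisible(path)
}

#' Read back a result table written by writeResults
#'
#' @param path file path.
#' @param csv set `TRUE` for comma-separated input.
#' @return data.frame.
#' @export
loadResults <- function(path, csv = FALSE) {
  .readTable(path, character(0), csv = csv)
}
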