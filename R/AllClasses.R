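#' @import methods
NULL

.QUANT_COLUMNS <- c("protein_id", "condition", "fraction", "replicate",
                    "spectral_index", "psm_count")
.TWO_FRACTIONS <- c("soluble", "insoluble")

#' QuantTable: per-protein spectral indices across condition, fraction and replicate
#'
#' Container for long-format spectral-index records from a fractionated
#' co-immunoprecipitation LC-MS/MS experiment, anchored to a bait protein.
#' Each record carries a `protein_id`, a `condition` label, a `fraction`
#' label (`soluble`/`insoluble` in two-fraction mode, `whole` in whole-lysate
#' mode), a positive integer `replicate`, a non-negative `spectral_index`
#' (relative abundance) and a non-negative integer `psm_count`
#' (peptide-spectrum matches, used downstream as a detection-confidence
#' filter).
#'
#' @slot records data.frame with columns `protein_id`, `condition`,
#'   `fraction`, `replicate`, `spectral_index`, `psm_count`.
#' @slot baitId character(1); the affinity-tagged bait protein. It must be
#'   measured in every condition present in the table.
#' @slot conditionLabels character(2); ordered pair (control label,
#'   treatment label).
#' @slot fractionMode character(1); `"two-fraction"` (soluble/insoluble) or
#'   `"whole-lysate"`.
#' @slot baitNormalized logical(1); whether [baitNormalize()] has been
#'   applied.
#'
#' @seealso [QuantTable()] for construction, [loadQuantTable()] to read one
#'   from TSV/CSV.
#' @export
setClass("QuantTable",
  representation(
    records = "data.frame",
    baitId = "character",
    conditionLabels = "character",
    fractionMode = "character",
    baitNormalized = "logical"
  )
)

setValidity("QuantTable", function(object) {
  rec <- object@records
  missing_cols <- setdiff(.QUANT_COLUMNS, names(rec))
  if (length(missing_cols) > 0L) {
    return(sprintf("records lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (length(object@baitId) != 1L || is.na(object@baitId)) {
    return("baitId must be a single identifier")
  }
  if (length(object@conditionLabels) != 2L ||
      anyDuplicated(object@conditionLabels)) {
    return("conditionLabels must be two distinct labels (control, treatment)")
  }
  if (!object@fractionMode %in% c("two-fraction", "whole-lysate")) {
    return("fractionMode must be 'two-fraction' or 'whole-lysate'")
  }
  if (nrow(rec) > 0L) {
    if (any(is.na(rec$spectral_index)) || any(rec$spectral_index < 0)) {
      return("spectral_index must be non-negative and non-missing")
    }
    if (any(is.na(rec$psm_count)) || any(rec$psm_count < 0) ||
        any(rec$psm_count != round(rec$psm_count))) {
      return("psm_count must be a non-negative integer")
    }
    if (any(is.na(rec$replicate)) || any(rec$replicate < 1) ||
        any(rec$replicate != round(rec$replicate))) {
      return("replicate must be a positive integer")
    }
    key <- paste(rec$protein_id, rec$condition, rec$fraction, rec$replicate,
                 sep = "\r")
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
      return(sprintf(
        "duplicate (protein_id, condition, fraction, replicate) key in rows: %s",
        paste(dup, collapse = ", ")))
    }
    extra_cond <- setdiff(unique(rec$condition), object@conditionLabels)
    if (length(extra_cond) > 0L) {
      return(sprintf("condition label(s) not in conditionLabels: %s",
                     paste(extra_cond, collapse = ", ")))
    }
    allowed <- if (object@fractionMode == "two-fraction") .TWO_FRACTIONS
               else "whole"
    bad_frac <- setdiff(unique(rec$fraction), allowed)
    if (length(bad_frac) > 0L) {
      return(sprintf("fraction label(s) %s not allowed in %s mode",
                     paste(bad_frac, collapse = ", "), object@fractionMode))
    }
    for (cond in intersect(object@conditionLabels, unique(rec$condition))) {
      if (!object@baitId %in% rec$protein_id[rec$condition == cond]) {
        return(sprintf("bait '%s' has no records in condition '%s'",
                       object@baitId, cond))
      }
    }
  }
  TRUE
})

#' Construct a QuantTable
#'
#' @param records data.frame of spectral records (see [QuantTable-class]).
#' @param bait_id identifier of the bait protein.
#' @param condition_labels ordered pair (control label, treatment label);
#'   when `NULL`, taken as the conditions in order of first appearance.
#' @param fraction_mode `"two-fraction"`, `"whole-lysate"`, or `NULL` to
#'   infer from the fraction labels present.
#' @return A validated [QuantTable-class] object.
#' @examples
#' rec <- data.frame(
#'   protein_id = rep(c("BAIT", "P1"), each = 4),
#'   condition = rep(rep(c("control", "treatment"), each = 2), 2),
#'   fraction = rep(c("soluble", "insoluble"), 4),
#'   replicate = 1L,
#'   spectral_index = c(50, 50, 50, 50, 4, 0, 0, 4),
#'   psm_count = 5L
#' )
#' qt <- QuantTable(rec, bait_id = "BAIT")
#' qt
#' @export
QuantTable <- function(records, bait_id, condition_labels = NULL,
                       fraction_mode = NULL) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("protein_id", "condition", "fraction")) {
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  }
  if (is.null(condition_labels)) {
    condition_labels <- unique(records$condition)
  }
  if (is.null(fraction_mode)) {
    fraction_mode <- if (all(unique(records$fraction) == "whole"))
      "whole-lysate" else "two-fraction"
  }
  new("QuantTable", records = records, baitId = as.character(bait_id),
      conditionLabels = as.character(condition_labels),
      fractionMode = fraction_mode, baitNormalized = FALSE)
}

setMethod("show", "QuantTable", function(object) {
  rec <- object@records
  cat(sprintf("QuantTable (%s): %d records, %d proteins\n",
              object@fractionMode, nrow(rec),
              length(unique(rec$protein_id))))
  cat(sprintf("  bait: %s%s\n", object@baitId,
              if (object@baitNormalized) " (bait-normalized)" else ""))
  cat(sprintf("  conditions: %s (control) vs %s (treatment)\n",
              object@conditionLabels[1L], object@conditionLabels[2L]))
})

#' DETable: gene-level differential-expression results
#'
#' Rows of (`gene_id`, `log2fc`, `p_value`) from one differential-expression
#' contrast. `p_value` may hold FDR-adjusted values if that is the intended
#' significance scale; thresholds are applied to whatever this column holds.
#'
#' @slot data data.frame with columns `gene_id`, `log2fc`, `p_value`.
#' @slot datasetLabel character(1) naming the contrast.
#' @export
setClass("DETable",
  representation(data = "data.frame", datasetLabel = "character")
)

setValidity("DETable", function(object) {
  d <- object@data
  missing_cols <- setdiff(c("gene_id", "log2fc", "p_value"), names(d))
  if (length(missing_cols) > 0L) {
    return(sprintf("data lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(d$gene_id)) return("gene_id must be unique per table")
  p_obs <- d$p_value[!is.na(d$p_value)]
  if (any(p_obs < 0 | p_obs > 1)) return("p_value must lie in [0, 1]")
  TRUE
})

#' Construct a DETable
#'
#' @param data data.frame with columns `gene_id`, `log2fc`, `p_value`.
#' @param dataset_label name of the contrast (used in messages and output).
#' @return A validated [DETable-class] object.
#' @export
DETable <- function(data, dataset_label = "dataset") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$gene_id <- as.character(data$gene_id)
  new("DETable", data = data, datasetLabel = as.character(dataset_label))
}

setMethod("show", "DETable", function(object) {
  cat(sprintf("DETable '%s': %d genes\n", object@datasetLabel,
              nrow(object@data)))
})

#' GeneSetCollection: named annotation sets over an explicit universe
#'
#' Named identifier sets (GO-style annotation categories) together with the
#' background universe against which over-representation is tested. On
#' construction every set is intersected with the universe, so the subset
#' invariant holds by design; the background is always explicit because the
#' choice of background dominates over-representation results.
#'
#' @slot sets named list of character vectors (duplicate members removed).
#' @slot universe character vector of identifiers.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", universe = "character")
)

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) > 0L && is.null(names(object@sets))) {
    return("sets must be named")
  }
  if (anyDuplicated(object@universe)) return("universe must be duplicate-free")
  for (nm in names(object@sets)) {
    s <- object@sets[[nm]]
    if (anyDuplicated(s)) return(sprintf("set '%s' contains duplicates", nm))
    if (length(setdiff(s, object@universe)) > 0L) {
      return(sprintf("set '%s' is not a subset of the universe", nm))
    }
  }
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of identifier vectors.
#' @param universe background identifiers. Defaults to the union of the sets.
#'   Set members outside the universe are dropped (harmonization is
#'   case-sensitive exact matching; no symbol aliasing is attempted).
#' @return A validated [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, universe = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) s[s %in% universe])
  new("GeneSetCollection", sets = sets, universe = universe)
}

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets over a universe of %d identifiers\n",
              length(object@sets), length(object@universe)))
})

#' EventTable: per-event large-particle flow-cytometry measurements
#'
#' One row per gated event (animal) with a time-of-flight `tof` (size proxy,
#' strictly positive) and `fluor_integral`, the integral of fluorescence
#' signal across the whole animal.
#'
#' @slot events data.frame with columns `event_id`, `tof`, `fluor_integral`.
#' @slot groupLabel character(1), e.g. `"control"` or `"sample"`.
#' @export
setClass("EventTable",
  representation(events = "data.frame", groupLabel = "character")
)

setValidity("EventTable", function(object) {
  d <- object@events
  missing_cols <- setdiff(c("event_id", "tof", "fluor_integral"), names(d))
  if (length(missing_cols) > 0L) {
    return(sprintf("events lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (nrow(d) > 0L) {
    if (any(is.na(d$tof)) || any(d$tof <= 0)) return("tof must be > 0")
    if (any(is.na(d$fluor_integral)) || any(d$fluor_integral < 0)) {
      return("fluor_integral must be non-negative")
    }
  }
  TRUE
})

#' Construct an EventTable
#'
#' @param events data.frame with columns `event_id`, `tof`, `fluor_integral`.
#' @param group_label group name for the events.
#' @return A validated [EventTable-class] object.
#' @export
EventTable <- function(events, group_label) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  new("EventTable", events = events, groupLabel = as.character(group_label))
}

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable '%s': %d events\n", object@groupLabel,
              nrow(object@events)))
})

#' CellTable: per-cell nuclear and proximal-cytosolic intensities
#'
#' One row per scored intestinal cell, at most 20 cells per animal (the
#' total number of C. elegans intestinal cells, which is also the fixed
#' denominator for the nuclear-localization percentage).
#'
#' @slot cells data.frame with columns `animal_id`, `cell_id`,
#'   `nucleus_intensity`, `cytosol_intensity`.
#' @export
setClass("CellTable", representation(cells = "data.frame"))

setValidity("CellTable", function(object) {
  d <- object@cells
  missing_cols <- setdiff(
    c("animal_id", "cell_id", "nucleus_intensity", "cytosol_intensity"),
    names(d))
  if (length(missing_cols) > 0L) {
    return(sprintf("cells lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (nrow(d) > 0L) {
    ints <- c(d$nucleus_intensity, d$cytosol_intensity)
    if (any(is.na(ints)) || any(ints < 0)) {
      return("intensities must be non-negative")
    }
    per_animal <- table(d$animal_id)
    if (any(per_animal > 20L)) {
      return(sprintf("animal(s) with more than 20 cells: %s",
                     paste(names(per_animal)[per_animal > 20L],
                           collapse = ", ")))
    }
  }
  TRUE
})

#' Construct a CellTable
#'
#' @param cells data.frame with columns `animal_id`, `cell_id`,
#'   `nucleus_intensity`, `cytosol_intensity`.
#' @return A validated [CellTable-class] object.
#' @export
CellTable <- function(cells) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells$animal_id <- as.character(cells$animal_id)
  new("CellTable", cells = cells)
}

setMethod("show", "CellTable", function(object) {
  cat(sprintf("CellTable: %d cells across %d animals\n",
              nrow(object@cells), length(unique(object@cells$animal_id))))
})

#' CtTable: qPCR threshold-cycle measurements with housekeeping genes
#'
#' Raw Ct values per (sample, gene, replicate) plus the identifiers of the
#' housekeeping genes used for normalization (e.g. tba-1 and Y45F10D.4).
#' Every sample must carry every housekeeping gene.
#'
#' @slot ct data.frame with columns `sample_label`, `gene_id`, `ct`,
#'   `replicate`.
#' @slot housekeepingIds character vector (length >= 1) of housekeeping
#'   gene identifiers.
#' @export
setClass("CtTable",
  representation(ct = "data.frame", housekeepingIds = "character")
)

setValidity("CtTable", function(object) {
  d <- object@ct
  missing_cols <- setdiff(c("sample_label", "gene_id", "ct", "replicate"),
                          names(d))
  if (length(missing_cols) > 0L) {
    return(sprintf("ct lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  if (length(object@housekeepingIds) < 1L) {
    return("at least one housekeeping gene is required")
  }
  if (nrow(d) > 0L) {
    if (any(is.na(d$ct)) || any(d$ct <= 0)) return("ct must be > 0")
    for (smp in unique(d$sample_label)) {
      have <- unique(d$gene_id[d$sample_label == smp])
      lack <- setdiff(object@housekeepingIds, have)
      if (length(lack) > 0L) {
        return(sprintf("sample '%s' lacks housekeeping gene(s): %s",
                       smp, paste(lack, collapse = ", ")))
      }
    }
  }
  TRUE
})

#' Construct a CtTable
#'
#' @param ct data.frame with columns `sample_label`, `gene_id`, `ct`,
#'   `replicate`.
#' @param housekeeping_ids identifiers of the housekeeping genes.
#' @return A validated [CtTable-class] object.
#' @export
CtTable <- function(ct, housekeeping_ids) {
  ct <- as.data.frame(ct, stringsAsFactors = FALSE)
  ct$sample_label <- as.character(ct$sample_label)
  ct$gene_id <- as.character(ct$gene_id)
  new("CtTable", ct = ct,
      housekeepingIds = as.character(housekeeping_ids))
}

setMethod("show", "CtTable", function(object) {
  cat(sprintf("CtTable: %d Ct values, %d samples, housekeeping: %s\n",
              nrow(object@ct), length(unique(object@ct$sample_label)),
              paste(object@housekeepingIds, collapse = ", ")))
})
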