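#' NPX dataset container
#'
#' Holds a samples-by-proteins matrix of NPX values (log2-scale relative
#' quantification, as delivered by proximity extension assay platforms)
#' together with per-protein limits of detection (LoD), the panel each assay
#' belongs to, and per-(sample, panel) QC warning flags. Missing cells are
#' encoded as `NA` in `values`.
#'
#' Protein identifiers must be unique. When the same protein name is assayed
#' on more than one panel, each assay is a distinct feature and identifiers
#' carry a `:PANEL` suffix (see [read_npx()]).
#'
#' @param values numeric matrix, rows = samples, columns = proteins, with
#'   dimnames set. `NA` marks missing cells; all other entries must be finite.
#' @param lod named numeric vector of per-protein limits of detection, in NPX
#'   units; names must cover every column of `values`.
#' @param panel named character vector mapping each protein id to its panel
#'   label. Defaults to a single panel `"ALL"`.
#' @param qc logical matrix of QC warning flags, rows = samples, columns =
#'   panels (dimnames set). Defaults to all-`FALSE`.
#' @return an object of class `npx_dataset` with elements `values`, `lod`,
#'   `panel`, `qc`.
#' @export
npx_dataset <- function(values, lod, panel = NULL, qc = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must have sample ids as rownames and protein ids as colnames")
  }
  sample_ids <- rownames(values)
  protein_ids <- colnames(values)
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(protein_ids)) {
    stopf("duplicate protein id: %s", protein_ids[duplicated(protein_ids)][1L])
  }
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) stopf("non-finite NPX values present")

  if (is.null(panel)) {
    panel <- stats::setNames(rep("ALL", length(protein_ids)), protein_ids)
  }
  if (is.null(names(panel)) || !all(protein_ids %in% names(panel))) {
    stopf("'panel' must be named and cover every protein id")
  }
  panel <- panel[protein_ids]

  lod <- unlist(lod)
  if (is.null(names(lod)) || !all(protein_ids %in% names(lod))) {
    missing <- setdiff(protein_ids, names(lod))
    stopf("missing LoD for protein(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  lod <- lod[protein_ids]
  if (any(!is.finite(lod))) {
    stopf("non-finite LoD for protein(s): %s",
          paste(utils::head(protein_ids[!is.finite(lod)], 5L), collapse = ", "))
  }

  panels <- sort(unique(unname(panel)))
  if (is.null(qc)) {
    qc <- matrix(FALSE, nrow = length(sample_ids), ncol = length(panels),
                 dimnames = list(sample_ids, panels))
  }
  if (!is.matrix(qc) || !is.logical(qc)) stopf("'qc' must be a logical matrix")
  if (!setequal(rownames(qc), sample_ids)) {
    stopf("'qc' rownames must equal the sample ids")
  }
  if (!all(panels %in% colnames(qc))) {
    stopf("'qc' must have one column per panel (%s)",
          paste(panels, collapse = ", "))
  }
  qc <- qc[sample_ids, panels, drop = FALSE]

  structure(list(values = values, lod = lod, panel = panel, qc = qc),
            class = "npx_dataset")
}

#' @export
dim.npx_dataset <- function(x) dim(x$values)

#' @export
print.npx_dataset <- function(x, ...) {
  d <- dim(x$values)
  miss <- mean(is.na(x$values))
  cat(sprintf("<npx_dataset> %d samples x %d proteins, %d panel(s), %.2f%% missing\n",
              d[1L], d[2L], length(unique(x$panel)), 100 * miss))
  invisible(x)
}

#' Sample and protein identifiers of an NPX dataset
#' @param ds an `npx_dataset`.
#' @return character vector of ids.
#' @export
npx_samples <- function(ds) rownames(ds$values)

#' @rdname npx_samples
#' @export
npx_proteins <- function(ds) colnames(ds$values)

#' Fraction of missing cells in an NPX dataset
#' @param ds an `npx_dataset`.
#' @return scalar in \[0, 1\].
#' @export
missing_fraction <- function(ds) mean(is.na(ds$values))

# Build unique protein ids from (name, panel): names assayed on more than one
# panel get a ":PANEL" suffix so each assay stays a distinct feature.
make_protein_ids <- function(protein, panel) {
  dup_names <- unique(protein[duplicated(protein)])
  ifelse(protein %in% dup_names, paste0(protein, ":", panel), protein)
}

#' Read an NPX table from disk
#'
#' Two layouts are supported. `"wide"`: first column sample id, remaining
#' columns one per protein; per-protein LoD values come from a companion file
#' (columns `protein`, `lod` and optionally `panel`), and QC warning flags
#' from a companion file (columns `sample`, `panel`, `flag`). `"long"`: one
#' row per measurement with columns `sample_id`, `protein`, `panel`, `npx`,
#' `lod`, `qc_warning`.
#'
#' Comma- and tab-separated files are auto-detected; the first row must be a
#' header; identifiers are whitespace-stripped and case-sensitive. In the wide
#' layout the panel of each protein is taken from the LoD file's `panel`
#' column if present, else from a `:PANEL` suffix on the protein id, else all
#' proteins fall into one panel `"ALL"`.
#'
#' @param path path to the NPX table.
#' @param layout `"wide"` or `"long"`.
#' @param lod_path path to the LoD companion file (wide layout only).
#' @param qc_path optional path to the QC companion file (wide layout only).
#' @return an [npx_dataset()].
#' @export
read_npx <- function(path, layout = c("wide", "long"),
                     lod_path = NULL, qc_path = NULL) {
  layout <- match.arg(layout)
  df <- read_delim_auto(path)
  if (layout == "wide") {
    if (ncol(df) < 2L) stopf("wide NPX file needs a sample column plus proteins")
    sample_ids <- trimws(as.character(df[[1L]]))
    if (anyDuplicated(sample_ids)) {
      stopf("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1L])
    }
    values <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- sample_ids

    if (is.null(lod_path)) stopf("wide layout requires 'lod_path'")
    lod_df <- read_delim_auto(lod_path)
    if (!all(c("protein", "lod") %in% names(lod_df))) {
      stopf("LoD file must have columns 'protein' and 'lod'")
    }
    lod <- stats::setNames(as.numeric(lod_df$lod),
                           trimws(as.character(lod_df$protein)))
    panel <- NULL
    if ("panel" %in% names(lod_df)) {
      panel <- stats::setNames(trimws(as.character(lod_df$panel)), names(lod))
    } else if (all(grepl(":", colnames(values), fixed = TRUE))) {
      panel <- stats::setNames(sub("^.*:", "", colnames(values)),
                               colnames(values))
    }
    qc <- NULL
    if (!is.null(qc_path)) {
      qc_df <- read_delim_auto(qc_path)
      if (!all(c("sample", "panel", "flag") %in% names(qc_df))) {
        stopf("QC file must have columns 'sample', 'panel' and 'flag'")
      }
      panels <- sort(unique(c(trimws(as.character(qc_df$panel)),
                              unique(unname(panel %||%
                                stats::setNames(rep("ALL", ncol(values)),
                                                colnames(values)))))))
      qc <- matrix(FALSE, nrow(values), length(panels),
                   dimnames = list(rownames(values), panels))
      flg <- qc_df$flag
      if (is.character(flg)) flg <- toupper(trimws(flg)) %in% c("TRUE", "T", "1", "YES", "WARN")
      flg <- as.logical(flg)
      for (i in seq_len(nrow(qc_df))) {
        s <- trimws(as.character(qc_df$sample[i]))
        p <- trimws(as.character(qc_df$panel[i]))
        if (s %in% rownames(qc)) qc[s, p] <- qc[s, p] || isTRUE(flg[i])
      }
    }
    return(npx_dataset(values, lod = lod, panel = panel, qc = qc))
  }

  # long layout
  need <- c("sample_id", "protein", "panel", "npx", "lod", "qc_warning")
  if (!all(need %in% names(df))) {
    stopf("long NPX file must have columns: %s", paste(need, collapse = ", "))
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  df$protein <- trimws(as.character(df$protein))
  df$panel <- trimws(as.character(df$panel))
  key <- paste(df$sample_id, df$protein, df$panel, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicate (sample, protein) row: sample '%s', protein '%s', panel '%s'",
          bad$sample_id, bad$protein, bad$panel)
  }
  pp <- unique(df[, c("protein", "panel")])
  pid_map <- make_protein_ids(pp$protein, pp$panel)
  names(pid_map) <- paste(pp$protein, pp$panel, sep = "\r")
  df$pid <- pid_map[paste(df$protein, df$panel, sep = "\r")]

  sample_ids <- unique(df$sample_id)
  protein_ids <- pid_map[!duplicated(pid_map)]
  values <- matrix(NA_real_, length(sample_ids), length(protein_ids),
                   dimnames = list(sample_ids, unname(protein_ids)))
  values[cbind(match(df$sample_id, sample_ids),
               match(df$pid, colnames(values)))] <- as.numeric(df$npx)

  lod_tab <- tapply(as.numeric(df$lod), df$pid, function(v) v[1L])
  lod <- stats::setNames(as.numeric(lod_tab), names(lod_tab))
  panel <- stats::setNames(pp$panel, unname(pid_map))

  flg <- df$qc_warning
  if (is.character(flg)) flg <- toupper(flg) %in% c("TRUE", "T", "1", "YES", "WARN")
  flg <- as.logical(flg)
  panels <- sort(unique(df$panel))
  qc <- matrix(FALSE, length(sample_ids), length(panels),
               dimnames = list(sample_ids, panels))
  agg <- tapply(flg, list(df$sample_id, df$panel), any)
  qc[rownames(agg), colnames(agg)] <- !is.na(agg) & agg

  npx_dataset(values, lod = lod, panel = panel, qc = qc)
}

#' Read and validate a clinical table
#'
#' Expected columns: `patient_id`, `gender` (`M`/`F` or 1/0, male = 1),
#' `age` (years), `disease_duration` (years), `baseline_das` (DAS28-ESR,
#' in \[0, 10\]), `delta_das` (change at 6 months) and `response`
#' (`R`/`NR` or 1/0, responder = 1).
#'
#' @param path path to a CSV/TSV file.
#' @return a validated `data.frame` (class `clinical_table`).
#' @export
read_clinical <- function(path) {
  df <- read_delim_auto(path)
  validate_clinical(df)
}

#' Validate an in-memory clinical table
#'
#' @param df data.frame with the columns documented in [read_clinical()].
#' @return the recoded, validated data.frame (class `clinical_table`).
#' @export
validate_clinical <- function(df) {
  need <- c("patient_id", "gender", "age", "disease_duration",
            "baseline_das", "delta_das", "response")
  if (!all(need %in% names(df))) {
    stopf("clinical table missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$patient_id <- trimws(as.character(df$patient_id))
  if (anyDuplicated(df$patient_id)) {
    stopf("duplicate patient id: %s", df$patient_id[duplicated(df$patient_id)][1L])
  }
  if (is.logical(df$gender)) {
    # an all-female column of "F"s parses as logical FALSE
    df$gender <- ifelse(df$gender, "M", "F")
  }
  if (is.character(df$gender)) {
    g <- toupper(trimws(df$gender))
    if (!all(g %in% c("M", "F"))) stopf("gender must be M/F or 1/0")
    df$gender <- as.numeric(g == "M")
  }
  if (is.character(df$response)) {
    r <- toupper(trimws(df$response))
    if (!all(r %in% c("R", "NR"))) stopf("response must be R/NR or 1/0")
    df$response <- as.numeric(r == "R")
  }
  if (!is_binary01(df$gender)) stopf("gender must be binary M=1/F=0")
  if (!is_binary01(df$response)) stopf("response must be binary R=1/NR=0")
  bd <- as.numeric(df$baseline_das)
  if (anyNA(bd) || any(bd < 0 | bd > 10)) {
    stopf("baseline_das must lie in [0, 10]")
  }
  df$baseline_das <- bd
  class(df) <- c("clinical_table", "data.frame")
  df
}
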