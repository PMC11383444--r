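#' Read a delimited numeric matrix
#'
#' Accepts comma- or tab-delimited text with an optional header row.
#' Validates the shape when one is expected and reports the coordinates of
#' any non-numeric cell.
#'
#' @param path File path.
#' @param expected_shape Optional `c(rows, cols)` to enforce.
#' @param header Whether the first row is a header (default: autodetect).
#' @return Numeric matrix (column names kept if a header is present).
#' @export
read_matrix <- function(path, expected_shape = NULL, header = NA) {
  if (!file.exists(path)) stop(sprintf("read_matrix: file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(cells))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  m <- suppressWarnings(apply(as.matrix(df), c(1, 2), as.numeric))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("read_matrix: non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  dimnames(m) <- if (header) list(NULL, colnames(df)) else NULL
  if (!is.null(expected_shape) && !all(dim(m) == expected_shape)) {
    stop(sprintf("read_matrix: %s has shape %dx%d, expected %dx%d",
                 path, nrow(m), ncol(m), expected_shape[1], expected_shape[2]))
  }
  m
}

#' Write a numeric matrix as delimited text
#'
#' Writes at full double precision (17 significant digits) so that
#' write-then-read round-trips are exact to well below 1e-12.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @param col_names Write a header row of column names.
#' @export
write_matrix <- function(m, path, sep = ",", col_names = !is.null(colnames(m))) {
  m <- as.matrix(m)
  lines <- apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = sep))
  if (col_names) lines <- c(paste(colnames(m), collapse = sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Save / load a run configuration
#'
#' Lossless YAML serialization of a [run_config()].
#'
#' @param config A `run_config`.
#' @param path File path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @return `load_config` returns the restored `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$modalities <- as.character(raw$modalities)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Write a cohort to disk as delimited files plus a manifest
#'
#' One file per subject per modality (time series, raw SC, gray-matter
#' volumes, morphology table) and a single manifest CSV with one row per
#' subject holding relative paths, the regression target and the class
#' label. Ground truth of a synthetic cohort, when present, is written
#' alongside (`planted_edges.csv`, `informative_columns.csv`).
#'
#' @param cohort A `maskgnn_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "maskgnn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(su) {
    id <- su$id
    paths <- list(ts = NA, sc = NA, gm = NA, morph = NA)
    if (!is.null(su$ts)) {
      paths$ts <- sprintf("%s_ts.csv", id)
      write_matrix(su$ts$values, file.path(dir, paths$ts))
    }
    if (!is.null(su$sc_raw)) {
      paths$sc <- sprintf("%s_sc.csv", id)
      write_matrix(su$sc_raw, file.path(dir, paths$sc))
    }
    if (!is.null(su$gm_volumes)) {
      paths$gm <- sprintf("%s_gm.csv", id)
      write_matrix(matrix(su$gm_volumes, ncol = 1), file.path(dir, paths$gm))
    }
    if (!is.null(su$morphology)) {
      paths$morph <- sprintf("%s_as.csv", id)
      write_matrix(su$morphology, file.path(dir, paths$morph))
    }
    data.frame(subject_id = id, ts_path = paths$ts, sc_path = paths$sc,
               gm_path = paths$gm, as_path = paths$morph,
               tr = if (!is.null(su$ts)) su$ts$tr else NA,
               target = su$y,
               label = if (is.null(su$label)) NA else su$label)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(as.data.frame(cohort$truth$planted_edges),
                     file.path(dir, "planted_edges.csv"), row.names = FALSE)
    utils::write.csv(data.frame(column = cohort$truth$informative_cols),
                     file.path(dir, "informative_columns.csv"),
                     row.names = FALSE)
  }
  invisible(mpath)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest CSV (one row per subject; paths relative to the
#' manifest's directory), validates that every listed file exists and that
#' subject ids are unique, and excludes — with a message — subjects that
#' lack a modality required by the configured task. Subjects must have at
#' least one modality.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param required Character vector of required modalities among
#'   `c("FC", "SC", "AS")` (a subject missing the corresponding files is
#'   excluded).
#' @return A `maskgnn_cohort`.
#' @export
load_cohort <- function(manifest_path, required = c("FC", "SC", "AS")) {
  if (!file.exists(manifest_path))
    stop(sprintf("load_cohort: manifest not found: %s", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(man))
    stop("load_cohort: manifest needs a subject_id column")
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup) > 0)
    stop(sprintf("load_cohort: duplicate subject_id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  base <- dirname(manifest_path)
  getpath <- function(row, col) {
    p <- man[[col]][row]
    if (is.null(p) || is.na(p) || p == "") return(NULL)
    fp <- file.path(base, p)
    if (!file.exists(fp))
      stop(sprintf("load_cohort: missing file for subject %s: %s",
                   man$subject_id[row], fp))
    fp
  }
  subjects <- list()
  excluded <- character(0)
  for (r in seq_len(nrow(man))) {
    ts_p <- getpath(r, "ts_path"); sc_p <- getpath(r, "sc_path")
    gm_p <- getpath(r, "gm_path"); as_p <- getpath(r, "as_path")
    has <- c(FC = !is.null(ts_p), SC = !is.null(sc_p) && !is.null(gm_p),
             AS = !is.null(as_p))
    if (!any(has))
      stop(sprintf("load_cohort: subject %s has no modality at all",
                   man$subject_id[r]))
    need <- intersect(required, c("FC", "SC", "AS"))
    if (!all(has[need])) {
      excluded <- c(excluded, man$subject_id[r])
      next
    }
    su <- list(id = man$subject_id[r],
               y = man$target[r],
               label = if ("label" %in% names(man) && !is.na(man$label[r]))
                 as.integer(man$label[r]) else NA_integer_)
    if (!is.null(ts_p))
      su$ts <- roi_timeseries(read_matrix(ts_p),
                              tr = if ("tr" %in% names(man)) man$tr[r] else 1)
    if (!is.null(sc_p)) su$sc_raw <- read_matrix(sc_p)
    if (!is.null(gm_p)) su$gm_volumes <- drop(read_matrix(gm_p))
    if (!is.null(as_p)) su$morphology <- read_matrix(as_p, header = TRUE)
    subjects[[length(subjects) + 1]] <- su
  }
  if (length(excluded) > 0)
    message(sprintf("load_cohort: excluded %d subject(s) missing a required modality: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  if (length(subjects) == 0)
    stop("load_cohort: no subject satisfies the modality requirements")
  q <- {
    su <- subjects[[1]]
    if (!is.null(su$ts)) ncol(su$ts$values)
    else if (!is.null(su$sc_raw)) ncol(su$sc_raw)
    else nrow(su$morphology)
  }
  structure(list(subjects = subjects, n = length(subjects), q = q,
                 roi_ids = paste0("ROI", seq_len(q)),
                 excluded = excluded),
            class = "maskgnn_cohort")
}
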