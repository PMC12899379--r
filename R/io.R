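#' Read a collection of time series from CSV
#'
#' Wide layout: one row per series, with an optional leading non-numeric
#' identifier column; all remaining cells numeric. Long layout: columns
#' `id`, `t`, `value` (row order irrelevant). All series must have equal
#' length.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param sampling_rate Optional sampling rate (Hz) to attach.
#' @return An `fbam_series`.
#' @export
read_series <- function(path, layout = c("wide", "long"),
                        sampling_rate = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("Input file not found: ", path, call. = FALSE)
  if (layout == "wide") {
    df <- readr::read_csv(path, col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)
    ids <- NULL
    if (!is.numeric(df[[1]])) {
      ids <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    }
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(bad) > 0) {
      stop("Non-numeric cells in columns: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(df)
    if (anyNA(X)) {
      rows <- which(apply(X, 1, anyNA))
      rid <- if (is.null(ids)) rows else ids[rows]
      stop("Missing values in series: ", paste(head(rid, 5), collapse = ", "),
           call. = FALSE)
    }
    fbam_series(X, series_ids = ids, sampling_rate = sampling_rate)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("id", "t", "value")
    if (!all(need %in% names(df))) {
      stop("Long layout requires columns: id, t, value.", call. = FALSE)
    }
    df <- dplyr::arrange(df, .data$id, .data$t)
    lens <- dplyr::count(df, .data$id)
    if (length(unique(lens$n)) != 1) {
      short <- lens$id[lens$n < max(lens$n)]
      stop("Unequal series lengths; offending series: ",
           paste(head(short, 5), collapse = ", "), call. = FALSE)
    }
    if (anyNA(df$value) || !is.numeric(df$value)) {
      stop("Non-numeric or missing values in `value` column.", call. = FALSE)
    }
    ids <- unique(df$id)
    X <- matrix(df$value, nrow = length(ids), byrow = TRUE)
    fbam_series(X, series_ids = as.character(ids),
                sampling_rate = sampling_rate)
  }
}

solution_to_list <- function(sol, T, sampling_rate = NULL) {
  groups <- lapply(seq_len(sol$J), function(j) {
    cuts <- sol$cuts[[j]]
    g <- list(subpopulation = j,
              cut_indices = as.integer(cuts),
              cut_frequencies = cut_frequency(cuts, T))
    if (!is.null(sampling_rate)) {
      g$cut_frequencies_hz <- g$cut_frequencies * sampling_rate
    }
    g
  })
  list(labels = as.integer(sol$labels), J = sol$J, L = sol$L,
       loss = sol$loss, groups = groups)
}

#' Write an FBAM fit to JSON
#'
#' Serializes provenance (seed, dimensions, taper count, GA settings), the
#' selected solution (labels, per-subpopulation cut indices with their
#' frequencies in cycles/sample and, when a sampling rate is known, Hz),
#' per-subpopulation collapsed measures, and the full criterion table.
#'
#' @param fit An `fbam_fit`.
#' @param path Output JSON path.
#' @param criteria_csv Optional path for a flat CSV of the criterion table
#'   (columns J, L, loss, S1, S2, scaled_sum).
#' @return `path`, invisibly.
#' @export
write_result <- function(fit, path, criteria_csv = NULL) {
  sp <- fit$spectra
  sol <- fit$best
  collapsed <- lapply(seq_len(sol$J), function(j) {
    cm <- collapsed_power(sp$power[sol$labels == j, , drop = FALSE],
                          sol$cuts[[j]], sol$w_min)
    list(subpopulation = j, band_means = cm$per_band_mean,
         band_sizes = as.integer(cm$band_sizes))
  })
  obj <- list(
    schema_version = "1.0",
    provenance = c(fit$provenance,
                   list(mode = fit$mode,
                        control = unclass(fit$control),
                        sampling_rate = sp$sampling_rate)),
    selected = list(J = fit$selected[["J"]], L = fit$selected[["L"]]),
    solution = solution_to_list(sol, sp$T, sp$sampling_rate),
    collapsed_measures = collapsed,
    criteria = list(a1 = fit$a1, a2 = fit$a2,
                    table = fit$table)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(criteria_csv)) {
    readr::write_csv(fit$table, criteria_csv)
  }
  invisible(path)
}

#' Read back a JSON result written by [write_result()]
#'
#' @param path JSON path.
#' @return The deserialized list (labels and cut indices as integers).
#' @export
read_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj$solution$labels <- as.integer(obj$solution$labels)
  obj
}
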