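#' Write an ensemble to tab-separated files
#'
#' Serializes an ensemble to a TSV table (one row per source: `source_id`,
#' `info_value`, `p_value`, `weight`), a companion null-value TSV (one row
#' per surrogate: `source_id`, `replicate_index`, `null_value`), and a JSON
#' sidecar holding the label and provenance. Numbers are written with 17
#' significant digits so that a write/read round trip reproduces every value
#' exactly.
#'
#' @param ensemble An `info_ensemble` object.
#' @param path Path of the ensemble TSV. The null table defaults to
#'   `<path minus .tsv>_nulls.tsv` and the config sidecar to
#'   `<path minus .tsv>_config.json`.
#' @param nulls_path,config_path Optional explicit companion paths; set
#'   `config_path = NA` to skip the sidecar.
#' @return The ensemble, invisibly.
#' @seealso [read_ensemble()]
#' @export
write_ensemble <- function(ensemble, path, nulls_path = NULL,
                           config_path = NULL) {
  stopifnot(inherits(ensemble, "info_ensemble"))
  stem <- sub("\\.tsv$", "", path)
  if (is.null(nulls_path)) nulls_path <- paste0(stem, "_nulls.tsv")
  if (is.null(config_path)) config_path <- paste0(stem, "_config.json")
  ids <- sprintf("src_%03d", seq_len(ensemble$n_sources))
  main <- data.frame(source_id = ids,
                     info_value = num17(ensemble$values),
                     p_value = num17(ensemble$p_values),
                     weight = num17(ensemble$weights))
  utils::write.table(main, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nulls <- data.frame(
    source_id = rep(ids, lengths(ensemble$nulls)),
    replicate_index = unlist(lapply(lengths(ensemble$nulls), seq_len)),
    null_value = num17(unlist(ensemble$nulls, use.names = FALSE)))
  utils::write.table(nulls, nulls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!isTRUE(is.na(config_path))) {
    cfg <- list(schema_version = "1.0",
                label = ensemble$label,
                n_sources = ensemble$n_sources,
                n_null_per_source = unname(lengths(ensemble$nulls)),
                provenance = ensemble$provenance)
    jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(ensemble)
}

num17 <- function(x) trimws(formatC(x, digits = 17, format = "g"))

#' Read an ensemble from tab-separated files
#'
#' Reads the TSV pair written by [write_ensemble()] (or produced by any
#' external analysis in the same layout) and validates it: unique source
#' ids, numeric values, p-values strictly inside `(0, 1]`. If the `p_value`
#' column is absent, p-values are recomputed from the null table with
#' [mc_pvalue()]; weights are always recomputed from the p-values.
#' Validation errors name the offending row and column.
#'
#' @param path Ensemble TSV path (tab-separated, header row, UTF-8).
#' @param nulls_path Companion null-table path; defaults to
#'   `<path minus .tsv>_nulls.tsv`.
#' @param config_path Optional JSON sidecar; read into the ensemble's
#'   provenance when present.
#' @return An `info_ensemble` object.
#' @export
read_ensemble <- function(path, nulls_path = NULL, config_path = NULL) {
  stem <- sub("\\.tsv$", "", path)
  if (is.null(nulls_path)) nulls_path <- paste0(stem, "_nulls.tsv")
  if (is.null(config_path)) {
    cand <- paste0(stem, "_config.json")
    config_path <- if (file.exists(cand)) cand else NA
  }
  main <- read_tsv_checked(path, required = c("source_id", "info_value"))
  ids <- main$source_id
  if (anyDuplicated(ids)) {
    stop_input("duplicate source_id in ", path, ": ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  values <- parse_numeric_column(main, "info_value", path)
  if (!file.exists(nulls_path)) {
    stop_input("null table not found: ", nulls_path,
               " (required to rebuild or KS-test the ensemble)")
  }
  ntab <- read_tsv_checked(nulls_path,
                           required = c("source_id", "null_value"))
  nvals <- parse_numeric_column(ntab, "null_value", nulls_path)
  unknown <- setdiff(unique(ntab$source_id), ids)
  if (length(unknown) > 0L) {
    stop_input("null table ", nulls_path, " references unknown source_id: ",
               paste(unknown, collapse = ", "))
  }
  nulls <- split(nvals, factor(ntab$source_id, levels = ids))
  empty <- ids[lengths(nulls) == 0L]
  if (length(empty) > 0L) {
    stop_input("sources without null values in ", nulls_path, ": ",
               paste(empty, collapse = ", "))
  }
  p_values <- NULL
  if ("p_value" %in% names(main)) {
    p_values <- parse_numeric_column(main, "p_value", path)
    bad <- which(p_values <= 0 | p_values > 1)
    if (length(bad) > 0L) {
      stop_input("column p_value in ", path, ", row ", bad[1L], ": value ",
                 main$p_value[bad[1L]], " outside (0, 1]; Monte Carlo ",
                 "p-values are floored at 1/(2*n_mc) and cannot be 0")
    }
  }
  provenance <- list()
  label <- NULL
  if (!isTRUE(is.na(config_path)) && file.exists(config_path)) {
    cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
    provenance <- cfg$provenance %||% list()
    label <- cfg$label
  }
  ens <- info_ensemble(values, unname(nulls), p_values = p_values,
                       label = label, provenance = provenance)
  ens$source_ids <- ids
  ens
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop_input("cannot parse ", path, ": ",
                                   conditionMessage(e)))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_input("malformed header in ", path, ": missing column(s) ",
               paste(missing, collapse = ", "))
  }
  tab
}

parse_numeric_column <- function(tab, column, path) {
  raw <- tab[[column]]
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) | raw == "")
  if (length(bad) > 0L) {
    stop_input("column ", column, " in ", path, ", row ", bad[1L],
               ": non-numeric value '", raw[bad[1L]], "'")
  }
  out
}
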