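# Delimited-text readers and writers. All matrices follow the web-app
# convention: identifier (CpG or gene) as the first column, one column per
# sample for the remaining columns. Readers validate aggressively so that
# silently-corrupting inputs (out-of-range betas, duplicate ids,
# non-numeric cells) fail with explicit errors.

#' Read a beta-value matrix
#'
#' Expects a header row of sample ids and a CpG identifier as the first
#' column. Values must be numeric and inside \[0 - tol, 1 + tol\] (then
#' clipped to \[0,1\]). CRLF line endings are accepted.
#'
#' @param path CSV path.
#' @param tol numeric tolerance for range validation.
#' @return CpG x sample numeric matrix.
#' @export
read_beta_matrix <- function(path, tol = 1e-6) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop_ic("beta matrix needs an id column plus at least one sample",
            class = "icclock_parse_error")
  }
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_ic("duplicate CpG identifiers: ",
            paste(utils::head(unique(dup), 5), collapse = ", "),
            class = "icclock_parse_error")
  }
  if (anyDuplicated(names(df)[-1])) {
    stop_ic("duplicate sample identifiers", class = "icclock_parse_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m))) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (nrow(bad)) {
      sprintf(" (first at row %d, column %s)", bad[1, 1],
              colnames(m)[bad[1, 2]])
    } else ""
    stop_ic("non-numeric or missing beta values", loc,
            class = "icclock_parse_error")
  }
  out_of_range <- which(m < -tol | m > 1 + tol, arr.ind = TRUE)
  if (nrow(out_of_range)) {
    i <- out_of_range[1, ]
    stop_ic(sprintf(
      "beta value %.4g outside [0,1] at CpG %s, sample %s",
      m[i[1], i[2]], ids[i[1]], colnames(m)[i[2]]),
      class = "icclock_range_error")
  }
  m <- pmin(pmax(m, 0), 1)
  rownames(m) <- ids
  m
}

#' Write a beta (or expression) matrix in the id-first-column convention
#'
#' @param m matrix with rownames (ids) and colnames (samples).
#' @param path output CSV path.
#' @param id_name header for the identifier column.
#' @export
write_beta_matrix <- function(m, path, id_name = "cpg") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#' Duplicate members are removed with a warning; empty sets are skipped
#' with a warning.
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # count fields by separators: strsplit drops trailing empties, but a
    # line like "name<tab>desc<tab>" still has three (the last empty)
    n_fields <- lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE))) + 1L
    if (n_fields < 3L) {
      stop_ic("GMT line ", i, " has fewer than 3 fields",
              class = "icclock_parse_error")
    }
    members <- if (length(parts) > 2L) parts[-(1:2)] else character(0)
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", parts[1], "'; deduplicated")
      members <- unique(members)
    }
    if (!length(members)) {
      warning("empty gene set '", parts[1], "' skipped")
      next
    }
    sets[[parts[1]]] <- members
  }
  sets
}

#' Write a clock coefficient file
#'
#' CSV with header `cpg,weight` and a reserved `(Intercept)` row, plus an
#' optional JSON sidecar with model metadata (alpha, lambda, CV metrics and
#' training mean betas for imputation).
#'
#' @param model a `clock_model`.
#' @param path output CSV path.
#' @param sidecar write `<path>.json` metadata.
#' @export
write_clock_model <- function(model, path, sidecar = TRUE) {
  df <- data.frame(cpg = c("(Intercept)", names(model$weights)),
                   weight = c(model$intercept, unname(model$weights)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(alpha = model$alpha, lambda = model$lambda,
                 cv_mae = model$cv_mae, cv_corr = model$cv_corr,
                 n_cpgs = model$n_cpgs,
                 training_means = as.list(model$training_means))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a clock coefficient file
#'
#' @param path CSV with columns `cpg,weight` and an `(Intercept)` row.
#' @return a `clock_model` usable with [predict_clock()]; metadata sidecar
#'   (if present) restores training means for mean imputation.
#' @export
read_clock_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cpg", "weight") %in% names(df))) {
    stop_ic("coefficient file must have columns cpg,weight",
            class = "icclock_parse_error")
  }
  is_int <- df$cpg == "(Intercept)"
  if (sum(is_int) != 1L) {
    stop_ic("coefficient file must contain exactly one (Intercept) row",
            class = "icclock_parse_error")
  }
  w <- df$weight[!is_int]
  names(w) <- df$cpg[!is_int]
  tm <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$training_means)) tm <- unlist(meta$training_means)
  }
  clock_model(df$weight[is_int], w, training_means = tm)
}

#' Read a cell-type reference matrix
#'
#' CSV with CpG identifiers in the first column and one column per cell
#' type; values validated as betas.
#'
#' @param path CSV path.
#' @return CpG x cell-type matrix.
#' @export
read_reference_matrix <- function(path) {
  read_beta_matrix(path)
}
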