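#' Read a delimited matrix file
#'
#' Parses a CSV or TSV matrix (header row = column ids, first column =
#' row ids). The delimiter is taken from the file extension (`.tsv` /
#' `.tab` = tab, otherwise comma) unless given. Ragged rows, duplicate
#' ids and non-numeric cells are reported with their line numbers.
#'
#' @param path file path.
#' @param role what the matrix represents: `"response"` (empty, `NA` and
#'   `NaN` cells are allowed and become masked entries), `"similarity"`
#'   (must be square and symmetric) or `"feature"` (no missing cells).
#' @param sep field separator; `NULL` = infer from extension.
#' @return for `role = "response"` a [response_matrix()]; otherwise a
#'   numeric matrix with dimnames.
#' @export
read_matrix <- function(path, role = c("response", "similarity", "feature"),
                        sep = NULL) {
  role <- match.arg(role)
  check(file.exists(path), "file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  nf <- count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    check(FALSE, "ragged row at line ", bad, " of ", path,
          " (", nf[bad], " fields, expected ", nf[1], ")")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character",
                          na.strings = character(0))
  check(ncol(df) >= 2, "need an id column plus at least one data column")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  check(length(dup) == 0, "duplicate row ids in ", path, ": ",
        paste(unique(dup), collapse = ", "))
  col_ids <- colnames(df)[-1]
  dupc <- col_ids[duplicated(col_ids)]
  check(length(dupc) == 0, "duplicate column ids in ", path, ": ",
        paste(unique(dupc), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  missing_tok <- raw == "" | toupper(raw) %in% c("NA", "NAN")
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad_cell <- which(is.na(vals) & !missing_tok, arr.ind = TRUE)
  if (nrow(bad_cell) > 0) {
    check(FALSE, "non-numeric cell '", raw[bad_cell[1, , drop = FALSE]],
          "' at line ", bad_cell[1, 1] + 1L, ", column ",
          col_ids[bad_cell[1, 2]], " of ", path)
  }
  vals[missing_tok] <- NA
  dimnames(vals) <- list(ids, col_ids)
  if (role == "response") {
    return(response_matrix(vals))
  }
  check(!anyNA(vals), "missing cells not allowed in a ", role, " matrix: ", path)
  if (role == "similarity") {
    check(nrow(vals) == ncol(vals), "similarity matrix must be square: ", path)
    check(all(rownames(vals) == colnames(vals)),
          "similarity row and column ids must match: ", path)
  }
  vals
}

#' Write a matrix as CSV with an id column
#'
#' Values are written at full double precision (`%.17g`) so that a
#' write/read round trip reproduces them bit for bit. For a
#' [response_matrix()], masked entries are written as empty cells.
#'
#' @param x numeric matrix with dimnames, or a `response_matrix`.
#' @param path output path (written atomically via a temp file).
#' @param id_name header of the id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_name = "id") {
  if (inherits(x, "response_matrix")) {
    vals <- x$R
    vals[x$W == 0] <- NA
    x <- vals
  }
  check(is.matrix(x), "x must be a matrix")
  fmt <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  fmt[is.na(x)] <- ""
  lines <- c(paste(c(id_name, colnames(x)), collapse = ","),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], fmt[i, ]), collapse = ",")
             }, character(1)))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# internal: tidy per-drug CV table writer -> (drug, repeat, metric, value)
write_cv_result <- function(cv, dir) {
  pd <- cv$per_drug
  tidy <- do.call(rbind, lapply(c("pcc", "rmse", "pcc_sr", "rmse_sr"),
    function(mname) {
      data.frame(drug = pd$drug, rep = pd$rep, metric = mname,
                 value = pd[[mname]], stringsAsFactors = FALSE)
    }))
  utils::write.table(tidy, file.path(dir, "per_drug.csv"), sep = ",",
                     row.names = FALSE, qmethod = "double")
  utils::write.table(cv$summary, file.path(dir, "summary.csv"), sep = ",",
                     row.names = FALSE, qmethod = "double")
  invisible(dir)
}

# internal: reproducibility manifest written next to every CLI output
write_manifest <- function(dir, command, args, extra = list()) {
  manifest <- c(list(
    command = command,
    arguments = args,
    package_version = as.character(utils::packageVersion("wgrmf")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
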