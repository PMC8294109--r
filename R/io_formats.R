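#' Read an omics matrix from TSV/CSV
#'
#' Expects features in rows and samples in columns: the first row holds sample
#' ids, the first column feature ids. Empty cells and `NA` become missing
#' values; any other non-numeric cell is an error naming the offending
#' feature/sample.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param kind `"expression"` or `"methylation"` (enables the beta-range
#'   check).
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2) stop("expected a feature-id column plus >=1 sample column")
  fid <- df[[1]]
  sid <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], fid[bad[1, 1]], sid[bad[1, 2]]))
  dimnames(num) <- list(fid, sid)
  omics_matrix(num, kind = kind)
}

#' Write an omics matrix to TSV/CSV
#'
#' Inverse of [read_omics_matrix()]: feature ids in the first column,
#' sample ids in the header. Missing values are written as empty cells.
#'
#' @param x Matrix with dimnames.
#' @param path Output file path (extension picks the delimiter).
#' @export
write_omics_matrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time`, `vital_status`; `age` and `sex`
#' are carried along if present. Rows with missing or non-positive survival
#' time are dropped (with a message reporting the count). `vital_status` is
#' mapped case-insensitively: dead/deceased -> event 1, alive/censored ->
#' event 0; anything else errors naming the row.
#'
#' @param path TSV/CSV file path.
#' @return A [survival_table()].
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("sample_id", "os_time", "vital_status")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  status <- tolower(trimws(as.character(df$vital_status)))
  event <- ifelse(status %in% c("dead", "deceased"), 1L,
                  ifelse(status %in% c("alive", "censored"), 0L, NA_integer_))
  if (anyNA(event)) {
    i <- which(is.na(event))[1]
    stop(sprintf("unparseable vital_status '%s' for sample '%s' (row %d)",
                 df$vital_status[i], df$sample_id[i], i))
  }
  time <- suppressWarnings(as.numeric(df$os_time))
  keep <- !is.na(time) & time > 0
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped: missing or non-positive os_time")
  survival_table(df$sample_id[keep], time[keep], event[keep],
                 age = if ("age" %in% colnames(df)) df$age[keep],
                 sex = if ("sex" %in% colnames(df)) df$sex[keep])
}

#' Read / write a probe-to-gene map (TSV with columns locus_id, gene_id)
#'
#' @param path File path.
#' @return `read_probe_map` returns a [probe_gene_map()] data frame.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("locus_id", "gene_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  probe_gene_map(df$locus_id, df$gene_id)
}

#' @rdname read_probe_map
#' @param map A probe-gene map data frame.
#' @export
write_probe_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clinical table in the input format
#'
#' @param surv A [survival_table()].
#' @param path Output path.
#' @export
write_clinical_table <- function(surv, path) {
  df <- data.frame(sample_id = surv$sample_id, os_time = surv$time,
                   vital_status = ifelse(surv$event == 1, "dead", "alive"),
                   stringsAsFactors = FALSE)
  if (!is.null(surv$age)) df$age <- surv$age
  if (!is.null(surv$sex)) df$sex <- surv$sex
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
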