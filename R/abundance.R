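#' Read a taxa-abundance table
#'
#' Reads a tab-separated taxa-abundance table (FEAST/SourceTracker style:
#' a numeric body with taxon and sample identifiers on the margins) into a
#' numeric matrix with taxa in rows and samples in columns.
#'
#' @param path Path to a TSV file. The first column (or row, depending on
#'   `orientation`) holds identifiers; the first header cell is ignored.
#' @param orientation Either `"taxa-in-rows"` (default) or
#'   `"taxa-in-columns"`; the returned matrix always has taxa in rows.
#' @return A non-negative numeric matrix with unique `rownames` (taxon ids)
#'   and `colnames` (sample ids).
#' @seealso [align_taxa()], [normalize_columns()], [write_proportions()]
#' @export
read_abundance_table <- function(path,
                                 orientation = c("taxa-in-rows",
                                                 "taxa-in-columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("abundance table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("abundance table needs ids plus at least one ",
                           "data column: ", path, call. = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s at row '%s', column '%s' in %s",
                   dQuote(body[bad[1L], j]), ids[bad[1L]],
                   colnames(body)[j], path), call. = FALSE)
    }
    mat[, j] <- v
  }
  if (orientation == "taxa-in-columns") mat <- t(mat)
  validate_abundance(mat, path)
  mat
}

# Shared invariant checks: non-negative finite body, unique margins.
validate_abundance <- function(mat, what = "abundance table") {
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("missing or non-finite values in ", what, call. = FALSE)
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative abundance at taxon '%s', sample '%s' in %s",
                 rownames(mat)[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]],
                 what), call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate taxon ids in ", what, ": ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate sample ids in ", what, ": ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "), call. = FALSE)
  }
  invisible(mat)
}

#' Align two abundance tables on a common taxon set
#'
#' Expands both tables to the sorted union of their taxon ids, filling
#' taxa absent from one table with zeros. The model must see sink taxa
#' that are absent from every reference source -- they are what drives
#' mass into the unknown source -- so the union, not the intersection,
#' is used.
#'
#' @param sources,sinks Taxa-by-sample matrices with taxon `rownames`.
#' @return A list with elements `sources` and `sinks` sharing identical
#'   row ordering (lexicographic by taxon id).
#' @export
align_taxa <- function(sources, sinks) {
  taxa <- sort(union(rownames(sources), rownames(sinks)))
  if (length(taxa) == 0L) stop("empty taxon union", call. = FALSE)
  expand <- function(m) {
    out <- matrix(0, length(taxa), ncol(m),
                  dimnames = list(taxa, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  list(sources = expand(sources), sinks = expand(sinks))
}

#' Normalize columns to relative abundances
#'
#' Divides each column by its sum so that every sample is a point on the
#' taxon simplex. Raw counts and relative abundances are both accepted as
#' model input; normalization happens internally before solving.
#'
#' @param table Non-negative taxa-by-sample matrix.
#' @return Matrix of the same shape with unit column sums.
#' @export
normalize_columns <- function(table) {
  cs <- colSums(table)
  zero <- which(cs <= 0)
  if (length(zero)) {
    stop("all-zero sample column(s): ",
         paste(if (is.null(colnames(table))) zero else
               colnames(table)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(table, 2L, cs, "/")
}

#' Write estimated source proportions
#'
#' Writes one row per sink with a column per reference source plus a
#' final `Unknown` column, tab-separated. A write-then-read round trip
#' recovers the proportions to 1e-9.
#'
#' @param records A data.frame as produced by [proportion_records()]:
#'   first column `SinkID`, remaining columns proportions with the last
#'   named `Unknown`; or a list of such single-row data.frames.
#' @param path Output file path.
#' @param header_comment Optional comment line(s) written before the
#'   header, each prefixed with `# `.
#' @export
write_proportions <- function(records, path, header_comment = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  stopifnot(is.data.frame(records), colnames(records)[1L] == "SinkID")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  suppressWarnings(  # connection form warns about appending col names
    utils::write.table(format(records, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  invisible(path)
}

#' Read a proportion table written by [write_proportions()]
#'
#' @param path Path to the proportions TSV.
#' @return data.frame with `SinkID` plus one numeric column per source.
#' @export
read_proportions <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  for (j in seq_along(out)[-1L]) out[[j]] <- as.numeric(out[[j]])
  out
}

#' Assemble proportion records
#'
#' @param sink_ids Character vector of sink identifiers.
#' @param proportions Matrix (sinks in rows) or vector of proportions on
#'   the simplex; the final entry/column is the unknown source.
#' @param source_ids Reference source identifiers (without `"Unknown"`).
#' @return data.frame with columns `SinkID`, one per source, `Unknown`.
#' @export
proportion_records <- function(sink_ids, proportions, source_ids) {
  if (is.null(dim(proportions))) proportions <- matrix(proportions, 1L)
  stopifnot(length(sink_ids) == nrow(proportions),
            ncol(proportions) == length(source_ids) + 1L)
  bad <- abs(rowSums(proportions) - 1) > 1e-9 | proportions < -1e-12
  if (any(bad)) stop("proportions must lie on the simplex", call. = FALSE)
  out <- data.frame(SinkID = sink_ids, proportions,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("SinkID", source_ids, "Unknown")
  out
}

#' Read a FEAST-style metadata table
#'
#' @param path TSV with columns `SampleID` and `SourceSink` (values
#'   `source`/`sink`, case-insensitive).
#' @return List with character vectors `sources` and `sinks`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("SampleID", "SourceSink")
  if (!all(need %in% colnames(md))) {
    stop("metadata must have columns SampleID and SourceSink", call. = FALSE)
  }
  role <- tolower(md$SourceSink)
  list(sources = md$SampleID[role == "source"],
       sinks = md$SampleID[role == "sink"])
}
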