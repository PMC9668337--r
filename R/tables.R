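# Delimiter-separated tables: spectra/SAS matrices keyed by
# (subject, session, hemi), phenotype tables, pedigree tables.
# Delimiter is auto-detected among comma and tab; a header row is
# mandatory. Spectra files carry their normalization tag in a leading
# comment line.

.detectDelim <- function(path) {
  first <- readLines(path, n = 5L, warn = FALSE)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) stop("empty table: ", path)
  if (lengths(regmatches(first[1], gregexpr("\t", first[1]))) > 0) "\t"
  else ","
}

#' Read a tabular file (spectra, phenotypes, or pedigree schema)
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema one of "spectra" (returns a
#'   \linkS4class{SpectraTable}; requires subject/session/hemi key columns
#'   followed by value columns), "phenotypes" (requires a subject column),
#'   or "pedigree" (requires subject, family, zygosity columns).
#' @return A \linkS4class{SpectraTable} for schema "spectra"; a data.frame
#'   otherwise. Missing values are preserved as NA.
#' @export
readTable <- function(path, schema = c("spectra", "phenotypes", "pedigree")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .detectDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, fill = FALSE)
  if (schema == "spectra") {
    key <- c("subject", "session", "hemi")
    if (!all(key %in% names(df)))
      stop("spectra schema requires columns: ", paste(key, collapse = ", "))
    valcols <- setdiff(names(df), key)
    if (!length(valcols)) stop("spectra table has no value columns")
    vals <- as.matrix(df[, valcols, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric spectra values in ", path)
    norm <- "none"
    top <- readLines(path, n = 3L, warn = FALSE)
    m <- grep("^#\\s*normalization:", top, value = TRUE)
    if (length(m)) norm <- trimws(sub("^#\\s*normalization:", "", m[[1]]))
    return(SpectraTable(df[, key], vals, normalization = norm))
  }
  if (schema == "phenotypes") {
    if (!"subject" %in% names(df))
      stop("phenotypes schema requires a 'subject' column")
    df$subject <- as.character(df$subject)
    return(df)
  }
  key <- c("subject", "family", "zygosity")
  if (!all(key %in% names(df)))
    stop("pedigree schema requires columns: ", paste(key, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$family <- as.character(df$family)
  df
}

#' Write a tabular file
#'
#' @param x a \linkS4class{SpectraTable} or a data.frame.
#' @param path output path; extension .tsv selects tab, anything else comma.
#' @param valuePrefix column-name prefix for spectra value columns
#'   ("ev" for eigenvalues, "sas" for SAS tables).
#' @return The path, invisibly.
#' @export
writeTable <- function(x, path, valuePrefix = "ev") {
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  if (is(x, "SpectraTable")) {
    k <- ncol(x@values)
    cols <- sprintf("%s%04d", valuePrefix, seq_len(k))
    df <- cbind(x@info, as.data.frame(x@values))
    names(df) <- c(names(x@info), cols)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# normalization: ", x@normalization), con)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                       con, sep = delim, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(x, path, sep = delim, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
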