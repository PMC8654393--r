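# Shared formats: strict delimited tables (comma, header, '.' decimal,
# UTF-8) with full-precision round trip, and a JSON-based structured results
# container with metadata and a config hash.

#' Write / read a delimited table with a lossless numeric round trip
#'
#' Comma separator, header row, '.' decimal; numeric columns are written
#' with 17 significant digits so values round-trip exactly. Malformed input
#' (ragged rows, decimal commas) is rejected with the offending line.
#'
#' @param table a data.frame
#' @param path file path
#' @export
write_table <- function(table, path) {
  tab <- as.data.frame(table)
  fmt <- lapply(tab, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(paste(names(tab), collapse = ","),
             do.call(paste, c(fmt, sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty table file: ", path)
  nf <- count.fields(textConnection(lines), sep = ",", quote = "\"")
  if (any(nf != nf[[1]])) {
    bad <- which(nf != nf[[1]])[[1]]
    stop("ragged row at line ", bad, " of ", path, " (", nf[[bad]],
         " fields, expected ", nf[[1]], ")")
  }
  tab <- read.csv(textConnection(lines), stringsAsFactors = FALSE,
                  colClasses = "character")
  numeric_re <- "^\\s*[-+]?([0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?|Inf|NaN)\\s*$"
  for (j in seq_along(tab)) {
    col <- tab[[j]]
    if (any(grepl("^-?[0-9]+,[0-9]+", col)))
      stop("decimal comma detected in column '", names(tab)[[j]],
           "'; this dialect requires '.' decimals")
    ok <- grepl(numeric_re, col) | col %in% c("", "NA")
    if (all(ok) && any(grepl(numeric_re, col)))
      tab[[j]] <- suppressWarnings(as.numeric(col))
  }
  tab
}

.num17 <- function(x) sprintf("%.17g", x)

#' Write / read a structured results container
#'
#' JSON container holding named (possibly nested) values and arrays plus
#' metadata: package version, seeds, and a hash of the configuration used.
#' Doubles are serialized at 17 significant digits.
#'
#' @param x a (possibly nested) list of numeric/character/logical values,
#'   vectors and matrices
#' @param path file path
#' @param meta optional named list of metadata (seeds, config, ...)
#' @export
write_container <- function(x, path, meta = list()) {
  meta$package_version <- as.character(utils::packageVersion("cmcdcm"))
  meta[["config_hash"]] <- config_hash(meta[["config"]])
  obj <- list(meta = meta, payload = x)
  json <- jsonlite::serializeJSON(obj, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  if (!is.null(obj$meta[["config"]])) {
    h <- config_hash(obj$meta[["config"]])
    if (!identical(h, obj$meta$config_hash))
      warning("container config hash mismatch (provenance check failed)")
  }
  obj
}

#' Hash of a configuration object (md5 of its canonical JSON)
#' @param config any serializable object (NULL gives a fixed hash)
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
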