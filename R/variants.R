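#' Parse a missense variant list
#'
#' Accepts either single-token notation (\code{"K329E"}: wild-type residue,
#' 1-based query position, alternate residue) or a 3-column table
#' (position, wt, alt). Input may be a file path (one token per line, or a
#' TSV with an optional header) or a character vector of tokens. Duplicates
#' are preserved in input order.
#'
#' @param x file path or character vector.
#' @return data.frame with columns \code{position}, \code{wt}, \code{alt},
#'   \code{token}.
#' @examples
#' parseVariants(c("K329E", "D10Y"))
#' @export
parseVariants <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) stop("no variants in file: ", x)
    if (any(grepl("\t", lines, fixed = TRUE))) {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(fields) < 3L))
        stop("variant TSV needs 3 columns: position, wt, alt")
      # drop a header row if the first field is not numeric
      if (is.na(suppressWarnings(as.numeric(fields[[1L]][1L]))))
        fields <- fields[-1L]
      tokens <- vapply(fields, function(f)
        paste0(toupper(f[2L]), f[1L], toupper(f[3L])), character(1L))
    } else {
      tokens <- toupper(lines)
    }
  } else {
    tokens <- toupper(as.character(x))
  }
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- tokens[lengths(m) == 0L]
  if (length(bad))
    stop("malformed variant token(s): ", paste(bad, collapse = " "))
  wt <- vapply(m, `[`, character(1L), 2L)
  pos <- as.integer(vapply(m, `[`, character(1L), 3L))
  alt <- vapply(m, `[`, character(1L), 4L)
  nonStd <- !(wt %in% AA_STANDARD) | !(alt %in% AA_STANDARD)
  if (any(nonStd))
    stop("non-standard residue in variant(s): ",
         paste(tokens[nonStd], collapse = " "))
  if (any(pos < 1L))
    stop("variant position must be >= 1")
  same <- wt == alt
  if (any(same))
    stop("wild type equals alternate in variant(s): ",
         paste(tokens[same], collapse = " "))
  data.frame(position = pos, wt = wt, alt = alt, token = tokens)
}

# Normalize a variant given as token, list, or 1-row data.frame to a list
# with position / wt / alt.
.asVariant <- function(v) {
  if (is.character(v) && length(v) == 1L) {
    df <- parseVariants(v)
    return(list(position = df$position, wt = df$wt, alt = df$alt))
  }
  if (is.data.frame(v)) {
    stopifnot(nrow(v) == 1L)
    v <- as.list(v)
  }
  stopifnot(all(c("position", "wt", "alt") %in% names(v)))
  list(position = as.integer(v$position),
       wt = toupper(v$wt), alt = toupper(v$alt))
}
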