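#' Round half away from zero
#'
#' Report-level rounding used throughout the package. Base [round()] rounds
#' half to even (IEEE), whereas the published tables this package reproduces
#' use conventional half-up rounding (e.g. 0.625 -> 0.63). Internal
#' arithmetic is always full precision; this is applied only when a value is
#' rendered into a report or compared against a printed table.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the precision of the
#'   published composition and RSCU tables).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.625, -0.625, 1.005))
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the epsilon absorbs binary representation error (0.615 is stored
  # fractionally below 0.615); it is far smaller than half an ulp of any
  # value this package rounds
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: collapse a character vector of single letters to one string
.collapse <- function(x) paste(x, collapse = "")

# internal: split a sequence string into single uppercase characters
.chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

# internal: stop() without the call in the message
.stop <- function(...) stop(..., call. = FALSE)

# internal: path to a bundled data file
.extdata <- function(file) {
  path <- system.file("extdata", file, package = "mitocharacter")
  if (!nzchar(path)) .stop("bundled file not found: ", file)
  path
}

# internal: read a TSV that may carry a '# key: value' metadata header block
.read_tsv_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  meta <- list()
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", lines[meta_lines])
    kv <- kv[grepl(":", kv, fixed = TRUE)]
    for (x in kv) {
      key <- trimws(sub(":.*$", "", x))
      val <- trimws(sub("^[^:]*:", "", x))
      meta[[key]] <- val
    }
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, fill = TRUE,
                           blank.lines.skip = TRUE)
  list(meta = meta, table = tab)
}
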