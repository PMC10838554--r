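# Minimal single-record GenBank flat-file dialect: enough to round-trip the
# annotation of a circular mitogenome (LOCUS topology + length, CDS / tRNA /
# rRNA / D-loop features with simple or complement() or origin-spanning
# join() locations, /gene and /product qualifiers, ORIGIN sequence block).
# No installed R package parses this format, hence the hand-rolled reader.

# parse one location string into (start, stop, strand); supports
# '123..456', 'complement(123..456)' and 'join(a..L,1..b)' origin wraps
.parse_location <- function(loc, line_no) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "H"
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      .stop("line ", line_no, ": unsupported join() location: ", loc)
    a <- .parse_span(parts[1], line_no)
    b <- .parse_span(parts[2], line_no)
    return(list(start = a[1], stop = b[2], strand = strand))
  }
  s <- .parse_span(loc, line_no)
  list(start = s[1], stop = s[2], strand = strand)
}

.parse_span <- function(x, line_no) {
  if (grepl("^[0-9]+$", x)) return(c(as.integer(x), as.integer(x)))
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (length(m) != 3) .stop("line ", line_no, ": cannot parse location: ", x)
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Parse a single-record GenBank flat file
#'
#' Reads one GenBank record (file path or character vector of lines) and
#' returns the annotation together with the sequence. Feature keys `CDS`,
#' `tRNA`, `rRNA` and `D-loop` are mapped to feature types PCG / tRNA /
#' rRNA / CR; `gene` keys are used only for elements not covered by a typed
#' key. Gene names are normalised as in [parse_feature_table()].
#'
#' @param x path to a GenBank file, or its content as a character vector.
#' @return list with elements `annotation` (a `mito_annotation`) and
#'   `sequence` (one uppercase string; empty if the record has no ORIGIN).
#' @export
parse_genbank <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE)
           else x
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    .stop("line 1: malformed GenBank header (expected LOCUS)")
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  bp_at <- which(toks == "bp")
  if (length(bp_at) != 1 || bp_at < 3)
    .stop("line 1: malformed LOCUS line (no '<length> bp')")
  glen <- suppressWarnings(as.integer(toks[bp_at - 1]))
  if (is.na(glen)) .stop("line 1: malformed LOCUS length")
  circular <- any(tolower(toks) == "circular")
  genome_id <- toks[2]

  feat_start <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  end_at <- if (length(origin_at)) origin_at[1] else
    (if (length(grep("^//", lines))) grep("^//", lines)[1]
     else length(lines) + 1)

  rows <- list()
  if (length(feat_start)) {
    i <- feat_start[1] + 1
    while (i < end_at) {
      line <- lines[i]
      # a feature line: key in columns 6-20
      if (grepl("^\\s{1,10}\\S", line) && !grepl("^\\s*/", line)) {
        key <- trimws(substr(line, 1, 21))
        loc <- trimws(substring(line, 22))
        j <- i + 1
        quals <- character()
        while (j < end_at && grepl("^\\s{12,}", lines[j])) {
          more <- trimws(lines[j])
          if (!grepl("^/", more) && !length(quals)) {
            loc <- paste0(loc, more)   # continued location
          } else quals <- c(quals, more)
          j <- j + 1
        }
        if (key %in% c("CDS", "tRNA", "rRNA", "D-loop", "gene",
                       "misc_feature")) {
          getq <- function(q) {
            hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
            if (!length(hit)) return(NA_character_)
            gsub('^"|"$', "", sub(paste0("^/", q, "="), "", hit[1]))
          }
          name <- getq("gene")
          if (is.na(name)) name <- getq("product")
          if (is.na(name) && key == "D-loop") name <- "D-loop"
          pos <- .parse_location(loc, i)
          rows[[length(rows) + 1]] <- data.frame(
            key = key, gene = if (is.na(name)) key else name,
            strand = pos$strand, start = pos$start, stop = pos$stop,
            stringsAsFactors = FALSE)
        }
        i <- j
      } else i <- i + 1
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), gene = character(), strand = character(),
               start = integer(), stop = integer())

  # prefer typed keys; keep 'gene'/'misc_feature' rows only when no typed
  # feature shares their span
  typed <- rows[rows$key %in% c("CDS", "tRNA", "rRNA", "D-loop"), ,
                drop = FALSE]
  loose <- rows[!rows$key %in% c("CDS", "tRNA", "rRNA", "D-loop"), ,
                drop = FALSE]
  if (nrow(loose)) {
    dup <- paste(loose$start, loose$stop) %in% paste(typed$start, typed$stop)
    typed <- rbind(typed, loose[!dup, , drop = FALSE])
  }
  if (!nrow(typed)) .stop("no features")
  if (any(typed$stop > glen))
    .stop("feature beyond sequence length: ",
          paste(typed$gene[typed$stop > glen], collapse = ", "))

  seq <- ""
  if (length(origin_at)) {
    end_rec <- grep("^//", lines)
    end_rec <- if (length(end_rec)) end_rec[1] else length(lines) + 1
    block <- lines[(origin_at[1] + 1):(end_rec - 1)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(block, collapse = "")))
    if (nchar(seq) != glen)
      .stop("ORIGIN sequence length (", nchar(seq),
            ") does not match LOCUS length (", glen, ")")
  }

  ann <- parse_feature_table(typed[, c("gene", "strand", "start", "stop")],
                             genome_length = glen, circular = circular,
                             genome_id = genome_id)
  list(annotation = ann, sequence = seq)
}

#' Write a minimal GenBank flat file
#'
#' Emits a single-record GenBank file readable by [parse_genbank()]:
#' LOCUS line with length and topology, typed features (`CDS`, `tRNA`,
#' `rRNA`, `D-loop`) with `/gene` qualifiers, and the ORIGIN block.
#'
#' @param ann a `mito_annotation`.
#' @param seq genome sequence (one string); must match `ann$length`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(ann, seq, path) {
  if (nchar(seq) != ann$length)
    .stop("sequence length does not match annotation length")
  f <- ann$features
  key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop",
           unknown = "misc_feature")[f$type]
  loc <- ifelse(f$stop < f$start,
                sprintf("join(%d..%d,1..%d)", f$start, ann$length, f$stop),
                sprintf("%d..%d", f$start, f$stop))
  loc <- ifelse(f$strand == "L", sprintf("complement(%s)", loc), loc)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s     VRT",
            ann$genome_id, ann$length,
            if (ann$circular) "circular" else "linear"),
    sprintf("DEFINITION  %s mitochondrion.", ann$genome_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", ann$length))
  for (i in seq_len(nrow(f))) {
    out <- c(out,
             sprintf("     %-16s%s", key[i], loc[i]),
             sprintf("                     /gene=\"%s\"", f$name[i]))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(seq)
  starts <- seq(1, nchar(s), by = 60)
  for (p in starts) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
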