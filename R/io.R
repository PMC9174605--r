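# FASTA / TSV / BED input-output. All coordinates handed to or produced by
# this file are 0-based half-open; 1-based coordinates appear only in
# human-readable reports.

#' Read genomes from a FASTA file
#'
#' One [GenomeSeq-class] per record. Sequences are uppercased and `U` is
#' mapped to `T`. A record whose header description carries the flag
#' `circular=true` is marked circular. Empty files, duplicated ids and
#' non-IUPAC characters are rejected with an error naming the offending
#' record.
#'
#' @param path path to a (multi-)FASTA file.
#' @return Named list of [GenomeSeq-class] objects.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 circular=true", "ACGT"), tf)
#' readGenomeFasta(tf)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(sQuote(dup), collapse = ", "))
  circ <- grepl("circular\\s*=\\s*true", headers, ignore.case = TRUE)
  out <- lapply(seq_along(raw), function(i)
    GenomeSeq(ids[i], as.character(raw[[i]]), circular = circ[i]))
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' Circularity is recorded as a `circular=true` flag in the description so
#' that [readGenomeFasta()] round-trips it.
#'
#' @param genomes a `GenomeSeq` or list of them.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path, width = 70L) {
  if (is(genomes, "GenomeSeq")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    hdr <- if (isCircular(g)) paste0(genomeId(g), " circular=true") else genomeId(g)
    writeLines(paste0(">", hdr), con)
    s <- as.character(genomeSeq(g))
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Declare the expected columns of a TSV table
#'
#' @param ... named column types, in order; each one of `"character"`,
#'   `"numeric"`, `"integer"`, `"logical"`.
#' @return A `tableSpec` object (named character vector).
#' @examples
#' spec <- tableSpec(taxon = "character", t_mya = "numeric", ds = "numeric")
#' @export
tableSpec <- function(...) {
  types <- c(...)
  if (is.null(names(types)) || any(!nzchar(names(types))))
    stop("all columns must be named")
  if (anyDuplicated(names(types)))
    stop("duplicate column names in table spec")
  ok <- c("character", "numeric", "integer", "logical")
  if (!all(types %in% ok))
    stop("column types must be one of: ", paste(ok, collapse = ", "))
  structure(types, class = "tableSpec")
}

.parse_numeric_cell <- function(x) {
  # scientific notation (3.44483E-11) and thousands separators (1,068)
  suppressWarnings(as.numeric(gsub(",", "", trimws(x), fixed = TRUE)))
}

#' Read a typed tab-separated table
#'
#' The header must contain every column of `spec` (extra columns are kept as
#' character). Numeric columns are parsed with scientific-notation support
#' (e.g. `3.44483E-11`) and thousands separators are stripped (`1,068` reads
#' as 1068). Unparseable cells are reported with row and column coordinates.
#'
#' @param path path to a TSV file with a header row.
#' @param spec a [tableSpec()].
#' @return data.frame with columns typed per `spec`.
#' @export
readTypedTable <- function(path, spec) {
  if (!inherits(spec, "tableSpec")) stop("spec must come from tableSpec()")
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  miss <- setdiff(names(spec), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(sQuote(miss), collapse = ", "))
  for (col in names(spec)) {
    type <- spec[[col]]
    if (type == "character") next
    raw <- df[[col]]
    if (type == "logical") {
      val <- as.logical(toupper(trimws(raw)))
    } else {
      val <- .parse_numeric_cell(raw)
      if (type == "integer") val <- as.integer(round(val))
    }
    bad <- which(is.na(val) & nzchar(trimws(raw)))
    if (length(bad))
      stop(sprintf("unparseable cell at row %d, column '%s' of %s: %s",
                   bad[1], col, path, sQuote(raw[bad[1]])))
    df[[col]] <- val
  }
  df
}

#' Write a table as TSV
#'
#' Numeric columns are written with full precision (`%.17g`) so that a
#' write/read cycle through [readTypedTable()] reproduces identical values.
#'
#' @param rows data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(rows, path) {
  out <- rows
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#'
#' 0-based half-open, six columns (chrom, start, end, name, score, strand).
#' Intervals with `end` beyond `genome_length` (when given and the genome is
#' not circular) are refused.
#'
#' @param intervals data.frame with columns `genome_id`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @param genome_length optional named vector of genome lengths for bounds
#'   checking.
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path, genome_length = NULL) {
  need <- c("genome_id", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss)) stop("missing interval column(s): ", paste(miss, collapse = ", "))
  if (nrow(intervals) && any(intervals$start < 0 | intervals$end <= intervals$start))
    stop("invalid interval: need 0 <= start < end")
  if (!is.null(genome_length) && nrow(intervals)) {
    lim <- genome_length[intervals$genome_id]
    if (any(!is.na(lim) & intervals$end > lim))
      stop("interval end exceeds genome length")
  }
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", nrow(intervals))
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0L, nrow(intervals))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep("+", nrow(intervals))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$genome_id,
                   as.integer(intervals$start), as.integer(intervals$end),
                   name, as.character(score), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Blank lines and lines starting with `#` are ignored. Values that parse as
#' numbers are returned numeric; `true`/`false` become logical.
#'
#' @param path path to the config file.
#' @return Named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", sQuote(ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' Path to a bundled data table
#'
#' The package ships transcriptions of published comparative summary tables
#' for 20 seed-plant mitogenomes (genome sizes, per-branch substitution rates
#' and divergence times, pairwise shared-DNA fractions, repeat content) used
#' by the reproduction pipeline and the test-suite.
#'
#' @param name file name under `extdata`; with no argument, lists the
#'   available files.
#' @return Full path, or a character vector of file names.
#' @export
mitocompFixture <- function(name) {
  if (missing(name))
    return(dir(system.file("extdata", package = "mitocomp")))
  p <- system.file("extdata", name, package = "mitocomp")
  if (!nzchar(p)) stop("no bundled table named ", sQuote(name))
  p
}
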