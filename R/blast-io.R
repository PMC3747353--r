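#' Read alignment hits from BLAST tabular output
#'
#' Parses 12-column BLAST tabular records (outfmt-6 style: query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore) with the SD as query and the CNV as
#' subject.  Subject coordinates are 1-based inclusive on input and
#' converted to 0-based half-open; records with `sstart > send` are
#' normalised to forward coordinates with strand `-`.  An optional 13th
#' column may carry a match mask (`"a-b,c-d"`, 1-based inclusive subject
#' segments of exactly matched bases) used by [build_matrix()] in strict
#' mode.
#'
#' @param path Path to the tabular file.
#' @param min_identity Drop hits below this percent identity (default 0).
#' @return A data.frame of hits: `sd_id`, `cnv_id`, `cnv_start`, `cnv_end`,
#'   `identity`, `aln_length`, `strand`, `mask`.  An empty file yields an
#'   empty data.frame.
#' @export
read_blast_tab <- function(path, min_identity = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  empty <- data.frame(sd_id = character(), cnv_id = character(),
                      cnv_start = integer(), cnv_end = integer(),
                      identity = numeric(), aln_length = integer(),
                      strand = character(), mask = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad))
    stop(sprintf("malformed BLAST tabular record at line %d: expected 12 (or 13) columns, got %d",
                 bad[1L], nf[bad[1L]]))
  f <- function(i) vapply(fields, `[`, character(1), i)
  sstart <- as.integer(f(9L)); send <- as.integer(f(10L))
  if (anyNA(sstart) || anyNA(send))
    stop("malformed BLAST tabular record at line ",
         which(is.na(sstart) | is.na(send))[1L], ": non-integer subject coordinates")
  rev <- sstart > send
  hits <- data.frame(
    sd_id = f(1L), cnv_id = f(2L),
    cnv_start = ifelse(rev, send, sstart) - 1L,
    cnv_end = ifelse(rev, sstart, send),
    identity = as.numeric(f(3L)),
    aln_length = as.integer(f(4L)),
    strand = ifelse(rev, "-", "+"),
    mask = if (any(nf == 13L))
      vapply(fields, function(x) if (length(x) >= 13L) x[13L] else NA_character_,
             character(1))
    else NA_character_,
    stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write alignment hits as BLAST tabular records
#'
#' Inverse of [read_blast_tab()]: emits 12-column records with 1-based
#' inclusive subject coordinates (reversed for minus-strand hits).  Query
#' coordinates, mismatches, gap opens, e-value and bit score are synthesised
#' placeholders consistent with the hit length.
#'
#' @param hits Hit data.frame as from [read_blast_tab()].
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  s1 <- hits$cnv_start + 1L
  s2 <- hits$cnv_end
  rev <- hits$strand == "-"
  rec <- data.frame(hits$sd_id, hits$cnv_id, hits$identity, hits$aln_length,
                    0L, 0L, 1L, hits$aln_length,
                    ifelse(rev, s2, s1), ifelse(rev, s1, s2),
                    0, hits$aln_length * 2)
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Serialise an alignment matrix as a TSV of runs
#'
#' One row per maximal 1-run: `cnv_id`, `sd_id`, `start`, `end` (0-based
#' half-open).  Header comments record `n_cols` and the full row set so
#' zero-run rows survive the round trip.
#'
#' @param mat An [alignment_matrix()].
#' @param path Output path.
#' @export
write_matrix_runs <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_cols=%d", mat$n_cols), con)
  writeLines(sprintf("# sd_ids=%s", paste(mat$sd_ids, collapse = ",")), con)
  writeLines("# cnv_id\tsd_id\tstart\tend", con)
  if (nrow(mat$runs))
    utils::write.table(data.frame(mat$cnv_id, mat$runs$sd_id,
                                  mat$runs$start, mat$runs$end),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Read an alignment matrix from a runs TSV
#'
#' @param path Path written by [write_matrix_runs()].
#' @return An [alignment_matrix()].
#' @export
read_matrix_runs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  n_cols <- as.integer(sub("^# n_cols=", "", grep("^# n_cols=", lines, value = TRUE)[1L]))
  sd_line <- grep("^# sd_ids=", lines, value = TRUE)
  sd_ids <- if (length(sd_line))
    strsplit(sub("^# sd_ids=", "", sd_line[1L]), ",", fixed = TRUE)[[1L]]
  else NULL
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) return(alignment_matrix("NA", n_cols, sd_ids = sd_ids))
  fields <- strsplit(body, "\t", fixed = TRUE)
  runs <- data.frame(sd_id = vapply(fields, `[`, character(1), 2L),
                     start = as.integer(vapply(fields, `[`, character(1), 3L)),
                     end = as.integer(vapply(fields, `[`, character(1), 4L)),
                     stringsAsFactors = FALSE)
  alignment_matrix(vapply(fields, `[`, character(1), 1L)[1L], n_cols, runs,
                   sd_ids = sd_ids)
}

#' Read BED intervals
#'
#' Reads BED3+ records (0-based half-open) into an interval data.frame; a
#' missing name column is filled with `region_<i>`.
#'
#' @param path Path to a BED file.
#' @return A data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(chrom = vapply(fields, `[`, character(1), 1L),
                   start = as.integer(vapply(fields, `[`, character(1), 2L)),
                   end = as.integer(vapply(fields, `[`, character(1), 3L)),
                   name = vapply(fields, function(x)
                     if (length(x) >= 4L) x[4L] else NA_character_, character(1)),
                   stringsAsFactors = FALSE)
  df$name[is.na(df$name)] <- sprintf("region_%d", which(is.na(df$name)))
  df
}

#' Write intervals as BED
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  name <- if (is.null(intervals$name))
    sprintf("region_%d", seq_len(nrow(intervals))) else intervals$name
  utils::write.table(data.frame(intervals$chrom, intervals$start,
                                intervals$end, name),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write duplicon calls as BED6+2
#'
#' Columns: CNV id (chrom slot), start, end, duplicon name, score (copy
#' number rounded to integer), strand (`.`), then `p_value` and
#' `state_label`.  Records are sorted by (chrom, start).
#'
#' @param calls Call data.frame from [call_duplicons()].
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tstrand\tp_value\tstate_label", con)
  if (!nrow(calls)) return(invisible(NULL))
  calls <- calls[order(calls$cnv_id, calls$start), , drop = FALSE]
  name <- sprintf("%s_dup%d", calls$cnv_id, seq_len(nrow(calls)))
  utils::write.table(data.frame(calls$cnv_id, calls$start, calls$end, name,
                                round(calls$copy_number), ".",
                                calls$p_value, calls$state_label),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read duplicon calls written by [write_calls_bed()]
#'
#' @param path Path to the BED6+2 file.
#' @return A data.frame with `cnv_id`, `start`, `end`, `name`, `score`,
#'   `p_value`, `state_label`.
#' @export
read_calls_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(cnv_id = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      p_value = numeric(), state_label = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(cnv_id = vapply(fields, `[`, character(1), 1L),
             start = as.integer(vapply(fields, `[`, character(1), 2L)),
             end = as.integer(vapply(fields, `[`, character(1), 3L)),
             name = vapply(fields, `[`, character(1), 4L),
             score = as.integer(vapply(fields, `[`, character(1), 5L)),
             p_value = as.numeric(vapply(fields, `[`, character(1), 7L)),
             state_label = vapply(fields, `[`, character(1), 8L),
             stringsAsFactors = FALSE)
}

#' Read duplicon occurrences from TSV
#'
#' Expected columns: `duplicon_id`, `chrom`, `start`, `end`, `identity`,
#' `length` (tab-separated, with header).
#'
#' @param path Path to the TSV.
#' @return An occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write duplicon occurrences as TSV
#' @param occurrences Occurrence data.frame.
#' @param path Output path.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.table(occurrences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read chromosome sizes from a two-column TSV
#' @param path Path to `<chrom>\t<size>` records.
#' @return Named numeric vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Write a binary profile matrix as TSV
#' @param profiles Matrix from [build_profiles()].
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(data.frame(segment = rownames(profiles), profiles,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a profile matrix written by [write_profiles()]
#' @param path Path to the TSV.
#' @return Binary matrix with segment rownames.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (or `key=value`); `#` starts a comment.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
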