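#' Construct a binary alignment matrix in run-list form
#'
#' An alignment matrix records, for one CNV, which positions of the CNV are
#' covered by each segmental duplication (SD) that aligns to it: entry
#' (i, j) is 1 when SD i aligns over position j.  Because covered positions
#' come in long contiguous stretches, the matrix is stored sparsely as
#' maximal runs of 1s per row rather than as a dense 0/1 matrix.
#'
#' @param cnv_id Identifier of the CNV the matrix describes.
#' @param n_cols Length of the CNV in bases (number of matrix columns).
#' @param runs A data.frame with columns `sd_id`, `start`, `end` giving the
#'   maximal 1-runs of each row in 0-based half-open coordinates.  Runs
#'   belonging to one `sd_id` must be disjoint and non-adjacent (maximal).
#' @param sd_ids Optional character vector fixing the row order; defaults to
#'   the sorted unique `sd_id` values in `runs`.
#'
#' @return An object of class `alignment_matrix`: a list with elements
#'   `cnv_id`, `n_cols`, `m` (number of rows), `sd_ids` and `runs`.
#' @seealso [build_matrix()] to construct one from alignment hits,
#'   [column_stats()] for the per-column summaries used by the HMM.
#' @export
alignment_matrix <- function(cnv_id, n_cols, runs = NULL, sd_ids = NULL) {
  if (is.null(runs)) {
    runs <- data.frame(sd_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }
  n_cols <- as.integer(n_cols)
  if (length(n_cols) != 1L || is.na(n_cols) || n_cols < 1L)
    stop("`n_cols` must be a single positive integer")
  runs <- data.frame(sd_id = as.character(runs$sd_id),
                     start = as.integer(runs$start),
                     end = as.integer(runs$end),
                     stringsAsFactors = FALSE)
  if (nrow(runs)) {
    if (any(runs$start >= runs$end))
      stop("all runs must satisfy start < end")
    if (any(runs$start < 0L) || any(runs$end > n_cols))
      stop("runs must lie within [0, n_cols)")
    runs <- runs[order(runs$sd_id, runs$start), , drop = FALSE]
    rownames(runs) <- NULL
    by_row <- split(runs, runs$sd_id)
    ok <- vapply(by_row, function(r) {
      nrow(r) < 2L || all(r$start[-1L] > r$end[-nrow(r)])
    }, logical(1))
    if (!all(ok))
      stop("runs within a row must be disjoint and non-adjacent (maximal): ",
           paste(names(by_row)[!ok], collapse = ", "))
  }
  if (is.null(sd_ids)) sd_ids <- sort(unique(runs$sd_id))
  sd_ids <- as.character(sd_ids)
  if (!all(runs$sd_id %in% sd_ids))
    stop("`runs` contains sd_ids absent from `sd_ids`")
  structure(list(cnv_id = as.character(cnv_id), n_cols = n_cols,
                 m = length(sd_ids), sd_ids = sd_ids, runs = runs),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("alignment_matrix: CNV '%s', %d SD rows x %d columns, %d runs\n",
              x$cnv_id, x$m, x$n_cols, nrow(x$runs)))
  if (nrow(x$runs)) {
    ones <- sum(x$runs$end - x$runs$start)
    cat(sprintf("  1s: %d (density %.4f)\n", ones,
                ones / (x$m * as.numeric(x$n_cols))))
  }
  invisible(x)
}

#' @export
as.matrix.alignment_matrix <- function(x, ...) {
  dense <- matrix(0L, nrow = x$m, ncol = x$n_cols,
                  dimnames = list(x$sd_ids, NULL))
  if (nrow(x$runs)) {
    ri <- match(x$runs$sd_id, x$sd_ids)
    for (k in seq_len(nrow(x$runs)))
      dense[ri[k], (x$runs$start[k] + 1L):x$runs$end[k]] <- 1L
  }
  dense
}

#' Build an alignment matrix from alignment hits
#'
#' Rows are indexed by distinct SD: all HSPs of one SD against the CNV are
#' OR-ed into a single row, with overlapping or book-ended spans merged into
#' maximal runs.  Strand is ignored (coverage is orientation-free).  When a
#' hit carries a non-`NA` `mask` field (see [read_blast_tab()]), only the
#' masked match segments are marked rather than the whole HSP span.
#'
#' @param hits A data.frame of alignment hits as returned by
#'   [read_blast_tab()]; all rows must have `cnv_id` equal to `cnv_id`.
#' @param cnv_id Identifier of the target CNV.
#' @param cnv_len Length of the CNV in bases; must be at least the largest
#'   `cnv_end` among the hits.
#' @return An [alignment_matrix()].
#' @examples
#' hits <- data.frame(sd_id = c("s1", "s1"), cnv_id = "c1",
#'                    cnv_start = c(0L, 3L), cnv_end = c(5L, 8L),
#'                    identity = 99, aln_length = 5L, strand = "+")
#' build_matrix(hits, "c1", 10)$runs   # single merged run [0, 8)
#' @export
build_matrix <- function(hits, cnv_id, cnv_len) {
  cnv_len <- as.integer(cnv_len)
  if (is.null(hits) || nrow(hits) == 0L)
    return(alignment_matrix(cnv_id, cnv_len))
  if (!all(hits$cnv_id == cnv_id))
    stop("all hits must target CNV '", cnv_id, "'")
  bad <- which(hits$cnv_end > cnv_len | hits$cnv_start < 0L)
  if (length(bad))
    stop(sprintf("hit %d (SD '%s', [%d,%d)) exceeds CNV length %d",
                 bad[1L], hits$sd_id[bad[1L]], hits$cnv_start[bad[1L]],
                 hits$cnv_end[bad[1L]], cnv_len))
  sd_id <- hits$sd_id
  start0 <- hits$cnv_start
  end0 <- hits$cnv_end
  if (!is.null(hits$mask) && any(!is.na(hits$mask))) {
    pieces <- lapply(seq_len(nrow(hits)), function(i) {
      if (is.na(hits$mask[i]))
        return(data.frame(sd_id = sd_id[i], start = start0[i], end = end0[i]))
      seg <- parse_match_mask(hits$mask[i])
      data.frame(sd_id = sd_id[i], start = seg$start, end = seg$end)
    })
    pieces <- do.call(rbind, pieces)
    sd_id <- pieces$sd_id; start0 <- pieces$start; end0 <- pieces$end
  }
  ir <- IRanges::IRanges(start = start0 + 1L, end = end0)
  merged <- IRanges::reduce(S4Vectors::split(ir, factor(sd_id)))
  lens <- S4Vectors::elementNROWS(merged)
  flat <- unlist(merged, use.names = FALSE)
  runs <- data.frame(sd_id = rep(names(merged), lens),
                     start = IRanges::start(flat) - 1L,
                     end = IRanges::end(flat),
                     stringsAsFactors = FALSE)
  alignment_matrix(cnv_id, cnv_len, runs)
}

# "a-b,c-d" 1-based inclusive subject segments -> 0-based half-open
parse_match_mask <- function(mask) {
  seg <- strsplit(strsplit(mask, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  s <- vapply(seg, function(x) as.integer(x[1L]), integer(1))
  e <- vapply(seg, function(x) as.integer(x[2L]), integer(1))
  data.frame(start = s - 1L, end = e)
}

#' Per-column counts of 1s and adjacent-column 0/1 pattern frequencies
#'
#' Computes, from the run-list representation and without materialising the
#' dense matrix, the observation sequence `o` (number of 1s per column) and,
#' for every adjacent column pair (j, j+1), the pattern counts `f11`
#' (rows with 1 in both columns), `f01` (0 then 1) and `f10` (1 then 0)
#' that drive the HMM transition probabilities.
#'
#' @param mat An [alignment_matrix()].
#' @return An object of class `column_stats`: list with integer vectors `o`
#'   (length `n_cols`), `f11`, `f01`, `f10` (length `n_cols - 1`), plus `m`
#'   and `n_cols`.
#' @export
column_stats <- function(mat) {
  stopifnot(inherits(mat, "alignment_matrix"))
  n <- mat$n_cols
  if (n < 1L) stop("empty matrix: n_cols must be >= 1")
  runs <- mat$runs
  o <- cumsum(tabulate(runs$start + 1L, nbins = n) -
              tabulate(runs$end + 1L, nbins = n))
  if (n >= 2L) {
    np <- n - 1L
    # a run [s,e) covers pair j (cols j, j+1; 1-based pair index) for
    # j in [s+1, e-1]; starts at col s+1 give an 0->1 step at pair s;
    # ends at col e give a 1->0 step at pair e (when e <= n-1)
    f11 <- cumsum(tabulate(runs$start + 1L, nbins = np) -
                  tabulate(runs$end, nbins = np))
    f01 <- tabulate(runs$start, nbins = np)
    f10 <- tabulate(runs$end, nbins = np)
  } else {
    f11 <- f01 <- f10 <- integer(0)
  }
  structure(list(o = as.integer(o), f11 = as.integer(f11),
                 f01 = as.integer(f01), f10 = as.integer(f10),
                 m = mat$m, n_cols = n),
            class = "column_stats")
}

#' @export
print.column_stats <- function(x, ...) {
  cat(sprintf("column_stats: %d columns over %d rows; max o = %d\n",
              x$n_cols, x$m, if (x$n_cols) max(x$o) else NA_integer_))
  invisible(x)
}
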