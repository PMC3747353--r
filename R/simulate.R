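#' Generate an alignment matrix with planted duplicon blocks
#'
#' Emulates the structure the duplicon decoder expects from real data:
#' true duplicons produce column blocks of 1s carried by a large fraction
#' of rows, while spurious alignments produce short scattered runs.  Each
#' planted block is covered by a full-width run in a Bernoulli
#' (`carrier_fraction`) subset of rows; background noise places, per row, a
#' Poisson(`noise_rate`) number of runs with geometric lengths (mean
#' `noise_len_mean`) at uniform positions.  Overlapping spans within a row
#' are merged into maximal runs.
#'
#' @param m Number of SD rows.
#' @param n_cols Number of columns (CNV length).
#' @param blocks A data.frame with columns `start`, `end`,
#'   `carrier_fraction` describing the planted blocks (0-based half-open,
#'   non-overlapping), or `NULL` for none.
#' @param noise_rate Expected number of background runs per row (default 2).
#' @param noise_len_mean Mean geometric length of background runs (default
#'   20 bases).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param cnv_id Identifier for the simulated CNV.
#' @return A list with `matrix` (an [alignment_matrix()]) and `truth` (a
#'   list with the block table including realised `carriers` counts and the
#'   per-row carrier assignment).
#' @export
generate_matrix <- function(m, n_cols, blocks = NULL, noise_rate = 2,
                            noise_len_mean = 20, seed, cnv_id = "sim_cnv") {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (noise_rate < 0) stop("`noise_rate` must be >= 0")
  if (!is.null(blocks) && nrow(blocks)) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (any(blocks$start < 0L) || any(blocks$end > n_cols))
      stop("blocks must lie within [0, n_cols)")
    if (any(blocks$carrier_fraction <= 0) || any(blocks$carrier_fraction > 1))
      stop("carrier_fraction must lie in (0, 1]")
    if (nrow(blocks) > 1L &&
        any(blocks$start[-1L] < blocks$end[-nrow(blocks)]))
      stop("planted blocks must not overlap")
  }
  set.seed(seed)
  sd_ids <- sprintf("sd_%03d", seq_len(m))
  hits <- list()
  carrier <- NULL
  if (!is.null(blocks) && nrow(blocks)) {
    carrier <- matrix(FALSE, nrow = m, ncol = nrow(blocks))
    for (b in seq_len(nrow(blocks))) {
      carrier[, b] <- stats::runif(m) < blocks$carrier_fraction[b]
      rows <- which(carrier[, b])
      if (length(rows))
        hits[[length(hits) + 1L]] <- data.frame(
          sd_id = sd_ids[rows], start = blocks$start[b], end = blocks$end[b],
          stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(m)) {
    k <- stats::rpois(1L, noise_rate)
    if (k == 0L) next
    lens <- pmin(1L + stats::rgeom(k, prob = 1 / noise_len_mean), n_cols)
    starts <- vapply(lens, function(l)
      sample.int(n_cols - l + 1L, 1L) - 1L, integer(1))
    hits[[length(hits) + 1L]] <- data.frame(
      sd_id = sd_ids[i], start = starts, end = starts + lens,
      stringsAsFactors = FALSE)
  }
  if (length(hits)) {
    spans <- do.call(rbind, hits)
    ir <- IRanges::IRanges(spans$start + 1L, spans$end)
    merged <- IRanges::reduce(S4Vectors::split(ir, factor(spans$sd_id)))
    lens <- S4Vectors::elementNROWS(merged)
    flat <- unlist(merged, use.names = FALSE)
    runs <- data.frame(sd_id = rep(names(merged), lens),
                       start = IRanges::start(flat) - 1L,
                       end = IRanges::end(flat), stringsAsFactors = FALSE)
  } else {
    runs <- NULL
  }
  mat <- alignment_matrix(cnv_id, n_cols, runs, sd_ids = sd_ids)
  truth_blocks <- if (!is.null(blocks) && nrow(blocks)) {
    cbind(blocks, carriers = colSums(carrier))
  } else {
    data.frame(start = integer(), end = integer(),
               carrier_fraction = numeric(), carriers = integer())
  }
  list(matrix = mat,
       truth = list(blocks = truth_blocks, carrier = carrier,
                    seed = as.integer(seed)))
}

#' Generate grouped duplication segments with shared duplicons
#'
#' Emulates the clustering structure of duplication segments that descend
#' from common seeding blocks: segments within a group share most of the
#' group's duplicons while cross-group sharing is absent.  One designated
#' core duplicon per group is forced into more than 67% of the group's
#' segments (80% by construction).
#'
#' @param n_groups Number of duplication groups.
#' @param segments_per_group Segments per group.
#' @param duplicons_per_group Distinct duplicons private to each group
#'   (default 12, so segments pass the 10-duplicon profiling threshold).
#' @param sharing Probability that a segment carries each non-core group
#'   duplicon (in (0, 1]).
#' @param seed Integer seed.
#' @param segment_len Length of each simulated segment in bases.
#' @return A list with `segments` (interval data.frame), `occurrences`
#'   (duplicon occurrence data.frame with identity 99 and length 500),
#'   `groups` (named vector segment -> group) and `cores` (named vector
#'   group -> core duplicon id).
#' @export
generate_segment_set <- function(n_groups, segments_per_group,
                                 duplicons_per_group = 12L, sharing = 0.9,
                                 seed, segment_len = 10000L) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (sharing <= 0 || sharing > 1) stop("`sharing` must lie in (0, 1]")
  set.seed(seed)
  segs <- list(); occs <- list()
  groups <- character(0); cores <- character(0)
  occ_len <- 500L
  # segments must be long enough to hold every group duplicon
  segment_len <- max(as.integer(segment_len),
                     duplicons_per_group * occ_len * 2L)
  for (g in seq_len(n_groups)) {
    dups <- sprintf("g%d_dup%02d", g, seq_len(duplicons_per_group))
    core <- dups[1L]
    cores[sprintf("group_%d", g)] <- core
    n_core <- ceiling(0.8 * segments_per_group)
    core_in <- sample.int(segments_per_group, n_core)
    for (s in seq_len(segments_per_group)) {
      seg_name <- sprintf("g%d_seg%02d", g, s)
      chrom <- seg_name   # each segment on its own contig
      present <- dups[c(s %in% core_in,
                        stats::runif(duplicons_per_group - 1L) < sharing)]
      starts <- seq(0L, by = occ_len * 2L, length.out = length(present))
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = 0L, end = as.integer(segment_len),
        name = seg_name, stringsAsFactors = FALSE)
      groups[seg_name] <- sprintf("group_%d", g)
      if (length(present))
        occs[[length(occs) + 1L]] <- data.frame(
          duplicon_id = present, chrom = chrom, start = starts,
          end = starts + occ_len, identity = 99, length = occ_len,
          stringsAsFactors = FALSE)
    }
  }
  list(segments = do.call(rbind, segs), occurrences = do.call(rbind, occs),
       groups = groups, cores = cores)
}

#' Generate a CNV with planted flanking duplicon pairs
#'
#' Places `n_pairs` duplicons once in the left 25% window and once in the
#' right 25% window of a CNV, plus filler occurrences in the middle half,
#' so the planted pair count is the exact cross-product expected from
#' [flanking_pairs()].
#'
#' @param cnv_len CNV length in bases (>= 100).
#' @param n_pairs Number of planted flanking duplicon pairs.
#' @param seed Integer seed.
#' @param n_fillers Number of filler occurrences in the middle half
#'   (default 3).
#' @return A list with `cnv` (single-row interval data.frame) and
#'   `occurrences`.
#' @export
generate_flanked_cnv <- function(cnv_len, n_pairs, seed, n_fillers = 3L) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (cnv_len < 100L) stop("`cnv_len` must be >= 100")
  set.seed(seed)
  w <- floor(0.25 * cnv_len)
  occ_len <- max(50L, min(200L, w %/% 2L))
  place <- function(lo, hi) {   # uniform start of a fully contained copy
    lo + sample.int(hi - lo - occ_len + 1L, 1L) - 1L
  }
  occs <- list()
  for (i in seq_len(n_pairs)) {
    id <- sprintf("flank_dup%02d", i)
    s_left <- place(0L, w)
    s_right <- place(cnv_len - w, cnv_len)
    occs[[length(occs) + 1L]] <- data.frame(
      duplicon_id = c(id, id), chrom = "sim_chr",
      start = c(s_left, s_right), end = c(s_left, s_right) + occ_len,
      identity = 99, length = occ_len, stringsAsFactors = FALSE)
  }
  mid_lo <- w + occ_len
  mid_hi <- cnv_len - w - occ_len
  for (i in seq_len(n_fillers)) {
    if (mid_hi - mid_lo <= occ_len) break
    s <- place(mid_lo, mid_hi)
    occs[[length(occs) + 1L]] <- data.frame(
      duplicon_id = sprintf("mid_dup%02d", i), chrom = "sim_chr",
      start = s, end = s + occ_len, identity = 99, length = occ_len,
      stringsAsFactors = FALSE)
  }
  occurrences <- if (length(occs)) do.call(rbind, occs) else
    data.frame(duplicon_id = character(), chrom = character(),
               start = integer(), end = integer(), identity = numeric(),
               length = integer(), stringsAsFactors = FALSE)
  rownames(occurrences) <- NULL
  list(cnv = data.frame(chrom = "sim_chr", start = 0L,
                        end = as.integer(cnv_len), name = "sim_cnv",
                        stringsAsFactors = FALSE),
       occurrences = occurrences)
}
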