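#' Binary phylogenetic profiles of duplication segments
#'
#' A duplication segment (an SD or CNV interval) is profiled by the
#' presence (1) or absence (0) of each duplicon: a bit is set when an
#' occurrence of the duplicon with identity at least `min_identity` percent
#' and length at least `min_len` bases overlaps the segment.  Segments with
#' fewer than `min_duplicons` distinct duplicons present are dropped, and
#' duplicons absent from every retained segment are dropped from the index.
#'
#' @param segments A data.frame of intervals with columns `chrom`, `start`,
#'   `end`, `name` (0-based half-open).
#' @param occurrences A data.frame of duplicon occurrences with columns
#'   `duplicon_id`, `chrom`, `start`, `end`, `identity`, `length`.
#' @param min_duplicons Minimum distinct duplicons a segment must carry to
#'   be profiled (default 10).
#' @param min_identity Minimum percent identity of an occurrence (default
#'   95).
#' @param min_len Minimum occurrence length in bases (default 100).
#' @return A binary matrix, rows named by segment, columns by duplicon.
#' @export
build_profiles <- function(segments, occurrences, min_duplicons = 10L,
                           min_identity = 95, min_len = 100L) {
  occ <- occurrences[occurrences$identity >= min_identity &
                     occurrences$length >= min_len, , drop = FALSE]
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
    IRanges::IRanges(segments$start + 1L, segments$end))
  dup_ids <- sort(unique(occ$duplicon_id))
  prof <- matrix(0L, nrow = nrow(segments), ncol = length(dup_ids),
                 dimnames = list(segments$name, dup_ids))
  if (nrow(occ) && length(dup_ids)) {
    occ_gr <- GenomicRanges::GRanges(occ$chrom,
      IRanges::IRanges(occ$start + 1L, occ$end))
    hits <- GenomicRanges::findOverlaps(seg_gr, occ_gr)
    prof[cbind(S4Vectors::queryHits(hits),
               match(occ$duplicon_id[S4Vectors::subjectHits(hits)], dup_ids))] <- 1L
  }
  prof <- prof[rowSums(prof) >= min_duplicons, , drop = FALSE]
  prof[, colSums(prof) > 0L, drop = FALSE]
}

#' Hamming-fraction distance between two phylogenetic profiles
#'
#' The distance is the fraction of discordant bits.  Profiles that share no
#' duplicon (zero dot product) are additionally flagged as having no related
#' evolutionary history via the `"unrelated"` attribute.
#'
#' @param a,b Binary vectors over the same duplicon index.
#' @return The Hamming fraction in `[0, 1]`, with attribute `unrelated`.
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("profiles must share the same duplicon index")
  d <- mean(a != b)
  attr(d, "unrelated") <- sum(a * b) == 0
  d
}

#' Pairwise Hamming-fraction distances for a profile matrix
#'
#' @param profiles Binary matrix from [build_profiles()].
#' @return A `dist` object over the segments.
#' @export
profile_dist <- function(profiles) {
  stats::dist(profiles, method = "manhattan") / ncol(profiles)
}

#' Neighbor-joining tree of duplication segments
#'
#' Agglomerates segments by the standard neighbor-joining algorithm on
#' their profile distances.  Leaves are ordered lexicographically before
#' agglomeration so the result is deterministic.  NJ reconstructs the
#' generating tree (topology and branch lengths) exactly when the input
#' distances are additive.
#'
#' @param distances A `dist` object or symmetric zero-diagonal matrix over
#'   at least 3 segments.
#' @return An [ape] `phylo` tree, serialisable with [ape::write.tree()].
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 segments")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  ord <- order(rownames(d))
  ape::nj(stats::as.dist(d[ord, ord]))
}

# tips (integer indices) descending from each internal node of a phylo tree
clade_tips <- function(tree) {
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  lapply(parts, function(idx) labels[idx])
}

#' Core duplicons of each clade
#'
#' A core duplicon of a clade is a duplicon present in strictly more than
#' `share_threshold` of the clade's leaf segments.  Every internal node
#' with at least `min_clade` leaves is evaluated as a clade.
#'
#' @param tree A `phylo` tree over the profiled segments.
#' @param profiles Binary matrix from [build_profiles()]; its rows must
#'   cover all tree leaves.
#' @param share_threshold Sharing fraction that must be exceeded (default
#'   0.67).
#' @param min_clade Minimum clade size in leaves (default 3).
#' @return A data.frame with columns `clade`, `n_leaves`, `duplicon_id`,
#'   `share`.
#' @export
core_duplicons <- function(tree, profiles, share_threshold = 0.67,
                           min_clade = 3L) {
  missing_leaves <- setdiff(tree$tip.label, rownames(profiles))
  if (length(missing_leaves))
    stop("profiles missing for leaves: ", paste(missing_leaves, collapse = ", "))
  clades <- clade_tips(tree)
  out <- list()
  for (ci in seq_along(clades)) {
    leaves <- clades[[ci]]
    if (length(leaves) < min_clade) next
    share <- colMeans(profiles[leaves, , drop = FALSE])
    core <- which(share > share_threshold)
    if (length(core))
      out[[length(out) + 1L]] <- data.frame(
        clade = sprintf("clade_%d", ci), n_leaves = length(leaves),
        duplicon_id = colnames(profiles)[core],
        share = unname(share[core]), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(clade = character(), n_leaves = integer(),
                      duplicon_id = character(), share = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Duplicon pairs flanking the two ends of a CNV
#'
#' A pair of duplicon occurrences flanks a CNV when one lies wholly within
#' the first `end_frac` of the CNV, the other wholly within the last
#' `end_frac`, and they are copies of the same duplicon.  With sequences
#' supplied, "same duplicon" means pairwise identity `> min_sim` percent
#' and length ratio (shorter/longer) `> min_sim / 100`; without sequences
#' it means equal `duplicon_id`.  Such pairs are candidate substrates of
#' nonallelic homologous recombination.
#'
#' @param cnv A single-row data.frame (or list) with `chrom`, `start`,
#'   `end`; length must be at least 4 bases.
#' @param occurrences Duplicon occurrences as in [build_profiles()];
#'   only rows on `cnv$chrom` are considered.
#' @param end_frac Fraction of the CNV length forming each end window
#'   (default 0.25).
#' @param min_sim Percent similarity (and length-ratio) threshold, strict
#'   (default 90).
#' @param sequences Optional named character vector (or
#'   `Biostrings::DNAStringSet`) of occurrence sequences, indexed by
#'   occurrence row name, enabling the sequence-identity test.
#' @return A data.frame of qualifying pairs with the left and right
#'   occurrence coordinates and duplicon ids.
#' @export
flanking_pairs <- function(cnv, occurrences, end_frac = 0.25, min_sim = 90,
                           sequences = NULL) {
  len <- cnv$end - cnv$start
  if (len < 4L) stop("CNV too short to define end windows (length < 4)")
  w <- floor(end_frac * len)
  left <- c(cnv$start, cnv$start + w)
  right <- c(cnv$end - w, cnv$end)
  occ <- occurrences[occurrences$chrom == cnv$chrom, , drop = FALSE]
  in_left <- occ$start >= left[1] & occ$end <= left[2]
  in_right <- occ$start >= right[1] & occ$end <= right[2]
  li <- which(in_left)
  ri <- which(in_right)
  out <- list()
  for (i in li) for (j in ri) {
    if (i == j) next
    if (is.null(sequences)) {
      if (occ$duplicon_id[i] != occ$duplicon_id[j]) next
    } else {
      len_i <- occ$end[i] - occ$start[i]
      len_j <- occ$end[j] - occ$start[j]
      if (min(len_i, len_j) / max(len_i, len_j) <= min_sim / 100) next
      pid <- pairwise_identity(sequences[[rownames(occ)[i]]],
                               sequences[[rownames(occ)[j]]])
      if (pid <= min_sim) next
    }
    out[[length(out) + 1L]] <- data.frame(
      duplicon_left = occ$duplicon_id[i], left_start = occ$start[i],
      left_end = occ$end[i], duplicon_right = occ$duplicon_id[j],
      right_start = occ$start[j], right_end = occ$end[j],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(duplicon_left = character(), left_start = integer(),
                      left_end = integer(), duplicon_right = character(),
                      right_start = integer(), right_end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# percent identity of a global pairwise alignment (requires Biostrings)
pairwise_identity <- function(seq_a, seq_b) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("sequence-identity mode requires the Biostrings package")
  aln <- Biostrings::pairwiseAlignment(as.character(seq_a),
                                       as.character(seq_b))
  Biostrings::pid(aln)
}

#' Weighted duplicon density of a genomic region
#'
#' The weighted density of a region is the sum of the weights of the
#' duplicon occurrences belonging to the region, divided by the region
#' length.  An occurrence belongs to the region when at least half of its
#' bases fall inside; the weight of a duplicon is its frequency among the
#' training CNVs (see [duplicon_weights()]).
#'
#' @param region A single-row data.frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param occurrences Duplicon occurrences as in [build_profiles()].
#' @param weights Named numeric vector of per-duplicon weights; duplicons
#'   missing from it weigh 0.
#' @return The weighted density (weight per base).
#' @export
weighted_density <- function(region, occurrences, weights) {
  len <- region$end - region$start
  if (len < 1L) stop("region length must be >= 1")
  occ <- occurrences[occurrences$chrom == region$chrom, , drop = FALSE]
  if (!nrow(occ)) return(0)
  ov <- pmin(occ$end, region$end) - pmax(occ$start, region$start)
  inside <- ov / (occ$end - occ$start) >= 0.5
  w <- weights[occ$duplicon_id[inside]]
  w[is.na(w)] <- 0
  sum(w) / len
}

#' Per-duplicon weights from training-CNV duplicon calls
#'
#' The weight of a duplicon is the number of training CNVs that contain a
#' significant call of it.
#'
#' @param calls A data.frame of significant calls with columns `cnv_id` and
#'   `duplicon_id`.
#' @return A named numeric vector of weights.
#' @export
duplicon_weights <- function(calls) {
  if (!nrow(calls)) return(stats::setNames(numeric(0), character(0)))
  tab <- table(unique(calls[, c("duplicon_id", "cnv_id")])$duplicon_id)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Complement of merged CNV regions within chromosome bounds
#'
#' Non-CNV regions are the genomic stretches between known CNVs: CNV
#' intervals are merged and the complement is taken within each
#' chromosome's `[0, size)`.
#'
#' @param cnvs A data.frame of CNV intervals (`chrom`, `start`, `end`).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return A data.frame of non-CNV intervals with `chrom`, `start`, `end`,
#'   `name`.
#' @export
noncnv_regions <- function(cnvs, chrom_sizes) {
  gr <- GenomicRanges::GRanges(cnvs$chrom,
    IRanges::IRanges(cnvs$start + 1L, cnvs$end),
    seqlengths = chrom_sizes)
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(gr))
  gaps <- gaps[BiocGenerics::strand(gaps) == "*"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gaps)),
                   start = GenomicRanges::start(gaps) - 1L,
                   end = GenomicRanges::end(gaps),
                   stringsAsFactors = FALSE)
  df <- df[df$end > df$start, , drop = FALSE]
  df$name <- sprintf("noncnv_%d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

#' Welch's two-sample t test on density collections
#'
#' Compares weighted duplicon densities between two groups of regions
#' (typically CNV versus non-CNV) with Welch's unequal-variance t test,
#' two-tailed.
#'
#' @param cnv_densities,noncnv_densities Numeric vectors with at least two
#'   values each.
#' @return A list with `t`, `df` (Welch-Satterthwaite), `p_value`,
#'   `mean_cnv`, `mean_noncnv`.
#' @export
compare_densities <- function(cnv_densities, noncnv_densities) {
  if (length(cnv_densities) < 2L || length(noncnv_densities) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(cnv_densities) == 0 && stats::var(noncnv_densities) == 0)
    stop("both groups have zero variance: t statistic undefined")
  tt <- stats::t.test(cnv_densities, noncnv_densities, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_cnv = mean(cnv_densities),
       mean_noncnv = mean(noncnv_densities))
}
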