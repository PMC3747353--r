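#' Copy number of a duplicon segment
#'
#' The copy number of a duplicon is the average, over its positions, of the
#' number of SD rows aligned there: the mean column sum of the alignment
#' matrix across the segment.
#'
#' @param mat An [alignment_matrix()].
#' @param start,end Column interval of the segment, 0-based half-open.
#' @param o Optional precomputed per-column 1-counts (from
#'   [column_stats()]).
#' @return Mean per-position coverage, a non-negative number.
#' @examples
#' # four SDs covering the same 10-column stretch: copy number 4
#' h <- data.frame(sd_id = paste0("s", 1:4), cnv_id = "c", cnv_start = 10L,
#'                 cnv_end = 20L, identity = 99, aln_length = 10L, strand = "+")
#' copy_number(build_matrix(h, "c", 30), 10, 20)
#' @export
copy_number <- function(mat, start, end, o = NULL) {
  if (end <= start) stop("segment must be non-empty (start < end)")
  if (start < 0 || end > mat$n_cols) stop("segment must lie within [0, n_cols)")
  if (is.null(o)) o <- column_stats(mat)$o
  mean(o[(start + 1L):end])
}

#' Randomly relocate alignment runs within each row
#'
#' Creates one artificial matrix for the permutation null: in every row
#' independently, the maximal 1-runs keep their lengths but are re-placed at
#' random — run order is shuffled and the gaps are drawn uniformly from all
#' arrangements that keep the runs separated (interior gaps of at least one
#' zero, so runs stay maximal; the two end gaps may be empty).  Each row
#' keeps exactly its original number of 1s and its multiset of run lengths.
#'
#' Uses the current R random number generator state; seed control belongs to
#' the caller (see [null_distribution()]).
#'
#' @param mat An [alignment_matrix()].
#' @return A new [alignment_matrix()] with the same dimensions and row ids.
#' @export
permute_matrix <- function(mat) {
  stopifnot(inherits(mat, "alignment_matrix"))
  runs <- mat$runs
  if (nrow(runs) == 0L) return(mat)
  n <- mat$n_cols
  by_row <- split(runs$end - runs$start, runs$sd_id)
  out <- vector("list", length(by_row))
  for (i in seq_along(by_row)) {
    lens <- by_row[[i]]
    r <- length(lens)
    lens <- lens[sample.int(r)]
    z <- n - sum(lens)            # total zeros in the row
    slack <- z - (r - 1L)         # zeros beyond the mandatory interior gaps
    if (slack < 0L)
      stop("row '", names(by_row)[i], "': runs cannot be separated within ",
           n, " columns")
    # uniform composition of `slack` into r+1 non-negative parts
    if (r + slack > 0L && r > 0L) {
      bars <- sort(sample.int(slack + r, r))
      parts <- diff(c(0L, bars, slack + r + 1L)) - 1L
    } else {
      parts <- integer(r + 1L)
    }
    gaps <- parts[seq_len(r)] + c(0L, rep(1L, r - 1L))  # interior gaps >= 1
    starts <- cumsum(gaps) + c(0L, cumsum(lens)[-r])
    out[[i]] <- data.frame(sd_id = names(by_row)[i], start = starts,
                           end = starts + lens, stringsAsFactors = FALSE)
  }
  alignment_matrix(mat$cnv_id, n, do.call(rbind, out), sd_ids = mat$sd_ids)
}

#' Permutation null distribution of maximum duplicon copy number
#'
#' Builds `B` artificial matrices with [permute_matrix()], decodes each with
#' the HMM ([viterbi()] + [extract_candidates()]), and records the maximum
#' copy number among its candidate duplicons (0 when a permuted matrix
#' yields no candidate).
#'
#' @param mat An [alignment_matrix()].
#' @param params An [hmm_params()].
#' @param B Number of artificial matrices (default 100).
#' @param seed Integer seed; required so the null is reproducible.
#' @return An object of class `duplicon_null`: list with
#'   `max_copy_numbers` (length `B`), `B` and `seed`.
#' @export
null_distribution <- function(mat, params, B = 100L, seed) {
  stopifnot(inherits(mat, "alignment_matrix"), B >= 1L)
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  set.seed(seed)
  maxima <- numeric(B)
  for (b in seq_len(B)) {
    pm <- permute_matrix(mat)
    st <- column_stats(pm)
    cand <- extract_candidates(viterbi(pm, params, st), params$min_len,
                               cnv_id = mat$cnv_id)
    maxima[b] <- if (nrow(cand) == 0L) 0 else
      max(vapply(seq_len(nrow(cand)), function(i)
        copy_number(pm, cand$start[i], cand$end[i], o = st$o), numeric(1)))
  }
  structure(list(max_copy_numbers = maxima, B = as.integer(B),
                 seed = as.integer(seed)), class = "duplicon_null")
}

#' @export
print.duplicon_null <- function(x, ...) {
  cat(sprintf("duplicon_null: B = %d (seed %d), max copy numbers %.2f-%.2f\n",
              x$B, x$seed, min(x$max_copy_numbers), max(x$max_copy_numbers)))
  invisible(x)
}

#' Permutation P value for an observed copy number
#'
#' The P value is the fraction of artificial matrices whose maximum duplicon
#' copy number is strictly larger than the observed copy number; ties do not
#' count against the candidate.
#'
#' @param observed_cn Observed copy number of the candidate duplicon.
#' @param null A `duplicon_null` from [null_distribution()], or a bare
#'   numeric vector of null maxima.
#' @return A P value in `{0, 1/B, ..., 1}`.
#' @examples
#' p_value(30, c(rep(10, 90), rep(40, 10)))  # 0.1
#' p_value(30, rep(10, 100))                 # 0
#' @export
p_value <- function(observed_cn, null) {
  maxima <- if (inherits(null, "duplicon_null")) null$max_copy_numbers
            else as.numeric(null)
  if (length(maxima) == 0L) stop("null distribution is empty")
  mean(maxima > observed_cn)
}

#' Full duplicon-calling pipeline for one alignment matrix
#'
#' Decodes candidate duplicons with the HMM, computes their copy numbers,
#' builds one shared permutation null for the matrix, assigns each candidate
#' a P value, retains candidates with `p_value < alpha`, and removes
#' duplicate calls (same CNV, reciprocal overlap of at least
#' `dedupe_overlap`), keeping the call with the lower P value (higher copy
#' number on ties).
#'
#' @param mat An [alignment_matrix()].
#' @param params An [hmm_params()].
#' @param alpha Significance level (default 0.01).
#' @param B Number of artificial matrices for the null (default 100).
#' @param seed Integer seed for the permutation null.
#' @param dedupe_overlap Reciprocal-overlap fraction above which two
#'   significant calls are considered identical (default 0.95).
#' @param keep_all Return every candidate (with its `significant` flag)
#'   instead of only the significant, deduplicated calls.
#' @return A data.frame of calls: `cnv_id`, `start`, `end`, `state_label`,
#'   `length`, `copy_number`, `p_value`, `significant`.
#' @export
call_duplicons <- function(mat, params, alpha = 0.01, B = 100L, seed,
                           dedupe_overlap = 0.95, keep_all = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]")
  st <- column_stats(mat)
  cand <- extract_candidates(viterbi(mat, params, st), params$min_len,
                             cnv_id = mat$cnv_id)
  if (nrow(cand) == 0L) {
    return(data.frame(cnv_id = character(), start = integer(),
                      end = integer(), state_label = character(),
                      length = integer(), copy_number = numeric(),
                      p_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  cand$copy_number <- vapply(seq_len(nrow(cand)), function(i)
    copy_number(mat, cand$start[i], cand$end[i], o = st$o), numeric(1))
  null <- null_distribution(mat, params, B = B, seed = seed)
  cand$p_value <- vapply(cand$copy_number, p_value, numeric(1), null = null)
  cand$significant <- cand$p_value < alpha
  if (keep_all) return(cand)
  sig <- cand[cand$significant, , drop = FALSE]
  dedupe_calls(sig, min_overlap = dedupe_overlap)
}

#' Remove duplicate duplicon calls by reciprocal overlap
#'
#' Calls on the same CNV whose reciprocal overlap is at least `min_overlap`
#' are collapsed to the one with the lowest P value (largest copy number on
#' ties).
#'
#' @param calls A data.frame of calls (as from [call_duplicons()]).
#' @param min_overlap Reciprocal-overlap threshold (default 0.95).
#' @return The deduplicated calls, ordered by `cnv_id` then `start`.
#' @export
dedupe_calls <- function(calls, min_overlap = 0.95) {
  if (nrow(calls) <= 1L) return(calls)
  ord <- order(calls$p_value, -calls$copy_number, calls$start)
  calls <- calls[ord, , drop = FALSE]
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ki <- which(keep)
    same <- ki[calls$cnv_id[ki] == calls$cnv_id[i]]
    dup <- FALSE
    for (j in same) {
      ov <- min(calls$end[i], calls$end[j]) - max(calls$start[i], calls$start[j])
      if (ov > 0 &&
          ov / (calls$end[i] - calls$start[i]) >= min_overlap &&
          ov / (calls$end[j] - calls$start[j]) >= min_overlap) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$cnv_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
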