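# Shared fixtures and independent oracles used across the suite.

# densify a run-list alignment matrix by direct bookkeeping
densify <- function(mat) {
  d <- matrix(0L, nrow = mat$m, ncol = mat$n_cols,
              dimnames = list(mat$sd_ids, NULL))
  if (nrow(mat$runs)) {
    for (k in seq_len(nrow(mat$runs))) {
      i <- match(mat$runs$sd_id[k], mat$sd_ids)
      d[i, (mat$runs$start[k] + 1L):mat$runs$end[k]] <- 1L
    }
  }
  d
}

# run-list matrix from a dense 0/1 matrix (row-wise rle)
dense_to_amat <- function(d, cnv_id = "c") {
  sd_ids <- if (is.null(rownames(d))) sprintf("s%02d", seq_len(nrow(d)))
            else rownames(d)
  runs <- NULL
  for (i in seq_len(nrow(d))) {
    r <- rle(d[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values == 1L
    if (any(keep))
      runs <- rbind(runs, data.frame(sd_id = sd_ids[i], start = starts[keep],
                                     end = ends[keep]))
  }
  alignment_matrix(cnv_id, ncol(d), runs, sd_ids = sd_ids)
}

random_amat <- function(m, n, density = 0.3) {
  dense_to_amat(matrix(as.integer(runif(m * n) < density), nrow = m))
}

# brute-force column statistics from a dense matrix
dense_column_stats <- function(d) {
  n <- ncol(d)
  list(o = as.integer(colSums(d)),
       f11 = vapply(seq_len(n - 1L), function(j)
         sum(d[, j] == 1L & d[, j + 1L] == 1L), integer(1)),
       f01 = vapply(seq_len(n - 1L), function(j)
         sum(d[, j] == 0L & d[, j + 1L] == 1L), integer(1)),
       f10 = vapply(seq_len(n - 1L), function(j)
         sum(d[, j] == 1L & d[, j + 1L] == 0L), integer(1)))
}

# exhaustive maximum log-probability over all 3^n state paths, built
# directly from the dense matrix and the model definition
exhaustive_log_score <- function(d, p, P_o, prob_floor = 1e-300) {
  m <- nrow(d); n <- ncol(d)
  o <- colSums(d)
  lf <- log(prob_floor)
  le_d <- pmax(pbinom(o, m, P_o, log.p = TRUE), lf)
  le_n <- pmax(pbinom(o, m, P_o, lower.tail = FALSE, log.p = TRUE), lf)
  emis <- rbind(le_d, le_d, le_n)       # rows: D1, D2, N
  trans <- vector("list", max(n - 1L, 0L))
  for (j in seq_len(n - 1L)) {
    f11 <- sum(d[, j] == 1L & d[, j + 1L] == 1L)
    f01 <- sum(d[, j] == 0L & d[, j + 1L] == 1L)
    f10 <- sum(d[, j] == 1L & d[, j + 1L] == 0L)
    tot <- f11 + f01 + f10
    w <- if (tot > 0) f11 / tot else 0
    g <- if (f01 + f10 > 0) f01 / (f01 + f10) else 0
    stay <- p * w; sw <- (1 - stay) * g; tn <- (1 - stay) * (1 - g)
    tr <- rbind(c(stay, sw, tn), c(sw, stay, tn), rep(1 / 3, 3))
    trans[[j]] <- log(pmax(tr, prob_floor))
  }
  init <- c(log(0.5), -Inf, log(0.5))
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  score <- init[paths[, 1L]] + emis[cbind(paths[, 1L], 1L)]
  for (j in seq_len(n)[-1L])
    score <- score + trans[[j - 1L]][cbind(paths[, j - 1L], paths[, j])] +
      emis[cbind(paths[, j], j)]
  max(score)
}

# does the (possibly unrooted) tree contain a branch inducing this tip set?
has_split <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  any(vapply(parts, function(p)
    setequal(labels[p], tips) || setequal(labels[-p], tips), logical(1)))
}

# reference hmm parameters used by most HMM tests
test_params <- function(...) hmm_params(P_o = 0.2, min_len = 100L, ...)
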