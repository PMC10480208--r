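#' Observed pairwise taxon correlations
#'
#' Symmetric taxa x taxa correlation matrix of relative abundances across
#' samples. Taxa with zero variance (constant columns) get correlation 0
#' with every partner and are reported via attribute `"constant_taxa"` and
#' a message.
#'
#' @param table an [abundance_table()] (samples x taxa).
#' @param method `"pearson"` (default, matching the network stage) or
#'   `"spearman"`.
#' @return taxa x taxa matrix, entries in `[-1, 1]`, unit diagonal.
#' @export
observed_correlations <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  table <- as_abundance_table(table)
  if (nrow(table) < 3)
    stop("insufficient data: need >= 3 samples to correlate, got ", nrow(table))
  if (ncol(table) < 2) stop("need >= 2 taxa")
  m <- unclass(table)
  const <- apply(m, 2, function(v) stats::var(v) == 0)
  r <- suppressWarnings(stats::cor(m, method = method))
  if (any(const)) {
    message("constant taxa set to correlation 0: ",
            paste(colnames(m)[const], collapse = ", "))
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  attr(r, "constant_taxa") <- colnames(m)[const]
  r
}

#' Null-model-corrected correlations (taxa-shuffle null)
#'
#' Subtracts from each observed pairwise correlation the mean correlation
#' over `n_iters` taxa-shuffle null iterations, in which every taxon's
#' abundance vector is independently permuted across samples before the
#' whole correlation matrix is recomputed. The corrected matrix is
#' symmetric by construction; entries live in `[-2, 2]`.
#'
#' The permutation stream is fixed by `seed`: iterations are drawn in
#' order, and within an iteration each taxon column (left to right) draws
#' one `sample.int(n_samples)` permutation.
#'
#' @param table an [abundance_table()].
#' @param n_iters number of null iterations (default 200).
#' @param method correlation method, see [observed_correlations()].
#' @param seed RNG seed for the permutation stream.
#' @return taxa x taxa corrected matrix with attributes `"observed"` and
#'   `"null_mean"`.
#' @export
null_corrected_correlations <- function(table, n_iters = 200,
                                        method = c("pearson", "spearman"),
                                        seed = 1) {
  method <- match.arg(method)
  n_iters <- check_count(n_iters, "n_iters")
  table <- as_abundance_table(table)
  obs <- observed_correlations(table, method)
  m <- unclass(table)
  n <- nrow(m); p <- ncol(m)
  null_sum <- matrix(0, p, p)
  with_seed(seed, {
    for (it in seq_len(n_iters)) {
      perm <- m
      for (j in seq_len(p)) perm[, j] <- m[sample.int(n), j]
      r <- suppressWarnings(stats::cor(perm, method = method))
      r[!is.finite(r)] <- 0
      null_sum <- null_sum + r
    }
  })
  null_mean <- null_sum / n_iters
  diag(null_mean) <- 1
  corrected <- obs - null_mean
  diag(corrected) <- 0
  dimnames(corrected) <- dimnames(obs)
  attr(corrected, "observed") <- obs
  attr(corrected, "null_mean") <- null_mean
  attr(corrected, "n_null_iters") <- n_iters
  attr(corrected, "seed") <- as.integer(seed)
  corrected
}

#' Per-taxon positive and negative connectedness
#'
#' Connectedness of a taxon is the average of its strictly positive
#' (respectively strictly negative) corrected correlations with the other
#' taxa; 0 if it has none of that sign. The diagonal is ignored.
#'
#' @param corrected symmetric taxa x taxa corrected-correlation matrix.
#' @return list with numeric vectors `pos` (>= 0) and `neg` (<= 0), named
#'   by taxon.
#' @export
connectedness <- function(corrected) {
  if (!is.matrix(corrected) || nrow(corrected) != ncol(corrected))
    stop("`corrected` must be a square matrix")
  if (max(abs(corrected - t(corrected))) > 1e-8)
    stop("`corrected` must be symmetric")
  p <- ncol(corrected)
  pos <- neg <- numeric(p)
  for (i in seq_len(p)) {
    v <- corrected[i, -i]
    up <- v[v > 0]; dn <- v[v < 0]
    pos[i] <- if (length(up)) mean(up) else 0
    neg[i] <- if (length(dn)) mean(dn) else 0
  }
  names(pos) <- names(neg) <- colnames(corrected)
  list(pos = pos, neg = neg)
}

#' Per-sample positive and negative cohesion
#'
#' Cohesion of a sample is the sum over taxa of relative abundance times
#' connectedness: an abundance-weighted average of connectedness, so it is
#' bounded by the most extreme connectedness of taxa present.
#'
#' @param table an [abundance_table()].
#' @param pos,neg per-taxon connectedness vectors (named by taxon), as from
#'   [connectedness()].
#' @return list with per-sample vectors `pos` (>= 0) and `neg` (<= 0).
#' @export
cohesion <- function(table, pos, neg) {
  table <- as_abundance_table(table)
  if (is.null(names(pos)) || is.null(names(neg)))
    stop("connectedness vectors must be named by taxon")
  if (!setequal(colnames(table), names(pos)) ||
      !setequal(colnames(table), names(neg)))
    stop("alignment error: taxa of `table` and connectedness vectors differ")
  m <- unclass(table)
  list(pos = drop(m %*% pos[colnames(m)]),
       neg = drop(m %*% neg[colnames(m)]))
}

#' Full cohesion analysis of an abundance table
#'
#' Convenience wrapper chaining [null_corrected_correlations()],
#' [connectedness()] and [cohesion()].
#'
#' @inheritParams null_corrected_correlations
#' @return object of class `"cohesion_result"`: corrected matrix,
#'   connectedness, per-sample cohesion, iteration count and seed.
#' @export
cohesion_analysis <- function(table, n_iters = 200,
                              method = c("pearson", "spearman"), seed = 1) {
  method <- match.arg(method)
  table <- as_abundance_table(table)
  corrected <- null_corrected_correlations(table, n_iters, method, seed)
  conn <- connectedness(corrected)
  coh <- cohesion(table, conn$pos, conn$neg)
  structure(list(corrected_corr = corrected,
                 pos_connectedness = conn$pos, neg_connectedness = conn$neg,
                 pos_cohesion = coh$pos, neg_cohesion = coh$neg,
                 n_null_iters = n_iters, method = method,
                 seed = as.integer(seed)),
            class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat("Cohesion analysis (taxa-shuffle null, ", x$n_null_iters,
      " iterations, ", x$method, ")\n", sep = "")
  cat(sprintf("  taxa: %d  samples: %d\n",
              length(x$pos_connectedness), length(x$pos_cohesion)))
  cat(sprintf("  positive cohesion: %.4f .. %.4f (mean %.4f)\n",
              min(x$pos_cohesion), max(x$pos_cohesion), mean(x$pos_cohesion)))
  cat(sprintf("  negative cohesion: %.4f .. %.4f (mean %.4f)\n",
              min(x$neg_cohesion), max(x$neg_cohesion), mean(x$neg_cohesion)))
  invisible(x)
}

#' Pearson association between positive cohesion and temperature
#'
#' @param pos_cohesion named per-sample vector of positive cohesion.
#' @param metadata metadata data.frame (sample ids as row names, column
#'   `temperature`).
#' @return list with `r`, `p`, and `n`.
#' @export
cohesion_temperature_association <- function(pos_cohesion, metadata) {
  ids <- names(pos_cohesion)
  if (is.null(ids)) stop("`pos_cohesion` must be named by sample id")
  miss <- setdiff(ids, rownames(metadata))
  if (length(miss))
    stop("alignment error: samples absent from metadata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(ids) < 3) stop("need >= 3 matched samples")
  temp <- metadata[ids, "temperature"]
  ct <- stats::cor.test(temp, pos_cohesion, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}
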