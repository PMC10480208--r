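# shared fixtures and independent oracles, all built in code

# quick abundance table from a plain matrix (rows renormalized)
make_table <- function(values, samples = NULL, taxa = NULL) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(values)))
  if (is.null(taxa)) taxa <- sprintf("t%d", seq_len(ncol(values)))
  dimnames(values) <- list(samples, taxa)
  as_abundance_table(values, renormalize = TRUE)
}

# textbook Pearson correlation, coded independently of stats::cor
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(0)
  num / den
}

brute_corr_matrix <- function(m) {
  p <- ncol(m)
  out <- diag(1, p)
  for (i in seq_len(p)) for (j in seq_len(p)) if (i != j)
    out[i, j] <- brute_pearson(m[, i], m[, j])
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# brute-force taxa-shuffle null correction consuming the same permutation
# stream as the implementation: per iteration, each column (left to right)
# draws one sample.int(n)
oracle_null_corrected <- function(m, n_iters, seed) {
  obs <- brute_corr_matrix(m)
  n <- nrow(m); p <- ncol(m)
  acc <- matrix(0, p, p)
  set.seed(seed)
  for (it in seq_len(n_iters)) {
    perm <- m
    for (j in seq_len(p)) perm[, j] <- m[sample.int(n), j]
    acc <- acc + brute_corr_matrix(perm)
  }
  out <- obs - acc / n_iters
  diag(out) <- 0
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# closed-form polar angle from the projection on the y = x axis, with a
# snap to the 45-degree boundaries to absorb floating-point error
oracle_theta <- function(da, db) {
  th <- asin((da + db) / (sqrt(2) * sqrt(da^2 + db^2))) * 180 / pi
  # asin loses ~1e-6 degrees of precision near +/-90; snap to boundaries
  snap <- round(th / 45) * 45
  if (abs(th - snap) < 1e-5) snap else th
}

# independent region lookup for the angle-mode classification
oracle_label <- function(th) {
  if (th == -90) "equally inhibited"
  else if (th > -90 && th < -45) "competition"
  else if (th == -45) "amensalism"
  else if (th > -45 && th < 45 && th != 0) "parasitism"
  else if (th == 0) "parasitism"
  else if (th == 45) "commensalism"
  else if (th < 90) "mutualism"
  else "equally facilitated"
}

# adjusted Rand index (mclust is the independent comparator)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# F1 of a selection against a truth set
f1_score <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# 12-node two-module toy graph with hand-computed Zi/Pi (helper-fixture)
toy_role_graph <- function() {
  edges <- rbind(
    c("a1", "a2"), c("a1", "a3"), c("a1", "a4"), c("a1", "a5"), c("a1", "a6"),
    c("a2", "a3"), c("a4", "a5"),
    c("b1", "b2"), c("b1", "b3"), c("b1", "b4"), c("b2", "b3"), c("b5", "b6"),
    c("a6", "b1"), c("a2", "b5"))
  corr <- matrix(0, 12, 12,
                 dimnames = list(c(paste0("a", 1:6), paste0("b", 1:6)),
                                 c(paste0("a", 1:6), paste0("b", 1:6))))
  for (k in seq_len(nrow(edges))) {
    corr[edges[k, 1], edges[k, 2]] <- 0.9
    corr[edges[k, 2], edges[k, 1]] <- 0.9
  }
  diag(corr) <- 1
  membership <- stats::setNames(rep(c("A", "B"), each = 6), rownames(corr))
  list(corr = corr, membership = membership)
}

# latent-factor data with three planted blocks (block correlation ~ rho)
planted_block_data <- function(n_samples = 50, block_size = 20, rho = 0.8,
                               seed = 21) {
  set.seed(seed)
  blocks <- rep(seq_len(3), each = block_size)
  f <- matrix(stats::rnorm(n_samples * 3), n_samples, 3)
  x <- sapply(seq_along(blocks), function(j)
    sqrt(rho) * f[, blocks[j]] + sqrt(1 - rho) * stats::rnorm(n_samples))
  colnames(x) <- sprintf("t%02d", seq_along(blocks))
  list(x = x, blocks = stats::setNames(blocks, colnames(x)))
}
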