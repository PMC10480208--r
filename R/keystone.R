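#' Criterion 1: overall abundant taxa
#'
#' Taxa whose mean relative abundance across samples is strictly above
#' `min_mean_abundance` (default 0.1%). `mode = "rank"` instead keeps the
#' top `rank_fraction` of taxa by mean abundance.
#'
#' @param table an [abundance_table()].
#' @param min_mean_abundance mean-abundance cutoff (fraction; strict `>`).
#' @param mode `"abundance"` (default) or `"rank"`.
#' @param rank_fraction fraction of top-ranked taxa kept in rank mode.
#' @return character vector of taxon ids.
#' @export
criterion_abundant <- function(table, min_mean_abundance = 0.001,
                               mode = c("abundance", "rank"),
                               rank_fraction = 0.001) {
  mode <- match.arg(mode)
  table <- as_abundance_table(table)
  mu <- colMeans(unclass(table))
  if (mode == "abundance") return(names(mu)[mu > min_mean_abundance])
  k <- max(1L, ceiling(rank_fraction * length(mu)))
  names(sort(mu, decreasing = TRUE))[seq_len(k)]
}

#' Criterion 2: ubiquitous taxa
#'
#' Taxa detected (abundance > 0) in strictly more than `min_prevalence` of
#' samples (default 80%).
#'
#' @param table an [abundance_table()].
#' @param min_prevalence prevalence cutoff (fraction of samples; strict `>`).
#' @return character vector of taxon ids.
#' @export
criterion_ubiquitous <- function(table, min_prevalence = 0.8) {
  table <- as_abundance_table(table)
  prev <- colMeans(unclass(table) > 0)
  names(prev)[prev > min_prevalence]
}

# per-sample mark: taxa in the minimal descending-abundance prefix reaching
# `cumulative_mass`; ties at the boundary abundance are all included
mark_top_mass <- function(x, cumulative_mass) {
  ord <- order(x, decreasing = TRUE)
  cs <- cumsum(x[ord])
  k <- which(cs >= cumulative_mass)[1]
  if (is.na(k)) k <- length(x)
  boundary <- x[ord[k]]
  marked <- x >= boundary & x > 0
  marked
}

#' Criterion 3: frequently abundant taxa
#'
#' Per sample, taxa are ranked by abundance and the minimal prefix whose
#' cumulative abundance reaches `cumulative_mass` (default 80%) is marked
#' "abundant in that sample"; taxa tied at the prefix boundary are all
#' marked. Returns taxa marked in strictly more than `min_sample_fraction`
#' of samples (default 50%).
#'
#' @param table an [abundance_table()].
#' @param cumulative_mass per-sample cumulative-abundance mass in `(0, 1)`.
#' @param min_sample_fraction fraction of samples (strict `>`).
#' @return character vector of taxon ids.
#' @export
criterion_frequently_abundant <- function(table, cumulative_mass = 0.8,
                                          min_sample_fraction = 0.5) {
  if (cumulative_mass <= 0 || cumulative_mass >= 1)
    stop("`cumulative_mass` must be in (0, 1)")
  table <- as_abundance_table(table)
  m <- unclass(table)
  marked <- t(apply(m, 1, mark_top_mass, cumulative_mass = cumulative_mass))
  frac <- colMeans(marked)
  names(frac)[frac > min_sample_fraction]
}

#' Criterion 4: taxa with significant random-forest importance for
#' positive cohesion
#'
#' Fits a random-forest regression of positive cohesion on taxon relative
#' abundances (`n_trees` trees) and reads each taxon's %IncMSE importance
#' (out-of-bag permutation importance). A null distribution of each
#' taxon's importance is built by refitting the forest with the response
#' permuted `n_perm` times; the permutation p-value uses the `(b+1)/(n+1)`
#' correction. Taxa with `perm_p < alpha` are selected. Repeated k-fold
#' cross-validated R-squared is reported as a model diagnostic.
#'
#' @param table an [abundance_table()].
#' @param pos_cohesion per-sample positive cohesion, named by sample id.
#' @param n_trees trees per forest (default 500).
#' @param n_perm response permutations for the null (default 1000).
#' @param cv_repeats,cv_folds repeated cross-validation design (defaults 5
#'   and 10); `cv_repeats = 0` skips the diagnostic.
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return list with `inc_mse`, `perm_p`, `selected` (taxon ids), `cv_r2`,
#'   and the settings used.
#' @export
criterion_poscoh_rf <- function(table, pos_cohesion, n_trees = 500,
                                n_perm = 1000, cv_repeats = 5, cv_folds = 10,
                                alpha = 0.05, seed = 1) {
  table <- as_abundance_table(table)
  n_perm <- check_count(n_perm, "n_perm")
  if (is.null(names(pos_cohesion)) ||
      !setequal(names(pos_cohesion), rownames(table)))
    stop("alignment error: `pos_cohesion` must be named by the table's samples")
  x <- as.data.frame(unclass(table))
  colnames(x) <- make.names(colnames(table))   # RF-safe predictor names
  y <- pos_cohesion[rownames(table)]
  n <- nrow(x)
  if (cv_repeats > 0 && n < cv_folds)
    stop("cross-validation error: fewer samples (", n, ") than folds (",
         cv_folds, ")")
  with_seed(seed, {
    fit <- randomForest::randomForest(x, y, ntree = n_trees, importance = TRUE)
    inc_mse <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
    null_ge <- integer(length(inc_mse))
    for (b in seq_len(n_perm)) {
      fb <- randomForest::randomForest(x, sample(y), ntree = n_trees,
                                       importance = TRUE)
      imp_b <- randomForest::importance(fb, type = 1, scale = TRUE)[, 1]
      null_ge <- null_ge + (imp_b >= inc_mse)
    }
    perm_p <- (null_ge + 1) / (n_perm + 1)
    cv_r2 <- NA_real_
    if (cv_repeats > 0) {
      r2 <- numeric(cv_repeats)
      for (rep_i in seq_len(cv_repeats)) {
        fold <- sample(rep_len(seq_len(cv_folds), n))
        pred <- numeric(n)
        for (f in seq_len(cv_folds)) {
          hold <- fold == f
          ft <- randomForest::randomForest(x[!hold, , drop = FALSE], y[!hold],
                                           ntree = n_trees)
          pred[hold] <- stats::predict(ft, x[hold, , drop = FALSE])
        }
        r2[rep_i] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      }
      cv_r2 <- mean(r2)
    }
  })
  names(inc_mse) <- names(perm_p) <- colnames(table)
  list(inc_mse = inc_mse, perm_p = perm_p,
       selected = colnames(table)[perm_p < alpha], cv_r2 = cv_r2,
       settings = list(n_trees = n_trees, n_perm = n_perm,
                       cv_repeats = cv_repeats, cv_folds = cv_folds,
                       alpha = alpha, seed = as.integer(seed)))
}

#' Four-criteria keystone screen
#'
#' Intersects the overall-abundance, ubiquity, frequent-abundance and
#' positive-cohesion random-forest criteria and reports per-taxon flags,
#' importances, permutation p-values and the fraction of total reads the
#' selected taxa account for (their summed mean relative abundance).
#'
#' @param table an [abundance_table()].
#' @param pos_cohesion per-sample positive cohesion, named by sample id.
#' @param min_mean_abundance,min_prevalence,cumulative_mass,min_sample_fraction
#'   criterion cutoffs (see the individual criterion functions).
#' @param n_trees,n_perm,cv_repeats,cv_folds,alpha,seed random-forest stage
#'   settings (see [criterion_poscoh_rf()]).
#' @return object of class `"keystone_report"`: data.frame `report` (taxon,
#'   C1..C4, inc_mse, perm_p, selected), `selected`,
#'   `selected_fraction_of_reads`, `cv_r2`, `settings`.
#' @export
screen_keystones <- function(table, pos_cohesion,
                             min_mean_abundance = 0.001, min_prevalence = 0.8,
                             cumulative_mass = 0.8, min_sample_fraction = 0.5,
                             n_trees = 500, n_perm = 1000, cv_repeats = 5,
                             cv_folds = 10, alpha = 0.05, seed = 1) {
  table <- as_abundance_table(table)
  taxa <- colnames(table)
  c1 <- criterion_abundant(table, min_mean_abundance)
  c2 <- criterion_ubiquitous(table, min_prevalence)
  c3 <- criterion_frequently_abundant(table, cumulative_mass,
                                      min_sample_fraction)
  c4 <- criterion_poscoh_rf(table, pos_cohesion, n_trees = n_trees,
                            n_perm = n_perm, cv_repeats = cv_repeats,
                            cv_folds = cv_folds, alpha = alpha, seed = seed)
  report <- data.frame(taxon = taxa,
                       C1 = taxa %in% c1, C2 = taxa %in% c2,
                       C3 = taxa %in% c3, C4 = taxa %in% c4$selected,
                       inc_mse = unname(c4$inc_mse[taxa]),
                       perm_p = unname(c4$perm_p[taxa]),
                       stringsAsFactors = FALSE)
  report$selected <- report$C1 & report$C2 & report$C3 & report$C4
  selected <- taxa[report$selected]
  frac <- sum(colMeans(unclass(table))[selected])
  structure(list(report = report, selected = selected,
                 selected_fraction_of_reads = frac, cv_r2 = c4$cv_r2,
                 settings = c(list(min_mean_abundance = min_mean_abundance,
                                   min_prevalence = min_prevalence,
                                   cumulative_mass = cumulative_mass,
                                   min_sample_fraction = min_sample_fraction),
                              c4$settings)),
            class = "keystone_report")
}

#' @export
print.keystone_report <- function(x, ...) {
  cat("Keystone screen (four criteria)\n")
  cat(sprintf("  C1 abundant: %d  C2 ubiquitous: %d  C3 frequently abundant: %d  C4 PosCoh-RF: %d\n",
              sum(x$report$C1), sum(x$report$C2), sum(x$report$C3),
              sum(x$report$C4)))
  cat(sprintf("  selected (all four): %d taxon/taxa covering %.1f%% of reads\n",
              length(x$selected), 100 * x$selected_fraction_of_reads))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  if (is.finite(x$cv_r2))
    cat(sprintf("  RF cross-validated R2: %.3f (%dx%d-fold)\n", x$cv_r2,
                x$settings$cv_repeats, x$settings$cv_folds))
  invisible(x)
}
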