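#' Prepare an abundance table for network construction
#'
#' Follows the molecular-ecological-network recipe: average the composition
#' over all time points of each pile (one row per pile), drop taxa present
#' in fewer than `min_prevalence` of the pile averages, and log-transform
#' after adding a pseudocount (default: half the smallest nonzero relative
#' abundance).
#'
#' @param table an [abundance_table()] of all samples.
#' @param metadata metadata data.frame (row names sample ids, column `pile`).
#' @param min_prevalence minimum number of pile averages a taxon must be
#'   present in (abundance > 0); default `ceiling(n_piles / 2)`, i.e. 5 of 10.
#' @param pseudocount added before log; `NULL` for the default above.
#' @return piles x taxa matrix of log-transformed averaged abundances, with
#'   attributes `"pseudocount"` and `"dropped_taxa"`.
#' @export
prepare_network_input <- function(table, metadata, min_prevalence = NULL,
                                  pseudocount = NULL) {
  table <- as_abundance_table(table)
  metadata <- align_metadata(table, metadata)
  piles <- unique(as.character(metadata$pile))
  avg <- t(vapply(piles, function(p) {
    rows <- rownames(metadata)[metadata$pile == p]
    if (length(rows) == 0) stop("pile with zero samples: ", p)
    colMeans(unclass(table)[rows, , drop = FALSE])
  }, numeric(ncol(table))))
  rownames(avg) <- piles
  if (is.null(min_prevalence)) min_prevalence <- ceiling(length(piles) / 2)
  present <- colSums(avg > 0)
  keep <- present >= min_prevalence
  dropped <- colnames(avg)[!keep]
  avg <- avg[, keep, drop = FALSE]
  if (ncol(avg) == 0) stop("no taxa pass the prevalence filter")
  if (is.null(pseudocount)) {
    nz <- avg[avg > 0]
    pseudocount <- min(nz) / 2
  }
  out <- log(avg + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "dropped_taxa") <- dropped
  out
}

# chi-square of spacings against a reference density, on sqrt(n) bins
spacing_chisq <- function(d, cdf) {
  nb <- max(5L, floor(sqrt(length(d))))
  brk <- seq(0, max(d) * (1 + 1e-9), length.out = nb + 1)
  obs <- graphics::hist(d, breaks = brk, plot = FALSE)$counts
  p <- diff(cdf(brk))
  p[p < 1e-12] <- 1e-12
  expd <- length(d) * p / sum(p)
  sum((obs - expd)^2 / expd)
}

#' RMT scan for the correlation threshold
#'
#' For each candidate threshold `s`, entries with `|r| < s` are zeroed, the
#' eigenvalue spectrum of the thresholded matrix is computed and unfolded
#' (smooth polynomial fit to the cumulative spectral density), and the
#' nearest-neighbour spacing distribution is scored by chi-square against
#' both the Poisson law `exp(-d)` (modular signal) and the Wigner-Dyson
#' (GOE) surmise (correlated noise). The chosen threshold is the smallest
#' candidate at which the Poisson fit first beats the Wigner-Dyson fit.
#'
#' Exactly degenerate eigenvalues (ties produced by the thresholded zeros)
#' are collapsed before unfolding; candidates with fewer than
#' `min_spacings` spacings are skipped.
#'
#' @param corr symmetric correlation matrix.
#' @param s_min,s_max,step scan grid (defaults 0.30 to 0.99 by 0.01).
#' @param unfold_degree polynomial degree of the unfolding fit (default 10).
#' @param min_spacings minimum usable spacings per candidate (default 20).
#' @return object of class `"rmt_scan"`: data.frame `scan` (threshold,
#'   chi-square statistics, spacing count) and `chosen_threshold`.
#' @export
rmt_threshold <- function(corr, s_min = 0.30, s_max = 0.99, step = 0.01,
                          unfold_degree = 10, min_spacings = 20) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("`corr` must be a square matrix")
  if (max(abs(corr - t(corr))) > 1e-8) stop("`corr` must be symmetric")
  cand <- seq(s_min, s_max, by = step)
  chi_p <- chi_w <- rep(NA_real_, length(cand))
  nsp <- integer(length(cand))
  cdf_pois <- function(x) 1 - exp(-pmax(x, 0))
  cdf_goe <- function(x) 1 - exp(-pi * pmax(x, 0)^2 / 4)
  for (k in seq_along(cand)) {
    a <- corr
    a[abs(a) < cand[k]] <- 0
    diag(a) <- 1
    ev <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    ev <- ev[c(TRUE, diff(ev) > 1e-8)]      # collapse exact degeneracies
    nsp[k] <- max(0L, length(ev) - 1L)
    if (nsp[k] < min_spacings) next
    deg <- min(unfold_degree, length(ev) - 2)
    cum <- seq_along(ev) / length(ev)
    # orthogonal-polynomial fit; drop the degree if extreme outlying
    # eigenvalues make the basis rank-deficient
    fit <- NULL
    while (is.null(fit) && deg >= 2) {
      fit <- tryCatch(stats::lm(cum ~ stats::poly(ev, degree = deg)),
                      error = function(e) NULL)
      if (is.null(fit)) deg <- deg - 1
    }
    if (is.null(fit)) next
    unf <- sort(length(ev) * stats::fitted(fit))
    d <- diff(unf)
    d <- d / mean(d)
    chi_p[k] <- spacing_chisq(d, cdf_pois)
    chi_w[k] <- spacing_chisq(d, cdf_goe)
  }
  usable <- which(!is.na(chi_p))
  if (!length(usable))
    stop("insufficient spectrum: no candidate threshold yields >= ",
         min_spacings, " spacings")
  hit <- usable[chi_p[usable] < chi_w[usable]]
  chosen <- if (length(hit)) cand[hit[1]]
            else cand[usable[which.min(chi_p[usable] / chi_w[usable])]]
  structure(list(scan = data.frame(threshold = cand, chisq_poisson = chi_p,
                                   chisq_wigner = chi_w, n_spacings = nsp),
                 chosen_threshold = chosen),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  ok <- !is.na(x$scan$chisq_poisson)
  cat(sprintf("RMT threshold scan: %d candidates (%.2f .. %.2f), %d usable\n",
              nrow(x$scan), min(x$scan$threshold), max(x$scan$threshold),
              sum(ok)))
  cat(sprintf("chosen threshold: %.2f\n", x$chosen_threshold))
  invisible(x)
}

# topological indices shared by the observed network and null ensembles
network_indices <- function(graph) {
  comm <- igraph::cluster_fast_greedy(graph, weights = NA)
  c(nodes = igraph::vcount(graph),
    edges = igraph::ecount(graph),
    average_degree = 2 * igraph::ecount(graph) / igraph::vcount(graph),
    clustering_coefficient = igraph::transitivity(graph, type = "global"),
    average_path_length = igraph::mean_distance(graph, directed = FALSE, weights = NA),
    modularity = igraph::modularity(comm))
}

#' Build a thresholded co-occurrence network
#'
#' Keeps an edge between two taxa iff `|r| >= threshold`, recording the
#' correlation and its sign; isolated nodes are dropped. Modules are
#' detected by greedy modularity maximization and network-level topological
#' indices are computed.
#'
#' @param corr symmetric correlation matrix with taxon ids as dimnames.
#' @param threshold correlation cutoff in `(0, 1)` (or an `"rmt_scan"`).
#' @return object of class `"cooccurrence_network"` with elements `graph`
#'   (igraph, edge attributes `weight` and `sign`), `edges` (data.frame),
#'   `threshold`, `modules` (named membership vector) and `indices`.
#' @export
build_network <- function(corr, threshold) {
  if (inherits(threshold, "rmt_scan")) threshold <- threshold$chosen_threshold
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  if (is.null(rownames(corr))) rownames(corr) <- colnames(corr) <-
      sprintf("n%d", seq_len(nrow(corr)))
  a <- corr
  diag(a) <- 0
  a[abs(a) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::ecount(g) == 0)
    stop("empty graph: no edge with |r| >= ", threshold)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight > 0, "positive", "negative")
  ends <- igraph::ends(g, igraph::E(g))
  edges <- data.frame(source = ends[, 1], target = ends[, 2],
                      r = igraph::E(g)$weight, sign = igraph::E(g)$sign,
                      stringsAsFactors = FALSE)
  comm <- igraph::cluster_fast_greedy(g, weights = NA)
  modules <- stats::setNames(igraph::membership(comm),
                             igraph::V(g)$name)
  structure(list(graph = g, edges = edges, threshold = threshold,
                 modules = modules, indices = network_indices(g)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network (|r| >= %.2f): %d nodes, %d edges (%d+/%d-), %d modules\n",
              x$threshold, igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative"),
              length(unique(x$modules))))
  print(round(x$indices, 3))
  invisible(x)
}

#' Maslov-Sneppen null ensemble for a network
#'
#' Builds `n_random` degree-preserving randomizations of the observed graph
#' by double-edge swaps and summarizes each topological index as null mean,
#' null sd and the observed z-score. Every random graph has exactly the
#' observed degree sequence.
#'
#' @param net a `"cooccurrence_network"`.
#' @param n_random ensemble size (default 100).
#' @param n_swaps_per_edge attempted swaps per edge per graph (default 10).
#' @param seed RNG seed.
#' @param keep_graphs also return the random graphs (for auditing).
#' @return object of class `"random_ensemble_summary"`: data.frame
#'   `summary` (index, observed, null_mean, null_sd, z) and optionally
#'   `graphs`.
#' @export
maslov_sneppen_ensemble <- function(net, n_random = 100, n_swaps_per_edge = 10,
                                    seed = 1, keep_graphs = FALSE) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n_random <- check_count(n_random, "n_random")
  g <- net$graph
  if (igraph::ecount(g) < 2) stop("need >= 2 edges to rewire")
  niter <- n_swaps_per_edge * igraph::ecount(g)
  canon <- function(gr) {
    e <- igraph::ends(gr, igraph::E(gr))
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), collapse = ";")
  }
  obs_canon <- canon(g)
  idx <- matrix(NA_real_, n_random, length(net$indices),
                dimnames = list(NULL, names(net$indices)))
  graphs <- if (keep_graphs) vector("list", n_random) else NULL
  unchanged <- TRUE
  with_seed(seed, {
    for (b in seq_len(n_random)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      if (unchanged && canon(gr) != obs_canon) unchanged <- FALSE
      idx[b, ] <- network_indices(gr)
      if (keep_graphs) graphs[[b]] <- gr
    }
  })
  if (unchanged)
    warning("no degree-preserving swap changed the graph; ensemble is ",
            n_random, " identical copies")
  mu <- colMeans(idx); sdv <- apply(idx, 2, stats::sd)
  z <- ifelse(sdv > 0, (net$indices - mu) / sdv, NA_real_)
  structure(list(summary = data.frame(index = names(net$indices),
                                      observed = unname(net$indices),
                                      null_mean = unname(mu),
                                      null_sd = unname(sdv),
                                      z = unname(z),
                                      stringsAsFactors = FALSE),
                 n_random = n_random, graphs = graphs),
            class = "random_ensemble_summary")
}

#' @export
print.random_ensemble_summary <- function(x, ...) {
  cat("Maslov-Sneppen ensemble (", x$n_random, " random networks)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Within-module connectivity (Zi), among-module connectivity (Pi) and roles
#'
#' `Zi` is the z-score of a node's within-module degree relative to its
#' module; `Pi = 1 - sum_m (k_im / k_i)^2` is the participation coefficient
#' over modules. Nodes are labelled `peripheral`, `module hub`
#' (`Zi > z_thresh`), `connector` (`Pi > p_thresh`) or `network hub`
#' (both); non-peripheral nodes are the keystone calls.
#'
#' @param net a `"cooccurrence_network"`.
#' @param membership optional named module membership; default: the modules
#'   detected at build time.
#' @param z_thresh,p_thresh role cutoffs (defaults 2.5 and 0.62).
#' @return data.frame (taxon, module, degree, within_degree, Zi, Pi, role,
#'   keystone).
#' @export
module_roles <- function(net, membership = NULL, z_thresh = 2.5,
                         p_thresh = 0.62) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  if (is.null(membership)) membership <- net$modules
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(membership)))
    stop("membership missing node(s): ",
         paste(utils::head(setdiff(nodes, names(membership)), 5), collapse = ", "))
  mem <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)
  mods <- sort(unique(mem))
  # within-module degree of every node toward every module
  k_to_mod <- vapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]),
                     numeric(length(nodes)))
  if (length(nodes) == 1) k_to_mod <- matrix(k_to_mod, nrow = 1)
  colnames(k_to_mod) <- as.character(mods)
  k_within <- k_to_mod[cbind(seq_along(nodes), match(mem, mods))]
  zi <- rep(NA_real_, length(nodes))
  for (m in mods) {
    in_m <- which(mem == m)
    if (length(in_m) == 1) {
      warning("singleton module ", m, ": Zi undefined, node flagged peripheral")
      next
    }
    mu <- mean(k_within[in_m]); sdv <- stats::sd(k_within[in_m])
    zi[in_m] <- if (sdv > 0) (k_within[in_m] - mu) / sdv else 0
  }
  pi_v <- 1 - rowSums((k_to_mod / deg)^2)
  role <- rep("peripheral", length(nodes))
  is_hub <- !is.na(zi) & zi > z_thresh
  is_con <- pi_v > p_thresh
  role[is_hub & !is_con] <- "module hub"
  role[!is_hub & is_con] <- "connector"
  role[is_hub & is_con] <- "network hub"
  data.frame(taxon = nodes, module = unname(mem), degree = unname(deg),
             within_degree = unname(k_within), Zi = unname(zi),
             Pi = unname(pi_v), role = role, keystone = role != "peripheral",
             stringsAsFactors = FALSE)
}

#' Extract the sub-network around focal taxa
#'
#' Induces the graph on the focal taxa plus their direct neighbours and
#' reports the fraction of focal-incident edges that are positive.
#'
#' @param net a `"cooccurrence_network"`.
#' @param focal character vector of focal taxon ids (must be nodes).
#' @return list with `subnetwork` (a `"cooccurrence_network"`),
#'   `positive_fraction` and `n_focal_edges`.
#' @export
extract_subnetwork <- function(net, focal) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  missing <- setdiff(focal, igraph::V(g)$name)
  if (length(missing))
    stop("focal taxa absent from network: ", paste(missing, collapse = ", "))
  nb <- unique(unlist(lapply(focal, function(v)
    igraph::neighbors(g, v)$name)))
  keep <- union(focal, nb)
  sg <- igraph::induced_subgraph(g, keep)
  ends <- igraph::ends(sg, igraph::E(sg))
  focal_edge <- ends[, 1] %in% focal | ends[, 2] %in% focal
  pos_frac <- if (any(focal_edge))
    mean(igraph::E(sg)$sign[focal_edge] == "positive") else NA_real_
  edges <- data.frame(source = ends[, 1], target = ends[, 2],
                      r = igraph::E(sg)$weight, sign = igraph::E(sg)$sign,
                      stringsAsFactors = FALSE)
  comm <- igraph::cluster_fast_greedy(sg, weights = NA)
  sub <- structure(list(graph = sg, edges = edges, threshold = net$threshold,
                        modules = stats::setNames(igraph::membership(comm),
                                                  igraph::V(sg)$name),
                        indices = network_indices(sg)),
                   class = "cooccurrence_network")
  list(subnetwork = sub, positive_fraction = pos_frac,
       n_focal_edges = sum(focal_edge))
}

#' One-call network construction from an abundance table
#'
#' Chains [prepare_network_input()], Pearson correlation, [rmt_threshold()]
#' and [build_network()].
#'
#' @inheritParams prepare_network_input
#' @param s_min,s_max,step RMT scan grid.
#' @return list with `prepared`, `correlations`, `scan`, `network`.
#' @export
build_cooccurrence_network <- function(table, metadata, min_prevalence = NULL,
                                       pseudocount = NULL, s_min = 0.30,
                                       s_max = 0.99, step = 0.01) {
  prep <- prepare_network_input(table, metadata, min_prevalence, pseudocount)
  corr <- stats::cor(prep, method = "pearson")
  scan <- rmt_threshold(corr, s_min = s_min, s_max = s_max, step = step)
  net <- build_network(corr, scan$chosen_threshold)
  list(prepared = prep, correlations = corr, scan = scan, network = net)
}

#' Write a network edge list to TSV
#' @param net a `"cooccurrence_network"`.
#' @param path output TSV path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network to GraphML
#' @param net a `"cooccurrence_network"`.
#' @param path output GraphML path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
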