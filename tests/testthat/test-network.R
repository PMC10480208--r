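test_that("network input preparation: pile averaging, prevalence, log", {
  sim <- simulate_composting(simulation_config(seed = 2))
  prep <- prepare_network_input(sim$table, sim$metadata)
  expect_equal(nrow(prep), 10)                 # one averaged row per pile
  kept <- colnames(prep)
  # every kept taxon is present in >= 5 of the 10 pile averages
  avg <- t(sapply(unique(sim$metadata$pile), function(p)
    colMeans(unclass(sim$table)[sim$metadata$pile == p, , drop = FALSE])))
  expect_true(all(colSums(avg[, kept] > 0) >= 5))
  dropped <- attr(prep, "dropped_taxa")
  if (length(dropped))
    expect_true(all(colSums(avg[, dropped, drop = FALSE] > 0) < 5))
  # single-pile table: averaging is the identity on that pile
  one <- sim$metadata[sim$metadata$pile == "P01", , drop = FALSE]
  tab1 <- as_abundance_table(unclass(sim$table)[rownames(one)[1], , drop = FALSE])
  prep1 <- prepare_network_input(tab1, one[1, , drop = FALSE],
                                 min_prevalence = 1)
  pc <- attr(prep1, "pseudocount")
  expect_equal(unname(exp(prep1[1, ]) - pc),
               unname(unclass(tab1)[1, colnames(prep1)]), tolerance = 1e-12)
})

test_that("RMT scan: bookkeeping, no-signal case and error path", {
  # identity-like matrix (pure noise correlations) is Poisson from the start
  set.seed(3)
  x <- matrix(rnorm(50 * 40), 50, 40)
  corr <- cor(x)
  scan <- rmt_threshold(corr, s_min = 0.30, s_max = 0.60, step = 0.01)
  expect_s3_class(scan, "rmt_scan")
  expect_equal(nrow(scan$scan), length(seq(0.30, 0.60, 0.01)))
  expect_true(scan$chosen_threshold %in% scan$scan$threshold)
  ok <- !is.na(scan$scan$chisq_poisson)
  expect_gt(sum(ok), 0)
  first_ok <- which(ok)[1]
  expect_lt(scan$scan$chisq_poisson[first_ok], scan$scan$chisq_wigner[first_ok])
  expect_equal(scan$chosen_threshold, scan$scan$threshold[first_ok])
  # too-small matrix: insufficient spectrum
  expect_error(rmt_threshold(cor(matrix(rnorm(50), 10, 5))),
               "insufficient spectrum")
})

test_that("planted-block matrix: threshold separates blocks, modules recover",
{
  pb <- planted_block_data()
  corr <- cor(pb$x)
  scan <- rmt_threshold(corr)
  net <- build_network(corr, scan$chosen_threshold)
  expect_lt(scan$chosen_threshold, 0.8)        # blocks survive the cut
  expect_gt(ari(net$modules, pb$blocks[names(net$modules)]), 0.9)
})

test_that("build_network thresholds edges, drops isolates, errors when empty",
{
  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- 0.9
  corr[1, 3] <- corr[3, 1] <- 0.2
  dimnames(corr) <- list(c("A", "B", "C"), c("A", "B", "C"))
  net <- build_network(corr, 0.8)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))
  expect_equal(net$edges$sign, "positive")
  expect_error(build_network(corr, 0.95), "empty graph.*0.95")
})

test_that("edge count is non-increasing in the threshold", {
  pb <- planted_block_data(seed = 5)
  corr <- cor(pb$x)
  counts <- sapply(seq(0.3, 0.7, 0.1), function(s)
    nrow(build_network(corr, s)$edges))
  expect_true(all(diff(counts) <= 0))
})

test_that("Maslov-Sneppen ensemble preserves the degree sequence exactly", {
  pb <- planted_block_data(seed = 7)
  net <- build_network(cor(pb$x), 0.5)
  ens <- maslov_sneppen_ensemble(net, n_random = 25, seed = 1,
                                 keep_graphs = TRUE)
  d_obs <- sort(igraph::degree(net$graph))
  for (g in ens$graphs)
    expect_identical(sort(igraph::degree(g)), d_obs)
  expect_identical(ens$summary$index, names(net$indices))
})

test_that("rigid star graph yields a warning and zero-variance ensemble", {
  corr <- diag(5)
  corr[1, 2:5] <- corr[2:5, 1] <- 0.9
  dimnames(corr) <- list(letters[1:5], letters[1:5])
  net <- build_network(corr, 0.5)
  expect_warning(ens <- maslov_sneppen_ensemble(net, n_random = 10, seed = 2),
                 "identical copies")
  expect_true(all(ens$summary$null_sd == 0))
})

test_that("Erdos-Renyi networks sit inside their own null ensemble", {
  set.seed(8)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- sprintf("n%d", 1:40)
  igraph::E(g)$weight <- 1; igraph::E(g)$sign <- "positive"
  ends <- igraph::ends(g, igraph::E(g))
  net <- structure(list(graph = g,
                        edges = data.frame(source = ends[, 1],
                                           target = ends[, 2]),
                        threshold = 0.5,
                        modules = igraph::membership(
                          igraph::cluster_fast_greedy(g, weights = NA)),
                        indices = compostcoop:::network_indices(g)),
                   class = "cooccurrence_network")
  ens <- maslov_sneppen_ensemble(net, n_random = 100, seed = 3)
  z_cc <- ens$summary$z[ens$summary$index == "clustering_coefficient"]
  expect_lt(abs(z_cc), 3)
})

test_that("Zi/Pi match hand-computed values on the two-module toy graph", {
  toy <- toy_role_graph()
  net <- build_network(toy$corr, 0.5)
  roles <- module_roles(net, membership = toy$membership)
  rownames(roles) <- roles$taxon
  # hand-worked within-module degrees: A = (5,2,2,2,2,1), B = (3,2,2,1,1,1)
  zi_a <- (c(5, 2, 2, 2, 2, 1) - mean(c(5, 2, 2, 2, 2, 1))) /
    sd(c(5, 2, 2, 2, 2, 1))
  zi_b <- (c(3, 2, 2, 1, 1, 1) - mean(c(3, 2, 2, 1, 1, 1))) /
    sd(c(3, 2, 2, 1, 1, 1))
  expect_equal(roles[paste0("a", 1:6), "Zi"], zi_a, tolerance = 1e-12)
  expect_equal(roles[paste0("b", 1:6), "Zi"], zi_b, tolerance = 1e-12)
  # participation: closed forms 1 - sum((k_im/k_i)^2)
  expect_equal(roles["a1", "Pi"], 0)                      # all edges inside
  expect_equal(roles["a2", "Pi"], 1 - (2/3)^2 - (1/3)^2)  # 4/9
  expect_equal(roles["a6", "Pi"], 0.5)                    # degree 2 split 1/1
  expect_equal(roles["b1", "Pi"], 1 - (3/4)^2 - (1/4)^2)
  expect_equal(roles["b4", "Pi"], 0)
  expect_true(all(roles$Pi >= 0 & roles$Pi <= 1))
})

test_that("nodes with an even 2/2 module split get Pi = 0.5", {
  corr <- diag(5)
  corr[1, 2:5] <- corr[2:5, 1] <- 0.9
  dimnames(corr) <- list(letters[1:5], letters[1:5])
  net <- build_network(corr, 0.5)
  mem <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  roles <- module_roles(net, membership = mem)
  expect_equal(roles$Pi[roles$taxon == "a"], 1 - 0.5^2 - 0.5^2)
})

test_that("singleton modules flag their node peripheral with a warning", {
  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- 0.9
  corr[2, 3] <- corr[3, 2] <- 0.9
  dimnames(corr) <- list(c("x", "y", "z"), c("x", "y", "z"))
  net <- build_network(corr, 0.5)
  expect_warning(roles <- module_roles(net, membership = c(x = 1, y = 1, z = 2)),
                 "singleton module")
  expect_true(is.na(roles$Zi[roles$taxon == "z"]))
  expect_equal(roles$role[roles$taxon == "z"], "peripheral")
})

test_that("sub-network extraction reports focal positive-edge fraction", {
  corr <- diag(6)
  # focal node f: 3 positive neighbours, 1 negative; plus a detached pair
  corr[1, 2] <- corr[2, 1] <- 0.9
  corr[1, 3] <- corr[3, 1] <- 0.8
  corr[1, 4] <- corr[4, 1] <- 0.7
  corr[1, 5] <- corr[5, 1] <- -0.9
  corr[5, 6] <- corr[6, 5] <- 0.9
  dimnames(corr) <- list(c("f", "n1", "n2", "n3", "n4", "far"),
                         c("f", "n1", "n2", "n3", "n4", "far"))
  net <- build_network(corr, 0.5)
  sub <- extract_subnetwork(net, "f")
  expect_equal(sub$positive_fraction, 0.75)
  expect_setequal(igraph::V(sub$subnetwork$graph)$name,
                  c("f", "n1", "n2", "n3", "n4"))
  # focal = all nodes reproduces the input graph
  all_sub <- extract_subnetwork(net, igraph::V(net$graph)$name)
  expect_equal(igraph::ecount(all_sub$subnetwork$graph),
               igraph::ecount(net$graph))
  expect_error(extract_subnetwork(net, c("f", "ghost")), "ghost")
})

test_that("edge list and GraphML writers emit readable files", {
  toy <- toy_role_graph()
  net <- build_network(toy$corr, 0.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  el <- utils::read.delim(f)
  expect_equal(nrow(el), igraph::ecount(net$graph))
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g)
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))
})
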