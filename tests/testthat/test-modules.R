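test_that("definition parser handles leaves, steps, alternatives, complexes", {
  d <- parse_module_definition("K00001")
  expect_equal(d$tree, list(op = "ko", ko = "K00001"))
  d2 <- parse_module_definition("(K1,K2) K3+K4")
  expect_equal(d2$tree$op, "seq")
  expect_length(d2$tree$args, 2)
  expect_equal(d2$tree$args[[1]],
               list(op = "alt", args = list(list(op = "ko", ko = "K1"),
                                            list(op = "ko", ko = "K2"))))
  expect_equal(d2$tree$args[[2]],
               list(op = "cat", args = list(list(op = "ko", ko = "K3"),
                                            list(op = "ko", ko = "K4"))))
  # optional components are marked, not dropped, at parse time
  d3 <- parse_module_definition("K1-K2")
  expect_equal(d3$tree$args[[2]]$op, "opt")
})

test_that("parse errors carry positions", {
  expect_error(parse_module_definition("K1 (K2"), "parse error at position")
  expect_error(parse_module_definition("K1,,K2"), "empty alternative")
  expect_error(parse_module_definition("K1 & K2"), "illegal character")
  expect_error(parse_module_definition("K1 K2)"), "position")
  expect_error(parse_module_definition("   "), "non-empty")
})

test_that("unparse(parse(text)) re-parses to an identical tree", {
  defs <- c(builtin_module_definitions(),
            x1 = "(K1 K2,K3 K4) K5", x2 = "K1+K2-K3 (K4,K5+K6)",
            x3 = "((K1,K2) K3,K4) K5")
  for (txt in defs) {
    tree <- parse_module_definition(txt)$tree
    round <- parse_module_definition(unparse_module_definition(tree))$tree
    expect_identical(round, tree)
  }
})

test_that("completeness scores steps with best-alternative credit", {
  d <- parse_module_definition("(K1,K2) K3")
  expect_equal(completeness(c("K1", "K2", "K3"), d), 1)
  expect_equal(completeness("K2", d), 0.5)
  expect_equal(completeness(character(0), d), 0)
  # complexes are all-or-nothing within a step
  dc <- parse_module_definition("K1+K2 K3")
  expect_equal(completeness(c("K1", "K3"), dc), 0.5)
  expect_equal(completeness(c("K1", "K2"), dc), 0.5)
  expect_equal(completeness(c("K1", "K2", "K3"), dc), 1)
  # OR over parenthesized multi-step alternatives: best alternative's fraction
  dm <- parse_module_definition("((K1 K2),(K3 K4 K5)) K6")
  expect_equal(completeness(c("K1"), dm), 0.25)       # best alt 1/2 -> step 0.5
  expect_equal(completeness(c("K3", "K4"), dm), 1/3)  # best alt 2/3
  expect_equal(completeness(c("K1", "K2", "K6"), dm), 1)
  # optional components never penalize
  do <- parse_module_definition("K1 -K2")
  expect_equal(completeness("K1", do), 1)
  expect_equal(completeness(character(0), do), 0)
})

test_that("completeness matches hand-coded step enumeration over power sets", {
  # independent oracles: each definition's step logic coded explicitly
  cases <- list(
    list(text = "(K1,K2) K3",
         kos = c("K1", "K2", "K3"),
         oracle = function(s) mean(c(("K1" %in% s) || ("K2" %in% s),
                                     "K3" %in% s))),
    list(text = "K1 K2+K3 (K4,(K5 K6))",
         kos = c("K1", "K2", "K3", "K4", "K5", "K6"),
         oracle = function(s) mean(c("K1" %in% s,
                                     ("K2" %in% s) && ("K3" %in% s),
                                     max("K4" %in% s,
                                         mean(c("K5" %in% s, "K6" %in% s)))))),
    list(text = "K1 -K2 K3",
         kos = c("K1", "K2", "K3"),
         oracle = function(s) mean(c("K1" %in% s, "K3" %in% s))))
  for (cs in cases) {
    def <- parse_module_definition(cs$text)
    n <- length(cs$kos)
    for (mask in 0:(2^n - 1)) {
      s <- cs$kos[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      expect_equal(completeness(s, def), cs$oracle(s),
                   info = paste(cs$text, "with", paste(s, collapse = ",")))
    }
  }
})

test_that("completeness is monotone under KO insertion", {
  set.seed(14)
  defs <- lapply(builtin_module_definitions(), parse_module_definition)
  all_kos <- unique(unlist(lapply(defs, module_kos, include_optional = TRUE)))
  for (rep_i in 1:20) {
    s <- sample(all_kos, sample.int(length(all_kos) - 1, 1) - 1)
    extra <- sample(setdiff(all_kos, s), 1)
    for (d in defs)
      expect_gte(completeness(c(s, extra), d), completeness(s, d))
  }
})

test_that("completeness matrix + clustering split disjoint populations", {
  defs <- c(MA = "K1 K2 K3", MB = "K4 K5 K6")
  ann <- rbind(
    data.frame(genome_id = rep(sprintf("g%d", 1:4), each = 3),
               ko_id = rep(c("K1", "K2", "K3"), 4)),
    data.frame(genome_id = rep(sprintf("h%d", 1:4), each = 3),
               ko_id = rep(c("K4", "K5", "K6"), 4)))
  cm <- completeness_matrix(ann, defs)
  expect_equal(dim(cm), c(8, 2))
  expect_true(all(cm >= 0 & cm <= 1))
  grp <- group_genomes(cm, k = 2)
  truth <- rep(1:2, each = 4)
  expect_equal(ari(grp, truth), 1)
  # k = number of genomes: singleton groups
  expect_equal(length(unique(group_genomes(cm, k = 8))), 8)
  expect_error(group_genomes(cm, k = 0), ">= 1")
  expect_error(group_genomes(cm, k = 9), "exceeds")
})

test_that("planted genome groups are recovered from completeness profiles", {
  gn <- simulate_genomes(n_genomes = 105, n_groups = 7,
                         producer_fraction = 0.1, seed = 6)
  cm <- completeness_matrix(gn$annotations, gn$module_defs)
  grp <- group_genomes(cm, k = 7)
  expect_gte(ari(grp[names(gn$truth$group)], gn$truth$group), 0.9)
})

test_that("group completeness rule: strictly over half above the cutoff", {
  cm <- matrix(c(1.0, 1.0, 1.0, 0.2,
                 0.7, 0.5, 0.7, 0.5), 4, 2,
               dimnames = list(sprintf("g%d", 1:4), c("M1", "M2")))
  groups <- stats::setNames(c(1, 1, 1, 1), rownames(cm))
  out <- group_complete_modules(cm, groups, 0.67, 0.5)
  expect_true("M1" %in% out[["1"]])               # 3/4 > 1/2
  expect_false("M2" %in% out[["1"]])              # 2/4 not > 1/2 (strict)
  two <- matrix(c(0.7, 0.5), 2, 1,
                dimnames = list(c("a", "b"), "M"))
  out2 <- group_complete_modules(two, c(a = 1, b = 1), 0.67, 0.5)
  expect_length(out2[["1"]], 0)                   # 1/2 not > 1/2
  expect_equal(attr(out, "completeness_cutoff"), 0.67)
  expect_equal(attr(out, "member_fraction"), 0.5)
  expect_error(group_complete_modules(cm, groups, 2, 0.5), "\\(0, 1\\]")
})

test_that("shared/unique counts are exclusive and total-preserving", {
  gm <- list(I = c("m1", "m2", "m3", "m5"),
             II = c("m2", "m3", "m4"),
             III = c("m3", "m4", "m6"))
  out <- shared_unique_sets(gm)
  # brute-force oracle over the 7 combinations
  lookup <- stats::setNames(out$count, out$combination)
  expect_equal(unname(lookup[["I"]]), 2)          # m1, m5
  expect_equal(unname(lookup[["I+II"]]), 1)       # m2
  expect_equal(unname(lookup[["I+II+III"]]), 1)   # m3
  expect_equal(unname(lookup[["II+III"]]), 1)     # m4
  expect_equal(unname(lookup[["III"]]), 1)        # m6
  expect_equal(unname(lookup[["II"]]), 0)
  expect_equal(unname(lookup[["I+III"]]), 0)
  expect_equal(sum(out$count), length(unique(unlist(gm))))
  expect_error(shared_unique_sets(gm["I"]), ">= 2 groups")
})
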