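#' Parse a KEGG-style module definition
#'
#' Grammar subset of the KEGG DEFINITION language: whitespace separates
#' serial steps (AND), a comma separates alternatives (OR), `+` joins the
#' subunits of a complex (AND within a step), a leading `-` marks an
#' optional component (never scored), and parentheses nest. Precedence,
#' loosest to tightest: space, comma, plus.
#'
#' @param text definition string, e.g. `"(K1,K2) K3+K4"`.
#' @param module_id optional module identifier to attach.
#' @return object of class `"module_definition"`: the source `text`, the
#'   `module_id`, and the parse `tree` (nested lists with `op` in
#'   `seq`/`alt`/`cat`/`opt`/`ko`).
#' @export
parse_module_definition <- function(text, module_id = NA_character_) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("module definition must be a non-empty string")
  toks <- tokenize_definition(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  tree <- parse_seq(st)
  if (st$pos <= length(st$toks$type)) {
    tk <- st$toks
    stop("parse error at position ", tk$at[st$pos], " in \"", text,
         "\": unexpected '", tk$value[st$pos], "'")
  }
  structure(list(module_id = module_id, text = text, tree = tree),
            class = "module_definition")
}

tokenize_definition <- function(text) {
  chars <- strsplit(text, "")[[1]]
  type <- character(0); value <- character(0); at <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      # collapse runs of whitespace into one step separator
      if (length(type) && type[length(type)] != "ws") {
        type <- c(type, "ws"); value <- c(value, " "); at <- c(at, i)
      }
      i <- i + 1L
    } else if (ch %in% c("(", ")", ",", "+", "-")) {
      type <- c(type, ch); value <- c(value, ch); at <- c(at, i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[j])) j <- j + 1L
      type <- c(type, "ko")
      value <- c(value, paste(chars[i:(j - 1)], collapse = ""))
      at <- c(at, i)
      i <- j
    } else {
      stop("parse error at position ", i, " in \"", text,
           "\": illegal character '", ch, "'")
    }
  }
  # strip leading/trailing whitespace tokens
  keep <- !(type == "ws" & (seq_along(type) == 1 | seq_along(type) == length(type)))
  if (length(type) && type[length(type)] == "ws") keep[length(type)] <- FALSE
  if (length(type) && type[1] == "ws") keep[1] <- FALSE
  list(type = type[keep], value = value[keep], at = at[keep])
}

peek <- function(st) if (st$pos <= length(st$toks$type)) st$toks$type[st$pos] else ""
perr <- function(st, msg) {
  at <- if (st$pos <= length(st$toks$at)) st$toks$at[st$pos] else nchar(st$text) + 1L
  stop("parse error at position ", at, " in \"", st$text, "\": ", msg)
}

parse_seq <- function(st) {
  steps <- list(parse_alt(st))
  while (peek(st) == "ws") {
    st$pos <- st$pos + 1L
    steps <- c(steps, list(parse_alt(st)))
  }
  if (length(steps) == 1) steps[[1]] else list(op = "seq", args = steps)
}

parse_alt <- function(st) {
  alts <- list(parse_cat(st))
  while (peek(st) == ",") {
    st$pos <- st$pos + 1L
    if (peek(st) %in% c("", ")", ",", "ws")) perr(st, "empty alternative")
    alts <- c(alts, list(parse_cat(st)))
  }
  if (length(alts) == 1) alts[[1]] else list(op = "alt", args = alts)
}

parse_cat <- function(st) {
  parts <- list(parse_unit(st))
  while (peek(st) %in% c("+", "-")) {
    optional <- st$toks$type[st$pos] == "-"
    st$pos <- st$pos + 1L
    u <- parse_unit(st)
    if (optional) u <- list(op = "opt", args = list(u))
    parts <- c(parts, list(u))
  }
  if (length(parts) == 1) parts[[1]] else list(op = "cat", args = parts)
}

parse_unit <- function(st) {
  t <- peek(st)
  if (t == "ko") {
    v <- st$toks$value[st$pos]; st$pos <- st$pos + 1L
    list(op = "ko", ko = v)
  } else if (t == "-") {
    st$pos <- st$pos + 1L
    list(op = "opt", args = list(parse_unit(st)))
  } else if (t == "(") {
    st$pos <- st$pos + 1L
    inner <- parse_seq(st)
    if (peek(st) != ")") perr(st, "unbalanced parentheses (expected ')')")
    st$pos <- st$pos + 1L
    inner
  } else {
    perr(st, "expected a KO identifier or '('")
  }
}

#' Serialize a parsed module definition back to text
#' @param def a `"module_definition"` (or a parse tree).
#' @return definition string that re-parses to an identical tree.
#' @export
unparse_module_definition <- function(def) {
  tree <- if (inherits(def, "module_definition")) def$tree else def
  un <- function(node, parent) {
    if (node$op == "ko") return(node$ko)
    if (node$op == "opt") return(paste0("-", un(node$args[[1]], "cat")))
    sep <- switch(node$op, seq = " ", alt = ",", cat = "+")
    s <- paste(vapply(node$args, un, "", node$op), collapse = sep)
    # parenthesize when a looser operator sits under a tighter context
    need <- (node$op == "seq" && parent != "top") ||
            (node$op == "alt" && parent %in% c("cat", "alt")) ||
            (node$op == "cat" && parent == "cat")
    if (need) paste0("(", s, ")") else s
  }
  un(tree, "top")
}

#' @export
print.module_definition <- function(x, ...) {
  cat("module_definition",
      if (!is.na(x$module_id)) paste0("[", x$module_id, "]"), ":",
      x$text, "\n")
  invisible(x)
}

#' KO identifiers appearing in a module definition
#' @param def a `"module_definition"`.
#' @param include_optional also list KOs under optional markers.
#' @return character vector of unique KO ids.
#' @export
module_kos <- function(def, include_optional = FALSE) {
  tree <- if (inherits(def, "module_definition")) def$tree else def
  walk <- function(node) {
    if (node$op == "ko") return(node$ko)
    if (node$op == "opt" && !include_optional) return(character(0))
    unlist(lapply(node$args, walk))
  }
  unique(walk(tree))
}

#' Module completeness of a genome
#'
#' Completeness is the fraction of serial steps satisfied: the parse tree
#' is scored recursively with leaves as 0/1 presence in the KO set,
#' complexes (`+`) as the minimum of their parts, alternatives (`,`) as the
#' maximum — so an OR over multi-step alternatives scores the best
#' alternative's fractional completeness — serial steps (space) as the mean
#' of their parts, and optional components excluded entirely.
#'
#' @param ko_set character vector of KO ids the genome carries (or a
#'   one-genome annotation data.frame with column `ko_id`).
#' @param def a `"module_definition"` (or definition string).
#' @return completeness fraction in `[0, 1]`.
#' @export
completeness <- function(ko_set, def) {
  if (is.data.frame(ko_set)) ko_set <- ko_set$ko_id
  if (is.character(def)) def <- parse_module_definition(def)
  sc <- function(node) {
    switch(node$op,
           ko = as.numeric(node$ko %in% ko_set),
           opt = NA_real_,
           cat = { v <- vapply(node$args, sc, 0); v <- v[!is.na(v)]
                   if (length(v)) min(v) else NA_real_ },
           alt = { v <- vapply(node$args, sc, 0); v <- v[!is.na(v)]
                   if (length(v)) max(v) else NA_real_ },
           seq = { v <- vapply(node$args, sc, 0); v <- v[!is.na(v)]
                   if (length(v)) mean(v) else NA_real_ },
           stop("unknown node op: ", node$op))
  }
  out <- sc(if (inherits(def, "module_definition")) def$tree else def)
  if (is.na(out)) 0 else out
}

#' Genomes x modules completeness matrix
#'
#' @param annotations long data.frame (genome_id, ko_id).
#' @param module_defs named character vector of definitions, or a list of
#'   `"module_definition"` objects.
#' @return numeric genomes x modules matrix of completeness fractions.
#' @export
completeness_matrix <- function(annotations, module_defs) {
  if (!all(c("genome_id", "ko_id") %in% names(annotations)))
    stop("`annotations` needs columns genome_id and ko_id")
  defs <- if (is.character(module_defs))
    mapply(parse_module_definition, module_defs, names(module_defs),
           SIMPLIFY = FALSE)
  else module_defs
  if (is.null(names(defs))) names(defs) <-
      vapply(defs, function(d) d$module_id, "")
  ko_by_genome <- split(annotations$ko_id, annotations$genome_id)
  genomes <- names(ko_by_genome)
  out <- matrix(0, length(genomes), length(defs),
                dimnames = list(genomes, names(defs)))
  for (g in seq_along(genomes))
    for (m in seq_along(defs))
      out[g, m] <- completeness(ko_by_genome[[g]], defs[[m]])
  out
}

#' Cluster genomes into functional groups
#'
#' Agglomerative hierarchical clustering (Ward linkage, Euclidean distance)
#' of completeness profiles, cut at `k` groups. Deterministic given input
#' order.
#'
#' @param matrix genomes x modules completeness matrix.
#' @param k number of groups (default 7).
#' @return named integer group labels (I.. analogues as integers 1..k).
#' @export
group_genomes <- function(matrix, k = 7) {
  if (k < 1) stop("`k` must be >= 1")
  if (k > nrow(matrix)) stop("`k` exceeds number of genomes")
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Group-level complete modules
#'
#' A module is complete in a group iff strictly more than `member_fraction`
#' of the group's members have completeness strictly above
#' `completeness_cutoff` (defaults: over half above 67%).
#'
#' @param matrix genomes x modules completeness matrix.
#' @param groups named group labels for the genomes.
#' @param completeness_cutoff per-genome completeness cutoff in `(0, 1]`.
#' @param member_fraction group member fraction in `(0, 1]`.
#' @return named list: group label to character vector of complete modules,
#'   with the cutoffs attached as attributes.
#' @export
group_complete_modules <- function(matrix, groups, completeness_cutoff = 0.67,
                                   member_fraction = 0.5) {
  if (completeness_cutoff <= 0 || completeness_cutoff > 1 ||
      member_fraction <= 0 || member_fraction > 1)
    stop("cutoffs must be in (0, 1]")
  groups <- groups[rownames(matrix)]
  if (any(is.na(groups))) stop("groups missing for some genomes")
  out <- lapply(split(rownames(matrix), groups), function(members) {
    if (!length(members)) stop("empty group")
    sub <- matrix[members, , drop = FALSE]
    frac <- colMeans(sub > completeness_cutoff)
    colnames(matrix)[frac > member_fraction]
  })
  attr(out, "completeness_cutoff") <- completeness_cutoff
  attr(out, "member_fraction") <- member_fraction
  out
}

#' Exclusive shared/unique module counts across groups
#'
#' For every non-empty combination of groups, counts the modules complete
#' in exactly that combination (upset-style exclusive intersections).
#'
#' @param group_modules named list: group to complete-module set.
#' @return data.frame (combination, n_groups, count), one row per non-empty
#'   group combination, ordered by decreasing count.
#' @export
shared_unique_sets <- function(group_modules) {
  if (length(group_modules) < 2) stop("need >= 2 groups")
  gnames <- names(group_modules)
  all_modules <- unique(unlist(group_modules))
  combo_of <- vapply(all_modules, function(m) {
    inn <- gnames[vapply(group_modules, function(s) m %in% s, logical(1))]
    paste(inn, collapse = "+")
  }, "")
  # enumerate every non-empty combination (2^g - 1 of them)
  combos <- unlist(lapply(seq_along(gnames), function(sz)
    utils::combn(gnames, sz, paste, collapse = "+", simplify = FALSE)))
  counts <- vapply(combos, function(cb) sum(combo_of == cb), 0L)
  n_groups <- lengths(strsplit(unlist(combos), "+", fixed = TRUE))
  out <- data.frame(combination = unlist(combos), n_groups = n_groups,
                    count = counts, stringsAsFactors = FALSE)
  out[order(-out$count, out$n_groups, out$combination), , drop = FALSE]
}
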