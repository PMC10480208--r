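#' Relative yield changes of a co-cultured pair
#'
#' Computes each strain's yield change between co-culture and monoculture
#' replicates: by default the relative change
#' `(mean(co) - mean(mono)) / mean(mono)`; `"log"` gives
#' `log(mean(co)/mean(mono))` and `"absolute"` the raw difference.
#' Per-strain significance is a two-sided two-sample t-test on the
#' replicates at level `alpha`; with a single replicate per arm the flag is
#' `NA` (undefined) with a warning.
#'
#' @param mono_a,co_a,mono_b,co_b replicate yield vectors (> 0).
#' @param scale `"relative"` (default), `"log"`, or `"absolute"`.
#' @param alpha significance level (default 0.05).
#' @return list with `delta_a`, `delta_b`, `sig_a`, `sig_b`.
#' @export
yield_deltas <- function(mono_a, co_a, mono_b, co_b,
                         scale = c("relative", "log", "absolute"),
                         alpha = 0.05) {
  scale <- match.arg(scale)
  arms <- list(mono_a = mono_a, co_a = co_a, mono_b = mono_b, co_b = co_b)
  for (nm in names(arms)) {
    v <- arms[[nm]]
    if (!length(v)) stop("`", nm, "` needs >= 1 replicate")
    if (any(!is.finite(v)) || any(v <= 0))
      stop("yields must be finite and > 0 (", nm, ")")
  }
  dl <- function(mono, co) switch(scale,
    relative = (mean(co) - mean(mono)) / mean(mono),
    log = log(mean(co) / mean(mono)),
    absolute = mean(co) - mean(mono))
  sig <- function(mono, co) {
    if (length(mono) < 2 || length(co) < 2) {
      warning("single replicate: significance undefined")
      return(NA)
    }
    if (stats::sd(mono) == 0 && stats::sd(co) == 0)  # degenerate replicates
      return(mean(co) != mean(mono))
    tryCatch(stats::t.test(co, mono, alternative = "two.sided")$p.value < alpha,
             error = function(e) mean(co) != mean(mono))
  }
  list(delta_a = dl(mono_a, co_a), delta_b = dl(mono_b, co_b),
       sig_a = sig(mono_a, co_a), sig_b = sig(mono_b, co_b))
}

#' Polar angle of a pairwise interaction
#'
#' Plots the unordered pair of yield changes `(delta_a, delta_b)` in polar
#' coordinates under the convention that the line `y = -x` maps to 0
#' degrees: the pair is first reflected across `y = x` so the
#' representative has `delta_a >= delta_b` (the pair is unordered), then
#' `theta = atan2(delta_b, delta_a) + 45` degrees, landing in `[-90, 90]`.
#' So `(+1, +1)` gives 90 (equally facilitated), `(-1, -1)` gives -90
#' (equally inhibited), `(+1, -1)` gives 0 (the reference line), and
#' `(0, +1)` gives 45 (commensalism boundary).
#'
#' @param delta_a,delta_b yield changes; not both zero.
#' @return angle in degrees in `[-90, 90]`, with attribute `"reflected"`.
#' @export
polar_angle <- function(delta_a, delta_b) {
  if (!is.finite(delta_a) || !is.finite(delta_b))
    stop("deltas must be finite")
  if (delta_a == 0 && delta_b == 0)
    stop("undefined angle at the origin (both deltas zero)")
  reflected <- delta_a < delta_b
  if (reflected) { tmp <- delta_a; delta_a <- delta_b; delta_b <- tmp }
  theta <- atan2(delta_b, delta_a) * 180 / pi + 45
  structure(theta, reflected = reflected)
}

#' Interaction strength (magnitude)
#'
#' Default formula: the Euclidean norm `sqrt(delta_a^2 + delta_b^2)`;
#' pluggable via `formula`.
#'
#' @param delta_a,delta_b yield changes.
#' @param formula function of `(delta_a, delta_b)` returning a
#'   non-negative scalar.
#' @return magnitude `m >= 0`.
#' @export
interaction_magnitude <- function(delta_a, delta_b,
                                  formula = function(a, b) sqrt(a^2 + b^2)) {
  m <- formula(delta_a, delta_b)
  if (!is.finite(m) || m < 0) stop("magnitude formula must return a value >= 0")
  m
}

#' Classify an interaction from its polar angle
#'
#' Angle mode partitions `[-90, 90]`: `-90` equally inhibited,
#' `(-90, -45)` competition, `-45` amensalism, `(-45, 0)` and `(0, 45)`
#' parasitism, `0` on the reference line labelled per `zero_label`
#' (default parasitism), `45` commensalism, `(45, 90)` mutualism, `90`
#' equally facilitated. Gated mode first consults the per-strain
#' significance flags: neither significant gives neutral; exactly one
#' significant gives commensalism (theta > 0) or amensalism (theta < 0);
#' both significant fall through to the angle intervals.
#'
#' @param theta angle in degrees in `[-90, 90]`.
#' @param sig_a,sig_b per-strain significance flags (gated mode).
#' @param mode `"angle"` (default) or `"gated"`.
#' @param zero_label label for exactly 0 degrees in angle mode.
#' @return character label.
#' @export
classify_interaction <- function(theta, sig_a = NA, sig_b = NA,
                                 mode = c("angle", "gated"),
                                 zero_label = "parasitism") {
  mode <- match.arg(mode)
  if (!is.finite(theta) || theta < -90 || theta > 90)
    stop("`theta` must lie in [-90, 90], got ", theta)
  if (mode == "gated") {
    n_sig <- sum(c(isTRUE(sig_a), isTRUE(sig_b)))
    if (n_sig == 0) return("neutral")
    if (n_sig == 1) return(if (theta > 0) "commensalism" else "amensalism")
  }
  if (theta == -90) return("equally inhibited")
  if (theta < -45) return("competition")
  if (theta == -45) return("amensalism")
  if (theta == 0) return(zero_label)
  if (theta < 45) return("parasitism")
  if (theta == 45) return("commensalism")
  if (theta < 90) return("mutualism")
  "equally facilitated"
}

#' Call interactions for a table of co-culture records
#'
#' Aggregates replicate rows per pair, computes yield deltas, the polar
#' angle, the magnitude and the type label for every pair. Pairs whose
#' deltas are exactly `(0, 0)` are labelled neutral with an undefined
#' angle.
#'
#' @param records long co-culture data.frame as produced by
#'   [simulate_coculture()] / [read_coculture()].
#' @param scale,alpha see [yield_deltas()].
#' @param mode,zero_label see [classify_interaction()].
#' @return object of class `"interaction_calls"`: a data.frame (pair_id,
#'   temperature, medium, delta_a, delta_b, theta, magnitude, label,
#'   sig_a, sig_b).
#' @export
call_interactions <- function(records, scale = "relative", alpha = 0.05,
                              mode = c("gated", "angle"),
                              zero_label = "parasitism") {
  mode <- match.arg(mode)
  need <- c("pair_id", "mono_yield_a", "mono_yield_b", "co_yield_a",
            "co_yield_b")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(records, records$pair_id), function(rec) {
    d <- yield_deltas(rec$mono_yield_a, rec$co_yield_a,
                      rec$mono_yield_b, rec$co_yield_b,
                      scale = scale, alpha = alpha)
    m <- interaction_magnitude(d$delta_a, d$delta_b)
    if (d$delta_a == 0 && d$delta_b == 0) {
      theta <- NA_real_; label <- "neutral"
    } else {
      theta <- as.numeric(polar_angle(d$delta_a, d$delta_b))
      label <- classify_interaction(theta, d$sig_a, d$sig_b, mode = mode,
                                    zero_label = zero_label)
    }
    data.frame(pair_id = rec$pair_id[1],
               temperature = if ("temperature" %in% names(rec))
                 rec$temperature[1] else NA,
               medium = if ("medium" %in% names(rec)) rec$medium[1] else NA,
               delta_a = d$delta_a, delta_b = d$delta_b, theta = theta,
               magnitude = m, label = label,
               sig_a = d$sig_a, sig_b = d$sig_b, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$pair_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("interaction_calls", "data.frame")
  calls
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf("interaction calls for %d pairs; mean strength %.3f\n",
              nrow(x), mean(x$magnitude)))
  print(round(100 * table(x$label) / nrow(x), 1))
  invisible(as.data.frame(x))
}

#' Summarize interaction calls by grouping factors
#'
#' Per group: number of pairs, mean magnitude, and the proportion of every
#' interaction label. For each grouping factor with exactly two levels a
#' two-sided Welch t-test compares magnitudes between the levels.
#'
#' @param calls an `"interaction_calls"` data.frame.
#' @param by character vector of grouping columns (default
#'   `"temperature"`).
#' @return list with `groups` (summary data.frame) and `comparisons`
#'   (factor, level_a, level_b, p).
#' @export
summarize_interactions <- function(calls, by = "temperature") {
  miss <- setdiff(by, names(calls))
  if (length(miss)) stop("grouping column(s) absent: ",
                         paste(miss, collapse = ", "))
  key <- interaction(calls[by], drop = TRUE, sep = ":")
  labels <- sort(unique(calls$label))
  rows <- lapply(split(calls, key), function(g) {
    if (!nrow(g)) return(NULL)
    props <- as.list(vapply(labels, function(l) mean(g$label == l), 0))
    names(props) <- paste0("prop_", gsub(" ", "_", labels))
    cbind(data.frame(group = paste(vapply(by, function(b) as.character(g[[b]][1]), ""),
                                   collapse = ":"),
                     n = nrow(g), mean_magnitude = mean(g$magnitude),
                     stringsAsFactors = FALSE),
          as.data.frame(props))
  })
  groups <- do.call(rbind, rows)
  rownames(groups) <- NULL
  comps <- list()
  for (b in by) {
    lev <- unique(calls[[b]])
    if (length(lev) == 2) {
      m1 <- calls$magnitude[calls[[b]] == lev[1]]
      m2 <- calls$magnitude[calls[[b]] == lev[2]]
      p <- if (stats::sd(c(m1, m2)) == 0) 1
           else stats::t.test(m1, m2, alternative = "two.sided")$p.value
      comps[[length(comps) + 1]] <-
        data.frame(factor = b, level_a = as.character(lev[1]),
                   level_b = as.character(lev[2]), p = p,
                   stringsAsFactors = FALSE)
    }
  }
  list(groups = groups,
       comparisons = if (length(comps)) do.call(rbind, comps) else NULL)
}

#' Subtract a partner strain's yield from a total-yield measurement
#'
#' Helper for pairs whose qPCR marker overlaps the partner (e.g. a
#' Firmicutes partner measured jointly with a Firmicutes focal strain):
#' subtracts the partner's own yield from the total before calling deltas.
#'
#' @param total replicate vector of joint yields.
#' @param partner replicate vector of the partner's yields.
#' @return corrected yields (floored at a small positive value with a
#'   warning if the subtraction is non-positive).
#' @export
subtract_partner_yield <- function(total, partner) {
  out <- total - partner
  if (any(out <= 0)) {
    warning("non-positive corrected yield(s); floored at 1e-6")
    out[out <= 0] <- 1e-6
  }
  out
}
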