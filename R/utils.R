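# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage sub-seed from one global seed; independent of which
# stages are enabled so reruns with different toggles agree stage-by-stage.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, coculture = 211, genomes = 307, cohesion = 401,
               network = 503, screen = 601, mcn = 701, modules = 809,
               interactions = 907)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000003L) * 2011L + offsets[[stage]]
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop("`", name, "` must be an integer >= ", min)
  as.integer(x)
}
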