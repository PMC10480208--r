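#' Configuration for the composting community simulator
#'
#' Defaults emulate the full-scale composting study design the package's
#' analyses assume: 10 piles sampled at 6 time points (days 0, 5, 12, 20,
#' 25, 30), temperature rising from about 18.9 to 68.8 degrees C and then
#' relaxing back, amplicon tables rarefied to 12,507 reads per sample, and
#' a small set of abundant, slow-growing (low rrn copy number) keystone
#' taxa whose log abundance tracks temperature, positively co-varying with
#' a fast-growing high-rrn guild through a shared latent factor.
#'
#' @param n_piles number of composting piles.
#' @param n_timepoints sampling time points per pile.
#' @param n_taxa total number of taxa (ASVs).
#' @param n_keystones number of planted keystone taxa.
#' @param read_depth reads per sample for the multinomial closure.
#' @param temp_start,temp_peak starting and peak temperature (degrees C).
#' @param temp_coupling effect size of standardized temperature on keystone
#'   log abundance (dimensionless).
#' @param guild_correlation target latent-factor correlation among guild
#'   members, in `[0, 1)`.
#' @param noise_sd sd of log-abundance noise.
#' @param seed integer RNG seed.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_piles = 10, n_timepoints = 6, n_taxa = 80,
                              n_keystones = 3, read_depth = 12507,
                              temp_start = 18.9, temp_peak = 68.8,
                              temp_coupling = 0.6, guild_correlation = 0.6,
                              noise_sd = 0.5, seed = 1) {
  cfg <- list(n_piles = check_count(n_piles, "n_piles"),
              n_timepoints = check_count(n_timepoints, "n_timepoints"),
              n_taxa = check_count(n_taxa, "n_taxa"),
              n_keystones = check_count(n_keystones, "n_keystones"),
              read_depth = check_count(read_depth, "read_depth"),
              temp_start = temp_start, temp_peak = temp_peak,
              temp_coupling = temp_coupling,
              guild_correlation = guild_correlation,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$guild_correlation < 0 || cfg$guild_correlation >= 1)
    stop("`guild_correlation` must be in [0, 1)")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (cfg$n_keystones > cfg$n_taxa)
    stop("configuration error: n_keystones (", cfg$n_keystones,
         ") exceeds n_taxa (", cfg$n_taxa, ")")
  class(cfg) <- "simulation_config"
  cfg
}

# rise-plateau-relaxation temperature template over sampling days
temperature_curve <- function(days, temp_start, temp_peak) {
  n <- length(days)
  temp <- numeric(n)
  temp[1] <- temp_start
  if (n >= 2) temp[2] <- temp_peak           # linear rise over first two points
  if (n >= 3) temp[3] <- temp_peak           # plateau
  if (n >= 4) {
    rate <- 1 / 15                           # per-day relaxation toward start
    for (k in 4:n)
      temp[k] <- temp_start + (temp_peak - temp_start) * exp(-rate * (days[k] - days[3]))
  }
  temp
}

#' Simulate a composting community time series
#'
#' Generates one sample per pile x time point. Per-pile temperature follows
#' a rise-plateau-exponential-relaxation curve with Gaussian pile jitter
#' (sd 2 degrees C). Log-normal latent abundances are closed by a
#' multinomial draw at `read_depth` and renormalized to fractions. Keystone
#' taxa get log abundance proportional to `temp_coupling` times standardized
#' temperature and low rrn copy numbers (1-3); a fast-grower guild shares a
#' temperature-tracking latent factor with the keystones (positive
#' co-variation) and carries high rrn copy numbers (5-10); remaining taxa
#' are temperature-independent noise.
#'
#' @param config a [simulation_config()].
#' @return list with `table` ([abundance_table()], carrying the latent
#'   expected composition as attribute `"expected"`), `metadata`
#'   (sample_id, pile, day, temperature, moisture, cn_ratio), `traits`
#'   (taxon_id, copy_number, guild), and `truth` (keystone ids, guild
#'   memberships).
#' @export
simulate_composting <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    days <- if (cfg$n_timepoints == 6) c(0, 5, 12, 20, 25, 30)
            else round(seq(0, 30, length.out = cfg$n_timepoints))
    base_curve <- temperature_curve(days, cfg$temp_start, cfg$temp_peak)

    piles <- sprintf("P%02d", seq_len(cfg$n_piles))
    n_samples <- cfg$n_piles * cfg$n_timepoints
    sample_id <- character(n_samples)
    pile <- character(n_samples); day <- numeric(n_samples)
    temperature <- numeric(n_samples)
    k <- 0
    for (p in seq_len(cfg$n_piles)) {
      jit <- stats::rnorm(cfg$n_timepoints, 0, 2)   # pile-level jitter, sd 2 C
      for (t in seq_len(cfg$n_timepoints)) {
        k <- k + 1
        sample_id[k] <- sprintf("%s_D%02d", piles[p], days[t])
        pile[k] <- piles[p]; day[k] <- days[t]
        temperature[k] <- base_curve[t] + jit[t]
      }
    }

    taxa <- sprintf("ASV%d", seq_len(cfg$n_taxa))
    n_fast <- min(max(5L, round(0.15 * cfg$n_taxa)), cfg$n_taxa - cfg$n_keystones)
    guild <- rep("background", cfg$n_taxa)
    guild[seq_len(cfg$n_keystones)] <- "keystone"
    if (n_fast > 0)
      guild[cfg$n_keystones + seq_len(n_fast)] <- "fast"
    names(guild) <- taxa

    copy_number <- integer(cfg$n_taxa)
    copy_number[guild == "keystone"] <- sample(1:3, sum(guild == "keystone"), TRUE)
    copy_number[guild == "fast"] <- sample(5:10, sum(guild == "fast"), TRUE)
    copy_number[guild == "background"] <- sample(1:10, sum(guild == "background"), TRUE)

    # two-tier background (volatile opportunist commons + rare tail)
    # emulates the steep, bloom-dominated rank-abundance structure of real
    # amplicon tables, so the keystone screen's abundance / ubiquity /
    # frequent-abundance criteria keep the funnel shape they have on
    # sequencing data: commons are abundant and ubiquitous on average but
    # not stably dominant sample by sample
    base <- numeric(cfg$n_taxa)
    base[guild == "keystone"] <- 1.2        # stably dominant
    base[guild == "fast"] <- -2.5           # individually rare, high rrn
    bg <- which(guild == "background")
    n_common <- min(20L, length(bg))
    common_idx <- bg[seq_len(n_common)]
    base[common_idx] <- stats::rnorm(n_common, 0, 0.5)
    if (length(bg) > n_common)
      base[bg[-seq_len(n_common)]] <-
        stats::rnorm(length(bg) - n_common, -2.5, 1.2)

    zT <- as.numeric(scale(temperature))
    latent <- zT + stats::rnorm(n_samples, 0, 0.5)   # shared guild factor
    lam <- sqrt(cfg$guild_correlation / (1 - cfg$guild_correlation)) * cfg$noise_sd

    loga <- matrix(rep(base, each = n_samples), n_samples, cfg$n_taxa,
                   dimnames = list(sample_id, taxa))
    ks <- guild == "keystone"; fg <- guild == "fast"
    loga[, ks] <- loga[, ks] + cfg$temp_coupling * zT + lam * latent
    loga[, fg] <- loga[, fg] + lam * latent
    loga <- loga + matrix(stats::rnorm(n_samples * cfg$n_taxa, 0, cfg$noise_sd),
                          n_samples, cfg$n_taxa)
    # bloom-style overdispersion of the common background, scaled off the
    # global noise level so a zero-noise run is fully deterministic
    loga[, common_idx] <- loga[, common_idx] +
      matrix(stats::rnorm(n_samples * n_common, 0, 2.8 * cfg$noise_sd),
             n_samples, n_common)

    expected <- exp(loga)
    expected <- sweep(expected, 1, rowSums(expected), "/")
    counts <- t(apply(expected, 1, function(p)
      stats::rmultinom(1, cfg$read_depth, p)[, 1]))
    dimnames(counts) <- dimnames(expected)
    rel <- counts / cfg$read_depth
    table <- abundance_table(rel)
    attr(table, "expected") <- expected

    metadata <- data.frame(
      pile = pile, day = day, temperature = temperature,
      moisture = 70 - day + stats::rnorm(n_samples, 0, 2),
      cn_ratio = 25 - 13 * day / max(day) + stats::rnorm(n_samples, 0, 1),
      row.names = sample_id, stringsAsFactors = FALSE)

    traits <- data.frame(copy_number = copy_number, guild = guild,
                         row.names = taxa, stringsAsFactors = FALSE)

    truth <- list(keystone_taxa = taxa[ks],
                  guild_memberships = guild,
                  planted_interactions = NULL,
                  producer_genomes = NULL)
    list(table = table, metadata = metadata, traits = traits, truth = truth,
         config = cfg)
  })
}

#' Interaction types the co-culture simulator understands
#' @return character vector of supported planted interaction types.
#' @export
coculture_types <- function() {
  c("mutualism", "competition", "parasitism", "commensalism", "amensalism",
    "neutral")
}

# largest-remainder apportionment of n into proportions p
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  k
}

#' Simulate pairwise mono/co-culture yield experiments
#'
#' For each strain pair a planted interaction type sets the direction of
#' the co-culture yield change relative to monoculture (e.g. mutualism
#' raises both partners' yields by about `effect_size`; competition lowers
#' both; parasitism raises one and lowers the other; commensalism /
#' amensalism move exactly one; neutral moves neither). Replicate
#' measurements carry multiplicative log-normal noise of sd `noise_sd`.
#'
#' @param n_pairs number of strain pairs.
#' @param type_mix named proportions over [coculture_types()]; must sum to 1.
#' @param effect_size planted relative yield change (fraction).
#' @param noise_sd multiplicative measurement noise (fraction).
#' @param replicates biological replicates per arm (default 3).
#' @param seed RNG seed.
#' @return list with `records` (long data.frame: one row per pair x
#'   replicate with mono and co yields for both strains, plus temperature
#'   and medium factors) and `truth` (pair to planted type).
#' @export
simulate_coculture <- function(n_pairs = 100,
                               type_mix = c(mutualism = 0.4, competition = 0.2,
                                            parasitism = 0.15, commensalism = 0.1,
                                            amensalism = 0.1, neutral = 0.05),
                               effect_size = 0.6, noise_sd = 0.05,
                               replicates = 3, seed = 1) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  replicates <- check_count(replicates, "replicates")
  bad <- setdiff(names(type_mix), coculture_types())
  if (length(bad))
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         "; supported types are: ", paste(coculture_types(), collapse = ", "))
  if (abs(sum(type_mix) - 1) > 1e-8) stop("`type_mix` proportions must sum to 1")

  delta_for <- list(mutualism = c(1, 1), competition = c(-1, -1),
                    parasitism = c(1, -1), commensalism = c(1, 0),
                    amensalism = c(-1, 0), neutral = c(0, 0))

  with_seed(seed, {
    counts <- apportion(n_pairs, type_mix)
    types <- rep(names(type_mix), counts)
    types <- sample(types)                      # shuffle over pairs
    temperature <- rep_len(c(37, 50), n_pairs)
    medium <- rep_len(c("LB", "LB", "CL"), n_pairs)

    rows <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      dirs <- delta_for[[types[i]]]
      base_a <- stats::rlnorm(1, log(100), 0.1)
      base_b <- stats::rlnorm(1, log(100), 0.1)
      noise <- function(n) exp(stats::rnorm(n, 0, noise_sd))
      rows[[i]] <- data.frame(
        pair_id = sprintf("pair%03d", i),
        strain_a = sprintf("A%03d", i), strain_b = sprintf("B%03d", i),
        temperature = temperature[i], medium = medium[i],
        replicate = seq_len(replicates),
        mono_yield_a = base_a * noise(replicates),
        mono_yield_b = base_b * noise(replicates),
        co_yield_a = base_a * (1 + dirs[1] * effect_size) * noise(replicates),
        co_yield_b = base_b * (1 + dirs[2] * effect_size) * noise(replicates),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    truth <- list(planted_interactions =
                    stats::setNames(types, sprintf("pair%03d", seq_len(n_pairs))),
                  effect_size = effect_size)
    list(records = records, truth = truth)
  })
}

#' Built-in KEGG-style synthetic module definitions
#'
#' A compact set of hand-written module definitions in the KEGG DEFINITION
#' grammar subset the parser understands. `M_COB1` is the multi-step
#' "cobalamin-like" producer module; `M_MARKER` holds the dependence-marker
#' KOs (metH/mutA/rsmB analogues).
#'
#' @return named character vector: module id to definition string.
#' @export
builtin_module_definitions <- function() {
  c(M_COB1 = "K0201 K0202 (K0203,K0204) K0205 K0206+K0207 K0208 K0209 K0210 K0211",
    M_MARKER = "K00548 K01847 K03500",
    M_AA01 = "K0301 K0302 (K0303,K0304)",
    M_AA02 = "K0311 K0312+K0313 K0314",
    M_AA03 = "(K0321,K0322) K0323 K0324 K0325",
    M_VIT01 = "K0401 K0402 K0403",
    M_VIT02 = "K0411 (K0412,K0413) K0414 -K0415",
    M_VIT03 = "K0421 K0422",
    M_LIP01 = "K0501 K0502 K0503 K0504",
    M_LIP02 = "K0511+K0512 K0513",
    M_LIP03 = "((K0521 K0522),(K0523 K0524)) K0525",
    M_LIP04 = "K0531 K0532 (K0533,K0534+K0535)")
}

#' Simulate genome KO annotations with planted functional groups
#'
#' Genomes are assigned to `n_groups` groups with group-specific module
#' inventories (a group "carries" a module or not; members of a carrying
#' group hold each of the module's KOs with high probability, others with
#' low probability). Exactly `ceiling(producer_fraction * n_genomes)`
#' genomes additionally carry every KO of the designated producer module,
#' drawn preferentially from the last group (the "producer clade"). Most
#' genomes carry the dependence-marker KOs.
#'
#' @param n_genomes number of genomes (MAG analogues).
#' @param n_groups number of planted functional groups.
#' @param producer_fraction fraction of genomes carrying the complete
#'   producer module, in `(0, 1]`.
#' @param module_defs named character vector of module definitions
#'   (default [builtin_module_definitions()]).
#' @param producer_module id of the producer module (default `"M_COB1"`).
#' @param seed RNG seed.
#' @return list with `annotations` (long data.frame genome_id, ko_id),
#'   `module_defs`, and `truth` (group labels, producer genome ids).
#' @export
simulate_genomes <- function(n_genomes = 150, n_groups = 7,
                             producer_fraction = 0.1,
                             module_defs = builtin_module_definitions(),
                             producer_module = "M_COB1", seed = 1) {
  n_genomes <- check_count(n_genomes, "n_genomes")
  n_groups <- check_count(n_groups, "n_groups")
  if (n_groups > n_genomes)
    stop("configuration error: n_groups (", n_groups,
         ") exceeds n_genomes (", n_genomes, ")")
  if (!is.character(module_defs) || length(module_defs) == 0 ||
      is.null(names(module_defs)))
    stop("`module_defs` must be a non-empty named character vector")
  if (producer_fraction <= 0 || producer_fraction > 1)
    stop("`producer_fraction` must be in (0, 1]")
  if (!producer_module %in% names(module_defs))
    stop("producer module ", producer_module, " not among module_defs")

  parsed <- lapply(module_defs, parse_module_definition)
  kos_of <- lapply(parsed, module_kos)
  marker_kos <- c("K00548", "K01847", "K03500")

  with_seed(seed, {
    genomes <- sprintf("MAG%03d", seq_len(n_genomes))
    group <- sort(rep_len(seq_len(n_groups), n_genomes))
    names(group) <- genomes

    other_modules <- setdiff(names(module_defs), producer_module)
    # group x module carriage; resample until group profiles are distinct
    repeat {
      carry <- matrix(stats::runif(n_groups * length(other_modules)) < 0.5,
                      n_groups, length(other_modules),
                      dimnames = list(NULL, other_modules))
      if (n_groups == 1 || !anyDuplicated(apply(carry, 1, paste, collapse = "")))
        break
    }

    n_prod <- as.integer(ceiling(producer_fraction * n_genomes))
    producer_pool <- c(genomes[group == n_groups], genomes[group != n_groups])
    producers <- producer_pool[seq_len(n_prod)]

    ann <- vector("list", n_genomes)
    for (g in seq_len(n_genomes)) {
      kos <- character(0)
      for (m in other_modules) {
        p <- if (carry[group[g], m]) 0.95 else 0.10
        leaf <- kos_of[[m]]
        kos <- c(kos, leaf[stats::runif(length(leaf)) < p])
      }
      prod_leaf <- setdiff(kos_of[[producer_module]], marker_kos)
      if (genomes[g] %in% producers) {
        kos <- c(kos, prod_leaf)
      } else {
        kos <- c(kos, prod_leaf[stats::runif(length(prod_leaf)) < 0.10])
      }
      if (stats::runif(1) < 0.95) kos <- c(kos, marker_kos)
      kos <- unique(kos)
      ann[[g]] <- data.frame(genome_id = genomes[g], ko_id = kos,
                             stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann)
    truth <- list(group = group, producer_genomes = producers)
    list(annotations = annotations, module_defs = module_defs, truth = truth)
  })
}

#' Write co-culture records to CSV
#' @param records data.frame as returned by [simulate_coculture()].
#' @param path output CSV path.
#' @export
write_coculture <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read co-culture records from CSV
#' @param path CSV path.
#' @return data.frame of co-culture records.
#' @export
read_coculture <- function(path) {
  df <- read_table(path, sep = ",", row_ids = FALSE)
  need <- c("pair_id", "mono_yield_a", "mono_yield_b", "co_yield_a", "co_yield_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("co-culture file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write ground-truth labels to JSON
#' @param truth ground-truth list from a simulator.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
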