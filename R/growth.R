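#' Assign rrn copy numbers to taxa from a lookup table
#'
#' The lookup emulates the rrndb layout: columns `name`, `rank`
#' (`"species"` or `"genus"`) and `mean_copy_number`. A taxon id is matched
#' at species level first; failing that, its genus (the leading token
#' before the first underscore or space) is matched at genus level; taxa
#' matching neither are recorded as unmatched and carry no copy number.
#'
#' @param taxa character vector of taxon ids.
#' @param lookup data.frame with columns `name`, `rank`,
#'   `mean_copy_number`.
#' @return data.frame (taxon_id, rrn_copy_number, match_level) with
#'   `match_level` in `species`, `genus`, `unmatched`.
#' @export
assign_rrn <- function(taxa, lookup) {
  need <- c("name", "rank", "mean_copy_number")
  if (!is.data.frame(lookup) || nrow(lookup) == 0)
    stop("`lookup` must be a non-empty data.frame")
  miss <- setdiff(need, names(lookup))
  if (length(miss)) stop("lookup missing column(s): ", paste(miss, collapse = ", "))
  sp <- lookup[lookup$rank == "species", ]
  ge <- lookup[lookup$rank == "genus", ]
  genus_of <- sub("[ _].*$", "", taxa)
  cn <- rep(NA_real_, length(taxa))
  lvl <- rep("unmatched", length(taxa))
  i_sp <- match(taxa, sp$name)
  hit <- !is.na(i_sp)
  cn[hit] <- sp$mean_copy_number[i_sp[hit]]
  lvl[hit] <- "species"
  i_ge <- match(genus_of, ge$name)
  hit2 <- !hit & !is.na(i_ge)
  cn[hit2] <- ge$mean_copy_number[i_ge[hit2]]
  lvl[hit2] <- "genus"
  if (any(!is.na(cn) & cn <= 0)) stop("matched copy numbers must be positive")
  data.frame(taxon_id = taxa, rrn_copy_number = cn, match_level = lvl,
             stringsAsFactors = FALSE)
}

#' Abundance-weighted mean rrn copy number (MCN) per sample
#'
#' `mcn[s] = sum_i a[s,i] c_i / sum_i a[s,i]` over matched taxa `i`:
#' unmatched taxa are excluded and the weights renormalized, so MCN is
#' invariant to renormalizing abundances over matched taxa and always lies
#' between the smallest and largest matched copy number. `coverage[s]` is
#' the fraction of relative abundance carrying a matched copy number.
#'
#' @param table an [abundance_table()].
#' @param traits data.frame from [assign_rrn()] (or any with `taxon_id`,
#'   `rrn_copy_number`).
#' @return object of class `"mcn_result"`: data.frame `samples`
#'   (sample_id, mcn, coverage, flagged) plus the matched trait table.
#' @export
mcn <- function(table, traits) {
  table <- as_abundance_table(table)
  if (!all(c("taxon_id", "rrn_copy_number") %in% names(traits)))
    stop("`traits` needs columns taxon_id and rrn_copy_number")
  cn <- stats::setNames(traits$rrn_copy_number, traits$taxon_id)
  cn <- cn[colnames(table)]
  matched <- !is.na(cn)
  if (!any(matched)) stop("no taxon with a matched copy number")
  m <- unclass(table)[, matched, drop = FALSE]
  w <- rowSums(m)
  vals <- drop(m %*% cn[matched])
  mcn_v <- ifelse(w > 0, vals / w, NA_real_)
  flagged <- w <= 0
  if (any(flagged))
    warning("sample(s) with zero matched abundance, MCN undefined: ",
            paste(rownames(table)[flagged], collapse = ", "))
  structure(list(samples = data.frame(sample_id = rownames(table),
                                      mcn = unname(mcn_v),
                                      coverage = unname(w),
                                      flagged = unname(flagged),
                                      stringsAsFactors = FALSE),
                 traits = traits),
            class = "mcn_result")
}

#' @export
print.mcn_result <- function(x, ...) {
  ok <- !x$samples$flagged
  cat(sprintf("MCN over %d samples: %.2f .. %.2f (mean %.2f), coverage %.1f%% .. %.1f%%\n",
              nrow(x$samples), min(x$samples$mcn[ok]), max(x$samples$mcn[ok]),
              mean(x$samples$mcn[ok]), 100 * min(x$samples$coverage),
              100 * max(x$samples$coverage)))
  invisible(x)
}

#' Multiple linear regression of MCN on temperature and nutrients
#'
#' Ordinary least squares of per-sample MCN on temperature plus every
#' numeric nutrient covariate in the metadata. All variables are z-scored,
#' so the standardized coefficients are directly comparable as factor
#' importances. Collinear predictors are dropped with a rank-deficiency
#' warning.
#'
#' @param mcn_result an `"mcn_result"` (or a named per-sample numeric
#'   vector of MCN values).
#' @param metadata metadata data.frame (row names sample ids; column
#'   `temperature`; further numeric columns are used as covariates, `day`
#'   excluded).
#' @param covariates optional explicit covariate column names.
#' @return data.frame (term, estimate, std_estimate, p) with the fitted
#'   `lm` as attribute `"fit"`.
#' @export
mcn_model <- function(mcn_result, metadata, covariates = NULL) {
  v <- if (inherits(mcn_result, "mcn_result"))
    stats::setNames(mcn_result$samples$mcn, mcn_result$samples$sample_id)
  else mcn_result
  v <- v[!is.na(v)]
  miss <- setdiff(names(v), rownames(metadata))
  if (length(miss)) stop("samples absent from metadata: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  md <- metadata[names(v), , drop = FALSE]
  if (is.null(covariates)) {
    num <- names(md)[vapply(md, is.numeric, logical(1))]
    covariates <- setdiff(num, c("temperature", "day"))
  }
  preds <- c("temperature", covariates)
  if (length(v) < length(preds) + 2)
    stop("need >= 2 more samples than predictors")
  df_raw <- data.frame(mcn = v, md[preds], check.names = FALSE)
  df_std <- as.data.frame(lapply(df_raw, function(col) as.numeric(scale(col))))
  names(df_std) <- names(df_raw)
  fit_raw <- stats::lm(mcn ~ ., data = df_raw)
  fit_std <- stats::lm(mcn ~ ., data = df_std)
  if (any(is.na(stats::coef(fit_raw)))) {
    dropped <- names(stats::coef(fit_raw))[is.na(stats::coef(fit_raw))]
    warning("rank-deficient model; dropped term(s): ",
            paste(dropped, collapse = ", "))
  }
  sm <- summary(fit_std)$coefficients
  terms <- setdiff(names(stats::coef(fit_raw)), "(Intercept)")
  pick <- function(tm, col)
    if (tm %in% rownames(sm)) sm[tm, col] else NA_real_
  out <- data.frame(term = terms,
                    estimate = unname(stats::coef(fit_raw)[terms]),
                    std_estimate = vapply(terms, pick, 0, col = "Estimate"),
                    p = vapply(terms, pick, 0, col = "Pr(>|t|)"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit_raw
  out
}
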