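#' Diet-weighted resource baseline d15N
#'
#' The resource baseline is the sum of products of each dietary proportion
#' with its source's d15N, `sum_k p_k * d15N_k`. Proportions are renormalized
#' when their sum deviates from one by at most 1e-6; larger deviations are an
#' error.
#'
#' @param proportions Non-negative diet proportions (length K).
#' @param source_d15N Source d15N means in permil (length K).
#' @return Weighted mean d15N in permil.
#' @examples
#' resource_delta15N(c(0.325, 0.325, 0.350), c(5.3, 3.8, 5.9))
#' @export
resource_delta15N <- function(proportions, source_d15N) {
  if (length(proportions) != length(source_d15N)) {
    stop("proportions and source_d15N must have equal length")
  }
  if (any(proportions < 0)) stop("diet proportions must be non-negative")
  s <- sum(proportions)
  if (abs(s - 1) > 1e-6) stop("diet proportions must sum to 1 (within 1e-6)")
  sum(proportions / s * source_d15N)
}

#' Trophic position from the d15N elevation above the resource baseline
#'
#' `TP = (d15N_consumer - d15N_resource) / delta_per_level + 2`, where the
#' per-level enrichment defaults to 2.3 permil (one trophic level change in
#' aquatic environments) and 2 is the trophic level of the primary-consumer
#' baseline.
#'
#' @param delta15N_consumer Consumer (site-mean) d15N, permil.
#' @param delta15N_resource Diet-weighted resource baseline d15N, permil.
#' @param delta_per_level Per-trophic-level enrichment in permil (> 0).
#' @return Trophic position (continuous trophic level).
#' @examples
#' trophic_position(9.0, 5.04)  # ~ 3.72
#' @export
trophic_position <- function(delta15N_consumer, delta15N_resource,
                             delta_per_level = 2.3) {
  if (delta_per_level <= 0) stop("delta_per_level must be positive")
  (delta15N_consumer - delta15N_resource) / delta_per_level + 2
}

#' Per-site trophic position table
#'
#' For each site: the consumer mean d15N over individual crabs, the
#' diet-weighted resource baseline from the site's mean diet proportions and
#' source d15N means, and the resulting trophic position.
#'
#' @param consumers Data frame (`consumers` schema) of individual crab
#'   signatures.
#' @param diet_sites Site table from [summarize_diet()] (columns
#'   `p_mole_crab`, `p_amphipod`, `p_coquina`).
#' @param source_summaries Site x taxon summary table (e.g. from
#'   [build_source_summaries()]).
#' @param delta_per_level Per-level enrichment, permil.
#' @return Data frame `site`, `d15N_gc`, `d15N_res`, `tp`.
#' @export
trophic_position_table <- function(consumers, diet_sites, source_summaries,
                                   delta_per_level = 2.3) {
  taxa <- c("mole_crab", "amphipod", "coquina")
  pc <- paste0("p_", taxa)
  if (!all(pc %in% names(diet_sites))) {
    stop("diet_sites must have columns: ", paste(pc, collapse = ", "))
  }
  out <- lapply(diet_sites$site, function(s) {
    gc_n <- consumers$d15N[consumers$site == s]
    if (length(gc_n) == 0) {
      warning("no consumers at site ", s, "; skipped")
      return(NULL)
    }
    ss <- source_summaries[source_summaries$site == s, ]
    sn <- ss$d15N_mean[match(taxa, ss$taxon)]
    if (any(is.na(sn))) {
      warning("incomplete source summaries at site ", s, "; skipped")
      return(NULL)
    }
    p <- as.numeric(diet_sites[diet_sites$site == s, pc])
    res <- resource_delta15N(p, sn)
    data.frame(site = s, d15N_gc = mean(gc_n), d15N_res = res,
               tp = trophic_position(mean(gc_n), res, delta_per_level),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
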