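#' Convert an isotope ratio to delta notation
#'
#' Expresses a measured heavy/light isotope ratio as the per-mil (permil)
#' deviation from an international standard: `(r_sample/r_standard - 1) * 1000`.
#' For carbon the standard is Vienna PeeDee Belemnite; for nitrogen it is
#' atmospheric N2.
#'
#' @param r_sample Measured isotope ratio(s) (e.g. 13C/12C). Numeric.
#' @param r_standard Standard ratio, must be strictly positive.
#' @return Delta value(s) in permil.
#' @examples
#' delta_value(0.0112372 * 1.001, 0.0112372)  # ~ +1 permil
#' @export
delta_value <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    stop("isotope ratios must be numeric")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("r_standard must be a positive, finite ratio")
  }
  (r_sample / r_standard - 1) * 1000
}

# Soft plausibility envelope for field data; values outside warn, never reject.
.delta_plausible_range <- list(d13C = c(-60, 10), d15N = c(-10, 30))

#' Check isotope signatures for plausibility
#'
#' Warns (never errors) when delta values fall outside the ranges usually seen
#' in coastal food-web tissue: d13C in \[-60, 10\], d15N in \[-10, 30\] permil.
#' Non-finite values are an error.
#'
#' @param d13C,d15N Numeric vectors of delta values in permil.
#' @return Invisibly, a logical vector: TRUE where both values are plausible.
#' @export
check_signature <- function(d13C, d15N) {
  if (any(!is.finite(d13C)) || any(!is.finite(d15N))) {
    stop("isotope signatures must be finite")
  }
  ok_c <- d13C >= .delta_plausible_range$d13C[1] & d13C <= .delta_plausible_range$d13C[2]
  ok_n <- d15N >= .delta_plausible_range$d15N[1] & d15N <= .delta_plausible_range$d15N[2]
  if (any(!ok_c)) {
    warning(sprintf("%d d13C value(s) outside the plausible range [-60, 10] permil",
                    sum(!ok_c)))
  }
  if (any(!ok_n)) {
    warning(sprintf("%d d15N value(s) outside the plausible range [-10, 30] permil",
                    sum(!ok_n)))
  }
  invisible(ok_c & ok_n)
}

#' Summarize isotope replicates by site and taxon
#'
#' Aggregates replicate signatures into per site x taxon means, sample
#' standard deviations (n - 1 denominator, reported as `NA` when n = 1) and
#' replicate counts, for each isotope.
#'
#' @param replicates Data frame with columns `site`, `taxon`, `d13C`, `d15N`
#'   (one row per replicate; the `replicate_id` column, if present, is ignored).
#' @return Data frame with columns `site`, `taxon`, `d13C_mean`, `d13C_sd`,
#'   `d15N_mean`, `d15N_sd`, `n`, one row per site x taxon group.
#' @export
summarize_signatures <- function(replicates) {
  req <- c("site", "taxon", "d13C", "d15N")
  miss <- setdiff(req, names(replicates))
  if (length(miss)) stop("replicates is missing column(s): ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(replicates[, c("d13C", "d15N")])
  if (any(!keep)) {
    message(sprintf("summarize_signatures: skipping %d incomplete row(s)", sum(!keep)))
    replicates <- replicates[keep, , drop = FALSE]
  }
  if (nrow(replicates) == 0L) stop("no complete replicate rows to summarize")
  key <- interaction(replicates$site, replicates$taxon, drop = TRUE)
  out <- do.call(rbind, lapply(split(replicates, key), function(g) {
    n <- nrow(g)
    data.frame(
      site = g$site[1], taxon = g$taxon[1],
      d13C_mean = mean(g$d13C),
      d13C_sd = if (n >= 2) stats::sd(g$d13C) else NA_real_,
      d15N_mean = mean(g$d15N),
      d15N_sd = if (n >= 2) stats::sd(g$d15N) else NA_real_,
      n = n, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$site, out$taxon), , drop = FALSE]
}

#' Mix wrack component signatures by dry-mass proportion
#'
#' Sites with mixed wrack have each dominant material measured separately;
#' the basal resource signature is the dry-mass-weighted arithmetic mean of
#' the component signatures. Weights are renormalized to sum to one.
#'
#' @param d13C,d15N Component delta values in permil.
#' @param proportions Non-negative dry-mass proportions, sum > 0.
#' @return Named list with elements `d13C` and `d15N` (the mixed signature).
#' @export
mix_wrack_signature <- function(d13C, d15N, proportions) {
  if (length(d13C) != length(proportions) || length(d15N) != length(proportions)) {
    stop("component signatures and proportions must have equal length")
  }
  if (any(proportions < 0)) stop("wrack proportions must be non-negative")
  s <- sum(proportions)
  if (!is.finite(s) || s <= 0) stop("wrack proportions must have a positive sum")
  w <- proportions / s
  list(d13C = sum(w * d13C), d15N = sum(w * d15N))
}

## ---- CSV schemas -----------------------------------------------------------

.beachmix_schemas <- list(
  sites = c("site", "width_m", "slope_deg", "grain_mm", "wrack_g", "burrow_density"),
  signatures = c("site", "taxon", "replicate_id", "d13C", "d15N"),
  consumers = c("site", "crab_id", "d13C", "d15N"),
  wrack_components = c("site", "component", "dry_mass_prop", "d13C", "d15N")
)

#' Write a table with a provenance comment header
#'
#' All pipeline outputs start with `#`-prefixed comment lines recording the
#' package version, the seed in force and a hash of the configuration, so any
#' file can be traced back to the run that produced it.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Integer seed recorded in the header (or NA).
#' @param config Arbitrary R object whose hash is recorded (or NULL).
#' @return `path`, invisibly.
#' @export
write_beach_csv <- function(x, path, seed = NA, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# beachmix %s", as.character(utils::packageVersion("beachmix"))), con)
  writeLines(sprintf("# seed=%s config_hash=%s",
                     ifelse(is.na(seed), "NA", format(seed)),
                     config_hash(config)), con)
  # print doubles with 17 significant digits so a read round-trips exactly
  for (cn in names(x)) {
    if (is.double(x[[cn]])) {
      v <- x[[cn]]
      x[[cn]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    }
  }
  utils::write.csv(x, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_beach_csv()]
#'
#' @param path CSV path; `#` comment lines are skipped.
#' @param schema Optional schema name (`"sites"`, `"signatures"`, `"consumers"`,
#'   `"wrack_components"`); when given, the header is validated against it.
#' @return Data frame.
#' @export
read_beach_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, comment.char = "#", na.strings = c("", "NA"),
                       stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    want <- .beachmix_schemas[[schema]]
    if (is.null(want)) stop("unknown schema: ", schema)
    miss <- setdiff(want, names(x))
    if (length(miss)) {
      stop(sprintf("%s: missing required column(s) for schema '%s': %s",
                   path, schema, paste(miss, collapse = ", ")))
    }
  }
  message(sprintf("read %d row(s) from %s", nrow(x), basename(path)))
  x
}

#' @rdname read_beach_csv
#' @export
read_sites <- function(path) read_beach_csv(path, schema = "sites")

#' @rdname read_beach_csv
#' @export
read_signatures <- function(path) read_beach_csv(path, schema = "signatures")

#' @rdname read_beach_csv
#' @export
read_consumers <- function(path) read_beach_csv(path, schema = "consumers")

#' @rdname read_beach_csv
#' @export
read_wrack_components <- function(path) read_beach_csv(path, schema = "wrack_components")

#' Hash an R object for provenance headers
#'
#' Small FNV-1a hash of the deparsed object; stable across sessions for plain
#' lists/vectors. Used only to stamp output files.
#'
#' @param x Any R object (NULL gives `"none"`).
#' @return Character scalar (8 hex digits).
#' @export
config_hash <- function(x) {
  if (is.null(x)) return("none")
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
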