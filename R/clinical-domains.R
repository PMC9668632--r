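#' Within-cohort z-score of one clinical test
#'
#' Standardises raw scores across patients with non-missing data (n-1
#' denominator for the SD); missing values stay missing and do not enter
#' the mean/SD.
#'
#' @param raw Numeric vector of raw test scores (may contain `NA`).
#' @param test Test name, used in error messages.
#' @return Numeric vector of z-scores (mean 0, SD 1 over non-missing).
#' @export
test_zscore <- function(raw, test = "test") {
  ok <- !is.na(raw)
  if (sum(ok) < 2) stop("test '", test, "': fewer than 2 non-missing values")
  s <- sd(raw[ok])
  if (!is.finite(s) || s == 0) stop("test '", test, "' has zero spread")
  (raw - mean(raw[ok])) / s
}

#' Multi-domain clinical composite z-scores
#'
#' Each raw test is z-scored across patients, tests are averaged within
#' their domain over available (non-missing) tests, and the vision,
#' cognition, and brain-volume composites are multiplied by -1 so that all
#' domain scores are impairment indices (higher = worse). A patient missing
#' every test in a domain gets a missing domain score.
#'
#' @param raw_scores Data frame of raw test scores, one row per patient,
#'   one column per test.
#' @param domain_map Data frame with columns `test`, `domain` covering every
#'   test column (default [default_domain_map()]).
#' @param recode_domains Domains whose composite is sign-flipped
#'   (default vision, cognition, brain_volume).
#' @return Data frame, one row per patient, one column per domain, plus
#'   attribute `"test_z"` holding the per-test z-score matrix.
#' @export
domain_composite <- function(raw_scores,
                             domain_map = default_domain_map(),
                             recode_domains = c("vision", "cognition",
                                                "brain_volume")) {
  raw_scores <- as.data.frame(raw_scores)
  unknown <- setdiff(colnames(raw_scores), domain_map$test)
  if (length(unknown)) {
    stop("test column(s) not in domain map: ", paste(unknown, collapse = ", "))
  }
  missing_tests <- setdiff(domain_map$test, colnames(raw_scores))
  if (length(missing_tests)) {
    domain_map <- domain_map[!domain_map$test %in% missing_tests, ]
  }
  z <- vapply(domain_map$test,
              function(t) test_zscore(raw_scores[[t]], t),
              numeric(nrow(raw_scores)))
  domains <- unique(domain_map$domain)
  out <- as.data.frame(lapply(domains, function(d) {
    cols <- domain_map$test[domain_map$domain == d]
    rowMeans(z[, cols, drop = FALSE], na.rm = TRUE)
  }))
  names(out) <- domains
  out[is.nan(as.matrix(out))] <- NA
  for (d in intersect(recode_domains, domains)) out[[d]] <- -out[[d]]
  attr(out, "test_z") <- z
  out
}

edss_grid <- function(x) {
  ok <- is.na(x) | (x >= 0 & x <= 10 & abs(x * 2 - round(x * 2)) < 1e-9)
  if (!all(ok)) {
    stop("EDSS values off the 0-10 grid in 0.5 steps: ",
         paste(x[!ok], collapse = ", "))
  }
  x
}

#' Split patients into disability subgroups by EDSS percentiles
#'
#' Patients whose EDSS equals the sample median are excluded (the split is
#' undefined for them); of the rest, those at or below the nearest-rank
#' lower percentile (default 30th) form the `no_disability` group and those
#' at or above the nearest-rank upper percentile (default 70th) the
#' `mild_moderate` group. Remaining rated patients are `unassigned`;
#' unrated patients (`NA`) are `unrated`.
#'
#' @param edss Numeric vector of EDSS scores (0-10 grid in 0.5 steps; `NA`
#'   for unrated patients).
#' @param lower_pct,upper_pct Percentile thresholds (defaults 30 and 70).
#' @return Data frame with columns `EDSS` and `subgroup` (factor:
#'   `no_disability`, `mild_moderate`, `excluded_median`, `unassigned`,
#'   `unrated`), plus attributes `median`, `lower_cut`, `upper_cut`.
#' @export
edss_split <- function(edss, lower_pct = 30, upper_pct = 70) {
  edss <- edss_grid(edss)
  rated <- edss[!is.na(edss)]
  if (length(rated) < 5) stop("need at least 5 rated patients")
  if (length(unique(rated)) == 1) stop("all EDSS scores identical")
  med <- median(rated)
  srt <- sort(rated)
  n <- length(srt)
  lower_cut <- srt[max(1, ceiling(lower_pct / 100 * n))]
  upper_cut <- srt[max(1, ceiling(upper_pct / 100 * n))]
  sub <- rep(NA_character_, length(edss))
  sub[is.na(edss)] <- "unrated"
  idx <- !is.na(edss)
  sub[idx & edss == med] <- "excluded_median"
  rest <- idx & edss != med
  sub[rest & edss <= lower_cut] <- "no_disability"
  sub[rest & edss >= upper_cut] <- "mild_moderate"
  sub[rest & is.na(sub)] <- "unassigned"
  out <- data.frame(EDSS = edss,
                    subgroup = factor(sub, levels = c(
                      "no_disability", "mild_moderate", "excluded_median",
                      "unassigned", "unrated")))
  attr(out, "median") <- med
  attr(out, "lower_cut") <- lower_cut
  attr(out, "upper_cut") <- upper_cut
  out
}
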