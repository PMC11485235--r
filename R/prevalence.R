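#' Round a percentage to one decimal, half away from zero
#'
#' Matches the usual presentation of epidemiological prevalence figures
#' (e.g. 7.85 -> 7.9, -0.05 -> -0.1), unlike base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places; default 1.
#' @return Numeric rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 1L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stratum_rows <- function(snapshot, age_range = NULL, sex = NULL) {
  keep <- rep(TRUE, nrow(snapshot))
  if (!is.null(age_range)) {
    keep <- keep & snapshot$age_years >= age_range[1L] &
      snapshot$age_years <= age_range[2L]
  }
  if (!is.null(sex)) keep <- keep & snapshot$sex == sex
  keep
}

#' Point prevalence of a condition
#'
#' Proportion of persons in the (optionally age/sex restricted) stratum
#' with the condition flagged. An empty stratum is not computable and
#' returns `NA` with a warning rather than 0.
#'
#' @param snapshot A prevalence snapshot table.
#' @param condition Condition column name.
#' @param age_range Optional `c(lo, hi)` inclusive age filter.
#' @param sex Optional sex label filter.
#' @return Proportion in \[0, 1\], or `NA_real_` for an empty stratum.
#' @export
point_prevalence <- function(snapshot, condition, age_range = NULL,
                             sex = NULL) {
  if (!condition %in% names(snapshot)) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  keep <- stratum_rows(snapshot, age_range, sex)
  denom <- sum(keep)
  if (denom == 0L) {
    warning("empty stratum; prevalence not computable")
    return(NA_real_)
  }
  sum(snapshot[[condition]][keep] > 0) / denom
}

#' Observed-minus-expected joint prevalence of a condition pair
#'
#' Observed is the joint prevalence of the pair; expected is the product
#' of the two marginal prevalences (the independence expectation); excess
#' is observed minus expected. By default computed crudely over the whole
#' snapshot; an optional stratum filter restricts all three quantities to
#' that stratum.
#'
#' @param snapshot A prevalence snapshot table.
#' @param condition_a,condition_b Condition column names.
#' @param age_range,sex Optional stratum filter as in
#'   [point_prevalence()].
#' @return One-row `data.frame`: `condition_a`, `condition_b`, `observed`,
#'   `expected`, `excess`.
#' @export
observed_minus_expected <- function(snapshot, condition_a, condition_b,
                                    age_range = NULL, sex = NULL) {
  for (cn in c(condition_a, condition_b)) {
    if (!cn %in% names(snapshot)) stop("unknown condition: ", cn,
                                       call. = FALSE)
  }
  keep <- stratum_rows(snapshot, age_range, sex)
  denom <- sum(keep)
  if (denom == 0L) {
    warning("empty stratum; excess prevalence not computable")
    return(data.frame(condition_a = condition_a, condition_b = condition_b,
                      observed = NA_real_, expected = NA_real_,
                      excess = NA_real_))
  }
  fa <- snapshot[[condition_a]][keep] > 0
  fb <- snapshot[[condition_b]][keep] > 0
  observed <- sum(fa & fb) / denom
  expected <- (sum(fa) / denom) * (sum(fb) / denom)
  data.frame(condition_a = condition_a, condition_b = condition_b,
             observed = observed, expected = expected,
             excess = observed - expected)
}

#' Excess-prevalence table over a list of condition pairs
#'
#' @param snapshot A prevalence snapshot table.
#' @param pairs List of length-2 character vectors, or `NULL` for every
#'   pair of a given index condition with all other conditions.
#' @param index_condition Used when `pairs` is `NULL`; default
#'   `"diabetes"`.
#' @return A `data.frame` with one row per pair (see
#'   [observed_minus_expected()]).
#' @export
excess_prevalence_table <- function(snapshot, pairs = NULL,
                                    index_condition = "diabetes") {
  if (is.null(pairs)) {
    others <- setdiff(snapshot_conditions(snapshot), index_condition)
    pairs <- lapply(others, function(x) c(index_condition, x))
  }
  do.call(rbind, lapply(pairs, function(p) {
    observed_minus_expected(snapshot, p[1L], p[2L])
  }))
}

default_age_bands <- function() {
  lo <- c(seq(20L, 85L, by = 5L))
  data.frame(age_lo = lo,
             age_hi = c(lo[-1L] - 1L, 100L),
             band = c(paste(lo[-length(lo)], lo[-1L] - 1L, sep = "-"),
                      "85+"))
}

#' Distribution of condition counts by stratum
#'
#' For each age band x sex x index-condition stratum, the proportion of
#' persons carrying at least k conditions, k = 1..`max_k` (the top class
#' is "k or more"). Persons with the index condition (default diabetes)
#' count it among their conditions; the comparator group is persons
#' without the index condition, whose count covers the remaining
#' conditions only — so its k = 1 row is the share with at least one
#' other condition.
#'
#' @param snapshot A prevalence snapshot table.
#' @param index_condition Index condition column; default `"diabetes"`.
#' @param age_bands `data.frame` with `age_lo`, `age_hi`, `band`; default
#'   5-year bands 20--24 ... 85+.
#' @param max_k Largest count class; default 6.
#' @return A `data.frame`: `group` (`"diabetes"` label of the index
#'   condition or `"no_<index>"`), `sex`, `age_band`, `k`, `n_persons`
#'   (stratum denominator), `proportion`, `computable`.
#' @export
mltc_count_distribution <- function(snapshot,
                                    index_condition = "diabetes",
                                    age_bands = default_age_bands(),
                                    max_k = 6L) {
  conds <- snapshot_conditions(snapshot)
  if (!index_condition %in% conds) {
    stop("unknown index condition: ", index_condition, call. = FALSE)
  }
  others <- setdiff(conds, index_condition)
  flags <- as.matrix(as.data.frame(snapshot)[, conds, drop = FALSE]) > 0
  n_other <- rowSums(flags[, others, drop = FALSE])
  has_index <- flags[, index_condition]
  count <- ifelse(has_index, n_other + 1L, n_other)
  group <- ifelse(has_index, index_condition,
                  paste0("no_", index_condition))
  sexes <- sort(unique(snapshot$sex))
  rows <- list()
  for (g in unique(c(index_condition, paste0("no_", index_condition)))) {
    for (sx in sexes) {
      for (b in seq_len(nrow(age_bands))) {
        in_stratum <- group == g & snapshot$sex == sx &
          snapshot$age_years >= age_bands$age_lo[b] &
          snapshot$age_years <= age_bands$age_hi[b]
        denom <- sum(in_stratum)
        for (k in seq_len(max_k)) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, sex = sx, age_band = age_bands$band[b], k = k,
            n_persons = denom,
            proportion = if (denom > 0) sum(count[in_stratum] >= k) / denom
                         else NA_real_,
            computable = denom > 0
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}
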