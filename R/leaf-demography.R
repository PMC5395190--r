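# Leaf half-life from censored census intervals, and wood density.
#
# Under a constant abscission rate the number of live leaves in a marked
# cohort decays exponentially, so an interval with counts n1 -> n2 over
# t1 -> t2 yields LHL = (t2 - t1) * ln(1/2) / ln(n2 / n1).

#' Estimate leaf half-life from one census interval
#'
#' Vectorised over intervals. An interval is `usable` only when
#' `0 < n2 < n1`: equal counts mean no abscission was observed (half-life
#' unbounded, flagged `Inf`); a count of zero leaves the abscission rate
#' unbounded below the exponential model; a gain in leaves contradicts
#' the cohort design and is flagged `"leaf gain"`.
#'
#' @param n1,n2 Live-leaf counts at the start and end of the interval
#'   (`n1 >= 1`, `n2 >= 0`).
#' @param t1,t2 Interval endpoints, as `Date`s or days; `t2 > t1`.
#' @param continuity_correction If `TRUE`, zero end counts are replaced
#'   by 0.5 so complete-loss intervals yield a finite estimate. Off by
#'   default: such intervals are excluded rather than corrected.
#' @return A tibble with columns `n1`, `n2`, `delta_t`, `lhl_days`,
#'   `usable`, `reason`.
#' @export
#' @examples
#' estimate_lhl_interval(20, 10, 0, 120) # halving forces LHL = 120 d
estimate_lhl_interval <- function(n1, n2, t1, t2,
                                  continuity_correction = FALSE) {
  delta_t <- as.numeric(t2) - as.numeric(t1)
  if (any(delta_t <= 0)) {
    abort("t2 must be later than t1", class = "traitdecomp_validation_error")
  }
  if (any(n1 < 1)) {
    abort("n1 must be >= 1", class = "traitdecomp_validation_error")
  }
  n2c <- if (continuity_correction) ifelse(n2 == 0, 0.5, n2) else n2
  lhl <- ifelse(n2c > 0 & n2c < n1,
                delta_t * log(0.5) / log(n2c / n1), NA_real_)
  lhl[n2c == n1] <- Inf
  reason <- dplyr::case_when(
    n2c > n1 ~ "leaf gain",
    n2c == n1 ~ "no abscission",
    n2c == 0 ~ "complete loss",
    .default = NA_character_
  )
  tibble::tibble(n1 = n1, n2 = n2, delta_t = delta_t, lhl_days = lhl,
                 usable = is.na(reason), reason = reason)
}

# Per-interval estimates for every consecutive census pair of every
# cohort, in census order. Intervals starting after the cohort is
# exhausted (previous count 0) carry no information and are skipped.
lhl_intervals <- function(censuses, continuity_correction = FALSE) {
  censuses |>
    dplyr::group_by(.data$individual_id, .data$branch_id, .data$cohort_id) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::reframe({
      i <- which(.data$live_count[-dplyr::n()] >= 1)
      est <- estimate_lhl_interval(
        .data$live_count[i], .data$live_count[i + 1],
        .data$date[i], .data$date[i + 1],
        continuity_correction = continuity_correction
      )
      est$first_date <- .data$date[1]
      est
    })
}

#' Leaf half-life per individual
#'
#' Aggregates interval estimates to one half-life per individual. The
#' default policy keeps only the first cohort marked on each branch (the
#' cohort with the most leaves and hence the most stable estimates),
#' averages its usable interval estimates, and then averages across
#' branches. Individuals with no usable interval are excluded (not an
#' error) and reported via the `excluded` attribute and a message.
#'
#' @param censuses A census table (see [read_census_table()]).
#' @param policy `"first_cohort"` (default) or `"all_cohorts"`.
#' @param continuity_correction Passed to [estimate_lhl_interval()].
#' @return A tibble with `individual_id`, `lhl_days`, `n_branches`,
#'   `n_intervals`; excluded individuals in `attr(, "excluded")`.
#' @export
lhl_per_individual <- function(censuses,
                               policy = c("first_cohort", "all_cohorts"),
                               continuity_correction = FALSE) {
  policy <- match.arg(policy)
  est <- lhl_intervals(censuses, continuity_correction = continuity_correction)
  if (policy == "first_cohort") {
    est <- est |>
      dplyr::group_by(.data$individual_id, .data$branch_id) |>
      dplyr::filter(.data$first_date == min(.data$first_date)) |>
      dplyr::ungroup()
  }
  per_branch <- est |>
    dplyr::group_by(.data$individual_id, .data$branch_id) |>
    dplyr::summarise(
      lhl_days = mean(.data$lhl_days[.data$usable]),
      n_intervals = sum(.data$usable),
      reasons = paste(unique(.data$reason[!is.na(.data$reason)]), collapse = "; "),
      .groups = "drop"
    )
  out <- per_branch |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_branches = sum(is.finite(.data$lhl_days)),
      lhl_days = mean(.data$lhl_days[is.finite(.data$lhl_days)]),
      n_intervals = sum(.data$n_intervals),
      reasons = paste(unique(.data$reasons[nzchar(.data$reasons)]), collapse = "; "),
      .groups = "drop"
    )
  excluded <- out |>
    dplyr::filter(!is.finite(.data$lhl_days)) |>
    dplyr::transmute(.data$individual_id,
                     reason = ifelse(nzchar(.data$reasons), .data$reasons,
                                     "no usable interval"))
  if (nrow(excluded) > 0) {
    inform(sprintf("excluding %d individual(s) with no usable census interval: %s",
                   nrow(excluded),
                   paste(excluded$individual_id, collapse = ", ")))
  }
  out <- out |>
    dplyr::filter(is.finite(.data$lhl_days)) |>
    dplyr::select("individual_id", "lhl_days", "n_branches", "n_intervals")
  attr(out, "excluded") <- excluded
  out
}

#' Wood density from an increment core
#'
#' Wood density is core dry mass per fresh volume, in g/cm^3 (fresh
#' volume by water displacement, mass after drying).
#'
#' @param dry_mass Dry mass in g, > 0.
#' @param fresh_volume Fresh volume in cm^3, > 0.
#' @return Wood density, g/cm^3 (vectorised).
#' @export
#' @examples
#' wood_density(0.5, 1.0)
wood_density <- function(dry_mass, fresh_volume) {
  if (any(!is.finite(dry_mass) | dry_mass <= 0) ||
        any(!is.finite(fresh_volume) | fresh_volume <= 0)) {
    abort("dry_mass and fresh_volume must be positive",
          class = "traitdecomp_validation_error")
  }
  dry_mass / fresh_volume
}
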