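# Background (other-cause) mortality.
#
# Default is a Gompertz-Makeham hazard, h(age) = c + a * exp(b * age), chosen
# because it has a closed-form annual death probability and discrete life
# expectancy, which serve as independent oracles for the stochastic engine.
# A life-table override is provided for users with an empirical table.

#' Background mortality law
#'
#' Gompertz–Makeham other-cause mortality: the annual death probability at
#' integer age `x` is `q(x) = 1 - exp(-(c + a * exp(b * x)))`, with `q`
#' forced to 1 at `max_age` (absorbing cap). The defaults give the 40–70
#' uniform entry mix a cancer-free life expectancy of about 23.4 years,
#' reflecting the elevated background mortality of an uninsured, low-income
#' safety-net population rather than general-population life tables.
#'
#' @param makeham_c age-independent baseline hazard (per year), >= 0.
#' @param gompertz_a hazard scale (per year), >= 0.
#' @param gompertz_b log-hazard slope (per year of age), >= 0.
#' @param max_age absorbing maximum age in years (<= 120); everyone alive at
#'   `max_age` dies during that year.
#' @return An object of class `mortality_law` carrying the parameters and
#'   the precomputed vector of annual death probabilities for ages
#'   `0..max_age`.
#' @seealso [mortality_law_from_table()], [annual_death_prob()],
#'   [expected_remaining_years()]
#' @export
mortality_law <- function(makeham_c = 0.002, gompertz_a = 5e-5,
                          gompertz_b = 0.092, max_age = 100L) {
  if (!is.numeric(makeham_c) || makeham_c < 0) stop_field("makeham_c", "must be >= 0")
  if (!is.numeric(gompertz_a) || gompertz_a < 0) stop_field("gompertz_a", "must be >= 0")
  if (!is.numeric(gompertz_b) || gompertz_b < 0) stop_field("gompertz_b", "must be >= 0")
  max_age <- as.integer(max_age)
  if (is.na(max_age) || max_age > 120L || max_age <= MIN_ENTRY_AGE) {
    stop_field("max_age", "must be an integer in (40, 120]")
  }
  ages <- 0:max_age
  q <- 1 - exp(-(makeham_c + gompertz_a * exp(gompertz_b * ages)))
  q[length(q)] <- 1
  structure(
    list(
      type = "gompertz_makeham",
      makeham_c = makeham_c, gompertz_a = gompertz_a, gompertz_b = gompertz_b,
      max_age = max_age, q = q
    ),
    class = "mortality_law"
  )
}

#' Mortality law from an explicit life table
#'
#' @param table data frame with columns `age` and `annual_death_prob`
#'   covering every integer age from 0 (or the minimum simulated age) up to
#'   `max_age`; probabilities must lie in `[0, 1]`.
#' @param max_age absorbing maximum age; `q(max_age)` is forced to 1.
#' @return An object of class `mortality_law`.
#' @export
mortality_law_from_table <- function(table, max_age = 100L) {
  max_age <- as.integer(max_age)
  if (!is.data.frame(table) || !all(c("age", "annual_death_prob") %in% names(table))) {
    stop_field("life_table", "needs columns `age` and `annual_death_prob`")
  }
  check_prob(table$annual_death_prob, "life_table$annual_death_prob")
  q <- rep(NA_real_, max_age + 1L)
  idx <- table$age >= 0 & table$age <= max_age
  q[as.integer(table$age[idx]) + 1L] <- table$annual_death_prob[idx]
  q[seq_len(MIN_ENTRY_AGE)][is.na(q[seq_len(MIN_ENTRY_AGE)])] <- 0
  if (anyNA(q)) {
    stop_field("life_table", sprintf(
      "missing annual_death_prob for age(s) %s",
      paste(utils::head(which(is.na(q)) - 1L, 5L), collapse = ", ")
    ))
  }
  q[length(q)] <- 1
  structure(
    list(type = "table", max_age = max_age, q = q),
    class = "mortality_law"
  )
}

#' Read a life-table CSV override
#'
#' @param path CSV with header `age,annual_death_prob` (UTF-8, comma-separated).
#' @inheritParams mortality_law_from_table
#' @export
read_life_table <- function(path, max_age = 100L) {
  mortality_law_from_table(utils::read.csv(path), max_age = max_age)
}

#' Annual other-cause death probability
#'
#' @param age age(s) in completed years, `0 <= age <= max_age`.
#' @param law a [mortality_law()].
#' @return Probability of dying from other causes during the year of age
#'   `age`; exactly 1 at `max_age`.
#' @export
annual_death_prob <- function(age, law) {
  stopifnot(inherits(law, "mortality_law"))
  age <- as.integer(age)
  if (anyNA(age) || any(age < 0L) || any(age > law$max_age)) {
    stop_field("age", sprintf("must lie in [0, %d]", law$max_age))
  }
  law$q[age + 1L]
}

#' Closed-form discrete remaining life expectancy
#'
#' Expected number of complete further years lived by a person entering at
#' `entry_age`: `sum_{k>=1} prod_{j=0}^{k-1} (1 - q(entry_age + j))`. Under
#' the half-cycle accrual convention used throughout the package (the year
#' of death is credited 0.5 years) the expected accrued life years equal
#' this quantity plus 0.5 exactly, which is what [accrue()] and the
#' simulation engine report; set `half_cycle = TRUE` to get that directly.
#'
#' @param entry_age entry age in years, `<= max_age`.
#' @param law a [mortality_law()].
#' @param half_cycle if `TRUE`, add the 0.5-year credit for the death year.
#' @return Expected remaining years (scalar per entry age).
#' @export
expected_remaining_years <- function(entry_age, law, half_cycle = FALSE) {
  stopifnot(inherits(law, "mortality_law"))
  vapply(as.integer(entry_age), function(a) {
    if (is.na(a) || a < 0L || a > law$max_age) {
      stop_field("entry_age", sprintf("must lie in [0, %d]", law$max_age))
    }
    q <- law$q[(a:law$max_age) + 1L]
    sum(cumprod(1 - q)) + if (half_cycle) 0.5 else 0
  }, numeric(1))
}

#' @export
print.mortality_law <- function(x, ...) {
  cat("<mortality_law>", x$type, "\n")
  if (x$type == "gompertz_makeham") {
    cat(sprintf(
      "  h(age) = %.4g + %.4g * exp(%.4g * age), max_age = %d\n",
      x$makeham_c, x$gompertz_a, x$gompertz_b, x$max_age
    ))
  } else {
    cat(sprintf("  tabulated q for ages 0..%d\n", x$max_age))
  }
  invisible(x)
}
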