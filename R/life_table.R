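# Age-and-sex life tables supplying background mortality for the cohort
# engine.  The packaged default is synthetic: a Gompertz-Makeham schedule
# with the qualitative shape of national (ONS-style) period life tables,
# not their numeric values.

#' Generate a synthetic age-and-sex life table
#'
#' Builds a Gompertz-Makeham annual mortality schedule for ages 0-110 and
#' both sexes, increasing in age, with male mortality above female and the
#' age-110 probability forced to 1 (absorbing cap).  The seed perturbs the
#' sex-specific level slightly so distinct tables can be generated; the
#' shape is fixed.
#'
#' @param seed Integer seed controlling the level perturbation.
#' @return A tibble with columns `age` (0-110), `sex` (`"F"`/`"M"`) and
#'   `annual_death_prob`.
#' @export
#' @examples
#' lt <- generate_life_table(seed = 1)
#' dplyr::filter(lt, age == 65)
generate_life_table <- function(seed = 1L) {
  level <- withr::with_seed(seed, exp(rnorm(2, 0, 0.02)))
  age <- 0:110
  gompertz <- function(b, lev) {
    hazard <- 2e-4 + b * lev * exp(0.092 * age)
    q <- 1 - exp(-hazard)
    q[age == 110] <- 1
    pmin(q, 1)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(age = age, sex = "F", annual_death_prob = gompertz(3.0e-5, level[1])),
    tibble::tibble(age = age, sex = "M", annual_death_prob = gompertz(4.5e-5, level[2]))
  )
  validate_life_table(out)
}

#' Read a life table from delimited text
#'
#' Expects a comma-separated file with header `age,sex,annual_death_prob`,
#' ages 0-110 and sex coded `F`/`M`.
#'
#' @param path Path to the file.
#' @return A validated life-table tibble.
#' @export
read_life_table <- function(path) {
  validate_life_table(tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE)))
}

#' Write a life table to delimited text
#'
#' @param life_table A life-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  write.csv(validate_life_table(life_table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a life table
#'
#' Checks the column contract, probability ranges and age coverage per sex.
#'
#' @param life_table A data frame with columns `age`, `sex`,
#'   `annual_death_prob`.
#' @return The life table as a tibble, invisibly usable downstream.
#' @export
validate_life_table <- function(life_table) {
  env <- new_issues()
  needed <- c("age", "sex", "annual_death_prob")
  missing <- setdiff(needed, names(life_table))
  if (length(missing)) {
    add_issue(env, paste(missing, collapse = ", "), "required column missing")
    stop_if_issues(env, "life table")
  }
  if (!all(life_table$sex %in% c("F", "M"))) {
    add_issue(env, "sex", "must be 'F' or 'M'")
  }
  check_prob(env, life_table$annual_death_prob, "annual_death_prob")
  for (s in c("F", "M")) {
    ages <- sort(life_table$age[life_table$sex == s])
    if (!length(ages) || ages[length(ages)] < 110) {
      add_issue(env, paste0("sex ", s), "ages must extend to 110")
    }
  }
  stop_if_issues(env, "life table")
  tibble::as_tibble(life_table)
}

#' Default (cached) synthetic life table
#'
#' @return The life table from [generate_life_table()] with seed 1.
#' @export
default_life_table <- function() {
  if (is.null(the$life_table)) the$life_table <- generate_life_table(1L)
  the$life_table
}

# Sex-averaged monthly background death probability at each (fractional) age.
# Annual sex-specific probabilities are rescaled to monthly first, then mixed
# with the female fraction; ages are floored for the lookup and capped at the
# table maximum.
background_monthly <- function(life_table, ages, female_fraction) {
  lookup <- function(s) {
    sub <- life_table[life_table$sex == s, ]
    sub <- sub[order(sub$age), ]
    idx <- pmin(pmax(floor(ages), min(sub$age)), max(sub$age)) - min(sub$age) + 1L
    rescale_probability(sub$annual_death_prob, from = 12, to = 1)[idx]
  }
  female_fraction * lookup("F") + (1 - female_fraction) * lookup("M")
}
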