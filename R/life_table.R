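#' Construct a life table
#'
#' A life table holds annual all-cause mortality probabilities `q` by single
#' year of age and sex. The model uses it to extrapolate heart-failure
#' cohort mortality beyond the period covered by the registry's baseline
#' hazard, inflating the general-population risk by a relative risk.
#'
#' @param age Integer vector of ages (years), consecutive from the first age
#'   covered up to `max(age)`.
#' @param q_male,q_female Annual mortality probabilities in `[0, 1]`, same
#'   length as `age`. The terminal age's probabilities are forced to 1.
#' @param provenance Free-text provenance tag, e.g. `"synthetic"` or the
#'   name of a national life-table release.
#'
#' @return A `life_table` data frame with columns `age`, `q_male`,
#'   `q_female` and attribute `provenance`.
#' @export
life_table <- function(age, q_male, q_female, provenance = "user-supplied") {
  age <- as.integer(age)
  stopifnot(length(age) > 1L, length(q_male) == length(age),
            length(q_female) == length(age))
  if (any(diff(age) != 1L)) {
    stop("life_table(): `age` must be consecutive single years", call. = FALSE)
  }
  if (any(q_male < 0 | q_male > 1 | q_female < 0 | q_female > 1)) {
    stop("life_table(): probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- length(age)
  q_male[n] <- 1
  q_female[n] <- 1
  for (col in list(q_male, q_female)) {
    older <- age >= 60
    if (any(diff(col[older]) < 0)) {
      warning("life_table(): q not monotone non-decreasing above age 60",
              call. = FALSE)
    }
  }
  structure(
    data.frame(age = age, q_male = q_male, q_female = q_female),
    provenance = provenance,
    class = c("life_table", "data.frame")
  )
}

#' Read / write a life table file
#'
#' Plain tabular text with header columns `age`, `q_male`, `q_female`, one
#' row per single year of age. Any whitespace- or comma-separated file that
#' [utils::read.table()] understands is accepted.
#'
#' @param path File path.
#' @param lt A [life_table] object (for writing).
#' @param provenance Provenance tag recorded on the object read.
#' @return `read_life_table()` returns a [life_table]; `write_life_table()`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path, provenance = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("age", "q_male", "q_female")
  if (!all(need %in% names(df))) {
    stop("life-table file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  life_table(df$age, df$q_male, df$q_female, provenance = provenance)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.table(as.data.frame(lt), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ages ", min(x$age), "-", max(x$age), ", provenance: ",
      attr(x, "provenance"), "\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  cat("...\n")
  invisible(x)
}

#' Three-month mortality probability from a life table
#'
#' Looks up the annual mortality probability at `age`, weights the sexes
#' (`male_fraction` defaults to the modelled cohort's two-thirds male),
#' converts to a 3-month probability via `1 - (1 - q)^(1/4)`, multiplies by
#' a relative risk `rr` (heart-failure vs general population) and caps at 1.
#' Ages beyond the table use the terminal probability of 1.
#'
#' @param lt A [life_table].
#' @param age Attained age in whole years (vectorised).
#' @param male_fraction Proportion male in `[0, 1]`.
#' @param rr Relative risk multiplier, > 0.
#' @return Per-cycle (3-month) death probability in `[0, 1]`.
#' @examples
#' lt <- generate_life_table()
#' life_table_cycle_prob(lt, 80, male_fraction = 2 / 3, rr = 3.14)
#' @export
life_table_cycle_prob <- function(lt, age, male_fraction = 2 / 3, rr = 1) {
  stopifnot(inherits(lt, "life_table"),
            male_fraction >= 0, male_fraction <= 1, rr > 0)
  age <- as.integer(age)
  if (any(age < min(lt$age))) {
    stop("life_table_cycle_prob(): age below table range", call. = FALSE)
  }
  idx <- match(pmin(age, max(lt$age)), lt$age)
  q <- male_fraction * lt$q_male[idx] + (1 - male_fraction) * lt$q_female[idx]
  pmin(1, rr * (1 - (1 - q)^(1 / 4)))
}
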