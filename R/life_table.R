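#' Build a life table
#'
#' Age-indexed annual all-cause mortality probabilities used for background
#' (non-asthma) death. Ages must be strictly increasing and contiguous;
#' lookups beyond the last age carry the last row forward.
#'
#' @param age Integer ages (years).
#' @param qx Annual mortality probabilities in \[0, 1\].
#' @return An object of class `life_table` (a data frame `age`, `qx`).
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx) || !length(age))
    stop("age and qx must be nonempty vectors of equal length", call. = FALSE)
  if (any(diff(age) != 1))
    stop("life table ages must be strictly increasing and contiguous", call. = FALSE)
  if (any(!is.finite(qx) | qx < 0 | qx > 1))
    stop("life table qx values must lie in [0,1]", call. = FALSE)
  structure(data.frame(age = as.integer(age), qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

#' Read a life table from delimited text
#'
#' Expects a header line and columns `age`, `qx` (an optional `sex` column
#' is averaged per age; the cohort model applies a single blended table).
#'
#' @param path Path to a tab- or whitespace-delimited text file.
#' @return A `life_table`.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  if ("sex" %in% names(df))
    df <- aggregate(qx ~ age, data = df, FUN = mean)
  df <- df[order(df$age), ]
  life_table(df$age, df$qx)
}

#' Annual mortality at a given age
#'
#' @param lt A `life_table`.
#' @param age Age in years (>= 0); the integer part selects the row, ages
#'   past the table's end return the last row's value.
#' @return Annual mortality probability.
#' @export
annual_mortality <- function(lt, age) {
  a <- floor(age)
  i <- findInterval(a, lt$age)
  i[i < 1] <- 1L          # ages below the table start: first row
  i[i > nrow(lt)] <- nrow(lt)
  lt$qx[i]
}

#' Per-cycle mortality from an annual probability
#'
#' Converts the annual probability covering `age` to a per-cycle
#' probability under a constant hazard within the year:
#' `1 - (1 - q_annual)^(1/cycles_per_year)`.
#'
#' @param lt A `life_table`.
#' @param age Age in years.
#' @param cycles_per_year Cycles per year (default 52, weekly).
#' @return Per-cycle mortality probability.
#' @examples
#' lt <- life_table(40:41, c(0.001, 0.0011))
#' weekly_mortality(lt, 40)
#' @export
weekly_mortality <- function(lt, age, cycles_per_year = 52) {
  q <- annual_mortality(lt, age)
  1 - (1 - q)^(1 / cycles_per_year)
}

#' Synthetic national-style life table
#'
#' A Gompertz–Makeham annual mortality schedule
#' `qx = 1 - exp(-(A + B exp(theta * age)))` with defaults chosen to
#' resemble a contemporary UK national life table (e.g. q40 ~ 1e-3,
#' q80 ~ 5e-2). Shipped so that every run works without a download; users
#' should substitute the published national life table via
#' [load_life_table()] for applied work.
#'
#' @param ages Integer age range.
#' @param A Makeham (age-independent) hazard component.
#' @param B,theta Gompertz senescent-hazard parameters.
#' @return A `life_table`.
#' @export
default_life_table <- function(ages = 0:105, A = 2e-4, B = 2.5e-5, theta = 0.095) {
  hazard <- A + B * exp(theta * ages)
  life_table(ages, 1 - exp(-hazard))
}
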