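#' Body mass index from weight and height
#'
#' `BMI = W / H^2` with weight in kg and height in metres; heights are
#' supplied in cm everywhere in this package and converted internally here
#' only.
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return BMI in kg/m^2 (vectorised).
#' @export
#' @examples
#' compute_bmi(70, 175)  # 22.857...
compute_bmi <- function(weight, height) {
  if (!is.numeric(weight) || !is.numeric(height) ||
      any(!is.finite(weight)) || any(!is.finite(height)))
    stopf("weight and height must be finite numeric")
  if (any(weight <= 0)) stopf("weight must be positive (kg)")
  if (any(height <= 0)) stopf("height must be positive (cm)")
  weight / (height / 100)^2
}

#' Load a standard BMI-for-age table
#'
#' Reads a WHO-style table of median BMI by age and sex from a CSV with
#' columns `sex`, `age`, `bmi`.  The table shipped with the package is a
#' synthetic stand-in; supply the real reference for production use.
#'
#' @param path CSV path.
#' @param sex `"male"` or `"female"`; only rows for this sex are kept.
#' @return An object of class `standard_bmi_table` with fields `sex`,
#'   `ages`, `bmi_values`.
#' @export
load_bmi_table <- function(path, sex) {
  sex <- check_sex(sex)
  df <- read_strict_csv(path, c("sex", "age", "bmi"), "standard-BMI")
  df <- df[normalize_sex(df$sex) == sex, , drop = FALSE]
  standard_bmi_table(df$age, df$bmi, sex)
}

#' Construct a standard BMI table from vectors
#'
#' @param ages Ages in years, strictly increasing after sorting.
#' @param bmi_values Median BMI (kg/m^2) at each age, positive.
#' @param sex `"male"` or `"female"`.
#' @return A `standard_bmi_table` object.
#' @export
standard_bmi_table <- function(ages, bmi_values, sex) {
  sex <- check_sex(sex)
  if (length(ages) < 2L || length(ages) != length(bmi_values))
    stopf("standard BMI table needs >= 2 rows with matching lengths")
  ord <- order(ages)
  ages <- as.numeric(ages[ord]); bmi_values <- as.numeric(bmi_values[ord])
  if (any(diff(ages) <= 0)) stopf("BMI table ages must be strictly increasing")
  if (any(bmi_values <= 0)) stopf("BMI values must be positive")
  structure(list(sex = sex, ages = ages, bmi_values = bmi_values),
            class = "standard_bmi_table")
}

#' Standard BMI at an age, and the deviation from it
#'
#' `standard_bmi_at` linearly interpolates the reference BMI at `age`;
#' `compute_delta_bmi` returns `bmi` minus that reference value.  Ages
#' outside the table range are an error.
#'
#' @param table A [standard_bmi_table()].
#' @param age Age in years (vectorised).
#' @param bmi Observed BMI in kg/m^2.
#' @return kg/m^2.
#' @export
standard_bmi_at <- function(table, age) {
  if (!inherits(table, "standard_bmi_table"))
    stopf("`table` must be a standard_bmi_table")
  interp_grid(table$ages, table$bmi_values, age, "age")
}

#' @rdname standard_bmi_at
#' @export
compute_delta_bmi <- function(bmi, age, table) {
  bmi - standard_bmi_at(table, age)
}

#' A single subject measurement
#'
#' Bundles one growth measurement with its identifying fields and validates
#' the physiological ranges.
#'
#' @param subject_id Opaque identifier.
#' @param sex `"male"` or `"female"` (accepted codes include `M`/`F`).
#' @param age Chronological age in years, in (0, 25].
#' @param bone_age Skeletal age in years, in (0, 20].
#' @param height Height in cm, in (40, 230).
#' @param weight Weight in kg, in (2, 200).
#' @param adult_height Verified adult height in cm, or `NA` if unknown.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, sex, age, bone_age, height, weight,
                           adult_height = NA_real_) {
  sex <- normalize_sex(sex)
  check_number(age, "age", 0, 25, open_lower = TRUE)
  check_number(bone_age, "bone_age", 0, 20, open_lower = TRUE)
  check_number(height, "height", 40, 230, open_lower = TRUE, open_upper = TRUE)
  check_number(weight, "weight", 2, 200, open_lower = TRUE, open_upper = TRUE)
  if (!is.na(adult_height))
    check_number(adult_height, "adult_height", 40, 230,
                 open_lower = TRUE, open_upper = TRUE)
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 age = age, bone_age = bone_age, height = height,
                 weight = weight, adult_height = adult_height),
            class = "subject_record")
}

#' Six-feature encoding of one measurement
#'
#' Builds the model input vector `(bone_age, age, height, weight, bmi,
#' delta_bmi)` from a measurement: BMI is recomputed from the record's
#' weight and height (never taken on trust) and `delta_bmi` is the
#' deviation from the standard BMI-for-age.  Sex is deliberately not a
#' feature — separate male and female models are trained, keyed by sex.
#'
#' @param record A [subject_record()].
#' @param table A [standard_bmi_table()] for the record's sex.
#' @return A named numeric vector of length 6, in the order above.
#' @export
#' @examples
#' tab <- standard_bmi_table(c(8, 10, 12), c(16, 17, 18), "male")
#' rec <- subject_record("s1", "M", 10, 11, 140, 35)
#' build_features(rec, tab)
build_features <- function(record, table) {
  if (!inherits(record, "subject_record"))
    stopf("`record` must be a subject_record")
  bmi <- compute_bmi(record$weight, record$height)
  dbmi <- compute_delta_bmi(bmi, record$age, table)
  c(bone_age = record$bone_age, age = record$age, height = record$height,
    weight = record$weight, bmi = bmi, delta_bmi = dbmi)
}

feature_names <- function() {
  c("bone_age", "age", "height", "weight", "bmi", "delta_bmi")
}

#' Feature matrix for a cohort data frame
#'
#' Vectorised companion to [build_features()]: one row of features per
#' cohort row.
#'
#' @param cohort A data frame with columns `age`, `bone_age`, `height`,
#'   `weight` (e.g. from [load_cohort()] or [cohort_frame()]).
#' @param table A [standard_bmi_table()].
#' @return An `n x 6` numeric matrix with the standard feature columns.
#' @export
build_feature_matrix <- function(cohort, table) {
  need <- c("age", "bone_age", "height", "weight")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stopf("cohort lacks column(s): %s", paste(missing, collapse = ", "))
  if (anyNA(cohort[need])) stopf("cohort has missing values in %s",
                                 paste(need, collapse = "/"))
  bmi <- compute_bmi(cohort$weight, cohort$height)
  dbmi <- compute_delta_bmi(bmi, cohort$age, table)
  m <- cbind(cohort$bone_age, cohort$age, cohort$height, cohort$weight,
             bmi, dbmi)
  colnames(m) <- feature_names()
  m
}

#' Load a cohort CSV
#'
#' Expected columns: `subject_id, sex, age, bone_age, height, weight` and
#' optionally `adult_height`.  Sex codes `M`/`F` are accepted.
#'
#' @param path CSV path.
#' @return A data frame with normalised `sex` values.
#' @export
load_cohort <- function(path) {
  df <- read_strict_csv(path, c("subject_id", "sex", "age", "bone_age",
                                "height", "weight"), "cohort")
  df$sex <- normalize_sex(df$sex)
  df
}
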