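#' Mid-parental (genetic) height
#'
#' The linear target-height formula used as the simplest reference
#' predictor:
#' boys `56.699 + 0.419 * H_father + 0.265 * H_mother`,
#' girls `40.089 + 0.306 * H_father + 0.431 * H_mother` (heights in cm).
#'
#' @param sex `"male"` or `"female"`.
#' @param father_height,mother_height Parent heights in cm, each in
#'   (100, 230).
#' @return Predicted adult height in cm.
#' @export
#' @examples
#' genetic_height("male", 175, 160)    # 172.424
#' genetic_height("female", 175, 160)  # 162.599
genetic_height <- function(sex, father_height, mother_height) {
  sex <- check_sex(sex)
  check_number(father_height, "father_height", 100, 230,
               open_lower = TRUE, open_upper = TRUE)
  check_number(mother_height, "mother_height", 100, 230,
               open_lower = TRUE, open_upper = TRUE)
  if (sex == "male") 56.699 + 0.419 * father_height + 0.265 * mother_height
  else               40.089 + 0.306 * father_height + 0.431 * mother_height
}

#' Bayley-Pinneau adult-height prediction
#'
#' `Y = H / FP`: current height divided by the fraction of adult height
#' already attained at the current bone age (looked up, per sex and
#' developmental category, in a height-growth-percentage table).
#'
#' @param current_height Current height in cm (> 0).
#' @param fp Fraction of adult height attained, in (0, 1].
#' @return Predicted adult height in cm.
#' @export
#' @examples
#' bayley_pinneau(140, 0.8)  # 175
#' bayley_pinneau(165, 1.0)  # fully developed: 165
bayley_pinneau <- function(current_height, fp) {
  check_number(current_height, "current_height", 0, Inf, open_lower = TRUE)
  check_number(fp, "fp", 0, 1, open_lower = TRUE)
  current_height / fp
}

#' Load a percent-of-adult-height (FP) table
#'
#' CSV columns: `sex, category, bone_age, fp` and optionally
#' `fp_is_percent`.  `category` is the developmental type (`early`,
#' `normal`, `late`) — it is a required input here, not inferred.  FP is
#' stored as a fraction in (0, 1]; tables published as percentages are
#' divided by 100 when `fp_is_percent` (column or argument) says so.  No
#' published FP values ship with the package; the bundled table is a
#' synthetic stand-in for tests and examples.
#'
#' @param path CSV path.
#' @param sex `"male"` or `"female"`.
#' @param category `"early"`, `"normal"` or `"late"`.
#' @param fp_is_percent Force percentage interpretation (default: taken
#'   from the CSV column if present, else `FALSE`).
#' @return An object of class `fp_table` with fields `sex`, `category`,
#'   `bone_ages`, `fp`.
#' @export
load_fp_table <- function(path, sex, category, fp_is_percent = NULL) {
  sex <- check_sex(sex)
  if (!category %in% c("early", "normal", "late"))
    stopf('`category` must be "early", "normal" or "late"')
  df <- read_strict_csv(path, c("sex", "category", "bone_age", "fp"), "FP")
  df <- df[normalize_sex(df$sex) == sex & df$category == category, ,
           drop = FALSE]
  if (nrow(df) < 2L)
    stopf("FP table has fewer than 2 rows for %s/%s", sex, category)
  if (is.null(fp_is_percent))
    fp_is_percent <- "fp_is_percent" %in% names(df) &&
      any(as.logical(df$fp_is_percent))
  fp <- if (fp_is_percent) df$fp / 100 else df$fp
  fp_table(df$bone_age, fp, sex, category)
}

#' Construct an FP table from vectors
#'
#' @param bone_ages Strictly increasing bone ages in years.
#' @param fp Fractions of adult height in (0, 1], non-decreasing.
#' @param sex,category As in [load_fp_table()].
#' @return An `fp_table` object.
#' @export
fp_table <- function(bone_ages, fp, sex, category = "normal") {
  sex <- check_sex(sex)
  ord <- order(bone_ages)
  bone_ages <- as.numeric(bone_ages[ord]); fp <- as.numeric(fp[ord])
  if (any(diff(bone_ages) <= 0))
    stopf("FP bone ages must be strictly increasing")
  if (any(fp <= 0) || any(fp > 1))
    stopf("FP values must be fractions in (0, 1]")
  if (any(diff(fp) < 0))
    stopf("FP must be non-decreasing in bone age")
  structure(list(sex = sex, category = category,
                 bone_ages = bone_ages, fp = fp),
            class = "fp_table")
}

#' Look up the attained-height fraction at a bone age
#'
#' Linear interpolation between the bracketing table rows; bone ages
#' outside the table range are an error.
#'
#' @param table An [fp_table()].
#' @param bone_age Bone age in years (vectorised).
#' @return FP fraction(s) in (0, 1].
#' @export
#' @examples
#' tab <- fp_table(c(12, 13), c(0.84, 0.90), "male")
#' lookup_fp(tab, 12.5)  # 0.87
lookup_fp <- function(table, bone_age) {
  if (!inherits(table, "fp_table")) stopf("`table` must be an fp_table")
  interp_grid(table$bone_ages, table$fp, bone_age, "bone age")
}
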