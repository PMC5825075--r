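#' ICD-10 codes used to ascertain dementia
#'
#' Dementia is flagged at the person level when any of these codes appears as a
#' principal or additional diagnosis on any episode within the lookback window
#' (see [flag_dementia()]). The set covers vascular and unspecified dementias
#' (F00--F02), Alzheimer disease (G30) and other degenerative diseases of the
#' nervous system (G31). Matching is prefix-based on normalised codes, so
#' subcodes such as "F00.1" are captured.
#'
#' @return Character vector of ICD-10 code prefixes.
#' @export
#' @examples
#' dementia_codes()
dementia_codes <- function() {
  c("F00", "F01", "F02", "G30", "G31")
}

#' Cost subcategories that scale with length of stay
#'
#' The eleven DRG treatment-expense subcategories treated as *variable*, i.e.
#' accruing per day in hospital. Together with [fixed_subcategories()] they
#' partition the sixteen subcategories of a DRG reference row.
#'
#' @return Character vector of eleven subcategory labels, matching the column
#'   headers of a DRG reference table.
#' @seealso [fixed_subcategories()], [split_costs()]
#' @export
variable_subcategories <- function() {
  c("ward nursing", "ward medical", "non-clinical salaries", "pathology",
    "imaging", "allied health", "pharmacy", "supplies", "on-costs",
    "hotel", "depreciation")
}

#' One-off cost subcategories independent of length of stay
#'
#' The five DRG treatment-expense subcategories treated as *fixed*: incurred
#' once per episode regardless of how long the patient stays.
#'
#' @return Character vector of five subcategory labels.
#' @seealso [variable_subcategories()], [split_costs()]
#' @export
fixed_subcategories <- function() {
  c("critical care", "operating rooms", "emergency departments",
    "special procedure suites", "prosthesis")
}

#' Normalise ICD-10 diagnosis codes
#'
#' Uppercases and strips dots and whitespace, the standard preparation for
#' prefix matching in administrative data ("f00.1" -> "F001").
#'
#' @param x Character vector of raw codes.
#' @return Character vector of normalised codes.
#' @export
#' @examples
#' normalize_icd10(c("f00.1", " g30 ", "N39.0"))
normalize_icd10 <- function(x) {
  gsub("[. ]", "", toupper(trimws(as.character(x))))
}

# TRUE where any code in `codes` starts with any prefix in `prefixes`;
# both sides are assumed normalised.
match_any_prefix <- function(codes, prefixes) {
  if (length(codes) == 0L || length(prefixes) == 0L) return(FALSE)
  for (p in prefixes) {
    if (any(startsWith(codes, p))) return(TRUE)
  }
  FALSE
}

# split a semicolon-joined code field into a normalised character vector
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  normalize_icd10(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Packaged complication coding rules
#'
#' Rule table for the four nurse-sensitive hospital-acquired complications:
#' urinary tract infection, pressure injury, pneumonia and delirium. A
#' complication is flagged only from *additional* (secondary) diagnoses --
#' principal-diagnosis matches are treated as present on admission -- and only
#' when no aetiology-exclusion code applies (see [flag_complications()]).
#' Exclusions are conservative: patients predisposed to a condition by their
#' underlying illness are not coded as having acquired it in hospital. For
#' example a urinary-tract principal diagnosis blocks the UTI flag, and
#' paralysis anywhere on the record blocks the pressure-injury flag.
#'
#' The ICD-10-AM-style code lists are packaged illustrative vocabularies
#' (editable in `inst/extdata/complication_rules.csv`); the flagging engine,
#' not the vocabulary, is the tested artifact. The pneumonia and delirium
#' exclusion sets (immunodeficiency/cystic fibrosis and psychoactive-substance
#' disorders respectively) are assumptions in the same conservative spirit as
#' the two documented examples.
#'
#' @param path Optional path to a rules CSV with columns `name`,
#'   `inclusion_codes`, `exclusion_codes` (semicolon-separated) and
#'   `exclusion_scope` (`"principal_only"` or `"principal_or_additional"`).
#'   Defaults to the packaged table.
#' @return A validated data.frame of class `complication_rules`.
#' @export
#' @examples
#' default_complication_rules()
default_complication_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "complication_rules.csv",
                        package = "excesscost", mustWork = TRUE)
  }
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rules(rules)
}

#' Validate a complication rule table
#'
#' Checks that all four complications are present exactly once, that the
#' exclusion scope is recognised, and that within each rule no inclusion
#' prefix overlaps an exclusion prefix (in either prefix direction, since
#' matching is prefix-based).
#'
#' @param rules Data.frame with columns `name`, `inclusion_codes`,
#'   `exclusion_codes`, `exclusion_scope`.
#' @return The rules, classed `complication_rules`, invisibly usable downstream.
#' @export
validate_rules <- function(rules) {
  required <- c("name", "inclusion_codes", "exclusion_codes", "exclusion_scope")
  missing <- setdiff(required, names(rules))
  if (length(missing)) {
    stop("rule table is missing columns: ", paste(missing, collapse = ", "))
  }
  expected <- c("urinary_tract_infection", "pressure_injury", "pneumonia",
                "delirium")
  if (!identical(sort(rules$name), sort(expected))) {
    stop("rule table must contain each of ",
         paste(expected, collapse = ", "), " exactly once")
  }
  bad_scope <- setdiff(rules$exclusion_scope,
                       c("principal_only", "principal_or_additional"))
  if (length(bad_scope)) {
    stop("unknown exclusion_scope: ", paste(bad_scope, collapse = ", "))
  }
  for (i in seq_len(nrow(rules))) {
    inc <- split_codes(rules$inclusion_codes[i])
    exc <- split_codes(rules$exclusion_codes[i])
    if (length(inc) == 0L) {
      stop("rule '", rules$name[i], "' has no inclusion codes")
    }
    overlap <- outer(inc, exc, function(a, b) {
      startsWith(a, b) | startsWith(b, a)
    })
    if (any(overlap)) {
      stop("rule '", rules$name[i],
           "': inclusion and exclusion code sets overlap")
    }
  }
  class(rules) <- c("complication_rules", "data.frame")
  rules
}

#' Packaged Charlson comorbidity condition map
#'
#' Maps ICD-10 code prefixes to Charlson conditions and weights. The condition
#' list is restricted to those used as the comorbidity summary here: diabetes,
#' hemiplegia/paraplegia, any cancer, HIV/AIDS, and major cardiovascular,
#' renal, rheumatic, peptic ulcer and liver diseases, under the original
#' 1/2/3/6 weighting scheme. A dementia row is included so that
#' [compute_charlson()] can demonstrate its unconditional exclusion: dementia
#' is modelled as its own predictor, never inside the index.
#'
#' Code lists are packaged illustrative ICD-10-AM-style vocabularies
#' (editable in `inst/extdata/charlson_map.csv`), not a clinically validated
#' mapping.
#'
#' @param path Optional path to a CSV with columns `condition`, `weight`,
#'   `codes` (semicolon-separated prefixes). Defaults to the packaged table.
#' @return Data.frame with columns `condition`, `weight`, `codes`.
#' @export
#' @examples
#' default_charlson_map()
default_charlson_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "charlson_map.csv",
                        package = "excesscost", mustWork = TRUE)
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "weight", "codes")
  missing <- setdiff(required, names(map))
  if (length(missing)) {
    stop("charlson map is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(map$condition)) {
    stop("charlson map has duplicated conditions")
  }
  if (any(!is.finite(map$weight)) || any(map$weight < 0)) {
    stop("charlson weights must be non-negative numbers")
  }
  map
}
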