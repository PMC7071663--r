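#' Normalize an ICD-10 code
#'
#' Trims whitespace, upper-cases, and inserts the decimal point before
#' the fourth character when a 4+ character code lacks one, so that
#' \code{"I200"} and \code{"I20.0"} compare equal. Three-character
#' category codes are left as-is.
#'
#' @param raw character vector of raw codes.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalize_icd_code(c(" i20.0 ", "J449", "I10"))
normalize_icd_code <- function(raw) {
  x <- toupper(trimws(as.character(raw)))
  if (any(is.na(x) | x == ""))
    stop("empty ICD-10 code after trimming", call. = FALSE)
  no_dot <- !grepl(".", x, fixed = TRUE) & nchar(x) > 3L
  x[no_dot] <- paste0(substr(x[no_dot], 1L, 3L), ".",
                      substring(x[no_dot], 4L))
  x
}

#' Reference ICD-10 to NCD disease-group map
#'
#' The 33 diagnostic codes (out of the 200 codes responsible for the
#' most inpatient admissions nationally) attributable to the four main
#' NCD groups: 15 cardiovascular, 4 cancer, 6 diabetes and 8 chronic
#' respiratory. Transcribed as published, including the clinically
#' surprising assignments (e.g. J35.3 and O24.4 under diabetes).
#'
#' @return data frame with columns \code{icd10_code, group}.
#' @export
ncd_icd10_map <- function() {
  grp <- function(codes, group)
    data.frame(icd10_code = codes, group = group, stringsAsFactors = FALSE)
  rbind(
    grp(c("I20.0", "I25.1", "I10", "R07.4", "I64", "I50.0", "I25.9",
          "I21.9", "I48", "I50.9", "I80.2", "I51.6", "G45.9", "Z03.5",
          "I24.9"), "cardiovascular"),
    grp(c("Z51.1", "N83.2", "N63", "D48.7"), "cancer"),
    grp(c("J35.3", "O24.4", "E11.5", "E14.5", "E10.9", "E11.9"),
        "diabetes"),
    grp(c("J18.9", "J44.9", "R06.0", "J45.9", "J44.1", "J21.9", "J40",
          "J46"), "chronic_respiratory")
  )
}

#' Reference inpatient admission counts (national insurer claims, 2017)
#'
#' Admission counts for the 33 reference ICD-10 codes, extracted from the
#' two main public insurance organizations covering over 90% of the
#' population. Group sums: cardiovascular 205,823; cancer 29,898;
#' diabetes 22,800; chronic respiratory 95,052.
#'
#' @return data frame with columns \code{icd10_code, admissions}.
#' @export
ncd_reference_claims <- function() {
  data.frame(
    icd10_code = c("I20.0", "I25.1", "I10", "R07.4", "I64", "I50.0",
                   "I25.9", "I21.9", "I48", "I50.9", "I80.2", "I51.6",
                   "G45.9", "Z03.5", "I24.9",
                   "Z51.1", "N83.2", "N63", "D48.7",
                   "J35.3", "O24.4", "E11.5", "E14.5", "E10.9", "E11.9",
                   "J18.9", "J44.9", "R06.0", "J45.9", "J44.1", "J21.9",
                   "J40", "J46"),
    admissions = c(56238L, 29660L, 26819L, 16363L, 12663L, 11763L,
                   11437L, 10174L, 7187L, 6906L, 4048L, 3794L, 3412L,
                   3012L, 2347L,
                   21301L, 5645L, 2242L, 710L,
                   8531L, 5139L, 4013L, 1994L, 1933L, 1190L,
                   44902L, 16173L, 12856L, 12367L, 3281L, 2486L, 2021L,
                   966L),
    stringsAsFactors = FALSE
  )
}

#' Map a normalized ICD-10 code to its NCD disease group
#'
#' @param code character vector of normalized codes.
#' @param map a code-to-group data frame as from [ncd_icd10_map()].
#' @return character vector: the group, or \code{NA} for unmapped codes
#'   (never an error).
#' @export
map_code_to_group <- function(code, map = ncd_icd10_map()) {
  map$group[match(code, map$icd10_code)]
}

#' Aggregate inpatient claims into NCD disease groups
#'
#' Sums admissions per disease group. Duplicate codes are summed (claims
#' extracts from several insurers overlap in codes). Conservation holds
#' exactly: group totals plus the unmapped total equal the grand total.
#'
#' @param records data frame with columns \code{icd10_code, admissions}
#'   (nonnegative counts); codes are normalized before mapping.
#' @param map code-to-group map; defaults to [ncd_icd10_map()].
#' @return a list of class \code{"admission_summary"}: \code{by_group}
#'   (named numeric over the four groups), \code{unmapped},
#'   \code{total}, and \code{shares} (group totals / grand total).
#' @export
aggregate_admissions <- function(records, map = ncd_icd10_map()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  groups <- c("cardiovascular", "cancer", "diabetes", "chronic_respiratory")
  if (nrow(records) == 0L) {
    out <- list(by_group = stats::setNames(numeric(4), groups),
                unmapped = 0, total = 0,
                shares = stats::setNames(rep(NA_real_, 4), groups))
    class(out) <- "admission_summary"
    return(out)
  }
  adm <- records$admissions
  if (any(is.na(adm)) || any(adm < 0))
    stop("admissions must be nonnegative counts", call. = FALSE)
  code <- normalize_icd_code(records$icd10_code)
  g <- map_code_to_group(code, map)
  by_group <- vapply(groups, function(k) sum(adm[!is.na(g) & g == k]),
                     numeric(1))
  total <- sum(adm)
  out <- list(by_group = by_group,
              unmapped = total - sum(by_group),
              total = total,
              shares = if (total > 0) by_group / total else
                stats::setNames(rep(NA_real_, 4), groups))
  class(out) <- "admission_summary"
  out
}

#' @export
print.admission_summary <- function(x, ...) {
  cat("Inpatient admissions by NCD disease group\n")
  for (k in names(x$by_group))
    cat(sprintf("  %-20s %10.0f\n", k, x$by_group[[k]]))
  cat(sprintf("  %-20s %10.0f\n", "unmapped", x$unmapped))
  cat(sprintf("  %-20s %10.0f\n", "total", x$total))
  invisible(x)
}

#' The "4 diseases, 4 modifiable shared risk-factors" model
#'
#' Links each shared modifiable risk factor to the NCD disease groups it
#' contributes to: tobacco use to all four; unhealthy diet, physical
#' inactivity and harmful alcohol use to cardiovascular disease,
#' diabetes and cancer. Chronic respiratory disease is linked only to
#' tobacco.
#'
#' @return named list: risk factor -> character vector of disease groups.
#' @export
risk_factor_model <- function() {
  three <- c("cardiovascular", "diabetes", "cancer")
  list(
    tobacco             = c(three, "chronic_respiratory"),
    unhealthy_diet      = three,
    physical_inactivity = three,
    harmful_alcohol     = three
  )
}

## catalog area tags -> the risk-factor names of the 4x4 model
area_to_risk_factor <- c(tobacco = "tobacco",
                         alcohol = "harmful_alcohol",
                         diet = "unhealthy_diet",
                         physical_inactivity = "physical_inactivity")

#' Preventable-hospitalization scores (criterion 4)
#'
#' Scores each intervention by the inpatient admissions it could
#' plausibly avert under the 4x4 model: a risk-factor intervention gets
#' the sum of admissions over the disease groups its risk factor is
#' linked to; a clinical intervention gets its own disease group's
#' total. Scores are raw admission counts; column normalization happens
#' downstream in the MCDA.
#'
#' @param summary an \code{"admission_summary"}.
#' @param interventions an \code{"ncd_catalog"} subset; every item must
#'   carry a risk-factor or disease-group area tag (\code{"general"} is
#'   rejected).
#' @param model risk-factor links; defaults to [risk_factor_model()].
#' @return named numeric vector, one score per intervention code.
#' @export
criterion4_scores <- function(summary, interventions,
                              model = risk_factor_model()) {
  stopifnot(inherits(summary, "admission_summary"),
            inherits(interventions, "ncd_catalog"))
  if (any(interventions$area == "general"))
    stop("cannot score intervention(s) with area 'general': ",
         paste(interventions$code[interventions$area == "general"],
               collapse = ", "), call. = FALSE)
  scores <- vapply(seq_len(nrow(interventions)), function(i) {
    area <- interventions$area[i]
    if (area %in% names(area_to_risk_factor)) {
      sum(summary$by_group[model[[area_to_risk_factor[[area]]]]])
    } else {
      summary$by_group[[area]]
    }
  }, numeric(1))
  stats::setNames(scores, interventions$code)
}
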