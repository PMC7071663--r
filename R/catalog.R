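CATEGORIES <- c("overarching_action", "intervention")
AREAS <- c("tobacco", "alcohol", "diet", "physical_inactivity",
           "cardiovascular", "diabetes", "cancer", "chronic_respiratory",
           "general")
CE_TIERS <- c("best_buy", "effective_gt_100", "no_cea", "not_applicable")

## Split a dotted menu code "o.k" into objective and item index.
## Codes are kept as strings throughout: "3.4" and "3.40" are distinct
## items and numeric collation would conflate them.
parse_code <- function(code) {
  code <- as.character(code)
  parts <- strsplit(code, ".", fixed = TRUE)
  bad <- vapply(parts, function(p) {
    length(p) != 2L || anyNA(suppressWarnings(as.integer(p))) ||
      any(!grepl("^[0-9]+$", p))
  }, logical(1))
  if (any(bad)) {
    stop("malformed intervention code(s): ",
         paste(code[bad], collapse = ", "),
         " (expected \"objective.item\", e.g. \"3.4\")", call. = FALSE)
  }
  data.frame(
    objective = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    item      = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
}

#' Build an intervention catalog
#'
#' Assembles tabular menu records into a validated catalog, ordered by
#' (objective, item index). Codes must be unique dotted identifiers
#' \code{"o.k"} whose leading integer is the objective.
#'
#' @param rows a data frame with columns \code{code} and \code{title};
#'   optional columns \code{category} (\code{"overarching_action"} or
#'   \code{"intervention"}), \code{area} and \code{ce_tier} are filled
#'   with defaults (\code{"intervention"}, \code{"general"},
#'   \code{"not_applicable"}) when absent.
#' @return a data frame of class \code{"ncd_catalog"} with columns
#'   \code{code, title, objective, item, category, area, ce_tier}.
#' @seealso [who_ncd_catalog()] for the packaged WHO reference menu.
#' @export
build_catalog <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) {
    out <- data.frame(code = character(), title = character(),
                      objective = integer(), item = integer(),
                      category = character(), area = character(),
                      ce_tier = character(), stringsAsFactors = FALSE)
    class(out) <- c("ncd_catalog", "data.frame")
    return(out)
  }
  if (!all(c("code", "title") %in% names(rows)))
    stop("catalog rows need at least columns 'code' and 'title'",
         call. = FALSE)
  dup <- unique(rows$code[duplicated(rows$code)])
  if (length(dup))
    stop("duplicate catalog code(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  ok <- parse_code(rows$code)
  if (!("category" %in% names(rows))) rows$category <- "intervention"
  if (!("area" %in% names(rows))) rows$area <- "general"
  if (!("ce_tier" %in% names(rows))) rows$ce_tier <- "not_applicable"
  stopifnot(all(rows$category %in% CATEGORIES),
            all(rows$area %in% AREAS),
            all(rows$ce_tier %in% CE_TIERS))
  out <- data.frame(code = as.character(rows$code),
                    title = as.character(rows$title),
                    objective = ok$objective, item = ok$item,
                    category = rows$category, area = rows$area,
                    ce_tier = rows$ce_tier, stringsAsFactors = FALSE)
  out <- out[order(out$objective, out$item), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ncd_catalog", "data.frame")
  out
}

#' The WHO reference menu of NCD actions and interventions
#'
#' The packaged 105-item menu (2017 update): six objectives, 88
#' interventions and 17 overarching/enabling actions. Objectives 1, 2, 5
#' and 6 hold general policy options (4/4/5/5); objective 3 holds 49
#' risk-factor items (9 overarching actions and 40 interventions across
#' tobacco, alcohol, unhealthy diet and physical inactivity); objective 4
#' holds 38 health-system items (8 overarching actions and 30 clinical
#' interventions across the four main disease groups).
#'
#' Titles for the clinical and risk-factor interventions are the WHO menu
#' titles; titles of the overarching actions and general policy options
#' not individually discussed in the source documents are descriptive
#' placeholders. Cost-effectiveness tiers outside the documented missed
#' set are a reconstruction from the WHO best-buys classification.
#'
#' @return an \code{"ncd_catalog"} data frame with 105 rows.
#' @export
who_ncd_catalog <- function() {
  r <- function(code, title, category = "intervention",
                area = "general", ce = "not_applicable")
    data.frame(code = code, title = title, category = category,
               area = area, ce_tier = ce, stringsAsFactors = FALSE)

  rows <- list(
    ## objective 1: international priority and advocacy (4 policy options)
    r("1.1", "Raise the priority of NCDs in international development agendas"),
    r("1.2", "Advocate for NCD prevention within internationally agreed development goals"),
    r("1.3", "Strengthen international cooperation for resource mobilization, capacity-building, health workforce training and exchange of information on lessons learned and best practices"),
    r("1.4", "Engage international partners in strengthened advocacy for NCD prevention and control"),
    ## objective 2: national capacity, governance, multisectoral action
    r("2.1", "Strengthen national leadership and governance for NCD prevention and control"),
    r("2.2", "Assess national capacity for prevention and control of NCDs"),
    r("2.3", "Develop and sustain multisectoral partnerships for NCD prevention and control"),
    r("2.4", "Integrate NCD prevention and control into national development planning")
  )

  oa <- function(code, title, area)
    r(code, title, category = "overarching_action", area = area)
  iv <- function(code, title, area, ce) r(code, title, area = area, ce = ce)

  rows <- c(rows, list(
    ## objective 3, tobacco: 3 overarching actions + 9 interventions
    oa("3.1", "Strengthen implementation of the WHO Framework Convention on Tobacco Control", "tobacco"),
    oa("3.2", "Strengthen tobacco-control governance and national coordination", "tobacco"),
    oa("3.3", "Monitor tobacco use and prevention policies", "tobacco"),
    iv("3.4", "Increase excise taxes and prices on tobacco products", "tobacco", "best_buy"),
    iv("3.5", "Implement plain/standardized packaging and/or large graphic health warnings on all tobacco packages", "tobacco", "best_buy"),
    iv("3.6", "Enact and enforce comprehensive bans on tobacco advertising, promotion, and sponsorship", "tobacco", "best_buy"),
    iv("3.7", "Eliminate exposure to second-hand tobacco smoke in all indoor workplaces, public places, and public transport", "tobacco", "best_buy"),
    iv("3.8", "Implement effective mass media campaigns that educate the public about the harms of smoking/tobacco use and second-hand smoke", "tobacco", "best_buy"),
    iv("3.9", "Provide cost-covered, effective and population-wide support (including brief advice, national toll-free quitline services) for tobacco cessation to all those who want to quit", "tobacco", "effective_gt_100"),
    iv("3.10", "Implement measures to minimize illicit trade in tobacco products", "tobacco", "no_cea"),
    iv("3.11", "Ban cross-border advertising, including using modern means of communication", "tobacco", "no_cea"),
    iv("3.12", "Provide cessation for tobacco cessation to all those who want to quit", "tobacco", "effective_gt_100"),
    ## objective 3, alcohol: 3 overarching actions + 11 interventions
    oa("3.13", "Strengthen national alcohol policy and its multisectoral governance", "alcohol"),
    oa("3.14", "Strengthen monitoring and surveillance of harmful alcohol use", "alcohol"),
    oa("3.15", "Strengthen enforcement capacity for alcohol control measures", "alcohol"),
    iv("3.16", "Increase excise taxes on alcoholic beverages", "alcohol", "best_buy"),
    iv("3.17", "Enact and enforce bans or comprehensive restrictions on exposure to alcohol advertising (across multiple types of media)", "alcohol", "best_buy"),
    iv("3.18", "Enact and enforce restrictions on the physical availability of retailed alcohol (via reduced hours of sale)", "alcohol", "best_buy"),
    iv("3.19", "Enact and enforce drink-driving laws and blood alcohol concentration limits via sobriety checkpoints", "alcohol", "effective_gt_100"),
    iv("3.20", "Provide brief psychosocial intervention for persons with hazardous and harmful alcohol use", "alcohol", "effective_gt_100"),
    iv("3.21", "Carry out regular reviews of prices in relation to the level of inflation and income", "alcohol", "no_cea"),
    iv("3.22", "Establish minimum prices for alcohol where applicable", "alcohol", "no_cea"),
    iv("3.23", "Enact and enforce an appropriate minimum age for purchase or consumption of alcoholic beverages and reduce the density of retail outlets", "alcohol", "no_cea"),
    iv("3.24", "Restrict or ban promotions of alcoholic beverages in connection with sponsorships and activities targeting young people", "alcohol", "no_cea"),
    iv("3.25", "Provide prevention, treatment, and care for alcohol use disorders and comorbid conditions in health and social services", "alcohol", "no_cea"),
    iv("3.26", "Provide consumer information about, and label, alcoholic beverages to indicate, the harm related to alcohol", "alcohol", "no_cea"),
    ## objective 3, unhealthy diet: 2 overarching actions + 13 interventions
    oa("3.27", "Strengthen national nutrition policy and intersectoral food-system governance", "diet"),
    oa("3.28", "Monitor population diet and nutrition status", "diet"),
    iv("3.29", "Reduce salt intake through the reformulation of food products to contain less salt and the setting of target levels for the amount of salt in foods and meals", "diet", "best_buy"),
    iv("3.30", "Reduce salt intake through the establishment of a supportive environment in public institutions such as hospitals, schools, workplaces, and nursing homes, to enable lower sodium options to be provided", "diet", "best_buy"),
    iv("3.31", "Reduce salt intake through a behavior change communication and mass media campaign", "diet", "best_buy"),
    iv("3.32", "Reduce salt intake through the implementation of front-of-pack labeling", "diet", "best_buy"),
    iv("3.33", "Eliminate industrial trans-fats through the development of legislation to ban their use in the food chain", "diet", "best_buy"),
    iv("3.34", "Reduce sugar consumption through effective taxation on sugar-sweetened beverages", "diet", "effective_gt_100"),
    iv("3.35", "Promote and support exclusive breastfeeding for the first 6 months of life, including the promotion of breastfeeding", "diet", "effective_gt_100"),
    iv("3.36", "Implement subsidies to increase the intake of fruits and vegetables", "diet", "no_cea"),
    iv("3.37", "Replace trans-fats and saturated fats with unsaturated fats through reformulation, labeling, fiscal policies or agricultural policies", "diet", "effective_gt_100"),
    iv("3.38", "Limiting portion and package size to reduce energy intake and the risk of overweight/obesity", "diet", "no_cea"),
    iv("3.39", "Implement nutrition education and counseling in different settings (for example, in preschools, schools, workplaces, and hospitals) to increase the intake of fruits and vegetables", "diet", "no_cea"),
    iv("3.40", "Implement nutrition labeling to reduce total energy intake (kcal), sugars, sodium and fats", "diet", "no_cea"),
    iv("3.41", "Implement mass media campaign on healthy diets, including social marketing to reduce the intake of total fat, saturated fats, sugars, and salt, and promote the intake of fruits and vegetables", "diet", "effective_gt_100"),
    ## objective 3, physical inactivity: 1 overarching action + 7 interventions
    oa("3.42", "Strengthen national policy and environments supportive of physical activity", "physical_inactivity"),
    iv("3.43", "Implement community-wide public education and awareness campaign for physical activity which includes a mass media campaign combined with other community-based education, motivational and environmental programs aimed at supporting behavioral change of physical activity levels", "physical_inactivity", "best_buy"),
    iv("3.44", "Provide physical activity counseling and referral as part of routine primary health care services through the use of a brief intervention", "physical_inactivity", "effective_gt_100"),
    iv("3.45", "Ensure that macro-level urban design incorporates the core elements of residential density, connected street networks that include sidewalks, easy access to a diversity of destinations and access to public transport", "physical_inactivity", "no_cea"),
    iv("3.46", "Implement a whole-of-school program that includes quality physical education, availability of adequate facilities and programs to support physical activity for all children", "physical_inactivity", "no_cea"),
    iv("3.47", "Provide convenient and safe access to quality public open space and adequate infrastructure to support walking and cycling", "physical_inactivity", "no_cea"),
    iv("3.48", "Implement multi-component workplace physical activity programs", "physical_inactivity", "no_cea"),
    iv("3.49", "Promotion of physical activity through organized sports groups and clubs, programs and events", "physical_inactivity", "no_cea"),
    ## objective 4: 8 overarching/enabling actions
    oa("4.1", "Integrate NCD services into people-centered primary health care and universal health coverage", "general"),
    oa("4.2", "Explore viable health financing mechanisms and innovative economic tools supported by evidence", "general"),
    oa("4.3", "Scale up early detection and coverage, prioritizing very cost-effective high-impact interventions", "general"),
    oa("4.4", "Train and strengthen the health workforce for NCD prevention and management", "general"),
    oa("4.5", "Improve availability and affordability of essential NCD medicines and technologies", "general"),
    oa("4.6", "Strengthen referral systems between primary care and specialist NCD services", "general"),
    oa("4.7", "Develop and implement a palliative care policy, including access to opioids analgesics for pain relief, together with training for health workers", "general"),
    oa("4.8", "Strengthen self-care and patient empowerment for people living with NCDs", "general"),
    ## objective 4, cardiovascular disease: 10 interventions
    iv("4.9", "Drug therapy (including glycaemic control for diabetes mellitus and control of hypertension using a total risk approach) and counseling to individuals who have had a heart attack or stroke and to persons with high risk (>= 30%) of a fatal and non-fatal cardiovascular event in the next 10 years", "cardiovascular", "best_buy"),
    iv("4.10", "Treatment of new cases of acute myocardial infarction with either: acetylsalicylic acid, or acetylsalicylic acid and clopidogrel, or thrombolysis, or primary percutaneous coronary interventions (PCI)", "cardiovascular", "effective_gt_100"),
    iv("4.11", "Treatment of acute ischemic stroke with intravenous thrombolytic therapy", "cardiovascular", "effective_gt_100"),
    iv("4.12", "Primary prevention of rheumatic fever and rheumatic heart diseases by increasing appropriate treatment of streptococcal pharyngitis at the primary care level", "cardiovascular", "effective_gt_100"),
    iv("4.13", "Secondary prevention of rheumatic fever and rheumatic heart disease by developing a register of patients who receive regular prophylactic penicillin", "cardiovascular", "effective_gt_100"),
    iv("4.14", "Treatment of congestive cardiac failure with angiotensin-converting-enzyme inhibitor, beta-blocker, and diuretic", "cardiovascular", "effective_gt_100"),
    iv("4.15", "Cardiac rehabilitation post-myocardial infarction", "cardiovascular", "no_cea"),
    iv("4.16", "Anticoagulation for medium-and high-risk non-valvular atrial fibrillation and for mitral stenosis with atrial fibrillation", "cardiovascular", "no_cea"),
    iv("4.17", "Low-dose acetylsalicylic acid for ischemic stroke", "cardiovascular", "effective_gt_100"),
    iv("4.18", "Care of acute stroke and rehabilitation in stroke units", "cardiovascular", "no_cea"),
    ## objective 4, diabetes: 7 interventions
    iv("4.19", "Preventive foot care for people with diabetes (including educational programs, access to appropriate footwear, multidisciplinary clinics)", "diabetes", "no_cea"),
    iv("4.20", "Diabetic retinopathy screening for all diabetes patients and laser photocoagulation for prevention of blindness", "diabetes", "effective_gt_100"),
    iv("4.21", "Effective glycaemic control for people with diabetes, along with standard home glucose monitoring for people treated with insulin to reduce diabetes complications", "diabetes", "effective_gt_100"),
    iv("4.22", "Lifestyle interventions for preventing type 2 diabetes", "diabetes", "effective_gt_100"),
    iv("4.23", "Influenza vaccination for patients with diabetes", "diabetes", "no_cea"),
    iv("4.24", "Preconception care among women of reproductive age who have diabetes including patient education and intensive glucose management", "diabetes", "no_cea"),
    iv("4.25", "Screening of people with diabetes for proteinuria and treatment with angiotensin-converting enzyme inhibitor for the prevention and delay of renal disease", "diabetes", "effective_gt_100"),
    ## objective 4, cancer: 7 interventions
    iv("4.26", "Vaccination against human papillomavirus (2 doses) of 9-13-year-old girls", "cancer", "best_buy"),
    iv("4.27", "Prevention of cervical cancer by screening women aged 30-49 years", "cancer", "best_buy"),
    iv("4.28", "Screening with mammography (once every 2 years for women aged 50-69 years) linked with timely diagnosis and treatment of breast cancer", "cancer", "effective_gt_100"),
    iv("4.29", "Treatment of colorectal cancer stages I and II with surgery +/- chemotherapy and radiotherapy", "cancer", "effective_gt_100"),
    iv("4.30", "Prevention of liver cancer through hepatitis B immunization", "cancer", "best_buy"),
    iv("4.31", "Oral cancer screening in high-risk groups (for example, tobacco users, betel-nut chewers) linked with timely treatment", "cancer", "no_cea"),
    iv("4.32", "Population-based colorectal cancer screening, including through a faecal occult blood test, as appropriate, at age > 50 years, linked with timely treatment", "cancer", "no_cea"),
    ## objective 4, chronic respiratory: 6 interventions
    iv("4.33", "Symptom relief for patients with asthma with inhaled salbutamol", "chronic_respiratory", "effective_gt_100"),
    iv("4.34", "Symptom relief for patients with chronic obstructive pulmonary disease with inhaled salbutamol", "chronic_respiratory", "effective_gt_100"),
    iv("4.35", "Treatment of asthma using low dose inhaled beclometasone and short-acting beta-agonist", "chronic_respiratory", "best_buy"),
    iv("4.36", "Access to improved stoves and cleaner fuels to reduce indoor air pollution", "chronic_respiratory", "no_cea"),
    iv("4.37", "Cost-effective interventions to prevent occupational lung diseases, for example, from exposure to silica, asbestos", "chronic_respiratory", "no_cea"),
    iv("4.38", "Influenza vaccination for patients with chronic obstructive pulmonary disease", "chronic_respiratory", "no_cea"),
    ## objective 5: research and development (5 policy options)
    r("5.1", "Develop and implement a prioritized national NCD research agenda"),
    r("5.2", "Strengthen institutional capacity for NCD research"),
    r("5.3", "Promote the use of research evidence in NCD policy-making"),
    r("5.4", "Support innovation and technology transfer for NCD prevention"),
    r("5.5", "Foster international collaboration in NCD research"),
    ## objective 6: surveillance and monitoring (5 policy options)
    r("6.1", "Develop national targets and indicators based on the global monitoring framework"),
    r("6.2", "Strengthen surveillance of NCD risk factors and determinants"),
    r("6.3", "Strengthen registries and reporting of NCD-related mortality and morbidity"),
    r("6.4", "Monitor health-system capacity and response for NCDs"),
    r("6.5", "Evaluate progress towards national and global NCD targets")
  ))
  build_catalog(do.call(rbind, rows))
}

#' Codes excluded from the quantitative prioritization
#'
#' The nine objective-3 overarching actions plus the eight objective-4
#' overarching actions (codes 4.1 to 4.8): non-quantifiable items that do
#' not enter the MCDA.
#'
#' @return character vector of 17 codes.
#' @export
prioritization_exclusions <- function() {
  c("3.1", "3.2", "3.3", "3.13", "3.14", "3.15", "3.27", "3.28", "3.42",
    paste0("4.", 1:8))
}

#' Reconstructed national policy mention index (synthetic fixture)
#'
#' A mention table compatible with the documented gap-analysis outcome
#' for Iran: the 12 missed items have no mentions, 49 items are mentioned
#' in the national action plan (green) and the remaining 44 only in other
#' national documents (blue). Which 49 items were in the action plan is
#' not published, so the green/blue split beyond the documented red set
#' is a deterministic reconstruction: greens are taken in catalog order
#' from the mentioned items, with the tobacco-cessation support item 3.9
#' held blue (mentioned in national documents, but with its cost coverage
#' unresolved).
#'
#' @param catalog an \code{"ncd_catalog"}; defaults to the WHO reference.
#' @return data frame with columns \code{code, document_id,
#'   document_class} (and a \code{note} on item 3.9).
#' @export
iran_policy_mentions <- function(catalog = who_ncd_catalog()) {
  red <- missed_intervention_codes()
  mentioned <- catalog$code[!(catalog$code %in% red)]
  green_pool <- mentioned[mentioned != "3.9"]
  green <- green_pool[seq_len(49L)]
  blue <- setdiff(mentioned, green)
  out <- rbind(
    data.frame(code = green, document_id = "national_action_plan_ncd_2015",
               document_class = "national_action_plan",
               note = "", stringsAsFactors = FALSE),
    data.frame(code = blue, document_id = "other_national_policy_documents",
               document_class = "other_national_document",
               note = "", stringsAsFactors = FALSE)
  )
  out$note[out$code == "3.9"] <-
    "mentioned in national documents without resolution of cost coverage"
  rownames(out) <- NULL
  out
}

#' The 12 documented missed (red) intervention codes
#' @return character vector of 12 codes.
#' @export
missed_intervention_codes <- function() {
  c("1.3", "2.2", "4.2", "4.7",          # overarching/enabling
    "3.38", "3.45", "4.16", "4.31",      # no cost-effectiveness analysis
    "4.10", "4.12", "4.13",              # effective, > I$100 per DALY
    "4.26")                              # best buy
}

#' Label catalog items against national policy mentions
#'
#' Each item gets exactly one traffic-light label: \code{green} if it is
#' mentioned in the national action plan, else \code{blue} if mentioned
#' in any other national document, else \code{red} (not mentioned
#' anywhere). Precedence is green > blue > red, so adding mentions can
#' only move a label towards green.
#'
#' @param catalog an \code{"ncd_catalog"}.
#' @param mentions data frame with columns \code{code, document_id,
#'   document_class}; codes must exist in the catalog.
#' @return data frame with columns \code{code, label}, one row per
#'   catalog item, in catalog order.
#' @export
label_interventions <- function(catalog, mentions) {
  stopifnot(inherits(catalog, "ncd_catalog"))
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  if (nrow(mentions)) {
    unknown <- setdiff(unique(mentions$code), catalog$code)
    if (length(unknown))
      stop("mention(s) reference unknown code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad_class <- setdiff(unique(mentions$document_class),
                         c("national_action_plan", "other_national_document"))
    if (length(bad_class))
      stop("unknown document_class: ", paste(bad_class, collapse = ", "),
           call. = FALSE)
  }
  in_plan <- unique(mentions$code[
    mentions$document_class == "national_action_plan"])
  any_mention <- unique(mentions$code)
  label <- ifelse(catalog$code %in% in_plan, "green",
                  ifelse(catalog$code %in% any_mention, "blue", "red"))
  data.frame(code = catalog$code, label = label, stringsAsFactors = FALSE)
}

#' Summarize policy gaps
#'
#' Cross-tabulates labels by objective and cost-effectiveness tier and
#' lists the red (missed) items. In the red breakdown, items with tier
#' \code{not_applicable} form the overarching/enabling bucket (general
#' policy options and overarching actions alike).
#'
#' @param labels output of [label_interventions()].
#' @param catalog the catalog the labels refer to.
#' @return a list of class \code{"ncd_gap_report"} with elements
#'   \code{by_label}, \code{by_objective}, \code{red_by_tier},
#'   \code{red_items} (catalog rows, ordered by code), and \code{n}.
#' @export
gap_report <- function(labels, catalog) {
  stopifnot(inherits(catalog, "ncd_catalog"))
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  missing <- setdiff(catalog$code, labels$code)
  if (length(missing))
    stop("missing label(s) for code(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(labels$code))
    stop("more than one label for some codes", call. = FALSE)
  lab <- labels$label[match(catalog$code, labels$code)]
  by_label <- table(factor(lab, levels = c("green", "blue", "red")))
  by_objective <- table(objective = catalog$objective,
                        label = factor(lab, levels = c("green", "blue", "red")))
  red <- catalog[lab == "red", , drop = FALSE]
  red <- red[order(red$objective, red$item), , drop = FALSE]
  rownames(red) <- NULL
  red_by_tier <- table(factor(red$ce_tier, levels = CE_TIERS))
  out <- list(by_label = by_label, by_objective = by_objective,
              red_by_tier = red_by_tier, red_items = red,
              n = nrow(catalog))
  class(out) <- "ncd_gap_report"
  out
}

#' @export
print.ncd_gap_report <- function(x, ...) {
  cat("NCD policy gap report:", x$n, "catalog items\n")
  cat(sprintf("  green (in national action plan): %d\n", x$by_label[["green"]]))
  cat(sprintf("  blue  (other national documents): %d\n", x$by_label[["blue"]]))
  cat(sprintf("  red   (not mentioned anywhere):   %d\n", x$by_label[["red"]]))
  if (nrow(x$red_items)) {
    cat("missed items:\n")
    for (i in seq_len(nrow(x$red_items)))
      cat(sprintf("  %-5s [%s] %s\n", x$red_items$code[i],
                  x$red_items$ce_tier[i],
                  substr(x$red_items$title[i], 1, 60)))
  }
  invisible(x)
}

#' Select the prioritizable subset of a catalog
#'
#' Drops the excluded (non-quantifiable) codes and optionally restricts
#' to one objective. With the packaged WHO catalog and exclusion set this
#' yields the 40 risk-factor interventions of objective 3 or the 30
#' clinical interventions of objective 4. Order-preserving and
#' idempotent.
#'
#' @param catalog an \code{"ncd_catalog"}.
#' @param exclusions character vector of codes to drop; must all exist in
#'   the catalog. Defaults to [prioritization_exclusions()], in which
#'   case codes already absent are ignored, making repeated filtering
#'   idempotent.
#' @param objective optional objective number to restrict to.
#' @return the filtered \code{"ncd_catalog"}.
#' @export
filter_prioritizable <- function(catalog,
                                 exclusions = prioritization_exclusions(),
                                 objective = NULL) {
  stopifnot(inherits(catalog, "ncd_catalog"))
  unknown <- setdiff(exclusions, catalog$code)
  if (length(unknown) && !missing(exclusions))
    stop("exclusion code(s) not in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- catalog[!(catalog$code %in% exclusions), , drop = FALSE]
  if (!is.null(objective))
    out <- out[out$objective == objective, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ncd_catalog", "data.frame")
  out
}
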