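## exact fraction parsing: "1/3" must parse to one third, not a
## truncated decimal
parse_judgment <- function(x) {
  x <- trimws(as.character(x))
  out <- numeric(length(x))
  frac <- grepl("^[0-9]+(\\.[0-9]+)?\\s*/\\s*[0-9]+(\\.[0-9]+)?$", x)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/")
    out[frac] <- vapply(parts, function(p)
      as.numeric(p[1]) / as.numeric(p[2]), numeric(1))
  }
  plain <- !frac
  out[plain] <- suppressWarnings(as.numeric(x[plain]))
  if (any(is.na(out)))
    stop("unparseable judgment value(s): ",
         paste(x[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

read_checked_csv <- function(path, required, character_cols = "code") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ## dotted menu codes must stay strings: "3.4" and "3.40" are distinct
  head <- utils::read.csv(path, nrows = 1, fileEncoding = "UTF-8-BOM",
                          comment.char = "#")
  cls <- stats::setNames(
    rep("character", sum(names(head) %in% character_cols)),
    intersect(names(head), character_cols))
  if (!length(cls)) cls <- NA
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", comment.char = "#",
                        colClasses = cls)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read an intervention catalog from CSV
#'
#' Expects columns \code{code,title} and optionally
#' \code{category,area,ce_tier}; column order is irrelevant and a UTF-8
#' byte-order mark is tolerated.
#'
#' @param path CSV file path.
#' @return an \code{"ncd_catalog"}.
#' @export
read_catalog_csv <- function(path)
  build_catalog(read_checked_csv(path, c("code", "title")))

#' Read a policy mention index from CSV
#' @param path CSV with columns \code{code,document_id,document_class}.
#' @return mentions data frame.
#' @export
read_mentions_csv <- function(path)
  read_checked_csv(path, c("code", "document_id", "document_class"))

#' Read inpatient claims records from CSV
#' @param path CSV with columns \code{icd10_code,admissions}.
#' @return claims data frame.
#' @export
read_claims_csv <- function(path) {
  df <- read_checked_csv(path, c("icd10_code", "admissions"))
  df$admissions <- as.numeric(df$admissions)
  df
}

#' Read a pairwise comparison matrix from CSV
#'
#' The header row carries the criterion labels; each of the following n
#' rows holds n judgments. Saaty-scale fractions such as \code{"1/3"}
#' are parsed exactly.
#'
#' @param path CSV file path.
#' @return a reciprocal comparison matrix with labelled dimensions.
#' @export
read_pairwise_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8-BOM", comment.char = "#",
                        check.names = FALSE, colClasses = "character")
  labels <- names(df)
  a <- apply(as.matrix(df), c(1, 2), function(v) parse_judgment(v))
  a <- matrix(as.numeric(a), nrow = nrow(df),
              dimnames = list(labels, labels))
  check_pairwise(a)
  a
}

#' Read an interventions-by-criteria matrix from CSV
#' @param path CSV whose first column is \code{code}, remaining columns
#'   one per criterion.
#' @return numeric matrix with codes as rownames.
#' @export
read_criteria_csv <- function(path) {
  df <- read_checked_csv(path, "code")
  m <- as.matrix(df[setdiff(names(df), "code")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$code)
  m
}

provenance_string <- function(seed, config) {
  sprintf("ncdprior %s | seed=%s | config=%s",
          as.character(utils::packageVersion("ncdprior")),
          as.character(seed), config_hash(config))
}

## deterministic FNV-1a 32-bit hash of the deparsed configuration
config_hash <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a ranking to CSV
#'
#' Writes rank, code, composite score and the per-criterion
#' contributions, preceded by a \code{#}-comment provenance header.
#'
#' @param fit an \code{"mcda"} object.
#' @param path output path.
#' @param provenance optional provenance string for the header.
#' @return \code{path}, invisibly.
#' @export
write_ranking_csv <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "mcda"))
  contrib <- fit$contributions[fit$ranking$code, , drop = FALSE]
  colnames(contrib) <- paste0("contrib_", colnames(contrib))
  df <- cbind(fit$ranking, as.data.frame(contrib, check.names = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full prioritization pipeline
#'
#' Executes the stages end to end: label the catalog against the
#' mention index, build the gap report, derive and consistency-check
#' the criterion weights, select the prioritizable subset for the
#' requested objective, assemble the criteria matrix (from a file or
#' the synthetic generator, with the hospitalization criterion computed
#' from claims), normalize, score and rank. Writes
#' \code{ranking.csv}, \code{gap_report.json}, \code{weights.json},
#' \code{consistency.json} and \code{log.txt} into \code{out_dir};
#' every file carries a provenance header. Re-running with an identical
#' configuration reproduces the outputs byte for byte. Partial outputs
#' are removed if any stage fails.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   optional entries \code{catalog}, \code{mentions}, \code{matrices}
#'   (character vector of pairwise CSV paths), \code{claims},
#'   \code{criteria} (file paths; packaged/synthetic defaults used when
#'   absent), \code{objective} (3 or 4, default 3), \code{method},
#'   \code{tiebreak}, \code{seed} (default 1), \code{out_dir}
#'   (required) and \code{allow_inconsistent} (default FALSE: the run
#'   fails when CR >= 0.1).
#' @return (invisibly) a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir))
  objective <- if (is.null(config$objective)) 3L else
    as.integer(config$objective)
  if (!(objective %in% c(3L, 4L)))
    stop("objective must be 3 or 4", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("ranking.csv", "gap_report.json",
                                "weights.json", "consistency.json",
                                "log.txt"))
  names(paths) <- c("ranking", "gap_report", "weights", "consistency",
                    "log")
  written <- character()
  stage <- "setup"
  result <- tryCatch({
    stage <- "catalog"
    catalog <- if (is.null(config$catalog)) who_ncd_catalog() else
      read_catalog_csv(config$catalog)

    stage <- "label"
    mentions <- if (is.null(config$mentions))
      iran_policy_mentions(catalog) else read_mentions_csv(config$mentions)
    labels <- label_interventions(catalog, mentions)

    stage <- "gap_report"
    gap <- gap_report(labels, catalog)

    stage <- "weights"
    matrices <- if (is.null(config$matrices)) {
      gen_expert_matrices(synth_config(seed = seed))
    } else {
      lapply(config$matrices, read_pairwise_csv)
    }
    method <- if (is.null(config$method)) "eigenvector" else config$method
    fit_w <- ahp(matrices, method = method)
    if (!fit_w$consistency$pass && !isTRUE(config$allow_inconsistent))
      stop(sprintf(
        "consistency ratio %.4f exceeds the 0.1 acceptability threshold",
        fit_w$consistency$cr), call. = FALSE)

    stage <- "filter"
    sub <- filter_prioritizable(catalog, objective = objective)

    stage <- "criteria"
    criteria <- if (!is.null(config$criteria)) {
      read_criteria_csv(config$criteria)
    } else {
      sc <- synth_config(seed = seed)
      m <- gen_criteria_matrix(sc, sub)
      if (!is.null(config$claims)) {
        summ <- aggregate_admissions(read_claims_csv(config$claims))
        m[, "hospitalization"] <- criterion4_scores(summ, sub)
      }
      m
    }

    stage <- "rank"
    ## user-supplied matrices may label criteria differently from the
    ## criteria columns; fall back to positional matching
    w <- coef(fit_w)
    if (!is.null(colnames(criteria)) &&
        !setequal(names(w), colnames(criteria))) {
      if (length(w) != ncol(criteria))
        stop("number of weights does not match the number of criteria",
             call. = FALSE)
      names(w) <- colnames(criteria)
    }
    fit_m <- mcda(criteria, w,
                  tiebreak = if (is.null(config$tiebreak)) NULL else
                    config$tiebreak)

    stage <- "write"
    prov_cfg <- config[setdiff(names(config), "out_dir")]
    prov <- provenance_string(seed, prov_cfg)
    write_ranking_csv(fit_m, paths[["ranking"]], provenance = prov)
    written <- c(written, paths[["ranking"]])
    wj <- function(x, p) {
      jsonlite::write_json(c(list(provenance = prov), x), p,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <<- c(written, p)
    }
    wj(list(by_label = as.list(gap$by_label),
            red_by_tier = as.list(gap$red_by_tier),
            red_codes = gap$red_items$code), paths[["gap_report"]])
    wj(list(method = fit_w$method, n_experts = fit_w$n_experts,
            weights = as.list(fit_w$weights)), paths[["weights"]])
    cons <- fit_w$consistency
    wj(list(lambda_max = cons$lambda_max, ci = cons$ci, ri = cons$ri,
            cr = cons$cr, pass = cons$pass), paths[["consistency"]])
    log_lines <- c(
      paste("#", prov),
      sprintf("labels: green=%d blue=%d red=%d",
              gap$by_label[["green"]], gap$by_label[["blue"]],
              gap$by_label[["red"]]),
      sprintf("consistency_ratio: %.6f (%s)", cons$cr,
              if (cons$pass) "pass" else "fail"),
      sprintf("objective: %d, interventions ranked: %d", objective,
              nrow(fit_m$ranking)),
      sprintf("top priority: %s", fit_m$ranking$code[1]))
    writeLines(log_lines, paths[["log"]])
    written <- c(written, paths[["log"]])

    list(catalog = catalog, labels = labels, gap = gap, ahp = fit_w,
         mcda = fit_m, paths = paths)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
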