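test_that("the packaged WHO menu has the documented structure", {
  cat <- who_ncd_catalog()
  expect_s3_class(cat, "ncd_catalog")
  expect_equal(nrow(cat), 105L)
  expect_equal(as.integer(table(cat$objective)), c(4L, 4L, 49L, 38L, 5L, 5L))
  expect_equal(sum(cat$category == "overarching_action"), 17L)
  expect_equal(sum(cat$category == "intervention"), 88L)
  expect_equal(sum(cat$category == "overarching_action" &
                     cat$objective == 3), 9L)
  expect_equal(sum(cat$category == "overarching_action" &
                     cat$objective == 4), 8L)
  ## objective parses from the code; tier not_applicable exactly for
  ## overarching actions and the non-quantifiable objectives
  expect_true(all(cat$objective ==
                    as.integer(sub("\\..*", "", cat$code))))
  na_expected <- cat$category == "overarching_action" |
    cat$objective %in% c(1, 2, 5, 6)
  expect_identical(cat$ce_tier == "not_applicable", na_expected)
})

test_that("build_catalog validates codes and handles edge inputs", {
  expect_equal(nrow(build_catalog(data.frame())), 0L)
  rows <- data.frame(code = c("3.4", "3.4"), title = c("a", "b"))
  expect_error(build_catalog(rows), "3\\.4")
  expect_error(build_catalog(data.frame(code = "34", title = "x")),
               "malformed")
  expect_error(build_catalog(data.frame(code = "3.x", title = "x")),
               "malformed")
  ## string codes never collate numerically: 3.4 and 3.40 coexist
  both <- build_catalog(data.frame(code = c("3.40", "3.4"),
                                   title = c("forty", "four")))
  expect_equal(both$code, c("3.4", "3.40"))
})

test_that("an objective-3-only catalog has 49 items, 40 interventions", {
  full <- who_ncd_catalog()
  o3 <- build_catalog(full[full$objective == 3,
                           c("code", "title", "category", "area",
                             "ce_tier")])
  expect_equal(nrow(o3), 49L)
  expect_equal(sum(o3$category == "intervention"), 40L)
})

test_that("labeling applies green > blue > red precedence", {
  cat <- build_catalog(data.frame(code = c("3.4", "3.5", "3.6"),
                                  title = letters[1:3]))
  mentions <- data.frame(
    code = c("3.4", "3.4", "3.5"),
    document_id = c("plan", "other", "other"),
    document_class = c("national_action_plan", "other_national_document",
                       "other_national_document"))
  lab <- label_interventions(cat, mentions)
  expect_equal(lab$label, c("green", "blue", "red"))
  ## zero mentions at all -> everything red; unknown code rejected
  lab0 <- label_interventions(cat, mentions[0, ])
  expect_true(all(lab0$label == "red"))
  expect_error(label_interventions(cat, data.frame(
    code = "9.9", document_id = "d",
    document_class = "national_action_plan")), "9\\.9")
})

test_that("labels partition the catalog and mentions only promote", {
  cat <- who_ncd_catalog()
  set.seed(42)
  for (rep in 1:20) {
    n_m <- sample(0:150, 1)
    mentions <- data.frame(
      code = sample(cat$code, n_m, replace = TRUE),
      document_id = "doc",
      document_class = sample(c("national_action_plan",
                                "other_national_document"),
                              n_m, replace = TRUE))
    lab <- label_interventions(cat, mentions)
    expect_equal(nrow(lab), nrow(cat))
    expect_equal(sum(table(lab$label)), nrow(cat))
    ## adding one more mention never demotes any label
    extra <- data.frame(code = sample(cat$code, 1), document_id = "new",
                        document_class = "other_national_document")
    lab2 <- label_interventions(cat, rbind(mentions, extra))
    rank_of <- c(red = 0, blue = 1, green = 2)
    expect_true(all(rank_of[lab2$label] >= rank_of[lab$label]))
  }
})

test_that("the reconstructed mention fixture reproduces the gap counts", {
  cat <- who_ncd_catalog()
  lab <- label_interventions(cat, iran_policy_mentions(cat))
  rep <- gap_report(lab, cat)
  expect_equal(rep$by_label[["red"]], 12L)
  expect_equal(rep$by_label[["green"]], 49L)
  expect_equal(sort(rep$red_items$code),
               sort(missed_intervention_codes()))
  ## missed-item tier breakdown: 4 overarching/enabling, 4 without CEA,
  ## 3 effective above I$100/DALY, 1 best buy
  expect_equal(rep$red_by_tier[["not_applicable"]], 4L)
  expect_equal(rep$red_by_tier[["no_cea"]], 4L)
  expect_equal(rep$red_by_tier[["effective_gt_100"]], 3L)
  expect_equal(rep$red_by_tier[["best_buy"]], 1L)
  ## 8 of the 12 missed items sit in objective 4 (> 65%)
  expect_equal(sum(rep$red_items$objective == 4), 8L)
  ## 3.9 is blue: mentioned, but not in the action plan
  expect_equal(lab$label[lab$code == "3.9"], "blue")
  ## red list is ordered by code
  ord <- order(rep$red_items$objective, rep$red_items$item)
  expect_equal(ord, seq_len(12L))
  expect_error(gap_report(lab[-1, ], cat), "missing label")
})

test_that("filter_prioritizable yields 40 + 30 and is idempotent", {
  cat <- who_ncd_catalog()
  o3 <- filter_prioritizable(cat, objective = 3)
  o4 <- filter_prioritizable(cat, objective = 4)
  expect_equal(nrow(o3), 40L)
  expect_equal(nrow(o4), 30L)
  expect_true(all(o3$category == "intervention"))
  expect_equal(o4$code, paste0("4.", 9:38))
  ## idempotent and order-preserving
  again <- filter_prioritizable(o3, objective = 3)
  expect_equal(again, o3)
  expect_false(is.unsorted(match(o3$code, cat$code)))
  ## empty exclusion set is the identity
  expect_equal(nrow(filter_prioritizable(cat, exclusions = character())),
               105L)
  expect_error(filter_prioritizable(cat, exclusions = "9.9"), "9\\.9")
})
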