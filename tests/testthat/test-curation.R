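passingRecord <- function() {
  data.frame(compound_id = "C1", molecular_mass = 900,
             activity_comment = "", activity_type = "IC50",
             relation = "=", standard_value = 50,
             target_relationship_type = "D", confidence_score = 9L,
             target_id = "T1", stringsAsFactors = FALSE)
}

test_that("one-violation-per-filter fixture is fully rejected with a clean audit", {
  base <- passingRecord()
  recs <- do.call(rbind, replicate(6, base, simplify = FALSE))
  recs$compound_id <- paste0("C", 1:6)
  recs$molecular_mass[1] <- 1100                 # mass
  recs$activity_comment[2] <- "inconclusive"     # comment
  recs$activity_type[3] <- "other"               # type
  recs$standard_value[4] <- 20000                # potency range
  recs$target_relationship_type[5] <- "H"        # relationship type
  recs$confidence_score[6] <- 8L                 # confidence
  out <- curateRecords(recs)
  expect_equal(nrow(out$survivors), 0)
  expect_equal(unname(out$audit[c("mass", "comment", "type", "potency_range",
                                  "relationship_type", "confidence")]),
               rep(1L, 6))
  expect_equal(unname(out$audit["relation"]), 0L)

  ## the all-pass record survives; a non-"=" relation does not
  expect_equal(nrow(curateRecords(passingRecord())$survivors), 1)
  gt <- passingRecord(); gt$relation <- ">"
  outGt <- curateRecords(gt)
  expect_equal(nrow(outGt$survivors), 0)
  expect_equal(unname(outGt$audit["relation"]), 1L)
})

test_that("survivor set matches ground truth and ignores record order", {
  rec <- generateActivityRecords(3, 80)
  out <- curateRecords(rec)
  expect_setequal(out$survivors$compound_id, rec$compound_id[rec$pass])

  perm <- withr::with_seed(9, sample(nrow(rec)))
  out2 <- curateRecords(rec[perm, ], curationConfig())
  expect_setequal(out2$survivors$compound_id, out$survivors$compound_id)
})

test_that("an all-permissive configuration keeps every record", {
  rec <- generateActivityRecords(4, 40)
  rec$pass <- NULL
  ## the categorical filters are equality tests, so permissiveness there
  ## means conforming values; the numeric filters are opened fully
  rec$relation <- "="
  rec$target_relationship_type <- "D"
  rec$confidence_score <- 9L
  out <- curateRecords(rec, curationConfig(maxMass = Inf,
                                           excludedComments = character(0),
                                           allowedTypes = unique(rec$activity_type),
                                           potencyMin = 1e-12, potencyMax = Inf))
  expect_equal(nrow(out$survivors), nrow(rec))
})

test_that("malformed and duplicate records are reported", {
  rec <- rbind(passingRecord(), passingRecord(), passingRecord())
  rec$compound_id <- c("C1", "C1", "C2")
  rec$standard_value[3] <- NA
  out <- curateRecords(rec)
  expect_equal(unname(out$audit["malformed"]), 1L)
  expect_equal(unname(out$audit["duplicate"]), 1L)
  expect_equal(out$survivors$compound_id, "C1")

  small <- passingRecord()
  expect_warning(curateRecords(small, curationConfig(minClassSize = 5),
                               dropSmallClasses = TRUE), "minClassSize")
  expect_error(curateRecords(data.frame()), "non-empty")
  expect_error(curateRecords(passingRecord()[, 1:3]), "required fields")
})

test_that("balanced dataset construction samples decoys reproducibly", {
  act <- generateFingerprints(syntheticConfig(nPerClass = 50, nFeatures = 32,
                                              seed = 1))
  actives <- act[, compoundLabels(act) == "active"]
  pool <- generateFingerprints(syntheticConfig(nPerClass = 250, nFeatures = 32,
                                               seed = 2))
  decoys <- pool[, compoundLabels(pool) == "inactive"]
  colnames(decoys) <- paste0("DEC", seq_len(ncol(decoys)))

  ds <- buildClassificationDataset(actives, decoys, seed = 5)
  expect_equal(ncol(ds), 100)
  expect_equal(as.integer(table(compoundLabels(ds))), c(50, 50))
  ds2 <- buildClassificationDataset(actives, decoys, seed = 5)
  expect_identical(compoundIds(ds), compoundIds(ds2))

  tooSmall <- decoys[, 1:49]
  expect_error(buildClassificationDataset(actives, tooSmall, 1), "smaller")
})
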