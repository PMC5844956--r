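writeLinesTmp <- function(lines) {
  f <- tempfile(fileext = ".1D")
  writeLines(lines, f)
  f
}

test_that("readMotionFile parses the 6-column convention", {
  f <- writeLinesTmp(c("# header comment",
                       "0 0 0 0 0 0",
                       "0.1 0.2 0.3 1.0 2.0 3.0",
                       "0 0 0 0 0 0"))
  tr <- readMotionFile(f, samplingInterval = 0.5)
  expect_equal(nFrames(tr), 3)
  expect_equal(unname(rotations(tr)[2, ]), c(0.1, 0.2, 0.3))
  expect_equal(unname(translations(tr)[2, ]), c(1.0, 2.0, 3.0))
  # translations-first flips the triplets
  tr2 <- readMotionFile(f, 0.5, columnOrder = "translations-first")
  expect_equal(unname(translations(tr2)[2, ]), c(0.1, 0.2, 0.3))
  # radians are converted to degrees
  tr3 <- readMotionFile(f, 0.5, rotationUnit = "radians")
  expect_equal(unname(rotations(tr3)[2, 1]), 0.1 * 180 / pi)
})

test_that("an all-zero 3-row file yields a 3-frame zero trace", {
  f <- writeLinesTmp(rep("0 0 0 0 0 0", 3))
  tr <- readMotionFile(f, 2)
  expect_equal(nFrames(tr), 3)
  expect_true(all(rotations(tr) == 0) && all(translations(tr) == 0))
})

test_that("malformed motion files raise format errors naming the row", {
  f <- writeLinesTmp(c("0 0 0 0 0 0", "1 2 3 4 5"))
  expect_error(readMotionFile(f, 1), "row 2", class = "formatError")
  f <- writeLinesTmp(c("0 0 0 0 0 0", "1 2 x 4 5 6"))
  expect_error(readMotionFile(f, 1), "row 2", class = "formatError")
  f <- writeLinesTmp("0 0 0 0 0 0")
  expect_error(readMotionFile(f, 1), class = "formatError")
})

test_that("motion file write/read round-trips losslessly", {
  tr <- generateMotionTrace(1.4, 50, 0.72, seed = 8, subjectId = "rt")
  f <- tempfile(fileext = ".1D")
  writeMotionFile(tr, f)
  back <- readMotionFile(f, samplingInterval = 0.72, subjectId = "rt")
  expect_equal(rotations(back), rotations(tr), tolerance = 1e-12)
  expect_equal(translations(back), translations(tr), tolerance = 1e-12)
})

test_that("readPhenotypes derives SR class from the 1 Hz threshold", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("SUB_ID,SITE_ID,DX_PRIMARY,DX_DSM_IV_TR,AGE_AT_SCAN,SEX,MEDICATION",
               "A1,SLOW,TD,none,12,M,no",
               "A2,FAST,ASD,ASD,14,F,",
               "A3,FAST,ASD,AS,16,M,yes"), f)
  ph <- readPhenotypes(f, c(SLOW = 2.0, FAST = 0.645))
  expect_equal(ph$SR_CLASS, c("SR0", "SR1", "SR1"))
  expect_equal(ph$MEDICATION[2], "unreported")
  expect_error(readPhenotypes(f, c(SLOW = 2.0)), class = "lookupError")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("SUB_ID,SITE_ID,AGE_AT_SCAN", "A1,S,12"), f2)
  expect_error(readPhenotypes(f2, c(S = 1)), class = "formatError")
})

test_that("selectGroup implements the labelled selections", {
  rec <- makeRecords(
    dxPrimary = c(rep("ASD", 14), rep("TD", 3)),
    dxDsm = c(rep("AS", 5), rep("PDD", 3), rep("PDDNOS", 2), rep("ASD", 4),
              rep("none", 3)),
    sex = c(rep("F", 7), rep("M", 10)),
    medication = c(rep("yes", 4), rep("no", 9), rep("unreported", 4)))
  expect_equal(nrow(selectGroup(rec, "ASMIX")), 10)  # DSM-IV ASD excluded
  expect_equal(nrow(selectGroup(rec, "AS")), 5)
  expect_equal(nrow(selectGroup(rec, "ASD_DSM")), 4)
  expect_equal(nrow(selectGroup(rec, "TD")), 3)
  expect_equal(nrow(selectGroup(rec, "FEM")), 7)     # regardless of diagnosis
  expect_equal(nrow(selectGroup(rec, "MALES")), 10)
  expect_equal(nrow(selectGroup(rec, "MEDS")), 4)
  expect_error(selectGroup(rec, "bogus"), class = "invalidParameterError")
})

test_that("MEDS and NoMEDS require reported medication", {
  rec <- makeRecords(rep("ASD", 4), rep("ASD", 4),
                     medication = rep("unreported", 4))
  expect_equal(nrow(selectGroup(rec, "NoMEDS")), 0)
  expect_equal(nrow(selectGroup(rec, "MEDS")), 0)
})

test_that("diagnosis groups are disjoint and selections never exceed input", {
  spec <- CohortSpec(list(cohortGroup("TD", 8), cohortGroup("ASD", 6),
                          cohortGroup("AS", 4)), nFrames = 40, seed = 2)
  ph <- generateCohort(spec)$phenotypes
  td <- selectGroup(ph, "TD")$SUB_ID
  dsm <- selectGroup(ph, "ASD_DSM")$SUB_ID
  as_ <- selectGroup(ph, "AS")$SUB_ID
  expect_length(intersect(td, c(dsm, as_)), 0)
  for (lab in c("TD", "ASD", "ASD_DSM", "AS", "ASMIX", "FEM", "MALES",
                "MEDS", "NoMEDS"))
    expect_lte(nrow(selectGroup(ph, lab)), nrow(ph))
})
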