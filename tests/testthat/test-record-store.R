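rec1 <- function(start, dur, stage = "deep", type = "Long", interval = 30) {
  data.frame(start = as.POSIXct(start, tz = "UTC"), duration_s = dur,
             interval_s = interval, stage = stage, type = type)
}

test_that("record expansion conserves duration on every grid", {
  # worked example: 1,200 s of deep sleep at 30 s epochs -> 40 entries
  ex <- expandRecord(rec1("2021-12-16 06:30:00", 1200), 30)
  expect_equal(nrow(ex), 40L)
  expect_true(all(ex$stage == "deep"))
  expect_equal(ex$time[1], as.POSIXct("2021-12-16 06:30:00", tz = "UTC"))
  expect_equal(ex$time[40], as.POSIXct("2021-12-16 06:49:30", tz = "UTC"))
  expect_equal(nrow(expandRecord(rec1("2021-12-16 06:30:00", 1200), 60)), 20L)
  expect_equal(nrow(expandRecord(rec1("2021-12-16 06:30:00", 30), 30)), 1L)
  # conservation property across random records
  set.seed(4)
  for (i in 1:20) {
    dur <- sample(1:40, 1) * 30
    iv <- sample(c(15, 30), 1)
    ex <- expandRecords(rec1("2021-12-16 06:30:00", dur), iv)
    expect_equal(nrow(ex), dur / iv)
  }
  expect_message(expandRecord(rec1("2021-12-16 06:30:00", 70), 30),
                 "truncating")
  expect_error(expandRecord(rec1("2021-12-16 06:30:00", 20), 30), "shorter")
})

test_that("short records win over long coverage when merging", {
  merged <- recordsToHypnogram(exampleOverlapRecords(), 30)
  expect_equal(nEpochs(merged), 4L)
  df <- as.data.frame(merged)
  expect_identical(df$stage, c("light", "light", "wake", "wake"))
  expect_equal(df$time[3], as.POSIXct("2021-12-16 06:38:00", tz = "UTC"))
  # no duplicates -> identity (re-sorted)
  ent <- expandRecords(rbind(rec1("2021-12-16 06:00:00", 120, "light"),
                             rec1("2021-12-16 06:02:00", 60, "wake")), 30)
  out <- mergeShortLong(ent[sample(nrow(ent)), ])
  expect_identical(as.character(stages(out)),
                   c("light", "light", "light", "light", "wake", "wake"))
  # idempotence: merging the merged entries changes nothing
  ent2 <- as.data.frame(out)
  ent2$type <- "Long"; ent2$interval_s <- 30
  again <- mergeShortLong(ent2)
  expect_identical(as.data.frame(again), as.data.frame(out))
  # conflicting Short stages error
  bad <- rbind(rec1("2021-12-16 06:00:00", 30, "wake", "Short"),
               rec1("2021-12-16 06:00:00", 30, "deep", "Short"))
  expect_error(mergeShortLong(expandRecords(bad, 30)), "conflicting Short")
})

test_that("timestamps floor onto the coarser grid keeping the earliest entry", {
  df <- data.frame(
    time = as.POSIXct("2021-12-16 06:00:00", tz = "UTC") + c(0, 30, 59, 60),
    v = 1:4)
  out <- floorAlign(df, 60)
  expect_equal(as.numeric(out$time),
               as.numeric(as.POSIXct("2021-12-16 06:00:00", tz = "UTC")) +
                 c(0, 60))
  expect_equal(out$v, c(1L, 4L))    # earliest entry per cell survives
  onGrid <- data.frame(time = as.POSIXct("2021-12-16 06:02:00", tz = "UTC"),
                       v = 9)
  expect_equal(floorAlign(onGrid, 60)$time, onGrid$time)
})

test_that("natural join intersects timestamps and unions columns", {
  t0 <- as.POSIXct("2021-12-16 06:00:00", tz = "UTC")
  sleep <- data.frame(time = t0 + 60 * (0:9), stage = rep("light", 10))
  act <- data.frame(time = t0 + 60 * (0:19), steps = 1:20)
  j <- naturalJoin(list(sleep, act), interval = 60)
  expect_equal(nrow(j), 10L)            # min(m, n) when timestamps nest
  expect_setequal(names(j), c("time", "stage", "steps"))
  disj <- data.frame(time = t0 + 60 * (100:104), hr = 1:5)
  expect_equal(nrow(naturalJoin(list(sleep, disj), interval = 60)), 0L)
  dup <- data.frame(time = t0, stage = "x")
  expect_error(naturalJoin(list(sleep, dup), interval = 60), "collision")
  # commutativity/associativity against a set-intersection oracle
  set.seed(8)
  for (i in 1:5) {
    a <- data.frame(time = t0 + 60 * sort(sample(0:30, 12)), a = rnorm(12))
    b <- data.frame(time = t0 + 60 * sort(sample(0:30, 15)), b = rnorm(15))
    c_ <- data.frame(time = t0 + 60 * sort(sample(0:30, 9)), c = rnorm(9))
    nAll <- length(Reduce(intersect, list(a$time, b$time, c_$time)))
    j1 <- naturalJoin(list(a, b, c_), interval = 60)
    j2 <- naturalJoin(list(c_, a, b), interval = 60)
    expect_equal(nrow(j1), nAll)
    expect_equal(j1[names(j2)], j2[order(j2$time), names(j2)],
                 ignore_attr = TRUE)
  }
})

test_that("null rows are dropped per a row-scan oracle", {
  df <- toyFeatureFrame(50)
  expect_identical(dropNullRows(df), df)
  set.seed(9)
  mask <- matrix(runif(50 * 3) < 0.1, 50, 3)
  for (j in 1:3) df[[j + 1]][mask[, j]] <- NA
  out <- suppressMessages(dropNullRows(df))
  expect_equal(nrow(out), sum(rowSums(mask) == 0))
  expect_false(anyNA(out))
})

test_that("instance schemas carry the published column inventory", {
  sc <- instanceSchema()
  expect_equal(length(sc$I1_act$featureNames), 14L)
  expect_equal(length(sc$I2_hr$featureNames), 16L)
  expect_equal(length(sc$I3_hrv$featureNames), 19L)
  expect_equal(length(sc$I4_temp$featureNames), 20L)
  expect_equal(length(sc$I5_spo2$featureNames), 21L)
  expect_equal(length(sc$AW$featureNames), 7L)
  expect_equal(sc$AW$interval, 30)
  expect_equal(sc$MESA$interval, 15)
  # nesting: each instance's columns contain its predecessor's
  nm <- c("I1_act", "I2_hr", "I3_hrv", "I4_temp", "I5_spo2")
  for (i in 2:5)
    expect_true(all(sc[[nm[i - 1]]]$featureNames %in% sc[[nm[i]]]$featureNames))

  t0 <- as.POSIXct("2021-12-16 06:00:00", tz = "UTC")
  full <- data.frame(time = t0 + 30 * (0:9), patientId = 1L,
                     steps = 0, circadian = 0, cosine = 1, hr = 60,
                     stage = "light")
  inst <- buildInstance(full, "AW")
  expect_s4_class(inst, "EpochTable")
  expect_equal(schemaId(inst), "AW")
  expect_equal(ncol(epochData(inst)) + 1L, 7L)  # time + 6 data columns
  expect_error(buildInstance(full[, -3], "AW"), "steps")
})
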