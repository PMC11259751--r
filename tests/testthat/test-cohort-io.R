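test_that("volumes declared in mL are normalized to mm^3 on input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,skull_len,cavity",
               "Chihuahua,88.7,0.32",
               "St Bernard,240.0,4.54"), path)
  ch <- read_cohort(path, schema = list(
    columns = c(specimen_id = "breed", cbl = "skull_len", v_cav = "cavity"),
    units = c(v_cav = "mL")
  ))
  expect_equal(ch$v_cav, c(320, 4540))
  expect_equal(ch$cbl, c(88.7, 240.0))
  expect_equal(ch$role, c("fit", "fit"))
})

test_that("unit normalization is idempotent across write/read cycles", {
  ch <- make_two_breed_cohort()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, p1)
  once <- read_cohort(p1, canonical_schema())
  write_cohort(once, p2)
  twice <- read_cohort(p2, canonical_schema())
  expect_cohorts_equal(once, twice)
})

test_that("write/read round trip reproduces randomized cohorts exactly", {
  for (seed in 1:5) {
    ch <- random_cohort(seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(ch, path)
    back <- read_cohort(path, canonical_schema())
    expect_cohorts_equal(back, ch)
  }
})

test_that("written files have one header row, one row per specimen, and NA sentinels only in missing cells", {
  ch <- cohort(data.frame(specimen_id = c("a", "b"), cbl = c(100, 200),
                          v_mal = c(10, NA)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  cells <- strsplit(lines, ",")
  header <- gsub('"', "", cells[[1]])
  expect_equal(cells[[2]][header == "v_mal"], "10")
  expect_equal(cells[[3]][header == "v_mal"], "NA")
  expect_false("NA" %in% cells[[2]][header %in% c("specimen_id", "cbl")])
})

test_that("schema and validation errors are raised with no partial cohort", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("breed,skull_len", empty)
  sch <- list(columns = c(specimen_id = "breed", cbl = "skull_len"))
  expect_error(read_cohort(empty, sch), "no data rows")

  expect_error(read_cohort("/nonexistent/file.csv", sch), "not found")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,x", "a,1"), miss)
  expect_error(
    read_cohort(miss, list(columns = c(specimen_id = "breed", cbl = "nope"))),
    "schema error")
  expect_error(
    read_cohort(miss, list(columns = c(specimen_id = "breed"))),
    "schema error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,skull_len", "a,100", "a,120"), dup)
  expect_error(read_cohort(dup, sch), "duplicate specimen_id")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,skull_len", "a,100", "b,-3"), neg)
  expect_error(read_cohort(neg, sch), "non-positive .*cbl.*row 2|non-positive")
})

test_that("unparseable cells become missing traits, not errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,skull_len,mal", "a,100,8.5", "b,200,damaged"), path)
  ch <- read_cohort(path, schema = list(
    columns = c(specimen_id = "breed", cbl = "skull_len", v_mal = "mal")))
  expect_equal(ch$v_mal, c(8.5, NA))
  expect_true("v_mal" %in% missing_traits(ch)[["b"]])
  expect_false("v_mal" %in% missing_traits(ch)[["a"]])
})

test_that("cohort invariants are enforced", {
  expect_error(cohort(data.frame(specimen_id = c("a", "a"), cbl = c(1, 2))),
               "duplicate")
  expect_error(cohort(data.frame(specimen_id = "a", cbl = -5)),
               "non-positive")
  expect_error(cohort(data.frame(specimen_id = "a", cbl = 100,
                                 a_tm = 1, a_fp = 2)),
               "exceed")
  expect_error(cohort(data.frame(specimen_id = "a", cbl = 100,
                                 role = "held_out")),
               "invalid role")
  expect_error(cohort(data.frame(specimen_id = "a", cbl = 100,
                                 nonsense = 1)),
               "unknown cohort columns")
})

test_that("role assignments from schema mark projected specimens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,skull_len", "beagle,150", "wolf,250"), path)
  ch <- read_cohort(path, schema = list(
    columns = c(specimen_id = "breed", cbl = "skull_len"),
    roles = c(wolf = "projected")))
  expect_equal(ch$role, c("fit", "projected"))
  expect_equal(fit_specimens(ch)$specimen_id, "beagle")
})

test_that("YAML config files produce usable schemas", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("columns:",
               "  specimen_id: breed",
               "  cbl: skull_len",
               "  v_cav: cavity",
               "units:",
               "  v_cav: mL",
               "roles:",
               "  wolf: projected"), cfg)
  sch <- read_cohort_config(cfg)
  expect_equal(unname(sch$columns["v_cav"]), "cavity")
  expect_equal(unname(sch$units["v_cav"]), "mL")
  expect_equal(unname(sch$roles["wolf"]), "projected")
})
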