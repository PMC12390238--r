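test_that("packaged chronic toxicity table reads into 12 validated records", {
  tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
  expect_s3_class(tox, "toxicity_records")
  expect_identical(nrow(tox), 12L)
  expect_identical(nrow(row_errors(tox)), 0L)
  xl <- tox[tox$species == "Xenopus laevis", ]
  expect_equal(xl$concentration, 23)
  expect_equal(xl$duration, 84)
  expect_setequal(unique(tox$group),
                  c("algae", "crustaceans", "insects", "molluscs",
                    "amphibians", "fish"))
})

test_that("rows with non-positive or unparseable concentrations are rejected with a report", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,group,endpoint,concentration,duration",
               "A a,fish,NOEC,0,30",
               "B b,fish,NOEC,abc,30",
               "C c,fish,NOEC,10,30"), path)
  expect_warning(tox <- read_toxicity_table(path), "rejected")
  expect_identical(nrow(tox), 1L)
  errs <- row_errors(tox)
  expect_identical(errs$row, c(1L, 2L))
  expect_match(errs$problem, "concentration")
})

test_that("toxicity table survives a write-then-read round trip", {
  tox <- read_toxicity_table(ssdrisk_example("bpa_toxicity"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_toxicity_table(tox, path)
  back <- read_toxicity_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tox))
})

test_that("column-mapping dialect ingests foreign headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("latin_name,taxon,ep,conc_ugL,days",
               "Danio rerio,fish,NOEC,1500,21"), path)
  tox <- read_toxicity_table(path, dialect = list(
    species = "latin_name", group = "taxon", endpoint = "ep",
    concentration = "conc_ugL", duration = "days"))
  expect_identical(tox$species, "Danio rerio")
  expect_equal(tox$concentration, 1500)
  # missing a required mapped column is a configuration error
  expect_error(read_toxicity_table(path), class = "ssdrisk_error_config")
})

test_that("empty toxicity table raises an explicit empty-input error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,group,endpoint,concentration,duration", path)
  expect_error(read_toxicity_table(path), class = "ssdrisk_error_empty")
})

test_that("concentration table converts ng/L to ug/L and handles ND and '/' tokens", {
  conc <- read_concentration_table(ssdrisk_example("concentrations"))
  expect_identical(length(unique(conc$site_id)), 32L)
  liuxi <- conc[conc$location == "Liuxi River" & conc$chemical == "BPS", ]
  expect_equal(liuxi$conc_mean, 3.72)   # 3720 ng/L
  expect_equal(liuxi$conc_max, 65.6)    # 65,600 ng/L
  nd <- conc[!conc$detected & !conc$missing_data, ]
  expect_identical(nrow(nd), 5L) # four BPF sites and one BPS site
  expect_true(all(nd$conc_mean == 0 & nd$conc_max == 0))
  expect_true(all(nd$chemical %in% c("BPF", "BPS")))
  lanzhou_bpf <- conc[grepl("Lanzhou", conc$location) & conc$chemical == "BPF", ]
  expect_true(lanzhou_bpf$missing_data)
  expect_true(is.na(lanzhou_bpf$conc_mean))
})

test_that("concentration table round trip preserves values, ND and '/' markers", {
  conc <- read_concentration_table(ssdrisk_example("concentrations"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(conc, path)
  back <- read_concentration_table(path)
  expect_equal(as.data.frame(back), as.data.frame(conc))
})

test_that("empty concentration file raises an empty-input error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("location,sampling_year,chemical,conc_min,conc_max,conc_mean", path)
  expect_error(read_concentration_table(path), class = "ssdrisk_error_empty")
})

test_that("occurrence summary reproduces the packaged extremes", {
  conc <- read_concentration_table(ssdrisk_example("concentrations"))
  bpa <- summarize_occurrence(conc, "BPA")
  expect_equal(bpa$max_of_maxes, 7.48)              # 7480 ng/L
  expect_equal(bpa$mean_min, 0.00838)               # 8.38 ng/L
  expect_equal(bpa$mean_max, 0.922)                 # 922 ng/L
  bps <- summarize_occurrence(conc, "BPS")
  expect_equal(bps$max_of_maxes, 65.6)              # 65,600 ng/L
  expect_equal(bps$mean_min, 0)                     # ND site contributes 0
  expect_error(summarize_occurrence(conc, "XYZ"), class = "ssdrisk_error_empty")
})

test_that("occurrence summary bounds every individual record", {
  conc <- read_concentration_table(ssdrisk_example("concentrations"))
  for (chem in c("BPA", "BPS", "BPF")) {
    s <- summarize_occurrence(conc, chem)
    x <- conc[conc$chemical == chem & !conc$missing_data, ]
    expect_true(all(x$conc_min >= s$min_of_mins))
    expect_true(all(x$conc_max <= s$max_of_maxes))
    expect_true(all(x$conc_mean >= s$mean_min & x$conc_mean <= s$mean_max))
  }
})

test_that("summary of a single record collapses to that record", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,sampling_year,chemical,conc_min,conc_max,conc_mean",
               "Site,2020,X,5,5,5"), path)
  s <- summarize_occurrence(read_concentration_table(path), "X")
  expect_equal(unlist(s[c("min_of_mins", "max_of_maxes", "mean_min", "mean_max")],
                      use.names = FALSE),
               rep(0.005, 4)) # 5 ng/L = 0.005 ug/L
})

test_that("ng/L to ug/L conversion round trips to machine precision", {
  x <- c(0.016, 8.38, 922, 65600, 7480)
  expect_identical(x * 1e-3 * 1e3, x)
})

test_that("chemical registry validates uniqueness and positive weights", {
  chem <- read_chemical_table(ssdrisk_example("chemicals"))
  expect_identical(chem$abbreviation, c("BPA", "BPS", "BPF"))
  expect_true(all(chem$molecular_weight > 0))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,abbreviation,cas_number,molecular_weight",
               "A,X,1-1-1,100", "B,X,2-2-2,200"), path)
  expect_error(read_chemical_table(path), class = "ssdrisk_error_config")
})
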