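test_that("write/read round-trips a synthetic survey exactly", {
  p <- random_params(2)
  sv <- generate_survey(p, 300, seed = 7)
  f <- tempfile(fileext = ".csv")
  write_survey(sv, f)
  rd <- read_survey(f, vaw_codebook(p$covariate_spec))
  expect_equal(unclass(rd$responses)[, ], unname(sv$responses),
               ignore_attr = TRUE)
  expect_identical(unname(rd$covariates$X), unname(sv$X))
  expect_equal(unname(rd$assets), unname(sv$assets), ignore_attr = TRUE)
  expect_true(file.exists(paste0(f, ".truth.yaml")))
  side <- yaml::read_yaml(paste0(f, ".truth.yaml"))
  expect_equal(side$seed, 7)
  unlink(c(f, paste0(f, ".truth.yaml")))
})

test_that("invalid item codes and missing columns are fatal with location", {
  p <- random_params(2)
  sv <- generate_survey(p, 20, seed = 1)
  f <- tempfile(fileext = ".csv")
  df <- data.frame(sv$responses, sv$covariates_raw, check.names = FALSE)
  df$item04[3] <- 2
  write.csv(df, f, row.names = FALSE)
  expect_error(read_survey(f, vaw_codebook(p$covariate_spec)),
               "item04.*row 3")
  df$item04[3] <- 1
  names(df)[names(df) == "item09"] <- "oddname"
  write.csv(df, f, row.names = FALSE)
  expect_error(read_survey(f, vaw_codebook(p$covariate_spec)), "item09")
  # ... unless a column mapping translates it
  rd <- read_survey(f, vaw_codebook(p$covariate_spec),
                    mapping = c(item09 = "oddname"))
  expect_equal(ncol(rd$responses), 15)
  unlink(f)
})

test_that("missing values fail by default and drop listwise on request", {
  p <- random_params(2)
  sv <- generate_survey(p, 20, seed = 2)
  f <- tempfile(fileext = ".csv")
  df <- data.frame(sv$responses, sv$covariates_raw, check.names = FALSE)
  df$item01[5] <- NA
  write.csv(df, f, row.names = FALSE)
  expect_error(read_survey(f, vaw_codebook(p$covariate_spec)), "row 5")
  rd <- read_survey(f, vaw_codebook(p$covariate_spec), on_missing = "drop")
  expect_equal(nrow(rd$responses), 19)
  unlink(f)
})

test_that("dummy coding follows the codebook reference categories", {
  spec <- vaw_covariate_spec()
  expect_equal(length(spec$ethnicity$levels), 7)
  raw <- data.frame(lapply(spec, function(cv) cv$levels[1]),
                    stringsAsFactors = FALSE)
  names(raw) <- names(spec)
  raw <- raw[rep(1, 3), , drop = FALSE]
  raw$ethnicity <- c("Somali", "Luo", "Kamba")
  X <- dummy_code(raw, spec)
  eth_cols <- grep("^ethnicity:", colnames(X), value = TRUE)
  expect_equal(length(eth_cols), 6)            # 7 categories -> 6 dummies
  expect_false("ethnicity:Somali" %in% colnames(X))
  expect_equal(unname(X[, "ethnicity:Luo"]), c(0, 1, 0))
  expect_equal(sum(X[1, eth_cols]), 0)         # reference row all zero
  # dummy column count = sum(k_c - 1)
  expect_equal(ncol(X), sum(vapply(spec, function(cv)
    length(cv$levels) - 1L, integer(1))))
  # unknown label is fatal with the row index
  raw$religion[2] <- "unheard-of"
  expect_error(dummy_code(raw, spec), "unheard-of.*row 2")
})

test_that("write_results emits CSVs plus a manifest and rejects empty input", {
  d <- tempfile(); dir.create(d)
  tabs <- list(loadings = data.frame(item = 1:15, f1 = 0, f2 = 0, f3 = 0),
               fit = data.frame(index = "CFI", value = 1))
  man <- write_results(tabs, d, meta = list(seed = 1))
  expect_equal(length(man$files), 2)
  expect_true(all(file.exists(man$files)))
  expect_true(file.exists(file.path(d, "manifest.json")))
  got <- read.csv(file.path(d, "loadings.csv"))
  expect_equal(dim(got), c(15, 4))
  expect_error(write_results(list(), d), "no result tables")
  unlink(d, recursive = TRUE)
})
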