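#' Run the full analysis pipeline
#'
#' Orchestrates the stages descriptives -> tetrachoric -> ESEM -> covariate
#' screen -> Bayesian MIMIC -> report over either a simulated survey (a
#' preset name, n and seed) or a survey CSV readable by [read_survey()].
#' Every stochastic stage is seeded, so a configuration reruns to identical
#' outputs.
#'
#' @param config list (or YAML file path) with either `simulate = list(preset,
#'   n, seed)` or `input = <csv path>` (exactly one), optional `stages`
#'   (character subset of `c("descriptives", "tetrachoric", "esem",
#'   "screen", "mimic")`), `out_dir`, `seed`, `n_factors`, and `mimic`
#'   (arguments for [mimic_config()]).
#' @return Manifest list (also written as `manifest.json` in `out_dir`);
#'   component `results` holds the in-memory stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate); has_inp <- !is.null(config$input)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulate' or 'input'")
  stages <- config$stages
  if (is.null(stages))
    stages <- c("descriptives", "tetrachoric", "esem", "screen", "mimic")
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_factors <- if (is.null(config$n_factors)) 3 else config$n_factors

  if (has_sim) {
    sim <- config$simulate
    if (is.null(sim$seed)) stop("simulate block requires a seed")
    preset <- if (is.null(sim$preset)) "dreams" else sim$preset
    params <- vaw_preset(preset)
    survey <- generate_survey(params, sim$n, seed = sim$seed)
    responses <- item_response_matrix(survey$responses)
    covariates <- structure(list(X = survey$X, raw = survey$covariates_raw,
                                 codebook = params$covariate_spec),
                            class = "covariate_design")
    assets <- survey$assets
  } else {
    rd <- read_survey(config$input)
    responses <- rd$responses; covariates <- rd$covariates
    assets <- rd$assets
  }

  res <- list()
  tables <- list()
  if ("descriptives" %in% stages) {
    res$prevalence <- item_prevalence(responses)
    res$acts <- acts_distribution(responses)
    tables$item_prevalence <- res$prevalence
    tables$acts_cumulative <- res$acts$cumulative
    if (!is.null(covariates))
      tables$sample_summary <- summarize_sample(covariates)
    if (!is.null(assets)) {
      res$wealth <- wealth_index(assets)
      tables$wealth_terciles <-
        data.frame(tercile = c("poor", "medium", "wealthy"),
                   count = as.integer(table(factor(res$wealth$tercile,
                                                   levels = 1:3))))
    }
  }
  tet <- NULL
  if (any(c("tetrachoric", "esem") %in% stages)) {
    tet <- tetrachoric_matrix(responses)
    res$tetrachoric <- tet
    tables$tetrachoric_rho <- as.data.frame(tet$rho)
  }
  if ("esem" %in% stages) {
    res$esem <- esem(tet, n_factors = n_factors, seed = seed)
    L <- res$esem$Lambda_rotated
    colnames(L) <- c("psychological", "physical",
                     "sexual")[seq_len(ncol(L))]
    tables$esem_loadings <- data.frame(
      item = seq_len(nrow(L)), label = vaw_item_labels(),
      round(L, 4),
      major = c("psychological", "physical",
                "sexual")[apply(abs(L), 1, which.max)])
    tables$esem_fit <- data.frame(
      index = c("CFI", "TLI", "RMSEA", "RMSEA_lo90", "RMSEA_hi90", "WRMR"),
      value = c(res$esem$fit$CFI, res$esem$fit$TLI, res$esem$fit$RMSEA,
                res$esem$fit$RMSEA_CI[1], res$esem$fit$RMSEA_CI[2],
                res$esem$fit$WRMR))
  }
  screen <- NULL
  if ("screen" %in% stages && !is.null(covariates)) {
    screen <- run_screen(responses, covariates)
    res$screen <- screen
    tables$screen_stage1_p <- data.frame(item = rownames(screen$stage1_p),
                                         screen$stage1_p,
                                         check.names = FALSE)
  }
  if ("mimic" %in% stages && !is.null(covariates)) {
    margs <- config$mimic
    if (is.null(margs)) margs <- list()
    cfg <- do.call(mimic_config, margs)
    dm <- if (!is.null(screen)) screen else NULL
    fit <- mimic_fit(responses, covariates, dm, cfg, seed = seed)
    res$mimic <- fit
    summ <- mimic_standardize(fit, force = !isFALSE(config$force))
    res$mimic_summary <- summ
    tables$mimic_factor_effects <- summ$factor_effects
    if (!is.null(summ$direct_effects))
      tables$mimic_direct_effects <- summ$direct_effects
    tables$mimic_loadings <- summ$loadings
    tables$mimic_fit <- data.frame(index = c("PPP", "max_PSR"),
                                   value = c(summ$ppp, summ$psr_max))
  }
  manifest <- write_results(tables, out_dir,
                            meta = list(seed = seed, stages = stages,
                                        source = if (has_sim) "simulate"
                                                 else config$input))
  manifest$results <- res
  invisible(manifest)
}

#' Compare a pipeline bundle against reference values
#'
#' @param manifest manifest from [run_pipeline()] (or a path to a bundle
#'   directory containing `manifest.json`).
#' @param reference data.frame with columns `table`, `row`, `column`,
#'   `expected`, `tolerance` — each row checks one cell of one output table
#'   (CSV name without extension; `row` is the row number).
#' @return data.frame with one row per check: `value`, `expected`,
#'   `tolerance`, `pass` (FALSE with NA value when the artifact is missing).
#' @export
compare_to_reference <- function(manifest, reference) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(file.path(manifest, "manifest.json"),
                                    simplifyVector = TRUE)
  if (nrow(reference) == 0)
    return(data.frame(table = character(0), row = integer(0),
                      column = character(0), value = numeric(0),
                      expected = numeric(0), tolerance = numeric(0),
                      pass = logical(0)))
  files <- manifest$files
  names(files) <- sub("\\.csv$", "", basename(files))
  out <- reference
  out$value <- NA_real_; out$pass <- FALSE
  for (i in seq_len(nrow(reference))) {
    f <- files[reference$table[i]]
    if (is.na(f) || !file.exists(f)) next
    tb <- read.csv(f, check.names = FALSE)
    val <- tb[reference$row[i], reference$column[i]]
    if (is.null(val) || length(val) != 1 || is.na(suppressWarnings(as.numeric(val))))
      next
    out$value[i] <- as.numeric(val)
    out$pass[i] <- abs(out$value[i] - reference$expected[i]) <=
      reference$tolerance[i]
  }
  out
}
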