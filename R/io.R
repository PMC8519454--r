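#' Default codebook for the survey table
#'
#' Describes the expected CSV layout: 15 binary item columns item01..item15
#' and the 11 categorical covariates with their category labels and
#' reference categories. A user-editable mapping (YAML) can rename columns
#' of an externally deposited file onto this layout.
#'
#' @param covariate_spec covariate specification.
#' @return List with `items` (column names), `item_labels`, `domain_map`
#'   and `covariates` (the specification).
#' @export
vaw_codebook <- function(covariate_spec = vaw_covariate_spec()) {
  list(items = sprintf("item%02d", 1:15),
       item_labels = vaw_item_labels(),
       domain_map = vaw_domain_map(),
       covariates = covariate_spec)
}

#' Write a synthetic survey to CSV (with a YAML truth sidecar)
#'
#' @param survey `synthetic_survey`.
#' @param path CSV output path; a sidecar `<path>.truth.yaml` records the
#'   generating parameters and seed.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  df <- data.frame(survey$responses, survey$covariates_raw, survey$assets,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  truth <- survey$truth
  side <- list(seed = survey$seed,
               nu = as.numeric(truth$nu),
               Lambda = apply(truth$Lambda, 1, as.numeric, simplify = FALSE),
               A_nonzero = {
                 nz <- which(truth$A != 0, arr.ind = TRUE)
                 lapply(seq_len(nrow(nz)), function(i)
                   list(item = unname(nz[i, 1]),
                        column = colnames(truth$A)[nz[i, 2]],
                        value = truth$A[nz[i, 1], nz[i, 2]]))
               },
               B = apply(truth$B, 1, as.numeric, simplify = FALSE),
               Psi = apply(truth$Psi, 1, as.numeric, simplify = FALSE))
  yaml::write_yaml(side, paste0(path, ".truth.yaml"))
  invisible(path)
}

#' Read and validate a respondent-level survey CSV
#'
#' Single entry point for synthetic and external data. Item columns must be
#' coded 0/1; covariate categories must match the codebook. An optional
#' column mapping renames external column names onto the codebook layout
#' before validation.
#'
#' @param path CSV file with a header row.
#' @param codebook as from [vaw_codebook()].
#' @param mapping optional named character vector or YAML file path mapping
#'   codebook names to the file's column names.
#' @param on_missing `"fail"` (default) or `"drop"` (listwise deletion).
#' @return List with `responses` (class `item_response_matrix`: n x 15
#'   binary matrix with `item_labels`/`domain_map` attributes),
#'   `covariates` (class `covariate_design`: list of `X`, `raw`,
#'   `codebook`), and `assets` (matrix or NULL).
#' @export
read_survey <- function(path, codebook = vaw_codebook(),
                        mapping = NULL, on_missing = c("fail", "drop")) {
  on_missing <- match.arg(on_missing)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
    mapping <- unlist(yaml::read_yaml(mapping))
  if (!is.null(mapping))
    for (nm in names(mapping))
      names(df)[names(df) == mapping[[nm]]] <- nm
  miss <- setdiff(codebook$items, names(df))
  if (length(miss) > 0)
    stop("missing item column(s): ", paste(miss, collapse = ", "))
  need <- c(codebook$items, names(codebook$covariates))
  have <- intersect(need, names(df))
  any_na <- rowSums(is.na(df[have])) > 0
  if (any(any_na)) {
    if (on_missing == "fail")
      stop("missing values in ", sum(any_na), " row(s); first at row ",
           which(any_na)[1])
    df <- df[!any_na, , drop = FALSE]
  }
  Y <- as.matrix(df[codebook$items])
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(Y))
    stop("item value out of {0,1} in column ", codebook$items[rc[2]],
         " at row ", rc[1])
  }
  storage.mode(Y) <- "integer"
  responses <- item_response_matrix(Y, codebook)
  covs <- intersect(names(codebook$covariates), names(df))
  covariates <- NULL
  if (length(covs) == length(codebook$covariates)) {
    raw <- df[covs]
    X <- dummy_code(raw, codebook$covariates)
    covariates <- structure(list(X = X, raw = raw,
                                 codebook = codebook$covariates),
                            class = "covariate_design")
  }
  acols <- grep("^asset[0-9]+$", names(df), value = TRUE)
  assets <- if (length(acols) > 0) as.matrix(df[acols]) else NULL
  list(responses = responses, covariates = covariates, assets = assets)
}

#' Construct an item-response matrix container
#'
#' @param Y n x 15 binary matrix.
#' @param codebook codebook (for labels and the WHO domain map).
#' @return `item_response_matrix` (a matrix with attributes).
#' @export
item_response_matrix <- function(Y, codebook = vaw_codebook()) {
  Y <- as.matrix(Y)
  if (ncol(Y) != length(codebook$items))
    stop("expected ", length(codebook$items), " item columns, got ", ncol(Y))
  if (length(Y) > 0 && !all(Y %in% c(0L, 1L)))
    stop("item responses must be 0/1")
  colnames(Y) <- codebook$items
  structure(Y, item_labels = codebook$item_labels,
            domain_map = codebook$domain_map,
            class = c("item_response_matrix", class(Y)))
}

#' Write result tables plus a run manifest
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param meta named list of run metadata (seed, config, ...) stored in the
#'   manifest.
#' @return Manifest (list), invisibly; written as `manifest.json`.
#' @export
write_results <- function(tables, out_dir, meta = list()) {
  if (length(tables) == 0) stop("no result tables to write")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(files = files,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   meta = meta)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
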