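# Dataset reading/validation and the end-to-end pipeline.

#' Schema of a surveillance dataset
#'
#' Declares the columns a CSV must contain: the binary response, the wave
#' (time) column, and each covariate's admissible levels with the reference
#' level first. A schema can be written by hand or derived from a generator
#' configuration.
#'
#' @param response Response column name.
#' @param modifier Wave/time column name.
#' @param covariates Named list of character vectors of levels (reference
#'   first).
#' @param n_waves Optional wave count; wave values are validated against
#'   `[1, n_waves]` when given.
#' @return A list of class `"brfs_schema"`.
#' @export
brfs_schema <- function(response = "smoker", modifier = "wave",
                        covariates, n_waves = NULL) {
  stopifnot(is.list(covariates), length(names(covariates)) ==
              length(covariates))
  structure(list(response = response, modifier = modifier,
                 covariates = lapply(covariates, as.character),
                 n_waves = n_waves),
            class = "brfs_schema")
}

#' @describeIn brfs_schema Derive the schema from a [brfs_config()].
#' @param config A [brfs_config()].
#' @export
schema_from_config <- function(config) {
  stopifnot(inherits(config, "brfs_config"))
  brfs_schema(covariates = lapply(config$covariates, names),
              n_waves = config$n_waves)
}

#' Read and validate a surveillance dataset
#'
#' Reads a long-format CSV (one row per respondent), checks it against a
#' [brfs_schema()] — required columns present, categorical values among the
#' declared levels, wave indices in range — applies listwise deletion of
#' rows with missing values (count reported), and returns a typed data frame
#' with factors ordered reference-level-first.
#'
#' @param path CSV file path (or a data frame, validated in place).
#' @param schema A [brfs_schema()].
#' @return Validated data frame with the schema in `attr(, "schema")`.
#' @export
read_brfs <- function(path, schema) {
  stopifnot(inherits(schema, "brfs_schema"))
  d <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema$response, schema$modifier, names(schema$covariates))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema error: column(s) missing: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(d[need])
  if (!all(cc)) {
    message("listwise deletion: dropped ", sum(!cc), " of ", length(cc),
            " rows with missing values")
    d <- d[cc, , drop = FALSE]
  }
  for (v in names(schema$covariates)) {
    lev <- schema$covariates[[v]]
    x <- as.character(d[[v]])
    bad <- unique(x[!x %in% lev])
    if (length(bad))
      stop("schema error: unknown level(s) for '", v, "': ",
           paste(bad, collapse = ", "))
    d[[v]] <- factor(x, levels = lev)
  }
  w <- d[[schema$modifier]]
  if (!is.numeric(w)) stop("schema error: modifier column must be numeric")
  if (!is.null(schema$n_waves) &&
      (any(w < 1) || any(w > schema$n_waves)))
    stop("schema error: wave indices outside [1, ", schema$n_waves, "]")
  y <- d[[schema$response]]
  if (!all(y %in% c(0, 1)))
    stop("schema error: response must be coded 0/1")
  attr(d, "schema") <- schema
  d
}

read_run_config <- function(path) {
  if (is.list(path) && !is.character(path)) return(path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML run configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

config_stamp <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full surveillance trend analysis pipeline
#'
#' Reads (or accepts) a dataset, screens every covariate for time-varying
#' coefficients, forward-selects the varying terms, and writes the artifacts:
#' `screening.csv`, `selection_trace.csv`, `selection_trace.json`,
#' `model_summary.csv` (constant ORs with intervals plus smooth-term rows)
#' and one `or_curve_*.csv` per non-reference level of each selected varying
#' covariate, all stamped with a configuration hash and the seed. Any stage
#' failure stops with a stage-labelled message.
#'
#' @param config A list (or path to a JSON/YAML file) with elements:
#'   `data` (CSV path or data frame), `schema` (list with `response`,
#'   `modifier`, `covariates`, optional `n_waves`), and optional `k`,
#'   `degree`, `penalty_order`, `alpha`, `lambda_method`, `seed`, `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the screening table, selection object,
#'   final fit, summary and the paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% "trendvcm_output"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  k <- cfg$k %||% 55
  degree <- cfg$degree %||% 3
  penalty_order <- cfg$penalty_order %||% 2
  alpha <- cfg$alpha %||% 0.05
  method <- cfg$lambda_method %||% "gcv"
  seed <- cfg$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  schema <- stage("read", {
    sc <- cfg$schema
    brfs_schema(response = sc$response %||% "smoker",
                modifier = sc$modifier %||% "wave",
                covariates = sc$covariates, n_waves = sc$n_waves)
  })
  data <- stage("read", read_brfs(cfg$data, schema))
  fml <- stats::reformulate(names(schema$covariates), schema$response)
  set.seed(seed)
  screen <- stage("screen",
    screen_varying(fml, data, schema$modifier, alpha = alpha, k = k,
                   degree = degree, penalty_order = penalty_order,
                   method = method))
  sel <- stage("select",
    forward_select(fml, data, schema$modifier, screen = screen,
                   alpha = alpha, k = k, degree = degree,
                   penalty_order = penalty_order, method = method))
  fit <- sel$fit
  sm <- summary(fit)
  stamp <- data.frame(config_hash = config_stamp(cfg[setdiff(names(cfg),
                                                             "data")]),
                      seed = seed)
  paths <- c(screening = file.path(out_dir, "screening.csv"),
             trace = file.path(out_dir, "selection_trace.csv"),
             trace_json = file.path(out_dir, "selection_trace.json"),
             summary = file.path(out_dir, "model_summary.csv"),
             run_info = file.path(out_dir, "run_info.json"))
  stage("write", {
    utils::write.csv(cbind(as.data.frame(screen), stamp),
                     paths["screening"], row.names = FALSE)
    utils::write.csv(cbind(sel$trace, stamp), paths["trace"],
                     row.names = FALSE)
    jsonlite::write_json(
      list(trace = sel$trace, varying = sel$varying,
           varying_intercept = sel$varying_intercept,
           config_hash = stamp$config_hash, seed = seed),
      paths["trace_json"], auto_unbox = TRUE, digits = NA)
    const <- sm$constant
    const$term_type <- "constant"
    out_tab <- const
    if (!is.null(sm$smooth)) {
      smr <- sm$smooth
      tab2 <- data.frame(variable = smr$term, level = "",
                         estimate = NA, se = NA, lower = NA, upper = NA,
                         p_value = smr$p_value, or = NA, or_lower = NA,
                         or_upper = NA, term_type = "smooth",
                         stringsAsFactors = FALSE)
      tab2$edf <- smr$edf
      out_tab$edf <- NA
      out_tab <- rbind(out_tab, tab2[names(out_tab)])
    }
    utils::write.csv(cbind(out_tab, stamp), paths["summary"],
                     row.names = FALSE)
    jsonlite::write_json(list(config_hash = stamp$config_hash, seed = seed,
                              n = nrow(data), k = k, degree = degree,
                              penalty_order = penalty_order, alpha = alpha,
                              lambda_method = method),
                         paths["run_info"], auto_unbox = TRUE, digits = NA)
  })
  or_files <- stage("orplot",
    if (length(fit$spec$varying)) write_or_curves(fit, out_dir)
    else character(0))
  invisible(list(screen = screen, selection = sel, fit = fit, summary = sm,
                 paths = c(as.list(paths), list(or_curves = or_files))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
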