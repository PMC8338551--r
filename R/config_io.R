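#' @title Configuration input/output
#' @description Read and write model configurations as YAML or JSON documents
#'   with a stable canonical form, so serialized fixtures round-trip exactly.
#' @name config_io
NULL

config_to_list <- function(config) {
  par_list <- lapply(unname(config$parameters), function(p) {
    out <- list(name = p$name, mean = p$mean)
    if (!is.na(p$ci_low)) out$ci_low <- p$ci_low
    if (!is.na(p$ci_high)) out$ci_high <- p$ci_high
    out$dist <- p$dist
    out$units <- p$units
    out
  })
  strat_list <- lapply(config$strategies, function(s) {
    list(
      name = s$name,
      p_plx = s$p_plx,
      e_with_plx = s$e_with_plx,
      e_without_plx = s$e_without_plx,
      cost_items = lapply(s$cost_items, function(it) {
        list(label = it$label, category = it$category, payer = it$payer,
             quantity_factors = as.list(it$quantity_factors),
             unit_cost = it$unit_cost)
      })
    )
  })
  list(schema_version = config$schema_version,
       currency_year = config$currency_year,
       demographics = config$demographics,
       wages = config$wages,
       parameters = par_list,
       strategies = strat_list)
}

config_from_list <- function(x) {
  req <- c("schema_version", "currency_year", "demographics", "wages",
           "parameters", "strategies")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    stop("configuration document is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- lapply(x$parameters, function(p) {
    if (is.null(p$name) || is.null(p$mean) || is.null(p$dist)) {
      stop("parameter entry missing one of name/mean/dist", call. = FALSE)
    }
    uncertain_quantity(p$name, p$mean,
                       ci_low = if (is.null(p$ci_low)) NA_real_ else p$ci_low,
                       ci_high = if (is.null(p$ci_high)) NA_real_ else p$ci_high,
                       dist = p$dist,
                       units = if (is.null(p$units)) "" else p$units)
  })
  names(params) <- vapply(params, function(p) p$name, character(1))
  strategies <- lapply(x$strategies, function(s) {
    for (f in c("name", "p_plx", "e_with_plx", "e_without_plx")) {
      if (is.null(s[[f]])) stop("strategy missing required field '", f, "'",
                                call. = FALSE)
    }
    items <- lapply(s$cost_items, function(it) {
      cost_item(it$label, it$category, it$payer,
                quantity_factors = unlist(it$quantity_factors),
                unit_cost = it$unit_cost)
    })
    strategy_definition(s$name, items, s$p_plx, s$e_with_plx, s$e_without_plx)
  })
  # canonicalize scalar types (JSON/YAML parse whole numbers as integers)
  demo <- x$demographics
  for (f in c("employed_fraction", "retirement_age")) {
    if (!is.null(demo[[f]])) demo[[f]] <- as.numeric(demo[[f]])
  }
  wages <- lapply(x$wages, as.numeric)
  cfg <- model_config(strategies, params, demo, wages,
                      currency_year = x$currency_year,
                      schema_version = x$schema_version)
  viol <- validate_config(cfg)
  unresolved <- grep("unresolved parameter reference", viol, value = TRUE)
  if (length(unresolved)) stop(paste(unresolved, collapse = "\n"), call. = FALSE)
  cfg
}

#' Load a model configuration from a YAML or JSON document
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file, or a
#'   single string containing the document itself.
#' @param format `"auto"` (from file extension, YAML otherwise), `"yaml"` or
#'   `"json"`.
#' @return a validated [model_config()] object.
#' @seealso [save_config()], [validate_config()]
#' @export
load_config <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  is_file <- length(path) == 1L && !grepl("\n", path) && file.exists(path)
  if (format == "auto") {
    format <- if (is_file && grepl("\\.json$", path, ignore.case = TRUE)) {
      "json"
    } else if (!is_file && grepl("^\\s*\\{", path)) "json" else "yaml"
  }
  raw <- if (is_file) paste(readLines(path, warn = FALSE), collapse = "\n") else path
  x <- if (format == "json") {
    jsonlite::fromJSON(raw, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(raw)
  }
  config_from_list(x)
}

#' Save a model configuration
#'
#' Writes the canonical serialized form of a configuration. Canonicalization is
#' deterministic: saving, loading and saving again yields byte-identical text.
#'
#' @param config a [model_config()] object.
#' @param path output file path; if `NULL`, the document is returned as a
#'   string instead of written.
#' @param format `"yaml"` (default) or `"json"`.
#' @return invisibly, the serialized document text.
#' @export
save_config <- function(config, path = NULL, format = c("yaml", "json")) {
  format <- match.arg(format)
  x <- config_to_list(config)
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), pretty = TRUE))
  } else {
    yaml::as.yaml(x, precision = 15L)
  }
  if (!is.null(path)) writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Digest of a canonicalized configuration
#'
#' MD5 digest of the canonical YAML serialization; it changes iff the
#' canonicalized configuration changes. Used in run manifests.
#'
#' @param config a [model_config()] object.
#' @return a 32-character hex string.
#' @export
config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(save_config(config), tf, sep = "")
  unname(tools::md5sum(tf))
}
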