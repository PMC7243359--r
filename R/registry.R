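#' @title Model registry
#' @description Loads the shipped population-PK model catalogue (YAML) and
#'   resolves models by drug name; user-supplied catalogues and in-session
#'   registration (e.g. a local cefotaxime model) are supported.
#' @name registry
NULL

.icudose_env <- new.env(parent = emptyenv())

catalogue_path <- function() {
  system.file("extdata", "models.yaml", package = "icudose", mustWork = TRUE)
}

model_from_catalogue_entry <- function(drug, entry) {
  pk_model(
    drug = drug,
    n_compartments = entry$n_compartments,
    typical = entry$typical,
    covariate_model = entry$covariate_model %||% list(),
    iiv = entry$iiv %||% list(),
    residual_error = entry$residual_error,
    source_id = entry$source_id %||% "",
    source = entry$source %||% "",
    baseline_interval_h = entry$baseline_interval_h %||% 12,
    max_daily_frequency = entry$max_daily_frequency %||% 6L
  )
}

#' Read a model catalogue from YAML
#'
#' @param path Path to a YAML catalogue (one document, one entry per drug).
#'   Defaults to the catalogue shipped with the package.
#' @return Named list of [pk_model()] objects.
#' @export
read_model_catalogue <- function(path = NULL) {
  path <- path %||% catalogue_path()
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(d) model_from_catalogue_entry(d, raw[[d]]))
  names(out) <- tolower(names(raw))
  out
}

registry <- function() {
  if (is.null(.icudose_env$registry))
    .icudose_env$registry <- read_model_catalogue()
  .icudose_env$registry
}

#' Register a user-supplied model
#'
#' Adds (or replaces) a model in the in-session registry, e.g. a locally
#' developed cefotaxime model.
#'
#' @param model A [pk_model()].
#' @return The model, invisibly.
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "pk_model"))
  reg <- registry()
  reg[[model$drug]] <- model
  .icudose_env$registry <- reg
  invisible(model)
}

#' Look up a model by drug name
#'
#' @param drug_name Drug name; matching is case-insensitive.
#' @return A [pk_model()].
#' @export
get_model <- function(drug_name) {
  reg <- registry()
  key <- tolower(trimws(drug_name))
  if (!key %in% names(reg))
    stop("unknown drug '", drug_name, "'; registered models: ",
         paste(sort(names(reg)), collapse = ", "), call. = FALSE)
  reg[[key]]
}

#' List registered drug names
#' @return Character vector of drug names.
#' @export
list_models <- function() sort(names(registry()))
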