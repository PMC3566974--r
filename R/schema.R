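#' Define a canonical clinical variable
#'
#' A variable specification fixes the canonical name, measurement kind and
#' admissible values of one clinical sign, symptom or observation item, plus
#' the ordered list of proxy variables that may stand in for it when it was
#' not recorded (e.g. respiratory distress for dyspnea).
#'
#' @param canonical_name Variable identifier, unique within a schema.
#' @param kind One of `"binary"` (coded 0/1), `"numeric"` or `"ordinal"`.
#' @param units Measurement units for numeric variables (e.g. `"degC"`,
#'   `"bpm"`); `NA` for binary variables.
#' @param range Length-2 numeric `c(lo, hi)` for numeric variables.
#' @param allowed_values Admissible codes for ordinal variables.
#' @param proxy_candidates Ordered character vector of canonical names tried,
#'   in order, when the variable itself is absent.
#' @return A list of class `variable_spec`.
#' @export
variable_spec <- function(canonical_name, kind = c("binary", "numeric", "ordinal"),
                          units = NA_character_, range = NULL,
                          allowed_values = NULL, proxy_candidates = character()) {
  kind <- match.arg(kind)
  stopifnot(is.character(canonical_name), length(canonical_name) == 1L, nzchar(canonical_name))
  if (kind == "numeric") {
    if (is.null(range) || length(range) != 2L || range[1] > range[2])
      stop("numeric variable '", canonical_name, "' needs range = c(lo, hi)", call. = FALSE)
    if (is.na(units)) stop("numeric variable '", canonical_name, "' must carry units", call. = FALSE)
  }
  if (kind == "binary" && is.null(allowed_values)) allowed_values <- c(0, 1)
  if (canonical_name %in% proxy_candidates)
    stop("variable '", canonical_name, "' cannot proxy itself", call. = FALSE)
  structure(list(canonical_name = canonical_name, kind = kind, units = units,
                 range = range, allowed_values = allowed_values,
                 proxy_candidates = as.character(proxy_candidates)),
            class = "variable_spec")
}

#' Default canonical schema for pediatric serious-infection datasets
#'
#' Covers every variable referenced by the six supported rules and guidelines:
#' the five-stage decision tree (clinician instinct, dyspnea, temperature,
#' diarrhea), the pneumonia rule (shortness of breath, clinician concern), the
#' meningitis rule (petechiae, nuchal rigidity, coma), the six Yale
#' Observation Scale items (each scored 1/3/5), the NHG alarm symptoms and a
#' reconstructed NICE traffic-light feature set, plus heart and respiratory
#' rate as representative vital signs with realistic missingness.
#'
#' Proxy chains follow common recording practice: clinical sick impression
#' stands in for the clinician's gut feeling, respiratory distress / chest
#' flaring / nasal flaring for dyspnea and shortness of breath, meningeal
#' irritation and nuchal rigidity for one another, and unconsciousness for
#' coma and reduced consciousness. Resolution is single-step (never
#' recursive), so the mutual meningeal pair is well defined.
#'
#' @return A named list of [variable_spec()] objects, class `cpr_schema`.
#' @export
default_schema <- function() {
  b <- function(name, proxies = character()) variable_spec(name, "binary", proxy_candidates = proxies)
  specs <- list(
    variable_spec("temperature", "numeric", units = "degC", range = c(34, 43)),
    variable_spec("heart_rate", "numeric", units = "bpm", range = c(40, 260)),
    variable_spec("resp_rate", "numeric", units = "breaths/min", range = c(10, 140)),
    b("clinician_instinct", c("sick_impression")),
    b("sick_impression"),
    b("dyspnea", c("respiratory_distress", "chest_flaring")),
    b("respiratory_distress"),
    b("chest_flaring"),
    b("shortness_of_breath", c("dyspnea", "respiratory_distress", "chest_flaring", "nasal_flaring")),
    b("nasal_flaring"),
    b("clinician_concern", c("clinician_instinct", "sick_impression")),
    b("diarrhea"),
    b("petechiae"),
    b("nuchal_rigidity", c("meningeal_irritation")),
    b("meningeal_irritation", c("nuchal_rigidity")),
    b("coma", c("unconsciousness")),
    b("unconsciousness"),
    b("seriously_ill_impression", c("sick_impression", "clinician_instinct")),
    b("reduced_consciousness", c("unconsciousness", "coma")),
    b("persistent_vomiting"),
    b("tachypnea", c("dyspnea")),
    b("reduced_peripheral_circulation"),
    b("pallor"),
    b("mottled_skin"),
    b("grunting"),
    b("reduced_activity"),
    b("poor_feeding")
  )
  yos <- c("yos_cry", "yos_reaction_to_parent", "yos_state_variation",
           "yos_color", "yos_hydration", "yos_social_response")
  specs <- c(specs, lapply(yos, function(v)
    variable_spec(v, "ordinal", allowed_values = c(1, 3, 5))))
  names(specs) <- vapply(specs, `[[`, character(1), "canonical_name")
  validate_schema(structure(specs, class = "cpr_schema"))
}

#' @keywords internal
validate_schema <- function(schema) {
  nms <- vapply(schema, `[[`, character(1), "canonical_name")
  if (anyDuplicated(nms)) stop("duplicate canonical names in schema", call. = FALSE)
  for (sp in schema) {
    bad <- setdiff(sp$proxy_candidates, nms)
    if (length(bad))
      stop("proxy candidates of '", sp$canonical_name, "' not in schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  schema
}

#' Outcome column names of the serious-infection composite
#'
#' The composite outcome is defined as sepsis (including bacteremia),
#' meningitis, pneumonia, osteomyelitis, cellulitis or complicated
#' urinary-tract infection; `serious_infection` is true iff any component is.
#'
#' @return Character vector of component outcome names.
#' @export
outcome_components <- function() {
  c("sepsis", "meningitis", "pneumonia", "osteomyelitis", "cellulitis",
    "complicated_uti")
}

#' Read or write a schema as YAML
#'
#' @param schema A `cpr_schema` object.
#' @param path File path.
#' @return `read_schema_yaml()` returns a `cpr_schema`; `write_schema_yaml()`
#'   returns `path` invisibly.
#' @export
write_schema_yaml <- function(schema, path) {
  out <- lapply(unname(schema), function(sp) {
    x <- sp[!vapply(sp, is.null, logical(1))]
    class(x) <- NULL
    x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(x)
    variable_spec(x$canonical_name, x$kind,
                  units = x$units %||% NA_character_,
                  range = if (!is.null(x$range)) as.numeric(x$range),
                  allowed_values = if (!is.null(x$allowed_values)) as.numeric(x$allowed_values),
                  proxy_candidates = x$proxy_candidates %||% character()))
  names(specs) <- vapply(specs, `[[`, character(1), "canonical_name")
  validate_schema(structure(specs, class = "cpr_schema"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
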