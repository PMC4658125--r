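#' Metadata templates
#'
#' Templates define the metadata fields attached to each box, with optional
#' validation: mandatory flags, drop-down choice lists and value parsers
#' ("an integer value greater than zero", "a latitude", "a longitude",
#' "a date in the form YYYY-MM-DD", or an arbitrary regular expression).
#' Templates are written in YAML in `.inselect_template` files with top-level
#' keys `name`, `thumbnail_width`, `crop_filename` and `fields`.
#'
#' @name templates
NULL

PARSERS <- c("free-text", "integer-gt-zero", "latitude", "longitude",
             "date-ymd", "regex")

new_template <- function(name, fields, thumbnail_width = 4096L,
                         crop_filename = character()) {
  structure(list(name = name, thumbnail_width = as.integer(thumbnail_width),
                 crop_filename = as.character(crop_filename), fields = fields),
            class = "template_spec")
}

#' @export
print.template_spec <- function(x, ...) {
  cat(sprintf("<template_spec> '%s': %d fields (%d mandatory), thumbnail width %d\n",
              x$name, nrow(x$fields), sum(x$fields$mandatory), x$thumbnail_width))
  invisible(x)
}

regex_compiles <- function(pattern) {
  !inherits(tryCatch(grepl(pattern, "", perl = TRUE), error = identity,
                     warning = identity), c("error", "warning"))
}

#' Parse a metadata template from YAML text
#'
#' @param text A character scalar of YAML (or a vector of lines).
#' @return A `template_spec`: name, thumbnail width, crop-filename field
#'   pattern, and a tibble of field specifications (`name`, `mandatory`,
#'   `choices` list-column, `parser`, `pattern`).
#' @export
parse_template <- function(text) {
  raw <- tryCatch(yaml::yaml.load(paste(text, collapse = "\n")),
                  error = function(e) stop_format(paste0("malformed YAML: ", conditionMessage(e))))
  if (!is.list(raw)) stop_schema("template must be a YAML mapping")
  known <- c("name", "thumbnail_width", "crop_filename", "fields")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_schema(sprintf("unknown template key: '%s'", unknown[1]))
  if (is.null(raw$name) || !nzchar(raw$name)) stop_schema("template key 'name' is required")
  if (is.null(raw$fields) || !length(raw$fields)) stop_schema("template key 'fields' is required")
  tw <- raw$thumbnail_width %||% 4096L
  if (!is_count(tw)) stop_schema("'thumbnail_width' must be a positive integer")
  fields <- bind_rows(map(raw$fields, parse_field_spec))
  if (anyDuplicated(fields$name))
    stop_schema(sprintf("duplicate field name: '%s'", fields$name[duplicated(fields$name)][1]))
  crop <- as.character(unlist(raw$crop_filename) %||% character())
  bad <- setdiff(crop, fields$name)
  if (length(bad))
    stop_schema(sprintf("'crop_filename' names an unknown field: '%s'", bad[1]))
  new_template(raw$name, fields, thumbnail_width = as.integer(tw), crop_filename = crop)
}

parse_field_spec <- function(f) {
  if (is.character(f)) f <- list(name = f)
  known <- c("name", "mandatory", "choices", "parser", "pattern")
  unknown <- setdiff(names(f), known)
  if (length(unknown)) stop_schema(sprintf("unknown field key: '%s'", unknown[1]))
  if (is.null(f$name) || !nzchar(f$name)) stop_schema("every field needs a non-empty 'name'")
  parser <- f$parser %||% "free-text"
  if (!parser %in% PARSERS)
    stop_schema(sprintf("field '%s': unknown parser '%s'", f$name, parser))
  pattern <- f$pattern %||% NA_character_
  if (parser == "regex") {
    if (is.na(pattern))
      abort(sprintf("field '%s': parser 'regex' requires a 'pattern'", f$name),
            class = "drawerseg_pattern_error")
    if (!regex_compiles(pattern))
      abort(sprintf("field '%s': pattern does not compile", f$name),
            class = "drawerseg_pattern_error")
  } else if (!is.na(pattern)) {
    abort(sprintf("field '%s': 'pattern' is only allowed with parser 'regex'", f$name),
          class = "drawerseg_pattern_error")
  }
  tibble(name = f$name, mandatory = isTRUE(f$mandatory),
         choices = list(as.character(unlist(f$choices) %||% character())),
         parser = parser, pattern = pattern)
}

#' @rdname parse_template
#' @param path Path to a `.inselect_template` file.
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("template not found: %s", path))
  parse_template(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Render a template back to YAML
#'
#' `parse_template(render_template(spec))` is the identity.
#'
#' @param spec A `template_spec`.
#' @return A YAML string.
#' @export
render_template <- function(spec) {
  fields <- pmap(spec$fields, function(name, mandatory, choices, parser, pattern) {
    f <- list(name = name)
    if (mandatory) f$mandatory <- TRUE
    if (length(choices)) f$choices <- as.list(choices)
    if (parser != "free-text") f$parser <- parser
    if (!is.na(pattern)) f$pattern <- pattern
    f
  })
  payload <- list(name = spec$name, thumbnail_width = spec$thumbnail_width)
  if (length(spec$crop_filename)) payload$crop_filename <- as.list(spec$crop_filename)
  payload$fields <- fields
  yaml::as.yaml(payload)
}

#' @rdname render_template
#' @param path Output path.
#' @export
write_template <- function(spec, path) {
  writeLines(render_template(spec), path, useBytes = TRUE)
  invisible(path)
}

#' Validate one metadata value against a field specification
#'
#' Checks, in order: a missing value on a mandatory field
#' (`missing-mandatory`); membership of the choice list when one is set
#' (`not-in-choices`); and the field's parser (`parse-failure`). Regular
#' expressions are matched against the full string even when the pattern
#' carries no anchors, so a rule like nine digits admits no leading or
#' trailing whitespace. An empty value on an optional field is always valid.
#'
#' @param value A character scalar (or `NA`/`NULL` for absent).
#' @param field A one-row field spec (a row of `template$fields`).
#' @return `NA_character_` when valid, else the violation reason.
#' @export
validate_value <- function(value, field) {
  if (is.data.frame(field)) field <- as.list(field[1, ])
  if (is.list(field$choices)) field$choices <- field$choices[[1]]
  value <- if (is.null(value) || length(value) == 0L) NA_character_ else as.character(value)[1]
  if (is.na(value) || !nzchar(value))
    return(if (isTRUE(field$mandatory)) "missing-mandatory" else NA_character_)
  if (length(field$choices) && !value %in% field$choices) return("not-in-choices")
  ok <- switch(
    field$parser,
    "free-text" = TRUE,
    "integer-gt-zero" = grepl("^[0-9]+$", value) && as.numeric(value) > 0,
    "latitude" = is_decimal(value) && abs(as.numeric(value)) <= 90,
    "longitude" = is_decimal(value) && abs(as.numeric(value)) <= 180,
    "date-ymd" = is_valid_ymd(value),
    "regex" = grepl(paste0("^(?:", field$pattern, ")$"), value, perl = TRUE),
    stop_param(sprintf("unknown parser '%s'", field$parser))
  )
  if (ok) NA_character_ else "parse-failure"
}

is_decimal <- function(value) grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$", value)

is_valid_ymd <- function(value) {
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value)) return(FALSE)
  d <- as.Date(value, format = "%Y-%m-%d")
  !is.na(d) && format(d, "%Y-%m-%d") == value
}

#' Validate a box's metadata against a template
#'
#' Aggregates [validate_value()] over every template field; metadata keys not
#' present in the template are reported as `unknown-field` violations so a
#' template/document mismatch surfaces in batch runs rather than passing
#' silently.
#'
#' @param fields A named character vector of the box's metadata.
#' @param template A `template_spec`.
#' @return A `validation_report`: list with `ok` flag and a `violations`
#'   tibble (`field`, `reason`). `ok` is `TRUE` iff there are no violations.
#' @export
validate_box <- function(fields, template) {
  stopifnot(inherits(template, "template_spec"))
  fields <- fields %||% stats::setNames(character(), character())
  reasons <- map_chr(seq_len(nrow(template$fields)), function(i) {
    nm <- template$fields$name[i]
    val <- if (nm %in% names(fields)) fields[[nm]] else NA_character_
    validate_value(val, template$fields[i, ])
  })
  viol <- tibble(field = template$fields$name, reason = reasons) |>
    filter(!is.na(.data$reason))
  extra <- setdiff(names(fields), template$fields$name)
  if (length(extra))
    viol <- bind_rows(viol, tibble(field = extra, reason = "unknown-field"))
  structure(list(ok = nrow(viol) == 0L, violations = viol),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("<validation_report> ok\n")
  else {
    cat(sprintf("<validation_report> %d violation(s):\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' The built-in Simple Darwin Core template
#'
#' A template whose fields are the Simple Darwin Core terms (the flat
#' biodiversity metadata vocabulary: catalogNumber, scientificName, ...),
#' all optional free-text. The term list is vendored with the package so
#' builds need no network access. Addressable by the reserved name
#' `dwc-simple` via [get_template()].
#'
#' @return A `template_spec`.
#' @export
default_darwin_core_template <- function() {
  path <- system.file("extdata", "dwc_simple_terms.txt", package = "drawerseg",
                      mustWork = TRUE)
  terms <- readLines(path, warn = FALSE)
  terms <- terms[!grepl("^\\s*(#|$)", terms)]
  fields <- tibble(name = terms, mandatory = FALSE,
                   choices = rep(list(character()), length(terms)),
                   parser = "free-text", pattern = NA_character_)
  new_template("dwc-simple", fields, crop_filename = "catalogNumber")
}

#' Resolve a template by name or path
#'
#' The reserved name `dwc-simple` returns the built-in Simple Darwin Core
#' template; anything else is read as a `.inselect_template` file.
#'
#' @param name_or_path Template name or file path.
#' @return A `template_spec`.
#' @export
get_template <- function(name_or_path) {
  if (identical(name_or_path, "dwc-simple")) return(default_darwin_core_template())
  read_template(name_or_path)
}
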