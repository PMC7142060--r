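# Attribute validation against a fixed, documented subset of JSON Schema.
#
# Supported: `type` (object at the top level; string / number / integer /
# boolean per property), `properties`, `required`, `enum`, `minimum`,
# `maximum`, on flat (non-nested) objects. Any other keyword is an
# explicit "unsupported keyword" rejection, so a schema is either fully
# enforced or refused — never partially honoured.

supported_top_keywords <- c("type", "properties", "required")
supported_prop_keywords <- c("type", "enum", "minimum", "maximum")
supported_prop_types <- c("string", "number", "integer", "boolean")

#' Check that a schema lies within the supported subset
#'
#' @param schema a schema document (named list, as parsed from JSON).
#' @return invisibly `TRUE`; otherwise an error naming the unsupported
#'   keyword.
#' @export
check_schema <- function(schema) {
  stopifnot(is.list(schema))
  extra <- setdiff(names(schema), supported_top_keywords)
  if (length(extra) > 0L) {
    stop("unsupported keyword in schema: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(schema$type) && !identical(schema$type, "object")) {
    stop("unsupported keyword value: top-level type must be \"object\"",
         call. = FALSE)
  }
  for (prop in names(schema$properties)) {
    p <- schema$properties[[prop]]
    extra <- setdiff(names(p), supported_prop_keywords)
    if (length(extra) > 0L) {
      stop("unsupported keyword in property \"", prop, "\": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (!is.null(p$type) && !(p$type %in% supported_prop_types)) {
      stop("unsupported keyword value: property \"", prop, "\" type \"",
           p$type, "\"", call. = FALSE)
    }
  }
  if (!is.null(schema$required) && !is.character(unlist(schema$required))) {
    stop("`required` must be an array of property names", call. = FALSE)
  }
  invisible(TRUE)
}

violation <- function(field, rule, message) {
  data.frame(field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

type_ok <- function(value, type) {
  switch(type,
         string = is.character(value) && length(value) == 1L,
         number = is.numeric(value) && length(value) == 1L,
         integer = is.numeric(value) && length(value) == 1L &&
           value == round(value),
         boolean = is.logical(value) && length(value) == 1L,
         FALSE)
}

#' Validate an attribute document against a schema
#'
#' Deterministic, order-independent over document keys: the same document
#' and schema always yield the same violations, one record per failing
#' constraint. An empty schema accepts any document. Properties present in
#' the document but absent from the schema are allowed (additional
#' properties are not constrained in the supported subset).
#'
#' @param doc named list: the attribute document.
#' @param schema a schema document within the supported subset (checked
#'   via [check_schema()] first; an out-of-subset schema is an error, not
#'   a validation failure).
#' @return a list with `ok` (logical) and `violations` (data.frame with
#'   columns field, rule, message; zero rows when ok).
#' @export
validate_attributes <- function(doc, schema) {
  check_schema(schema)
  if (is.null(doc)) doc <- list()
  stopifnot(is.list(doc))
  v <- list()

  for (field in as.character(unlist(schema$required))) {
    if (!(field %in% names(doc))) {
      v[[length(v) + 1L]] <- violation(
        field, "required", paste0("missing required property \"", field, "\""))
    }
  }

  for (field in sort(intersect(names(doc), names(schema$properties)))) {
    p <- schema$properties[[field]]
    value <- doc[[field]]
    if (!is.null(p$type) && !type_ok(value, p$type)) {
      v[[length(v) + 1L]] <- violation(
        field, "type",
        paste0("property \"", field, "\" is not of type ", p$type))
      next
    }
    if (!is.null(p$enum)) {
      allowed <- unlist(p$enum)
      if (!(as.character(value) %in% as.character(allowed))) {
        v[[length(v) + 1L]] <- violation(
          field, "enum",
          paste0("property \"", field, "\" value ", deparse(value),
                 " not in {", paste(allowed, collapse = ", "), "}"))
      }
    }
    if (!is.null(p$minimum) && is.numeric(value) && value < p$minimum) {
      v[[length(v) + 1L]] <- violation(
        field, "minimum",
        paste0("property \"", field, "\" = ", value, " below minimum ",
               p$minimum))
    }
    if (!is.null(p$maximum) && is.numeric(value) && value > p$maximum) {
      v[[length(v) + 1L]] <- violation(
        field, "maximum",
        paste0("property \"", field, "\" = ", value, " above maximum ",
               p$maximum))
    }
  }

  violations <- if (length(v) > 0L) do.call(rbind, v) else
    violation(character(0), character(0), character(0))
  list(ok = nrow(violations) == 0L, violations = violations)
}
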