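#' The default broiler ethogram
#'
#' The behaviour vocabulary used throughout the package: thirteen behaviours,
#' each identified by a short case-sensitive acronym. Acronyms are the
#' canonical identifiers everywhere (bout tables, sequence databases, mined
#' patterns, reports); full names are display-only. The registry row order is
#' the canonical behaviour ordering used for deterministic output downstream.
#'
#' One behaviour, exploring enrichment objects (`Ex`), can only occur in an
#' enriched environment (perch, sandbox, hanging rings) and is flagged
#' `enriched_only`.
#'
#' @return An object of class `ethogram`: a data frame with columns
#'   `acronym`, `name`, `description` and `enriched_only` (logical), one row
#'   per behaviour.
#' @examples
#' eth <- load_default_ethogram()
#' nrow(eth)                      # 13
#' eth$acronym[eth$enriched_only] # "Ex"
#' @export
load_default_ethogram <- function() {
  entries <- data.frame(
    acronym = c("Ld", "P", "F", "W", "Db", "Wf", "Sf", "E", "D", "R",
                "St", "Ll", "Ex"),
    name = c("Lying down", "Preening", "Forage", "Walk", "Dust bathing",
             "Wing flap", "Shake feathers", "Eat", "Drink", "Run",
             "Stretching", "Lying laterally", "Explore"),
    description = c(
      "Resting with the ventral body on the litter, knees folded, eyes open or closed.",
      "Pecking or scratching at its own feathers, seated or standing.",
      "Neck extended, pecking at the litter substrate, seated or standing.",
      "Taking at least two steps without pecking at the ground.",
      "Lying on the litter tossing substrate over back and wings, ruffling and shaking.",
      "Repeated flapping of the wings.",
      "Ruffling and shaking the feathers of the whole body.",
      "Head inside the feeder, including small movements around its rim.",
      "Beak in contact with the drinker, including small movements around it.",
      "Leg-propelled locomotion clearly faster than walking.",
      "Extending one or both wings or legs and returning to the resting posture.",
      "Lying on one side with a leg and/or wing extended.",
      "Interacting with enrichment objects (pecking the perch, sandbox or hanging rings)."
    ),
    enriched_only = c(rep(FALSE, 12), TRUE),
    stringsAsFactors = FALSE
  )
  structure(entries, class = c("ethogram", "data.frame"))
}

#' Canonical behaviour ordering
#'
#' @param ethogram An [load_default_ethogram()] registry.
#' @return Character vector of acronyms in canonical (registry row) order.
#' @export
ethogram_codes <- function(ethogram = load_default_ethogram()) {
  ethogram$acronym
}

#' Validate a behaviour code against an ethogram
#'
#' Checks that `code` is a registered acronym and that it is permitted in the
#' stated environment: behaviours flagged `enriched_only` are rejected when
#' `enriched = FALSE`.
#'
#' @param code A single behaviour acronym (case-sensitive).
#' @param ethogram Behaviour registry; defaults to [load_default_ethogram()].
#' @param enriched Logical; is the environment enriched?
#' @return The validated code, invisibly identical to `code`.
#' @examples
#' validate_code("Ld", enriched = FALSE)
#' validate_code("Ex", enriched = TRUE)
#' \dontrun{
#' validate_code("Ex", enriched = FALSE) # environment violation
#' }
#' @export
validate_code <- function(code, ethogram = load_default_ethogram(),
                          enriched = FALSE) {
  stopifnot(is.character(code), length(code) == 1L)
  i <- match(code, ethogram$acronym)
  if (is.na(i)) {
    stop("unknown behaviour code: '", code, "'", call. = FALSE)
  }
  if (ethogram$enriched_only[i] && !isTRUE(enriched)) {
    stop("behaviour '", code,
         "' is exclusive to enriched environments (environment violation)",
         call. = FALSE)
  }
  code
}

#' Read an ethogram override from file
#'
#' Allows reuse with other vocabularies or species. Accepts a CSV (columns
#' `acronym,name,description,enriched_only`) or a YAML file (a list of entries
#' with the same fields).
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return An `ethogram` object.
#' @export
read_ethogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext %in% c("yml", "yaml")) {
    entries <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(entries, function(e) {
      data.frame(acronym = e$acronym, name = e$name,
                 description = if (is.null(e$description)) "" else e$description,
                 enriched_only = isTRUE(e$enriched_only),
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("unsupported ethogram file type: ", ext, call. = FALSE)
  }
  required <- c("acronym", "name", "description", "enriched_only")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("ethogram file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$enriched_only <- as.logical(df$enriched_only)
  if (anyDuplicated(df$acronym)) {
    stop("duplicate acronyms in ethogram file", call. = FALSE)
  }
  structure(df[required], class = c("ethogram", "data.frame"))
}

#' @export
print.ethogram <- function(x, ...) {
  cat("Ethogram with", nrow(x), "behaviours",
      sprintf("(%d enriched-only)\n", sum(x$enriched_only)))
  print.data.frame(x[, c("acronym", "name", "enriched_only")], row.names = FALSE)
  invisible(x)
}
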