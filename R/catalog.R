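#' Message framing categories
#'
#' The six framing categories of the message catalog: a neutral control plus
#' five theory-driven framings built from EPPM (fear/threat, efficacy) and
#' TPB (subjective norm) constructs, singly and in combination.
#'
#' @return Character vector of valid category names.
#' @export
message_categories <- function() {
  c("control", "fear", "efficacy", "norm", "fear_efficacy", "fear_efficacy_norm")
}

# Which construct components a framing category activates.
category_components <- function(category) {
  switch(category,
    control            = character(0),
    fear               = "threat",
    efficacy           = "efficacy",
    norm               = "norm",
    fear_efficacy      = c("threat", "efficacy"),
    fear_efficacy_norm = c("threat", "efficacy", "norm"),
    stop(sprintf("unknown message category '%s'", category), call. = FALSE)
  )
}

#' Default belief-activation delta magnitudes
#'
#' The per-construct activation increments applied when a message names a
#' construct. Magnitudes are a calibrated model constant (see the methods
#' vignette): threat and efficacy activations are stronger than the norm
#' activation, reflecting the evidence that threat and efficacy appeals
#' exert more influence on protective action than social cues alone.
#'
#' @return Named numeric vector with elements `threat`, `efficacy`, `norm`,
#'   each in \[0, 1\].
#' @export
default_deltas <- function() {
  c(threat = 0.35, efficacy = 0.35, norm = 0.25)
}

#' Construct-activation profile for a framing category
#'
#' Deterministically maps a message framing category to the belief increments
#' it applies: fear framings raise threat, efficacy framings raise efficacy,
#' norm framings raise subjective norm, and combined framings raise the union
#' of their components. Components not named by the category are exactly 0.
#'
#' @param category One of [message_categories()].
#' @param deltas Named numeric vector of increment magnitudes as in
#'   [default_deltas()].
#' @return Named numeric vector `c(delta_threat, delta_efficacy, delta_norm)`.
#' @examples
#' profile_for("control")            # all zero
#' profile_for("fear_efficacy_norm") # all three positive
#' @export
profile_for <- function(category, deltas = default_deltas()) {
  stopifnot(is.numeric(deltas), all(c("threat", "efficacy", "norm") %in% names(deltas)))
  if (any(deltas < 0 | deltas > 1)) {
    stop("configured deltas must lie in [0, 1]", call. = FALSE)
  }
  if (length(category) != 1 || !category %in% message_categories()) {
    stop(sprintf("unknown message category '%s'", category[1]), call. = FALSE)
  }
  comp <- category_components(category)
  prof <- c(delta_threat = 0, delta_efficacy = 0, delta_norm = 0)
  for (k in comp) prof[paste0("delta_", k)] <- unname(deltas[k])
  prof
}

#' Load a message catalog
#'
#' Reads a catalog of crisis messages with their framing categories and
#' construct-activation profiles. Two formats are accepted: JSON (an array
#' of objects with fields `id`, `category`, `text` and optional per-message
#' `delta_threat`/`delta_efficacy`/`delta_norm` overrides) and CSV in the
#' four-column published layout (variant id, category, content, theoretical
#' connection). Messages keep document order. Message text is carried for
#' reporting only and is never parsed; activations come solely from the
#' category (or explicit per-message overrides).
#'
#' @param source Path to a `.json` or `.csv` catalog file.
#' @param deltas Default activation magnitudes used for messages without
#'   explicit overrides.
#' @return A `maf_catalog` data frame with columns `id`, `category`, `text`,
#'   `delta_threat`, `delta_efficacy`, `delta_norm`.
#' @seealso [default_catalog()] for the bundled sixteen-message catalog.
#' @export
load_catalog <- function(source, deltas = default_deltas()) {
  stopifnot(file.exists(source))
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
    if (length(doc) == 0) return(empty_catalog())
    entries <- as.data.frame(doc, stringsAsFactors = FALSE)
  } else if (grepl("\\.csv$", source, ignore.case = TRUE)) {
    raw <- utils::read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(raw) == 0) return(empty_catalog())
    if (ncol(raw) < 3) stop("CSV catalog needs at least id, category, content columns",
                            call. = FALSE)
    entries <- data.frame(id = as.character(raw[[1]]),
                          category = as.character(raw[[2]]),
                          text = as.character(raw[[3]]),
                          stringsAsFactors = FALSE)
  } else {
    stop("catalog source must be a .json or .csv file", call. = FALSE)
  }
  build_catalog(entries, deltas)
}

empty_catalog <- function() {
  structure(data.frame(id = character(0), category = character(0),
                       text = character(0), delta_threat = numeric(0),
                       delta_efficacy = numeric(0), delta_norm = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("maf_catalog", "data.frame"))
}

# Accept both enum names and the published long category labels.
normalize_category <- function(x) {
  x0 <- tolower(trimws(x))
  x0 <- gsub("[^a-z]+", " ", x0)
  x0 <- trimws(x0)
  lookup <- c(
    "control" = "control",
    "fear" = "fear", "fear based" = "fear",
    "efficacy" = "efficacy", "efficacy based" = "efficacy",
    "norm" = "norm", "subjective norm" = "norm", "subjective norms" = "norm",
    "fear efficacy" = "fear_efficacy",
    "combined fear efficacy" = "fear_efficacy",
    "combined fear efficacy message" = "fear_efficacy",
    "fear efficacy norm" = "fear_efficacy_norm",
    "combined fear efficacy subjective norm" = "fear_efficacy_norm",
    "combined fear efficacy norm" = "fear_efficacy_norm"
  )
  out <- unname(lookup[x0])
  bad <- is.na(out)
  if (any(bad)) {
    stop(sprintf("unknown message category '%s'", x[bad][1]), call. = FALSE)
  }
  out
}

build_catalog <- function(entries, deltas = default_deltas()) {
  stopifnot(all(c("id", "category", "text") %in% names(entries)))
  entries$id <- as.character(entries$id)
  entries$category <- normalize_category(entries$category)
  dup <- entries$id[duplicated(entries$id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate message id '%s' in catalog", dup[1]), call. = FALSE)
  }
  prof <- t(vapply(entries$category, profile_for, numeric(3), deltas = deltas))
  for (k in colnames(prof)) {
    override <- entries[[k]]
    col <- prof[, k]
    if (!is.null(override)) {
      use <- !is.na(override)
      col[use] <- as.numeric(override[use])
    }
    entries[[k]] <- col
  }
  cat <- entries[, c("id", "category", "text",
                     "delta_threat", "delta_efficacy", "delta_norm")]
  rownames(cat) <- NULL
  class(cat) <- c("maf_catalog", "data.frame")
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  deltas <- as.matrix(cat[, c("delta_threat", "delta_efficacy", "delta_norm")])
  if (any(deltas < 0 | deltas > 1)) {
    stop("catalog activation deltas must lie in [0, 1]", call. = FALSE)
  }
  for (i in seq_len(nrow(cat))) {
    allowed <- paste0("delta_", category_components(cat$category[i]))
    off <- setdiff(colnames(deltas), allowed)
    if (any(deltas[i, off] != 0)) {
      stop(sprintf(
        "message '%s' (%s) has a nonzero activation outside its category's constructs",
        cat$id[i], cat$category[i]), call. = FALSE)
    }
  }
  invisible(cat)
}

#' The bundled sixteen-message catalog
#'
#' Loads the default catalog of one control message plus three variants in
#' each of five theory-driven framing categories (fear, efficacy, subjective
#' norm, fear+efficacy, fear+efficacy+norm), shipped with the package.
#'
#' @inheritParams load_catalog
#' @return A `maf_catalog` data frame with 16 rows.
#' @export
default_catalog <- function(deltas = default_deltas()) {
  load_catalog(system.file("extdata", "messages.json", package = "evactwin"),
               deltas = deltas)
}

#' Look up one message in a catalog
#'
#' @param catalog A `maf_catalog`.
#' @param id Message id.
#' @return The single catalog row for `id`.
#' @export
catalog_message <- function(catalog, id) {
  hit <- which(catalog$id == id)
  if (length(hit) != 1) {
    stop(sprintf("message id '%s' not found in catalog", id), call. = FALSE)
  }
  catalog[hit, , drop = FALSE]
}
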