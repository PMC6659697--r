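#' Landscape feature schema
#'
#' A feature schema is an ordered table of landscape feature classes, each
#' tagged with a category (`natural`, `anthropogenic`, or `protected_area`)
#' and a geometry (`polygonal` or `linear`). Polygonal non-protected classes
#' partition the land-cover grid; linear classes and the single
#' protected-area class are overlay masks that may co-occur with any cover.
#'
#' @param entries A data frame with columns `class_name`, `category`,
#'   `geometry`.
#' @return An object of class `feature_schema` (a validated data frame).
#' @export
feature_schema <- function(entries) {
  need <- c("class_name", "category", "geometry")
  if (!is.data.frame(entries) || !all(need %in% names(entries))) {
    err_schema("schema needs columns class_name, category, geometry")
  }
  entries <- as.data.frame(entries[, need], stringsAsFactors = FALSE)
  if (anyDuplicated(entries$class_name)) {
    err_schema("feature class names must be unique")
  }
  if (!all(entries$category %in% c("natural", "anthropogenic", "protected_area"))) {
    err_schema("category must be natural, anthropogenic or protected_area")
  }
  if (!all(entries$geometry %in% c("polygonal", "linear"))) {
    err_schema("geometry must be polygonal or linear")
  }
  if (sum(entries$category == "protected_area") != 1L) {
    err_schema("schema must contain exactly one protected_area class")
  }
  structure(entries, class = c("feature_schema", "data.frame"))
}

#' Default 15-class feature schema
#'
#' Nine natural classes (bare, deciduous, coniferous, mixed forests,
#' wetlands, grasslands, lakes, shrubs, streams), five anthropogenic classes
#' (development, crops, forage, rail lines, roads) and one protected-area
#' overlay -- the feature set of a working landscape with a protected-area
#' network. Streams, rail lines and roads are linear; all others polygonal.
#'
#' @return A `feature_schema` with 15 entries.
#' @export
default_feature_schema <- function() {
  feature_schema(data.frame(
    class_name = c(
      "bare", "deciduous", "coniferous", "mixed", "wetlands", "grasslands",
      "lakes", "shrubs", "streams",
      "development", "crops", "forage", "rail_lines", "roads",
      "protected_areas"
    ),
    category = c(rep("natural", 9), rep("anthropogenic", 5), "protected_area"),
    geometry = c(
      rep("polygonal", 8), "linear",
      rep("polygonal", 3), "linear", "linear",
      "polygonal"
    ),
    stringsAsFactors = FALSE
  ))
}

# Polygonal cover classes (exclude the protected-area overlay): these
# partition the grid.
cover_classes <- function(schema) {
  schema$class_name[schema$geometry == "polygonal" &
                      schema$category != "protected_area"]
}

linear_classes <- function(schema) {
  schema$class_name[schema$geometry == "linear"]
}

pa_class <- function(schema) {
  schema$class_name[schema$category == "protected_area"]
}
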