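tree_schema_version <- "1.0"

#' Write / read an airway tree as schema-versioned JSON
#'
#' Coordinates are serialized with 17 significant digits so that
#' `read_tree(write_tree(t))` reproduces every double bit-identically.
#'
#' @param tree An [airway_tree()] that passes [validate_tree()].
#' @param path File path (`.json`).
#' @return `write_tree()` returns `path` invisibly; `read_tree()` returns
#'   the [airway_tree()].
#' @export
write_tree <- function(tree, path) {
  diag <- validate_tree(tree)
  if (nrow(diag))
    stop("refusing to write an invalid tree: ",
         paste(unique(diag$rule), collapse = ", "), call. = FALSE)
  payload <- list(
    schema_version = tree_schema_version,
    root_id = tree$root_id,
    reference_plane = tree$reference_plane,
    frame = tree$frame,
    branches = lapply(unname(tree$branches), function(b) {
      list(
        id = b$id,
        parent_id = if (is.na(b$parent_id)) NULL else b$parent_id,
        child_ids = as.list(b$child_ids),
        centerline = apply(b$centerline, 1, as.list, simplify = FALSE),
        diameter_mm = b$diameter_mm,
        length_mm = b$length_mm,
        generation = if (is.na(b$generation)) NULL else b$generation,
        role_tag = b$role_tag,
        meta = b$meta
      )
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("schema_version", "root_id", "branches"))
    if (is.null(payload[[field]]))
      stop("malformed tree file: missing field '", field, "'", call. = FALSE)
  if (!identical(payload$schema_version, tree_schema_version))
    stop("tree schema version mismatch: file has '", payload$schema_version,
         "', expected '", tree_schema_version, "'", call. = FALSE)
  branches <- lapply(payload$branches, function(b) {
    for (field in c("id", "centerline", "diameter_mm", "role_tag"))
      if (is.null(b[[field]]))
        stop("malformed branch record: missing field '", field, "'",
             call. = FALSE)
    cl <- do.call(rbind, lapply(b$centerline, function(p) unlist(p)))
    airway_branch(
      id = b$id,
      parent_id = if (is.null(b$parent_id)) NA_character_ else b$parent_id,
      child_ids = unlist(b$child_ids) %||% character(),
      centerline = cl,
      diameter_mm = as.numeric(b$diameter_mm),
      generation = if (is.null(b$generation)) NA_integer_ else b$generation,
      role_tag = b$role_tag,
      meta = b$meta %||% list()
    )
  })
  airway_tree(
    branches = branches,
    root_id = payload$root_id,
    reference_plane = list(
      normal = as.numeric(unlist(payload$reference_plane$normal)),
      point = as.numeric(unlist(payload$reference_plane$point))
    ),
    frame = payload$frame
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the branch table as CSV
#'
#' One row per branch with units embedded in the column names.
#'
#' @param tree An [airway_tree()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_branch_csv <- function(tree, path) {
  tab <- branch_table(tree)
  write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}
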