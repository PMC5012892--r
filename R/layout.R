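VALID_ROLES <- c("vehicle", "treated", "blank")

#' Load and validate a plate layout table
#'
#' The layout CSV maps wells to experimental conditions with header columns
#' `well,treatment,concentration,unit,role,cells,meal`. Roles are
#' `vehicle` (normalisation reference), `treated`, or `blank` (no cells,
#' background only). Row order is irrelevant; the returned layout is sorted
#' by well.
#'
#' @param path CSV file path, or a data frame already in layout form.
#' @return A tibble with columns `well_id`, `treatment`, `concentration`,
#'   `unit`, `role`, `seeded_cells`, `meal`.
#' @export
load_layout <- function(path) {
  if (is.data.frame(path)) {
    df <- tibble::as_tibble(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  }
  req <- c("well", "treatment", "concentration", "unit", "role", "cells", "meal")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("layout is missing required column(s): ", paste(missing_cols, collapse = ", "))

  bad_role <- setdiff(unique(df$role), VALID_ROLES)
  if (length(bad_role) > 0)
    stop(sprintf("unknown role '%s' in layout; valid roles are: %s",
                 bad_role[1], paste(VALID_ROLES, collapse = ", ")))

  conc <- suppressWarnings(as.numeric(df$concentration))
  if (anyNA(conc))
    stop("non-numeric concentration in layout row(s): ",
         paste(which(is.na(conc)), collapse = ", "))
  if (any(conc < 0)) stop("concentration must be non-negative")

  cells <- suppressWarnings(as.integer(df$cells))
  if (anyNA(cells) || any(cells < 0))
    stop("layout column 'cells' must hold non-negative integers")

  out <- tibble::tibble(
    well_id = toupper(as.character(df$well)),
    treatment = as.character(df$treatment),
    concentration = conc,
    unit = as.character(df$unit),
    role = as.character(df$role),
    seeded_cells = cells,
    meal = as.character(df$meal))

  dup <- out$well_id[duplicated(out$well_id)]
  if (length(dup) > 0)
    stop("duplicate well_id in layout: ", paste(unique(dup), collapse = ", "))
  if (any(out$role == "blank" & out$seeded_cells != 0))
    stop("blank wells must have seeded_cells = 0: ",
         paste(out$well_id[out$role == "blank" & out$seeded_cells != 0], collapse = ", "))

  dplyr::arrange(out, .data$well_id)
}

#' Require at least one vehicle well in a layout
#' @param layout A layout tibble from [load_layout()].
#' @return The layout, invisibly; errors when no vehicle well exists.
#' @keywords internal
assert_has_vehicle <- function(layout) {
  if (!any(layout$role == "vehicle"))
    stop("normalization requested but the layout contains no vehicle well")
  invisible(layout)
}
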