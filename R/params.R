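#' Analysis parameters
#'
#' Parameters of the per-frame image pipeline. The defaults are the assay's
#' standard settings: top-hat background correction with a 20 um disk radius,
#' a fixed threshold of 2 corrected intensity units, exclusion of objects
#' below 50 um^2, and edge-split declumping enabled.
#'
#' @param tophat_radius_um Disk radius of the top-hat structuring element, um.
#' @param threshold_corrected_units Foreground threshold applied to the
#'   background-corrected image (inclusive: a pixel at exactly the threshold
#'   is foreground).
#' @param min_object_area_um2 Objects strictly below this area are removed
#'   (an object of exactly this area is retained).
#' @param edge_split Split merged regions containing several intensity maxima
#'   by marker-controlled watershed.
#' @param apply_area_filter_to_fluorescence Apply the area filter to
#'   fluorescent objects (it always applies to the phase confluence mask).
#' @param channel_of_interest Fluorescence channel quantified: `"green"` or
#'   `"red"`.
#' @param smoothing_sigma_px Gaussian sigma (pixels) used to smooth the
#'   corrected image before seed detection in the edge split.
#' @return An object of class `analysis_params` (a named list).
#' @examples
#' analysis_params()
#' @export
analysis_params <- function(tophat_radius_um = 20,
                            threshold_corrected_units = 2,
                            min_object_area_um2 = 50,
                            edge_split = TRUE,
                            apply_area_filter_to_fluorescence = TRUE,
                            channel_of_interest = c("green", "red"),
                            smoothing_sigma_px = 1.0) {
  channel_of_interest <- match.arg(channel_of_interest)
  stopifnot(tophat_radius_um > 0, threshold_corrected_units > 0,
            min_object_area_um2 >= 0, is.logical(edge_split),
            is.logical(apply_area_filter_to_fluorescence),
            smoothing_sigma_px >= 0)
  structure(
    list(tophat_radius_um = tophat_radius_um,
         threshold_corrected_units = threshold_corrected_units,
         min_object_area_um2 = min_object_area_um2,
         edge_split = edge_split,
         apply_area_filter_to_fluorescence = apply_area_filter_to_fluorescence,
         channel_of_interest = channel_of_interest,
         smoothing_sigma_px = smoothing_sigma_px),
    class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("<analysis_params>\n")
  cat(sprintf("  top-hat radius:        %g um\n", x$tophat_radius_um))
  cat(sprintf("  threshold:             %g corrected units\n", x$threshold_corrected_units))
  cat(sprintf("  min object area:       %g um^2 (fluorescence: %s)\n",
              x$min_object_area_um2,
              if (x$apply_area_filter_to_fluorescence) "on" else "off"))
  cat(sprintf("  edge split:            %s\n", if (x$edge_split) "on" else "off"))
  cat(sprintf("  channel of interest:   %s\n", x$channel_of_interest))
  cat(sprintf("  seed smoothing sigma:  %g px\n", x$smoothing_sigma_px))
  invisible(x)
}

#' Read analysis parameters from a TOML file
#'
#' Recognised keys match the arguments of [analysis_params()]; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path TOML file path.
#' @return An `analysis_params` object.
#' @export
load_params <- function(path) {
  vals <- parse_toml(path)
  known <- names(formals(analysis_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown analysis parameter(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(analysis_params, vals)
}

#' Parse a TOML configuration file (flat subset)
#'
#' Supports the subset used by this package's config files: comments,
#' bare `key = value` pairs, `[section]` tables (returned as nested lists),
#' strings, integers, floats, booleans and flat arrays.
#'
#' @param path TOML file path.
#' @return A named list.
#' @export
parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    # strip comments outside of quotes
    line <- sub('^([^"#]*("[^"]*"[^"#]*)*)#.*$', "\\1", line)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".", fixed = TRUE)[[1]]
      # pre-create the nested tables so [[<- has a path to assign into
      for (d in seq_along(section)) {
        if (is.null(out[[section[seq_len(d)]]]))
          out[[section[seq_len(d)]]] <- list()
      }
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("TOML parse error at %s line %d: expected 'key = value'", path, ln))
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    if (key == "" || val == "")
      stop(sprintf("TOML parse error at %s line %d: empty key or value", path, ln))
    out[[c(section, key)]] <- toml_value(val, path, ln)
  }
  out
}

toml_value <- function(s, path, ln) {
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(gsub("^\\[|\\]$", "", s))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(unlist(lapply(parts, toml_value, path = path, ln = ln)))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop(sprintf("TOML parse error at %s line %d: cannot interpret value '%s'",
               path, ln, s))
}
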