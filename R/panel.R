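#' Cytokine panels and functional groupings
#'
#' A cytokine panel is an ordered set of cytokine names together with a
#' partition of those names into functional groups. The default panel is the
#' 32-plex adaptive immune secretome panel with its five groups
#' (chemoattractive, effector, inflammatory, stimulatory, regulatory).
#'
#' @param cytokines Character vector of cytokine names (unique).
#' @param groups Named list of character vectors partitioning `cytokines`.
#' @return An object of class `cytokine_panel` with elements `cytokines`
#'   (ordered character vector) and `groups` (named list of character
#'   vectors).
#' @examples
#' p <- default_panel()
#' length(p$cytokines)     # 32
#' names(p$groups)         # five functional groups
#' @export
cytokine_panel <- function(cytokines, groups) {
  cytokines <- as.character(cytokines)
  if (anyDuplicated(cytokines) > 0) {
    stop("cytokine names must be unique", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("`groups` must be a fully named list", call. = FALSE)
  }
  groups <- lapply(groups, as.character)
  pooled <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(pooled) > 0) {
    dup <- unique(pooled[duplicated(pooled)])
    stop("cytokine(s) assigned to more than one group: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!setequal(pooled, cytokines)) {
    stop("group sets must partition the cytokine list exactly", call. = FALSE)
  }
  structure(list(cytokines = cytokines, groups = groups),
            class = "cytokine_panel")
}

#' @export
print.cytokine_panel <- function(x, ...) {
  cat("<cytokine_panel> ", length(x$cytokines), " cytokines in ",
      length(x$groups), " functional groups\n", sep = "")
  for (g in names(x$groups)) {
    cat("  ", format(g, width = 16), " (", length(x$groups[[g]]), "): ",
        paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' The default 32-plex adaptive immune secretome panel
#'
#' Thirty-two cytokines partitioned into the five functional groups used for
#' polyfunctional strength scoring: chemoattractive (4), effector (6),
#' inflammatory (6), stimulatory (9) and regulatory (7). Canonical names are
#' ASCII ("IFNg", "TNFa", "MIP-1b", ...); Greek-letter and other common
#' spellings are accepted as aliases everywhere names are matched (see
#' [normalize_cytokine_names()]). "IP-20" is the canonical token for the
#' chemoattractive interferon-induced protein; "IP-10" is an accepted alias.
#'
#' @return A `cytokine_panel` of 32 cytokines in 5 groups.
#' @export
default_panel <- function() {
  groups <- list(
    chemoattractive = c("CCL-11", "IP-20", "MIP-1b", "RANTES"),
    effector        = c("Granzyme B", "IFNg", "MIP-1a", "Perforin",
                        "TNFa", "TNFb"),
    inflammatory    = c("IL1b", "IL6", "IL17A", "IL17F", "MCP-1", "MCP-4"),
    stimulatory     = c("GMCSF", "IL2", "IL5", "IL7", "IL8", "IL9",
                        "IL12", "IL15", "IL21"),
    regulatory      = c("IL4", "IL10", "IL13", "IL22", "TGFb1",
                        "sCD137", "sCD40L")
  )
  cytokine_panel(unlist(groups, use.names = FALSE), groups)
}

# Aliases resolved after normalization; keys and values are normalized forms.
.cytokine_aliases <- c(
  ip10 = "ip20",       # the panel literature writes IP-10
  grzb = "granzymeb",
  gzmb = "granzymeb",
  tgfb = "tgfb1"
)

#' Normalize cytokine names for matching
#'
#' Lower-cases, strips hyphens/spaces/underscores/periods, and maps Greek
#' letters to ASCII (beta to "b", gamma to "g", alpha to "a") so that e.g.
#' "TNF-α", "TNFa" and "tnf a" all match. A small alias table maps
#' common synonyms (IP-10 to IP-20, GzmB to Granzyme B).
#'
#' @param x Character vector of names.
#' @return Character vector of normalized tokens.
#' @export
normalize_cytokine_names <- function(x) {
  y <- tolower(as.character(x))
  y <- gsub("α", "a", y)
  y <- gsub("β", "b", y)
  y <- gsub("γ", "g", y)
  y <- gsub("[-_. ]", "", y)
  hit <- match(y, names(.cytokine_aliases))
  y[!is.na(hit)] <- unname(.cytokine_aliases[hit[!is.na(hit)]])
  y
}

#' Match table columns against a panel
#'
#' Reports which panel cytokines are present in, missing from, or extra to a
#' set of column names, after canonical name normalization.
#'
#' @param panel A `cytokine_panel`.
#' @param columns Character vector of candidate column names (e.g. a table
#'   header).
#' @return A list of class `panel_match` with `matched` (tibble `column`,
#'   `cytokine`), `missing` (panel cytokines absent from the columns) and
#'   `extra` (columns matching no panel cytokine).
#' @export
validate_panel <- function(panel, columns) {
  stopifnot(inherits(panel, "cytokine_panel"))
  norm_cols <- normalize_cytokine_names(columns)
  norm_panel <- normalize_cytokine_names(panel$cytokines)
  panel_hits <- norm_cols %in% norm_panel
  if (anyDuplicated(norm_cols[panel_hits]) > 0) {
    dup <- unique(columns[panel_hits][duplicated(norm_cols[panel_hits])])
    stop("duplicate cytokine columns after name normalization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  idx <- match(norm_panel, norm_cols)
  matched <- tibble::tibble(
    column = columns[idx[!is.na(idx)]],
    cytokine = panel$cytokines[!is.na(idx)]
  )
  structure(list(
    matched = matched,
    missing = panel$cytokines[is.na(idx)],
    extra = columns[!panel_hits]
  ), class = "panel_match")
}

#' @export
print.panel_match <- function(x, ...) {
  cat("<panel_match> ", nrow(x$matched), " matched, ",
      length(x$missing), " missing, ", length(x$extra), " extra\n", sep = "")
  if (length(x$missing)) cat("  missing: ", paste(x$missing, collapse = ", "),
                             "\n", sep = "")
  invisible(x)
}

#' Map each panel cytokine to its functional group
#'
#' @param panel A `cytokine_panel`.
#' @return Named character vector: names are cytokines, values group names.
#' @export
panel_groups <- function(panel) {
  stopifnot(inherits(panel, "cytokine_panel"))
  out <- rep(names(panel$groups), lengths(panel$groups))
  names(out) <- unlist(panel$groups, use.names = FALSE)
  out[panel$cytokines]
}

#' Read/write a panel as YAML or JSON
#'
#' The on-disk document has two keys: `cytokines` (ordered list) and
#' `groups` (map from group name to cytokine list). Format is chosen by file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param panel A `cytokine_panel`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns a
#'   `cytokine_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "cytokine_panel"))
  doc <- list(cytokines = panel$cytokines, groups = panel$groups)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    stop("unsupported panel file extension: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported panel file extension: ", path, call. = FALSE)
  }
  cytokine_panel(doc$cytokines, as.list(doc$groups))
}
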