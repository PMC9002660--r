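## Lineage handling: hierarchical path (class, order, superfamily, clade)
## encoded in profile names such as "LTR/Copia/Ale:RT".

DOMAIN_LABELS <- c("GAG", "AP", "INT", "RT", "RH")

## Aliases seen across domain databases, normalized onto the five canonical
## polyprotein labels; anything else maps to "other".
normalize_domain_label <- function(label) {
  up <- toupper(label)
  up[up %in% c("PROT", "AP", "PR")] <- "AP"
  up[up %in% c("RNASEH", "RNASE_H", "RH")] <- "RH"
  up[up %in% c("RVT", "RT")] <- "RT"
  up[up %in% c("GAG")] <- "GAG"
  up[up %in% c("INT")] <- "INT"
  up[!up %in% DOMAIN_LABELS] <- "other"
  up
}

#' Construct a lineage
#'
#' A lineage is a hierarchical path through the TE classification:
#' optional class, order (always present), optional superfamily, optional
#' clade.  A clade requires a superfamily.
#'
#' @param order Order, e.g. `"LTR"`, `"LINE"`, `"TIR"`.
#' @param superfamily Superfamily, e.g. `"Copia"`, `"Gypsy"`, or `NA`.
#' @param clade Clade, e.g. `"Ale"`, `"CRM"`, or `NA`.
#' @param te_class Optional class, e.g. `"Class_I"`.
#' @return A list of class `te_lineage`.
#' @export
lineage <- function(order, superfamily = NA_character_, clade = NA_character_,
                    te_class = NA_character_) {
  order <- as.character(order)
  superfamily <- as.character(superfamily)
  clade <- as.character(clade)
  te_class <- as.character(te_class)
  if (is.na(order) || !nzchar(order)) {
    stop("a lineage requires an order", call. = FALSE)
  }
  if (!is.na(clade) && is.na(superfamily)) {
    stop("a clade-level lineage requires a superfamily", call. = FALSE)
  }
  structure(list(te_class = te_class, order = order,
                 superfamily = superfamily, clade = clade),
            class = "te_lineage")
}

#' Depth of a lineage
#'
#' @param lin A `te_lineage`.
#' @return `"order"`, `"superfamily"` or `"clade"`.
#' @export
lineage_depth <- function(lin) {
  if (!is.na(lin$clade)) "clade"
  else if (!is.na(lin$superfamily)) "superfamily"
  else "order"
}

#' Format a lineage as a path string
#'
#' @param lin A `te_lineage`.
#' @return `"LTR/Copia/Ale"`-style path (class omitted).
#' @export
format_lineage <- function(lin) {
  parts <- c(lin$order, lin$superfamily, lin$clade)
  paste(parts[!is.na(parts)], collapse = "/")
}

#' @export
print.te_lineage <- function(x, ...) {
  cat("<lineage> ", format_lineage(x), "\n", sep = "")
  invisible(x)
}

#' Parse a profile name into lineage and domain label
#'
#' The supported grammar (the package's `"path"` dialect, used by fixture
#' databases and by the sidecar metadata table) is
#' `[Class/]Order[/Superfamily[/Clade]]:Domain`, where a leading component
#' starting with `"Class"` is taken as the class.  Domain labels are
#' normalized onto `{GAG, AP, INT, RT, RH, other}` (`PROT` is an alias of
#' `AP`).
#'
#' @param name Profile name, e.g. `"LTR/Copia/Ale:RT"`.
#' @param dialect Naming dialect; only `"path"` is built in.  Databases with
#'   other naming schemes supply a metadata TSV instead (see
#'   [read_profile_db()]).
#' @return A list with elements `lineage` (a `te_lineage`) and
#'   `domain_label`.
#' @export
parse_profile_name <- function(name, dialect = "path") {
  dialect <- match.arg(dialect)
  if (!nzchar(name) || !grepl(":", name, fixed = TRUE)) {
    stop("profile name '", name, "' does not match the expected grammar ",
         "'[Class/]Order[/Superfamily[/Clade]]:Domain'", call. = FALSE)
  }
  path <- sub(":[^:]*$", "", name)
  dom <- sub("^.*:", "", name)
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  te_class <- NA_character_
  if (length(parts) > 1L && grepl("^Class", parts[1])) {
    te_class <- parts[1]
    parts <- parts[-1]
  }
  if (length(parts) < 1L || length(parts) > 3L || any(!nzchar(parts)) ||
      !nzchar(dom)) {
    stop("profile name '", name, "' does not match the expected grammar ",
         "'[Class/]Order[/Superfamily[/Clade]]:Domain'", call. = FALSE)
  }
  lin <- lineage(order = parts[1],
                 superfamily = if (length(parts) >= 2L) parts[2] else NA,
                 clade = if (length(parts) >= 3L) parts[3] else NA,
                 te_class = te_class)
  list(lineage = lin, domain_label = normalize_domain_label(dom))
}

#' Render a (lineage, domain label) pair back to a profile name
#'
#' Inverse of [parse_profile_name()] for the `"path"` dialect.
#'
#' @param lin A `te_lineage`.
#' @param domain_label Domain label.
#' @return The profile name string.
#' @export
render_profile_name <- function(lin, domain_label) {
  path <- format_lineage(lin)
  if (!is.na(lin$te_class)) path <- paste(lin$te_class, path, sep = "/")
  paste0(path, ":", domain_label)
}
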