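#' Congener panels
#'
#' A congener panel is the registry of the 16 EPA-priority polycyclic
#' aromatic hydrocarbons (PAHs) tracked by the pipeline: full chemical name,
#' short code, analytical limits of detection/quantification (LOD/LOQ,
#' ug/kg), a toxic equivalency factor (TEF) relative to benzo\[a\]pyrene,
#' and inert GC-MS ion metadata. The packaged registry carries the
#' validation constants of the survey method together with a
#' Nisbet–LaGoy-style TEF set.
#'
#' @param x A data frame with columns `abbrev`, `name`, `lod`, `loq`,
#'   `tef`; further columns are kept as metadata.
#' @param pah4 Character vector of the four congeners entering the EU
#'   regulatory "PAH4" sum.
#'
#' @return A `congener_panel`: a tibble with one row per congener, in panel
#'   order, with attribute `pah4`.
#' @export
#' @examples
#' panel <- default_panel()
#' panel$lod[panel$abbrev == "BaP"]
congener_panel <- function(x, pah4 = c("BaA", "Ch", "BbF", "BaP")) {
  x <- as_tibble(x)
  required <- c("abbrev", "name", "lod", "loq", "tef")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("congener registry is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) != 16L) {
    stop("a congener panel must have exactly 16 congeners, got ", nrow(x),
         call. = FALSE)
  }
  if (anyDuplicated(x$abbrev)) {
    stop("duplicate congener abbreviation(s): ",
         paste(unique(x$abbrev[duplicated(x$abbrev)]), collapse = ", "),
         call. = FALSE)
  }
  x$lod <- as.numeric(x$lod)
  x$loq <- as.numeric(x$loq)
  x$tef <- as.numeric(x$tef)
  if (any(!is.finite(x$lod)) || any(x$lod <= 0)) {
    stop("every LOD must be a positive number", call. = FALSE)
  }
  if (any(!is.finite(x$loq)) || any(x$loq < x$lod)) {
    stop("every LOQ must be >= its LOD", call. = FALSE)
  }
  if (any(!is.finite(x$tef)) || any(x$tef < 0)) {
    stop("every TEF must be >= 0", call. = FALSE)
  }
  if (!all(pah4 %in% x$abbrev) || length(pah4) != 4L) {
    stop("`pah4` must name exactly 4 congeners present in the panel",
         call. = FALSE)
  }
  structure(x, class = c("congener_panel", class(x)), pah4 = pah4)
}

#' Read a congener registry file
#'
#' @param path Path to a tab-delimited registry with columns `abbrev`,
#'   `name`, `lod`, `loq`, `tef` (and optional ion metadata).
#' @inheritParams congener_panel
#' @return A [congener_panel()].
#' @export
load_panel <- function(path, pah4 = c("BaA", "Ch", "BbF", "BaP")) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = character())
  congener_panel(x, pah4 = pah4)
}

#' @rdname congener_panel
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "congener_registry.tsv",
                         package = "pahrisk", mustWork = TRUE))
}

#' Congeners entering the PAH4 regulatory sum
#'
#' @param panel A [congener_panel()].
#' @return Character vector of four congener abbreviations.
#' @export
pah4_members <- function(panel) {
  stopifnot(inherits(panel, "congener_panel"))
  attr(panel, "pah4")
}

#' @export
print.congener_panel <- function(x, ...) {
  cat("<congener_panel> ", nrow(x), " congeners; PAH4 = {",
      paste(attr(x, "pah4"), collapse = ", "), "}\n", sep = "")
  NextMethod()
}
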