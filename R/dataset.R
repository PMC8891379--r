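#' Censored PAH concentration datasets
#'
#' A `pah_dataset` holds per-sample, per-congener measurements in ug/kg
#' together with product-type and brand labels. Non-detect cells (below the
#' analytical LOD) are stored as censored measurements without a numeric
#' value until [impute_nondetects()] substitutes one; the censored flag is
#' kept afterwards for audit.
#'
#' @param measurements Tibble with columns `sample_id`, `product_type`,
#'   `brand`, `congener`, `value` (ug/kg, `NA` when censored), `censored`.
#' @param panel A [congener_panel()].
#' @param imputed Logical provenance flag: `TRUE` once non-detects carry
#'   substituted values.
#' @return A `pah_dataset` object.
#' @export
pah_dataset <- function(measurements, panel, imputed = FALSE) {
  stopifnot(inherits(panel, "congener_panel"))
  m <- as_tibble(measurements)
  required <- c("sample_id", "product_type", "brand", "congener", "value",
                "censored")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("measurements are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(m$congener), panel$abbrev)
  if (length(unknown) > 0) {
    stop("measurement(s) reference congeners absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dup <- m %>%
    dplyr::count(sample_id, congener) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate measurements for sample/congener pairs, e.g. ",
         dup$sample_id[1], "/", dup$congener[1], call. = FALSE)
  }
  if (any(!m$censored & (is.na(m$value) | m$value < 0))) {
    stop("detected measurements must carry a nonnegative value",
         call. = FALSE)
  }
  if (imputed && any(m$censored & is.na(m$value))) {
    stop("an imputed dataset cannot contain censored cells without values",
         call. = FALSE)
  }
  structure(list(panel = panel, measurements = m, imputed = imputed),
            class = "pah_dataset")
}

#' @export
print.pah_dataset <- function(x, ...) {
  cat("<pah_dataset> ", length(unique(x$measurements$sample_id)),
      " samples x ", nrow(x$panel), " congeners; ",
      sum(x$measurements$censored), " censored cells; imputed: ",
      x$imputed, "\n", sep = "")
  invisible(x)
}

nd_pattern <- function(nd_tokens) {
  paste0("^(", paste(tolower(nd_tokens), collapse = "|"), ")$")
}

#' Read a wide concentration table
#'
#' Reads a delimited table with one row per sample and columns `sample_id`,
#' `product_type`, `brand`, followed by one column per panel congener.
#' Cells are either numeric concentrations (ug/kg) or a non-detect token
#' (by default `"nd"` or `"<LOD"`, case-insensitive).
#'
#' @param path Path to the delimited file.
#' @param panel A [congener_panel()].
#' @param nd_tokens Character vector of tokens marking non-detects.
#' @param delim Field delimiter (default tab).
#' @return A [pah_dataset()] (not yet imputed).
#' @export
read_concentrations <- function(path, panel, nd_tokens = c("nd", "<LOD"),
                                delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           na = character())
  id_cols <- c("sample_id", "product_type", "brand")
  missing_ids <- setdiff(id_cols, names(raw))
  if (length(missing_ids) > 0) {
    stop("concentration table is missing column(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  conc_cols <- setdiff(names(raw), id_cols)
  unknown <- setdiff(conc_cols, panel$abbrev)
  if (length(unknown) > 0) {
    stop("unknown congener column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(panel$abbrev, conc_cols)
  if (length(absent) > 0) {
    stop("concentration table lacks panel congener(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  long <- raw %>%
    pivot_longer(dplyr::all_of(panel$abbrev), names_to = "congener",
                 values_to = "cell") %>%
    mutate(censored = grepl(nd_pattern(nd_tokens), tolower(trimws(cell))),
           value = ifelse(censored, NA_real_,
                          suppressWarnings(as.numeric(cell))))
  bad <- long %>% filter(!censored & is.na(value))
  if (nrow(bad) > 0) {
    stop("unparseable concentration cell(s), e.g. '", bad$cell[1],
         "' for ", bad$congener[1], " in sample ", bad$sample_id[1],
         call. = FALSE)
  }
  neg <- long %>% filter(!censored & value < 0)
  if (nrow(neg) > 0) {
    stop("negative concentration for ", neg$congener[1], " in sample ",
         neg$sample_id[1], call. = FALSE)
  }
  pah_dataset(long %>% select(-cell), panel, imputed = FALSE)
}

#' Write a dataset back to a wide concentration table
#'
#' Censored cells are written as `"nd"`; the write/read round trip
#' preserves every cell including censored flags.
#'
#' @param ds A [pah_dataset()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(ds, path, delim = "\t") {
  stopifnot(inherits(ds, "pah_dataset"))
  wide <- ds$measurements %>%
    mutate(cell = ifelse(censored & is.na(value), "nd",
                         format(value, digits = 15, trim = TRUE,
                                scientific = FALSE))) %>%
    select(sample_id, product_type, brand, congener, cell) %>%
    pivot_wider(names_from = congener, values_from = cell) %>%
    select(dplyr::all_of(c("sample_id", "product_type", "brand",
                           ds$panel$abbrev)))
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Substitute non-detect measurements
#'
#' Replaces every censored cell by a deterministic function of the
#' congener's detection limit. The survey convention is half the LOD
#' (`"half_lod"`); `"zero"`, `"lod"` and `"loq"` are provided for
#' sensitivity analysis. Substitution is idempotent in effect: the censored
#' flags are retained, so re-running on the already-imputed dataset is an
#' error by provenance, and the substituted values are pure functions of
#' the panel.
#'
#' @param ds A [pah_dataset()] not yet imputed.
#' @param rule One of `"half_lod"`, `"zero"`, `"lod"`, `"loq"`.
#' @return The dataset with every censored cell carrying a value and
#'   `imputed = TRUE`.
#' @export
#' @examples
#' ds <- generate_dataset(seed = 1)
#' imp <- impute_nondetects(ds)
impute_nondetects <- function(ds, rule = c("half_lod", "zero", "lod", "loq")) {
  stopifnot(inherits(ds, "pah_dataset"))
  rule <- match.arg(rule)
  if (ds$imputed) {
    stop("dataset is already imputed; start from the censored original",
         call. = FALSE)
  }
  fill <- switch(rule,
    half_lod = ds$panel$lod / 2,
    zero = rep(0, nrow(ds$panel)),
    lod = ds$panel$lod,
    loq = ds$panel$loq
  )
  fill <- setNames(fill, ds$panel$abbrev)
  m <- ds$measurements %>%
    mutate(value = ifelse(censored, fill[congener], value))
  pah_dataset(m, ds$panel, imputed = TRUE)
}

#' Convert between concentration units
#'
#' Exact power-of-ten scaling between ng/kg, ug/kg and mg/kg. Summary
#' tables work in ug/kg; the risk equations take mg/kg.
#'
#' @param value Numeric concentration(s).
#' @param from,to Units, one of `"ng/kg"`, `"ug/kg"`, `"mg/kg"`.
#' @return Rescaled numeric vector.
#' @export
#' @examples
#' convert_concentration(0.45, "ug/kg", "mg/kg")  # 4.5e-4
convert_concentration <- function(value, from, to) {
  scale <- c("ng/kg" = 1e-9, "ug/kg" = 1e-6, "mg/kg" = 1e-3)
  if (!from %in% names(scale)) stop("unknown unit: ", from, call. = FALSE)
  if (!to %in% names(scale)) stop("unknown unit: ", to, call. = FALSE)
  value * unname(scale[from] / scale[to])
}
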