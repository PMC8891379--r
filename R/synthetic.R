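#' Packaged group targets and score rows
#'
#' `load_group_targets()` reads the per-product-type target table: for
#' each of the 9 cereal-based product types and each panel congener, the
#' group mean and sd (ug/kg) plus the observed range, with `nd` marking
#' congeners not detected in that group. `load_group_scores()` reads the
#' corresponding published group rows for the total PAH16 burden and the
#' PAH4 regulatory sum. Together they are the single source of truth for
#' the survey conditions the synthetic generator emulates.
#'
#' @param path Path to the delimited file (defaults to the packaged
#'   fixture).
#' @return A tibble; in `load_group_targets()` non-detect cells are `NA`
#'   and flagged by the logical column `all_nd`.
#' @export
load_group_targets <- function(path = system.file("extdata",
                                                  "group_targets.tsv",
                                                  package = "pahrisk",
                                                  mustWork = TRUE)) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = character())
  num <- function(v) suppressWarnings(as.numeric(ifelse(tolower(v) == "nd",
                                                        NA, v)))
  x %>%
    mutate(mean = num(mean), sd = num(sd), min = num(min), max = num(max),
           all_nd = is.na(mean))
}

#' @rdname load_group_targets
#' @export
load_group_scores <- function(path = system.file("extdata",
                                                 "group_scores.tsv",
                                                 package = "pahrisk",
                                                 mustWork = TRUE)) {
  readr::read_tsv(path, col_types = readr::cols(
    product_type = "c", statistic = "c", mean = "d", sd = "d",
    min = "d", max = "d"))
}

# parent mean of a normal truncated at 0 whose truncated mean equals
# `target`, with parent sd fixed at `sigma`
truncnorm_parent_mean <- function(target, sigma) {
  if (sigma <= 0) return(target)
  trunc_mean <- function(mu) {
    a <- -mu / sigma
    mu + sigma * dnorm(a) / pnorm(a, lower.tail = FALSE)
  }
  uniroot(function(mu) trunc_mean(mu) - target,
          lower = target - 20 * sigma, upper = target,
          extendInt = "upX", tol = 1e-10)$root
}

draw_cell <- function(target_mean, target_sd, n, family) {
  if (target_sd <= 0) return(rep(target_mean, n))
  if (family == "truncnorm") {
    mu <- truncnorm_parent_mean(target_mean, target_sd)
    draw_dist(dist_spec("normal", mean = mu, sd = target_sd, lower = 0), n)
  } else {
    draw_dist(dist_spec("lognormal", mean = target_mean, sd = target_sd), n)
  }
}

#' Generate a synthetic censored concentration dataset
#'
#' Emulates the survey design: per product type, `n_per_group` samples
#' (default 4, i.e. 36 samples over the 9 study product types, purchased
#' in duplicate from two brands assigned round-robin), with each congener
#' drawn from a zero-truncated noise family centred on the group target.
#' The truncated-normal family is parameterized so the post-truncation
#' mean equals the target mean (parent sd = target sd), keeping the
#' generator unbiased for the quantity the summaries recover. Draws below
#' the congener's LOD are recorded as non-detects when `censor_at_lod` is
#' on; congeners flagged all-non-detect in a group are always censored.
#'
#' @param targets Tibble from [load_group_targets()] (or the same shape).
#' @param panel A [congener_panel()].
#' @param n_per_group Samples per product type (default 4).
#' @param brands Brand labels cycled over samples within a group.
#' @param seed Integer seed; generation is deterministic given
#'   `(targets, config, seed)`.
#' @param family Noise family: `"truncnorm"` (default) or `"lognormal"`.
#' @param censor_at_lod Censor draws below the LOD?
#' @return A censored [pah_dataset()] (not imputed).
#' @export
#' @examples
#' ds <- generate_dataset(seed = 1)
#' ds
generate_dataset <- function(targets = load_group_targets(),
                             panel = default_panel(),
                             n_per_group = 4L, brands = c("A", "B"),
                             seed = NULL,
                             family = c("truncnorm", "lognormal"),
                             censor_at_lod = TRUE) {
  family <- match.arg(family)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  unknown <- setdiff(unique(targets$congener), panel$abbrev)
  if (length(unknown) > 0) {
    stop("targets reference congeners absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(targets$mean) & targets$mean < 0)) {
    stop("target means must be nonnegative", call. = FALSE)
  }
  lods <- setNames(panel$lod, panel$abbrev)
  groups <- unique(targets$product_type)
  with_local_seed(seed, {
    rows <- lapply(groups, function(g) {
      tg <- targets %>% filter(product_type == g)
      ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", g),
                     seq_len(n_per_group))
      brand_v <- rep_len(brands, n_per_group)
      cells <- lapply(panel$abbrev, function(cg) {
        row <- tg %>% filter(congener == cg)
        if (nrow(row) != 1) {
          stop("targets must have exactly one row per group/congener; ",
               g, "/", cg, call. = FALSE)
        }
        if (row$all_nd) {
          tibble(sample_id = ids, product_type = g, brand = brand_v,
                 congener = cg, value = NA_real_, censored = TRUE)
        } else {
          sdv <- if (is.na(row$sd)) 0 else row$sd
          v <- draw_cell(row$mean, sdv, n_per_group, family)
          cens <- censor_at_lod & (v < lods[[cg]])
          tibble(sample_id = ids, product_type = g, brand = brand_v,
                 congener = cg,
                 value = ifelse(cens, NA_real_, v), censored = cens)
        }
      })
      bind_rows(cells)
    })
    pah_dataset(bind_rows(rows), panel, imputed = FALSE)
  })
}

#' Compare a generated dataset against its targets
#'
#' For every product-type/congener cell with a numeric target, expresses
#' the deviation of the observed group mean from the target mean in
#' standard-error units (`se = target_sd / sqrt(n)`), and reports the
#' censoring rate. Observed means are computed after half-LOD
#' substitution when the dataset still contains censored cells. Cells with
#' zero target sd report `z = 0` when they match exactly and `Inf`
#' otherwise, so deliberately shifted targets are flagged.
#'
#' @param ds A [pah_dataset()] generated from `targets`.
#' @param targets The target tibble used for generation.
#' @return Tibble with columns `product_type`, `congener`, `target_mean`,
#'   `target_sd`, `n`, `observed_mean`, `se`, `z`, `censor_rate`,
#'   `all_nd`, `within_2se`.
#' @export
recovery_report <- function(ds, targets = load_group_targets()) {
  stopifnot(inherits(ds, "pah_dataset"))
  work <- if (ds$imputed) ds else impute_nondetects(ds, "half_lod")
  obs <- work$measurements %>%
    group_by(product_type, congener) %>%
    summarise(observed_mean = mean(value), n = dplyr::n(),
              censor_rate = mean(censored), .groups = "drop")
  targets %>%
    select(product_type, congener, target_mean = mean, target_sd = sd,
           all_nd) %>%
    left_join(obs, by = c("product_type", "congener")) %>%
    mutate(
      se = ifelse(all_nd, NA_real_, target_sd / sqrt(n)),
      z = dplyr::case_when(
        all_nd ~ NA_real_,
        target_sd > 0 ~ (observed_mean - target_mean) / se,
        abs(observed_mean - target_mean) < 1e-12 ~ 0,
        TRUE ~ Inf
      ),
      within_2se = !all_nd & is.finite(z) & abs(z) <= 2
    )
}
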