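#' Sum congener concentrations
#'
#' Arithmetic sum over a congener subset, used for the total PAH16 burden
#' and the EU regulatory PAH4 sum (BaA + Ch + BbF + BaP).
#'
#' @param values Named numeric vector of concentrations (ug/kg), names are
#'   congener abbreviations; values must be post-imputation.
#' @param subset Character vector of congeners to sum.
#' @return Numeric sum in ug/kg.
#' @export
#' @examples
#' congener_sum(c(BaA = 0.06, Ch = 0.26, BbF = 0.04, BaP = 0.11),
#'              c("BaA", "Ch", "BbF", "BaP"))
congener_sum <- function(values, subset) {
  missing_c <- setdiff(subset, names(values))
  if (length(missing_c) > 0) {
    stop("missing congener(s) in values: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values[subset])) {
    stop("values contain NA; impute non-detects first", call. = FALSE)
  }
  sum(values[subset])
}

score_levels <- function(panel) c(panel$abbrev, "sigma_pah16", "pah4")

# single-observation and all-identical groups report sd = 0
sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

new_pah_summary <- function(tbl, panel) {
  tbl <- tbl %>%
    mutate(statistic = factor(statistic, levels = score_levels(panel))) %>%
    arrange(factor(product_type, levels = unique(product_type)), statistic) %>%
    mutate(statistic = as.character(statistic))
  structure(tbl, class = c("pah_summary", class(tbl)), panel = panel)
}

#' Summarize a dataset by product type
#'
#' Computes, for every product type and every congener plus the derived
#' total-PAH16 and PAH4 scores, the mean, standard deviation, minimum and
#' maximum over samples (ug/kg), together with an `"overall"` row. The
#' overall mean of each statistic is the unweighted mean of the group
#' means, its sd is the dispersion of the group means, and its min/max are
#' the extrema of the group minima/maxima, mirroring how survey-level
#' tables aggregate per-product summaries when raw pooling is unavailable.
#'
#' @param ds An imputed [pah_dataset()].
#' @return A `pah_summary`: tibble with columns `product_type`,
#'   `statistic`, `mean`, `sd`, `min`, `max`, `n`.
#' @export
#' @examples
#' ds <- impute_nondetects(generate_dataset(seed = 1))
#' summarize_groups(ds)
summarize_groups <- function(ds) {
  stopifnot(inherits(ds, "pah_dataset"))
  if (!ds$imputed) {
    stop("dataset must be imputed before summarization; ",
         "see impute_nondetects()", call. = FALSE)
  }
  panel <- ds$panel
  p4 <- pah4_members(panel)
  per_sample <- ds$measurements %>%
    group_by(sample_id, product_type) %>%
    summarise(sigma_pah16 = sum(value),
              pah4 = sum(value[congener %in% p4]), .groups = "drop") %>%
    pivot_longer(c("sigma_pah16", "pah4"), names_to = "statistic",
                 values_to = "value")
  long <- ds$measurements %>%
    select(sample_id, product_type, statistic = congener, value) %>%
    bind_rows(per_sample)
  groups <- long %>%
    group_by(product_type, statistic) %>%
    summarise(mean = mean(value), sd = sd0(value), min = min(value),
              max = max(value), n = dplyr::n(), .groups = "drop")
  overall <- groups %>%
    group_by(statistic) %>%
    summarise(sd = sd0(mean), min = min(min), max = max(max), n = sum(n),
              mean = mean(mean), .groups = "drop") %>%
    mutate(product_type = "overall")
  new_pah_summary(bind_rows(groups, overall), panel)
}

#' @export
print.pah_summary <- function(x, ...) {
  cat("<pah_summary> ",
      length(setdiff(unique(x$product_type), "overall")),
      " product types + overall\n", sep = "")
  NextMethod()
}

#' Build a summary table from published group targets
#'
#' Turns the packaged per-product-type target table (group means/SDs and
#' ranges per congener, with `nd` marking non-detected cells) and the
#' published group score rows (total PAH16 and PAH4) into a `pah_summary`.
#' Non-detect cells enter as half the congener's LOD, the same substitution
#' applied to raw measurements, so downstream scoring and aggregation treat
#' printed tables and datasets identically.
#'
#' @param targets Tibble from [load_group_targets()].
#' @param scores Tibble from [load_group_scores()].
#' @param panel A [congener_panel()].
#' @return A `pah_summary` including the `"overall"` row.
#' @export
#' @examples
#' smry <- summary_from_targets()
#' subset(smry, product_type == "overall" & statistic == "sigma_pah16")
summary_from_targets <- function(targets = load_group_targets(),
                                 scores = load_group_scores(),
                                 panel = default_panel()) {
  half <- setNames(panel$lod / 2, panel$abbrev)
  cong <- targets %>%
    mutate(statistic = congener,
           mean = ifelse(is.na(mean), half[congener], mean),
           sd = ifelse(is.na(sd), 0, sd),
           min = ifelse(is.na(min), half[congener], min),
           max = ifelse(is.na(max), half[congener], max),
           n = NA_integer_) %>%
    select(product_type, statistic, mean, sd, min, max, n)
  sc <- scores %>% mutate(n = NA_integer_)
  groups <- bind_rows(cong, sc)
  overall <- groups %>%
    group_by(statistic) %>%
    summarise(sd = sd0(mean), min = min(min), max = max(max),
              n = NA_integer_, mean = mean(mean), .groups = "drop") %>%
    mutate(product_type = "overall")
  new_pah_summary(bind_rows(groups, overall), panel)
}

#' Locate the extreme product types for a statistic
#'
#' @param smry A `pah_summary`.
#' @param statistic `"sigma_pah16"`, `"pah4"`, or a congener abbreviation.
#' @return List with `max_group`, `max_value`, `min_group`, `min_value`
#'   (ug/kg). Ties are broken by first occurrence in table order.
#' @export
extreme_groups <- function(smry, statistic = "sigma_pah16") {
  stopifnot(inherits(smry, "pah_summary"))
  if (!statistic %in% score_levels(attr(smry, "panel"))) {
    stop("unknown statistic: ", statistic, call. = FALSE)
  }
  stat <- statistic
  rows <- smry %>%
    filter(product_type != "overall", .data$statistic == stat)
  if (nrow(rows) < 1) stop("summary has no groups", call. = FALSE)
  i_max <- which.max(rows$mean)
  i_min <- which.min(rows$mean)
  list(max_group = rows$product_type[i_max], max_value = rows$mean[i_max],
       min_group = rows$product_type[i_min], min_value = rows$mean[i_min])
}

#' Check group means against regulatory limits
#'
#' Compares each product type's mean BaP and PAH4 against the EU limits
#' for processed cereal-based infant foods (1 ug/kg each). A group is
#' compliant when its mean is strictly below the limit.
#'
#' @param smry A `pah_summary`.
#' @param limits Named numeric vector with elements `BaP` and `pah4`
#'   (ug/kg), both positive.
#' @return Tibble with per-group means and logical compliance flags.
#' @export
compliance <- function(smry, limits = c(BaP = 1, pah4 = 1)) {
  stopifnot(inherits(smry, "pah_summary"))
  if (any(limits <= 0)) stop("limits must be positive", call. = FALSE)
  smry %>%
    filter(product_type != "overall", statistic %in% c("BaP", "pah4")) %>%
    select(product_type, statistic, mean) %>%
    pivot_wider(names_from = statistic, values_from = mean) %>%
    rename(bap_mean = "BaP", pah4_mean = "pah4") %>%
    mutate(bap_compliant = bap_mean < limits[["BaP"]],
           pah4_compliant = pah4_mean < limits[["pah4"]])
}

#' One-way ANOVA across product types
#'
#' Classical one-way F test of a congener concentration (or a derived
#' score) across product types, the test used to compare contamination
#' between food categories. With two groups the F statistic equals the
#' square of the pooled two-sample t statistic. Degenerate data with zero
#' total variance return F = 0 and p = 1 by convention.
#'
#' @param ds An imputed [pah_dataset()].
#' @param statistic Congener abbreviation, `"sigma_pah16"`, or `"pah4"`.
#' @return List with `f`, `p`, `df1`, `df2`.
#' @export
oneway_anova <- function(ds, statistic = "sigma_pah16") {
  stopifnot(inherits(ds, "pah_dataset"))
  if (!ds$imputed) stop("dataset must be imputed first", call. = FALSE)
  if (!statistic %in% score_levels(ds$panel)) {
    stop("unknown statistic: ", statistic, call. = FALSE)
  }
  p4 <- pah4_members(ds$panel)
  if (statistic %in% ds$panel$abbrev) {
    df <- ds$measurements %>%
      filter(congener == statistic) %>%
      select(product_type, value)
  } else {
    subset_c <- if (statistic == "pah4") p4 else ds$panel$abbrev
    df <- ds$measurements %>%
      filter(congener %in% subset_c) %>%
      group_by(sample_id, product_type) %>%
      summarise(value = sum(value), .groups = "drop") %>%
      select(product_type, value)
  }
  sizes <- table(df$product_type)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need at least 2 groups with at least 2 samples each",
         call. = FALSE)
  }
  k <- length(sizes)
  n_tot <- nrow(df)
  if (sum((df$value - mean(df$value))^2) < .Machine$double.eps * n_tot) {
    return(list(f = 0, p = 1, df1 = k - 1, df2 = n_tot - k))
  }
  fit <- oneway.test(value ~ product_type, data = df, var.equal = TRUE)
  list(f = unname(fit$statistic), p = unname(fit$p.value),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]))
}
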