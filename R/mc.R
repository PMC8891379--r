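#' Monte Carlo configuration
#'
#' @param iterations Number of iterations (default 10000).
#' @param seed Integer seed; mandatory for pipeline reproducibility
#'   (default 20220217).
#' @param percentiles Percentiles to report, in (0, 100).
#' @return List of class `mc_config`.
#' @export
mc_config <- function(iterations = 10000L, seed = 20220217L,
                      percentiles = c(5, 50, 75, 95)) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 percentiles = percentiles),
            class = "mc_config")
}

#' Default distribution specs for the exposure parameters
#'
#' Point masses at the [exposure_params()] defaults, except the intake
#' rate, which carries the scenario's variability as a lognormal with
#' median `IR` and a 95th/50th percentile ratio of `q95_q50` (default 1.5,
#' the dispersion exhibited by the survey's published intake percentiles,
#' which is nearly identical across congeners and therefore attributable
#' to the shared exposure factors rather than the concentrations).
#'
#' @param params An [exposure_params()] supplying the central values.
#' @param q95_q50 95th/50th percentile ratio for the intake rate; set to
#'   `NULL` for an all-point (deterministic) parameter set.
#' @return Named list of [dist_spec()]s (`IR`, `EF`, `ED`, `BW`, `AT`,
#'   `SF`).
#' @export
default_param_dists <- function(params = exposure_params(), q95_q50 = 1.5) {
  ir <- if (is.null(q95_q50)) {
    dist_spec("point", value = params$IR)
  } else {
    dist_spec("lognormal", meanlog = log(params$IR),
              sdlog = log(q95_q50) / qnorm(0.95))
  }
  list(IR = ir,
       EF = dist_spec("point", value = params$EF),
       ED = dist_spec("point", value = params$ED),
       BW = dist_spec("point", value = params$BW),
       AT = dist_spec("point", value = params$AT),
       SF = dist_spec("point", value = params$SF))
}

#' Concentration distribution specs from a summary table
#'
#' Builds one [dist_spec()] per congener from a group's mean (and sd)
#' concentrations. Congeners never detected in any sample (their summary
#' is pinned at half the LOD with zero dispersion) are excluded by
#' default, matching how survey intake tables omit all-non-detect
#' congeners.
#'
#' @param smry A `pah_summary`.
#' @param product_type Group to use (default `"overall"`).
#' @param family `"point"` (default: intake variability is carried by the
#'   exposure-parameter specs) or `"lognormal"` (moment-matched to the
#'   summary mean/sd).
#' @param include_never_detected Keep all-non-detect congeners?
#' @return Named list of dist_specs in panel order (ug/kg scale).
#' @export
conc_specs <- function(smry, product_type = "overall",
                       family = c("point", "lognormal"),
                       include_never_detected = FALSE) {
  stopifnot(inherits(smry, "pah_summary"))
  family <- match.arg(family)
  panel <- attr(smry, "panel")
  pt <- product_type
  rows <- smry %>%
    filter(.data$product_type == pt, statistic %in% panel$abbrev)
  if (nrow(rows) == 0) stop("no such product type: ", pt, call. = FALSE)
  keep <- panel$abbrev
  if (!include_never_detected) {
    nd_all <- never_detected(smry)
    keep <- setdiff(keep, nd_all)
  }
  specs <- lapply(keep, function(cg) {
    m <- rows$mean[rows$statistic == cg]
    s <- rows$sd[rows$statistic == cg]
    if (family == "point" || s <= 0) {
      dist_spec("point", value = m)
    } else {
      dist_spec("lognormal", mean = m, sd = s)
    }
  })
  setNames(specs, keep)
}

#' Congeners never detected in any sample
#'
#' Identified from the overall summary row: an all-non-detect congener has
#' its overall mean pinned at exactly half its LOD with zero dispersion.
#'
#' @param smry A `pah_summary`.
#' @return Character vector of congener abbreviations.
#' @export
never_detected <- function(smry) {
  panel <- attr(smry, "panel")
  half <- setNames(panel$lod / 2, panel$abbrev)
  ov <- smry %>%
    filter(product_type == "overall", statistic %in% panel$abbrev)
  ov$statistic[abs(ov$mean - half[ov$statistic]) < 1e-12 & ov$sd < 1e-12]
}

#' Monte Carlo propagation through the exposure and risk equations
#'
#' Per iteration, draws every congener concentration (ug/kg; negative
#' draws are truncated at 0) and every exposure parameter, then evaluates
#' the TEF-weighted BaP-equivalent concentration, the per-congener
#' estimated daily intake, and the incremental lifetime cancer risk.
#' Percentiles are empirical order statistics with linear interpolation.
#'
#' @param conc_dists Named list of [dist_spec()]s, one per congener, on
#'   the ug/kg scale.
#' @param tefs A [tef_set()] covering the congeners.
#' @param param_dists Named list of dist_specs for `IR`, `EF`, `ED`, `BW`,
#'   `AT`, `SF`; see [default_param_dists()].
#' @param cfg An [mc_config()].
#' @param mode ILCR mode, see [ilcr()].
#' @param return_draws Keep the raw ILCR draws (for histograms)?
#' @return List of class `exposure_mc` with `edi` (tibble: `congener`,
#'   `percentile`, `value` in mg/kg bw/day), `ilcr` (named vector of
#'   percentiles), `ilcr_mean`, `cfg`, and optionally `draws`.
#' @export
#' @examples
#' smry <- summary_from_targets()
#' mc <- run_exposure_mc(conc_specs(smry), cfg = mc_config(iterations = 500))
#' head(mc$edi)
run_exposure_mc <- function(conc_dists, tefs = default_tefs(),
                            param_dists = default_param_dists(),
                            cfg = mc_config(),
                            mode = c("dose_consistent", "as_published"),
                            return_draws = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "mc_config"))
  if (is.null(names(conc_dists)) || any(names(conc_dists) == "")) {
    stop("conc_dists must be a named list of dist_specs", call. = FALSE)
  }
  missing_t <- setdiff(names(conc_dists), names(tefs))
  if (length(missing_t) > 0) {
    stop("no TEF for congener(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  needed <- c("IR", "EF", "ED", "BW", "AT", "SF")
  missing_p <- setdiff(needed, names(param_dists))
  if (length(missing_p) > 0) {
    stop("param_dists is missing: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$iterations < 100) {
    warning("fewer than 100 iterations: tail percentiles will be unstable",
            call. = FALSE)
  }
  n <- cfg$iterations
  congeners <- names(conc_dists)
  with_local_seed(cfg$seed, {
    conc <- vapply(conc_dists, function(s) pmax(draw_dist(s, n), 0),
                   numeric(n))
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, congeners))  # ug/kg
    pars <- lapply(param_dists[needed], draw_dist, n = n)
    conc_mg <- convert_concentration(conc, "ug/kg", "mg/kg")
    factor_d <- pars$IR * pars$EF * pars$ED / (pars$BW * pars$AT)
    edi_draws <- conc_mg * factor_d            # recycled column-wise by row
    bec_draws <- as.vector(conc_mg %*% unclass(tefs)[congeners])
    ilcr_draws <- if (mode == "dose_consistent") {
      bec_draws * factor_d * pars$SF
    } else {
      bec_draws * pars$EF * pars$ED * pars$SF / (pars$BW * pars$AT)
    }
    probs <- cfg$percentiles / 100
    edi_q <- apply(edi_draws, 2, quantile, probs = probs, names = FALSE,
                   type = 7)
    edi_q <- matrix(edi_q, nrow = length(probs),
                    dimnames = list(NULL, congeners))
    edi_tbl <- tibble(
      congener = rep(congeners, each = length(probs)),
      percentile = rep(cfg$percentiles, times = length(congeners)),
      value = as.vector(edi_q)
    )
    ilcr_q <- quantile(ilcr_draws, probs = probs, names = FALSE, type = 7)
    out <- list(
      edi = structure(edi_tbl, congener_order = congeners),
      ilcr = setNames(ilcr_q, paste0("p", cfg$percentiles)),
      ilcr_mean = mean(ilcr_draws),
      cfg = cfg, mode = mode
    )
    if (return_draws) out$draws <- list(ilcr = ilcr_draws)
    structure(out, class = "exposure_mc")
  })
}

#' Rank congeners by an intake percentile
#'
#' Descending order of the EDI values at percentile `q`; ties are broken
#' by the congener order of the table (panel order).
#'
#' @param edi_table Tibble with columns `congener`, `percentile`, `value`
#'   (as produced by [run_exposure_mc()]).
#' @param q Percentile to rank by; must be present in the table.
#' @return Character vector of congeners, most exposed first.
#' @export
rank_by_percentile <- function(edi_table, q = 95) {
  if (!q %in% unique(edi_table$percentile)) {
    stop("percentile ", q, " is not in the table", call. = FALSE)
  }
  rows <- edi_table %>% filter(percentile == q)
  ord <- attr(edi_table, "congener_order")
  if (is.null(ord)) ord <- unique(edi_table$congener)
  rows <- rows[match(ord, rows$congener), ]
  rows$congener[order(-rows$value)]
}

#' Monte Carlo convergence ladder
#'
#' Reruns the exposure simulation at increasing iteration counts (same
#' seed) and reports the maximum relative drift of the EDI percentile
#' table between successive rungs.
#'
#' @inheritParams run_exposure_mc
#' @param ladder Increasing vector of iteration counts (>= 2 rungs).
#' @param seed Seed shared by all rungs.
#' @param percentiles Percentiles tracked for the drift comparison.
#' @return Tibble with columns `iterations` and `drift` (`NA` for the
#'   first rung).
#' @export
convergence_check <- function(conc_dists, tefs = default_tefs(),
                              param_dists = default_param_dists(),
                              ladder = c(1000L, 10000L), seed = 20220217L,
                              percentiles = c(5, 50, 75, 95)) {
  if (length(ladder) < 2) stop("need at least 2 iteration counts",
                               call. = FALSE)
  tables <- lapply(ladder, function(it) {
    run_exposure_mc(conc_dists, tefs, param_dists,
                    mc_config(iterations = it, seed = seed,
                              percentiles = percentiles))$edi
  })
  drift <- c(NA_real_, vapply(seq_len(length(ladder) - 1), function(i) {
    a <- tables[[i]]$value
    b <- tables[[i + 1]]$value
    max(abs(b - a) / pmax(abs(a), .Machine$double.eps))
  }, numeric(1)))
  tibble(iterations = as.integer(ladder), drift = drift)
}
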