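#' Feature matrix for congener/product-type clustering
#'
#' Rows are the panel congeners plus the derived total-PAH16 and PAH4
#' scores; columns are product types; cells are group mean concentrations
#' (ug/kg). Rows are standardized to zero mean and unit variance by
#' default (the heat-map convention), and zero-variance rows — congeners
#' pinned at half-LOD in every group — are dropped, since a correlation
#' distance is undefined for them.
#'
#' @param smry A `pah_summary`.
#' @param standardize Standardize rows to mean 0, sd 1?
#' @param drop_constant Drop zero-variance rows (with a message)?
#' @return Numeric matrix (variables x product types).
#' @export
#' @examples
#' fm <- feature_matrix(summary_from_targets())
#' dim(fm)
feature_matrix <- function(smry, standardize = TRUE, drop_constant = TRUE) {
  stopifnot(inherits(smry, "pah_summary"))
  panel <- attr(smry, "panel")
  wide <- smry %>%
    filter(product_type != "overall") %>%
    select(product_type, statistic, mean) %>%
    pivot_wider(names_from = product_type, values_from = mean)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$statistic
  m <- m[score_levels(panel), , drop = FALSE]
  rv <- apply(m, 1, sd)
  if (drop_constant && any(rv == 0)) {
    message("dropping zero-variance row(s): ",
            paste(rownames(m)[rv == 0], collapse = ", "))
    m <- m[rv > 0, , drop = FALSE]
  }
  if (standardize) {
    m <- t(scale(t(m)))
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}

#' Pearson correlation distance
#'
#' `d(x, y) = 1 - r(x, y)`: 0 for identical (or perfectly correlated)
#' profiles, 2 for exactly anticorrelated ones. Invariant to affine
#' rescaling of each row.
#'
#' @param m Numeric matrix; distances are computed between rows.
#' @return Symmetric matrix with zero diagonal, values in `[0, 2]`.
#' @export
pearson_distance <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 observations per vector",
                        call. = FALSE)
  rv <- apply(m, 1, sd)
  if (any(rv == 0)) {
    stop("zero-variance row(s): ",
         paste(rownames(m)[rv == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - cor(t(m))
  d[d < 0] <- 0  # guard tiny negative rounding
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is
#' the mean of all pairwise inter-cluster dissimilarities.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal) or a `dist`.
#' @return An `hclust` tree.
#' @export
#' @examples
#' fm <- feature_matrix(summary_from_targets())
#' hc <- average_linkage(pearson_distance(fm))
average_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
      stop("dissimilarity matrix must be symmetric", call. = FALSE)
    }
    d <- as.dist(d)
  }
  hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param dendro An `hclust` tree.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(dendro, k) {
  stopifnot(inherits(dendro, "hclust"))
  n_leaves <- length(dendro$order)
  if (k < 1 || k > n_leaves) {
    stop("k must be between 1 and ", n_leaves, call. = FALSE)
  }
  cutree(dendro, k = k)
}

#' Render a report bundle
#'
#' Writes the pipeline outputs available to one directory: the
#' Table-style group summary, the compliance table, the deterministic
#' risk section (JSON), the Monte Carlo percentile tables, the cluster
#' assignments and a heat map with dendrograms, plus run metadata. Stages
#' not supplied are recorded as explicit gaps; tables contain no
#' timestamps, so a rerun with the same inputs is byte-identical.
#'
#' @param path Output directory (created if absent).
#' @param smry A `pah_summary` (required).
#' @param risk Optional `risk_result` from [assess_risk()].
#' @param mc Optional `exposure_mc` from [run_exposure_mc()].
#' @param k Number of clusters for the heat-map cut (default 3).
#' @param seed Seed recorded in the metadata.
#' @return Invisibly, a list with `files` written and `gaps`.
#' @export
render_report <- function(path, smry, risk = NULL, mc = NULL, k = 3,
                          seed = NULL) {
  stopifnot(inherits(smry, "pah_summary"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  gaps <- character(0)
  wr <- function(x, name) {
    f <- file.path(path, name)
    readr::write_tsv(x, f)
    files <<- c(files, f)
  }
  wr(as_tibble(smry), "group_summary.tsv")
  wr(compliance(smry), "compliance.tsv")

  if (!is.null(risk)) {
    f <- file.path(path, "risk.json")
    jsonlite::write_json(list(
      bec_ug_kg = risk$bec_ug_kg,
      contributions = as.list(risk$contributions),
      edi_mg_kg_bw_day = as.list(risk$edi),
      ilcr = risk$ilcr, zone = as.character(risk$zone),
      jecfa_exceeded = risk$jecfa_exceeded, mode = risk$mode
    ), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  } else gaps <- c(gaps, "risk")

  if (!is.null(mc)) {
    wr(mc$edi, "edi_percentiles.tsv")
    wr(tibble(percentile = names(mc$ilcr), value = unname(mc$ilcr)),
       "ilcr_percentiles.tsv")
  } else gaps <- c(gaps, "mc")

  fm <- try(feature_matrix(smry), silent = TRUE)
  if (!inherits(fm, "try-error") && nrow(fm) >= 3) {
    drow <- pearson_distance(fm)
    hc <- average_linkage(drow)
    cl <- cut_clusters(hc, min(k, nrow(fm)))
    wr(tibble(variable = names(cl), cluster = unname(cl)),
       "cluster_assignments.tsv")
    f <- file.path(path, "heatmap.png")
    grDevices::png(f, width = 900, height = 700)
    ph <- try(pheatmap::pheatmap(
      fm, clustering_distance_rows = as.dist(drow),
      clustering_distance_cols = "correlation",
      clustering_method = "average", silent = TRUE), silent = TRUE)
    if (!inherits(ph, "try-error")) grid::grid.draw(ph$gtable)
    grDevices::dev.off()
    files <- c(files, f)
  } else gaps <- c(gaps, "heatmap")

  meta <- list(
    package = "pahrisk",
    version = as.character(utils::packageVersion("pahrisk")),
    seed = seed, gaps = gaps
  )
  f <- file.path(path, "metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, null = "null")
  files <- c(files, f)
  invisible(list(files = files, gaps = gaps))
}
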