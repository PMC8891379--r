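# Brute-force average-linkage (UPGMA) oracle: maintains explicit cluster
# member lists and recomputes every inter-cluster mean distance from the
# original dissimilarities at each step. Returns the cophenetic matrix,
# which characterizes the dendrogram completely.
upgma_cophenetic_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# random symmetric dissimilarity matrix with distinct off-diagonal entries
random_dissimilarity <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 10)
  m + t(m)
}

# wide concentration table written to a temp file; all cells default "nd"
write_conc_fixture <- function(cells = list(), samples = c("s1", "s2"),
                               product_types = rep("rice-based",
                                                   length(samples)),
                               brands = rep("A", length(samples)),
                               panel = default_panel()) {
  wide <- data.frame(sample_id = samples, product_type = product_types,
                     brand = brands, check.names = FALSE,
                     stringsAsFactors = FALSE)
  for (cg in panel$abbrev) wide[[cg]] <- "nd"
  for (nm in names(cells)) {
    sample <- cells[[nm]]$sample
    wide[[nm]][wide$sample_id == sample] <- cells[[nm]]$value
  }
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(wide, path)
  path
}

# per-sample dataset around a single congener for light-weight ANOVA runs
single_congener_dataset <- function(values, groups, congener = "BaP",
                                    panel = default_panel()) {
  m <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(values)),
    product_type = groups, brand = "A", congener = congener,
    value = values, censored = FALSE
  )
  pah_dataset(m, panel, imputed = TRUE)
}
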