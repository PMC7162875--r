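# Sample-level methylome comparison: shared-site level matrices, Pearson
# correlation, PCA on mCG sites, and context-by-feature summaries.

#' Build a shared-site methylation level matrix
#'
#' Rows are cytosine sites of the requested context covered at least
#' `min_cov`-fold in *all* samples (set intersection); columns are samples.
#' Row order is deterministic (chrom, pos, strand).
#'
#' @param tables Named list of methylome tibbles.
#' @param context Sequence context to keep (default `"CpG"`).
#' @param min_cov Minimum coverage per sample (default 5).
#' @return Numeric matrix of levels with `chrom:pos:strand` rownames and a
#'   `sites` attribute holding the site key tibble.
#' @export
build_matrix <- function(tables, context = "CpG", min_cov = 5) {
  if (length(tables) < 2) abort("need at least 2 samples")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  qual <- lapply(tables, function(t) {
    t[t$context == context & (t$mC + t$uC) >= min_cov, ]
  })
  keys <- lapply(qual, function(t) paste(t$chrom, t$pos, t$strand, sep = ":"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) {
    limiting <- names(tables)[which.min(lengths(keys))]
    abort(sprintf(
      "no sites covered >= %d-fold in all samples (limiting sample: %s)",
      min_cov, limiting))
  }
  t1 <- qual[[1]]
  sites <- t1[keys[[1]] %in% shared, c("chrom", "pos", "strand")]
  sites <- arrange(sites, .data$chrom, .data$pos, .data$strand)
  skey <- paste(sites$chrom, sites$pos, sites$strand, sep = ":")
  m <- vapply(seq_along(qual), function(i) {
    qual[[i]]$level[match(skey, keys[[i]])]
  }, numeric(length(skey)))
  dimnames(m) <- list(skey, names(tables))
  attr(m, "sites") <- sites
  m
}

#' Pearson correlation between sample methylomes
#'
#' @param m Level matrix from [build_matrix()].
#' @return Symmetric sample-by-sample correlation matrix with unit diagonal;
#'   entries involving a zero-variance sample are `NA` (reported as
#'   undefined, not silently zero), with a warning.
#' @export
pearson_matrix <- function(m) {
  if (nrow(m) < 2) abort("need at least 2 sites")
  v <- apply(m, 2, var)
  r <- suppressWarnings(cor(m, method = "pearson"))
  if (any(v == 0)) {
    warn(paste("zero-variance sample(s):",
               paste(colnames(m)[v == 0], collapse = ", ")))
    r[v == 0, ] <- NA_real_
    r[, v == 0] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Principal component analysis of sample methylomes
#'
#' Site-wise (row) mean-centering followed by an eigendecomposition of the
#' sample Gram matrix (the dual of site-space PCA); no scaling to unit
#' variance since levels share the `[0, 1]` scale.  Sample coordinates are
#' `eigenvector * sqrt(eigenvalue)`, so inter-sample distances in component
#' space reproduce distances between centred methylation profiles.  Each
#' eigenvector's first nonzero loading is made positive for a deterministic
#' sign convention.
#'
#' @param m Level matrix from [build_matrix()].
#' @param n_comp Number of components (default: all `ncol(m) - 1` informative
#'   ones); more than that is truncated with a warning.
#' @return List with `coordinates` (samples x components),
#'   `var_explained` (fractions over all components, summing to 1) and
#'   `values` (eigenvalues).
#' @export
pca_samples <- function(m, n_comp = NULL) {
  n <- ncol(m)
  if (n < 2) abort("need at least 2 samples")
  k_max <- n - 1L             # row-centering removes one dimension
  if (is.null(n_comp)) n_comp <- k_max
  if (n_comp > k_max) {
    warn(sprintf("only %d informative components; truncating", k_max))
    n_comp <- k_max
  }
  xc <- m - rowMeans(m)
  g <- crossprod(xc)
  e <- eigen(g, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, j]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, j] < 0) vecs[, j] <- -vecs[, j]
  }
  k <- n_comp
  coords <- vecs[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), nrow = k)
  dimnames(coords) <- list(colnames(m), paste0("PC", seq_len(k)))
  list(coordinates = coords,
       var_explained = if (sum(ev) > 0) ev / sum(ev) else ev,
       values = ev)
}

#' Mean methylation by sequence context and feature class
#'
#' Coverage-pooled mean level (`sum(mC) / sum(mC + uC)`) per context for
#' promoters, CpG islands, gene bodies and the whole genome.  Combinations
#' with zero qualifying sites are reported as `NA`, not zero.
#'
#' @param table Methylome tibble.
#' @param genome A `ref_genome` providing the feature annotation.
#' @return Tibble (feature_class, context, n_sites, level).
#' @export
context_feature_summary <- function(table, genome) {
  gr_sites <- GenomicRanges::GRanges(
    table$chrom, IRanges::IRanges(table$pos + 1L, width = 1L))
  classes <- list(promoter = "promoter", CGI = "CGI", gene_body = "gene",
                  genome_wide = NULL)
  rows <- list()
  for (cls in names(classes)) {
    if (is.null(classes[[cls]])) {
      inside <- rep(TRUE, nrow(table))
    } else {
      f <- genome_features(genome, classes[[cls]])
      inside <- if (nrow(f)) {
        gr_f <- GenomicRanges::GRanges(
          f$chrom, IRanges::IRanges(f$start + 1L, f$end))
        IRanges::overlapsAny(gr_sites, gr_f)
      } else rep(FALSE, nrow(table))
    }
    for (ctx in c("CpG", "CHG", "CHH")) {
      sel <- inside & table$context == ctx
      tot <- sum(table$mC[sel] + table$uC[sel])
      rows[[length(rows) + 1L]] <- tibble(
        feature_class = cls, context = ctx, n_sites = sum(sel),
        level = if (sum(sel) > 0 && tot > 0) sum(table$mC[sel]) / tot
                else NA_real_)
    }
  }
  bind_rows(rows)
}
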