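# Multidimensional behavioral severity: z-score standardization, PCA,
# k-means (k = 2) in principal component space, genotype-accuracy
# validation, and genotype-centroid distance in 2-PC space.

#' Named measure sets for severity analysis
#'
#' Three measure sets mirror the three severity models: the behavior
#' battery alone (`battery7`: weight, rotarod day 1, rotarod day 5,
#' open-field distance, open-field center time, marbles buried, nest
#' building day 5); the battery plus distress call counts
#' (`battery_distress9`: the first six battery measures plus distress USV,
#' squeak, and ranging counts); and the battery plus distress and
#' courtship call counts (`battery_usv12`: all seven battery measures,
#' three distress counts, courtship USV and SV counts).
#'
#' @param name `"battery7"`, `"battery_distress9"`, or `"battery_usv12"`.
#' @return Character vector of measure (column) names.
#' @export
measure_set <- function(name = c("battery7", "battery_distress9",
                                 "battery_usv12")) {
  name <- match.arg(name)
  battery <- c("weight", "rotarod_d1", "rotarod_d5", "of_distance",
               "of_center_time", "marbles_buried", "nest_d5")
  distress <- c("distress_usv", "distress_squeak", "distress_ranging")
  courtship <- c("courtship_usv", "courtship_sv")
  switch(name,
    battery7 = battery,
    battery_distress9 = c(battery[1:6], distress),
    battery_usv12 = c(battery, distress, courtship)
  )
}

#' Z-score standardization of a cohort table
#'
#' Each measure is standardized as `z = (x - mean) / sd` using the
#' whole-cohort mean and sample SD, so measures with different units are
#' comparable. Zero-variance columns are dropped with a warning.
#'
#' @param table Numeric data.frame or matrix (mice x measures).
#' @return Numeric matrix of z-scores (every retained column has mean 0 and
#'   sample SD 1), with attribute `dropped` naming removed columns.
#' @export
standardize <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("measures must be numeric", call. = FALSE)
  if (nrow(x) < 2L) stop("standardization needs at least 2 mice", call. = FALSE)
  sds <- apply(x, 2L, sd)
  bad <- !is.finite(sds) | sds < 1e-12
  if (any(bad)) {
    warning("dropping zero-variance measure(s): ",
            paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
    x <- x[, !bad, drop = FALSE]
    sds <- sds[!bad]
  }
  if (ncol(x) == 0L) stop("all measures have zero variance", call. = FALSE)
  z <- scale(x, center = TRUE, scale = sds)
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "dropped") <- colnames(as.matrix(table))[bad]
  z
}

#' Principal component analysis of a standardized table
#'
#' @param z Z-scored matrix from [standardize()] (>= 2 measures, more mice
#'   than 1).
#' @return List with `loadings` (orthonormal, measures x PCs), `scores`
#'   (mice x PCs; centered data projected on the loadings), and
#'   `explained_variance` (percent per PC, summing to 100).
#' @export
principal_components <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) < 2L) stop("PCA needs at least 2 measures", call. = FALSE)
  if (nrow(z) < 2L) stop("PCA needs more than 1 mouse", call. = FALSE)
  fit <- prcomp(z, center = TRUE, scale. = FALSE)
  list(loadings = fit$rotation, scores = fit$x,
       explained_variance = 100 * fit$sdev^2 / sum(fit$sdev^2))
}

#' k-means clustering with k = 2 in PC space
#'
#' Standard k-means with two clusters on the first `n_pcs` score columns,
#' with multiple restarts (lowest within-cluster sum of squares wins) and a
#' seed-controlled, reproducible result.
#'
#' @param scores Score matrix (mice x PCs) from [principal_components()].
#' @param n_pcs Number of leading PCs to cluster on. Default 2 (the
#'   centroid-distance validation is defined in 2-PC space).
#' @param seed Integer seed. Default 1.
#' @param nstart Number of random restarts. Default 50.
#' @return Integer vector of cluster assignments in `{1, 2}`.
#' @export
cluster_two <- function(scores, n_pcs = 2, seed = 1, nstart = 50) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("clustering needs at least 2 mice", call. = FALSE)
  if (n_pcs > ncol(scores)) {
    stop("n_pcs exceeds the number of available PCs", call. = FALSE)
  }
  s <- scores[, seq_len(n_pcs), drop = FALSE]
  if (all(apply(s, 2L, function(col) diff(range(col)) < 1e-12))) {
    warning("all points identical; assigning a single cluster", call. = FALSE)
    return(rep(1L, nrow(s)))
  }
  with_seed(seed, as.integer(kmeans(s, centers = 2L, nstart = nstart)$cluster))
}

#' Genotype-prediction accuracy of a clustering
#'
#' Cluster labels are arbitrary, so accuracy is computed under the
#' cluster-to-genotype mapping that maximizes agreement (both mappings
#' tried); it is therefore always at least 0.5.
#'
#' @param assignments Cluster assignments (two levels at most).
#' @param genotypes Genotype labels of the same length.
#' @return Fraction of mice whose cluster matches their genotype under the
#'   best mapping.
#' @export
genotype_accuracy <- function(assignments, genotypes) {
  if (length(assignments) != length(genotypes)) {
    stop("assignments and genotypes differ in length", call. = FALSE)
  }
  a <- as.integer(factor(assignments))
  g <- as.integer(factor(genotypes))
  max(mean(a == g), mean(a == 3L - g))
}

#' Genotype centroids and centroid distance in 2-PC space
#'
#' Centroids are the per-genotype means of the (PC1, PC2) positions —
#' computed from actual genotype labels, not cluster assignments — and the
#' centroid distance is the Euclidean norm of their difference:
#' `sqrt((x1 - x2)^2 + (y1 - y2)^2)`.
#'
#' @param scores Score matrix (mice x PCs, >= 2 columns).
#' @param genotypes Genotype labels (`WT` / `AS`); both must be present.
#' @return List with `centroid_WT`, `centroid_AS` (named length-2 vectors)
#'   and `distance`.
#' @export
genotype_centroids <- function(scores, genotypes) {
  scores <- as.matrix(scores)
  for (g in c("WT", "AS")) {
    if (!any(genotypes == g)) stop("no mice with genotype ", g, call. = FALSE)
  }
  cen <- function(g) colMeans(scores[genotypes == g, 1:2, drop = FALSE])
  c_wt <- cen("WT")
  c_as <- cen("AS")
  list(centroid_WT = c_wt, centroid_AS = c_as,
       distance = sqrt(sum((c_wt - c_as)^2)))
}

#' Full severity analysis of a cohort table
#'
#' Runs standardize -> PCA -> k-means (k = 2, first `n_pcs` PCs) ->
#' genotype-accuracy validation and genotype-centroid distance. PC1 is
#' oriented so the WT centroid is negative (display stability only;
#' accuracy and distances are sign-invariant).
#'
#' @param table Cohort data.frame with `genotype` (and optionally
#'   `mouse_id`) plus numeric measure columns.
#' @param measures Character vector of measure columns to use; defaults to
#'   every numeric column except identifiers. See [measure_set()].
#' @param n_pcs PCs used for clustering. Default 2.
#' @param seed Seed for k-means restarts. Default 1.
#' @return An object of class `usv_severity`: list with `measures`,
#'   `z` (z-score matrix), `loadings`, `scores`, `explained_variance`,
#'   `clusters`, `accuracy`, `centroid_WT`, `centroid_AS`,
#'   `centroid_distance`, `genotypes`, `mouse_id`.
#' @export
severity_analysis <- function(table, measures = NULL, n_pcs = 2, seed = 1) {
  if (is.null(table$genotype)) stop("table needs a genotype column", call. = FALSE)
  if (is.null(measures)) {
    numeric_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    measures <- setdiff(numeric_cols, c("mouse_id"))
  }
  missing_cols <- setdiff(measures, names(table))
  if (length(missing_cols)) {
    stop("missing measure column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  z <- standardize(table[, measures, drop = FALSE])
  pca <- principal_components(z)
  genotypes <- table$genotype

  # orient PC1: WT centroid negative
  if (mean(pca$scores[genotypes == "WT", 1L]) > 0) {
    pca$scores[, 1L] <- -pca$scores[, 1L]
    pca$loadings[, 1L] <- -pca$loadings[, 1L]
  }

  clusters <- cluster_two(pca$scores, n_pcs = n_pcs, seed = seed)
  cent <- genotype_centroids(pca$scores, genotypes)
  structure(list(
    measures = colnames(z), z = z, loadings = pca$loadings,
    scores = pca$scores, explained_variance = pca$explained_variance,
    clusters = clusters,
    accuracy = genotype_accuracy(clusters, genotypes),
    centroid_WT = cent$centroid_WT, centroid_AS = cent$centroid_AS,
    centroid_distance = cent$distance,
    genotypes = genotypes, mouse_id = table$mouse_id %||% NULL
  ), class = "usv_severity")
}

#' @export
print.usv_severity <- function(x, ...) {
  cat("Severity analysis:", length(x$genotypes), "mice,",
      length(x$measures), "measures\n")
  cat(sprintf("  PC1 %.1f%% / PC2 %.1f%% of variance\n",
              x$explained_variance[1], x$explained_variance[2]))
  cat(sprintf("  genotype accuracy %.1f%% (%d/%d)\n", 100 * x$accuracy,
              round(x$accuracy * length(x$genotypes)), length(x$genotypes)))
  cat(sprintf("  centroid distance %.2f PC units\n", x$centroid_distance))
  invisible(x)
}
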