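metric_columns <- c("tac_sa", "rt_h", "t2r_h", "vi", "mnsd_scaled")

#' Log / centre / scale normalization of a metric table
#'
#' Each metric column is log-transformed (with a per-column offset of half the
#' smallest positive value when zeros are present, since S_A and T2R can be
#' exactly 0 on idealized paths), centred on its mean, and divided by its
#' standard deviation (`scale = "sd"`, the conventional unit-variance scaling)
#' or by its variance (`scale = "var"`). The fitted offsets, means and scale
#' factors are stored so held-out rows (e.g. simulated reference movers in
#' joint mode) can be projected identically.
#'
#' @param profiles a metric table (from [metric_table()]) containing the five
#'   metric columns.
#' @param columns metric columns to use.
#' @param scale `"sd"` (default) or `"var"`.
#' @return An object of class `metric_norm`: list with the normalized matrix
#'   `M` (rownames = individual ids) and the per-column parameters.
#' @export
normalize_metrics <- function(profiles, columns = metric_columns,
                              scale = c("sd", "var")) {
  scale <- match.arg(scale)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  missing_cols <- setdiff(columns, names(profiles))
  if (length(missing_cols)) stop("missing metric columns: ",
                                 paste(missing_cols, collapse = ", "))
  X <- as.matrix(profiles[, columns, drop = FALSE])
  if (any(X < 0)) stop("metrics must be non-negative for the log transform")
  eps <- apply(X, 2, function(v) {
    if (any(v == 0)) {
      pos <- v[v > 0]
      if (length(pos) == 0L) 1e-12 else min(pos) / 2
    } else 0
  })
  L <- log(sweep(X, 2, eps, "+"))
  ctr <- colMeans(L)
  sds <- apply(L, 2, stats::sd)
  if (any(sds == 0))
    stop("metric constant across individuals (zero scale): ",
         paste(columns[sds == 0], collapse = ", "))
  sc <- if (scale == "sd") sds else sds^2
  M <- sweep(sweep(L, 2, ctr, "-"), 2, sc, "/")
  rownames(M) <- profiles$individual_id
  structure(list(M = M, columns = columns, eps = eps, center = ctr,
                 scale_factor = sc, scale = scale), class = "metric_norm")
}

#' Project new metric rows through fitted normalization parameters
#' @param object a `metric_norm`.
#' @param newdata a metric table with the same metric columns.
#' @param ... unused.
#' @return A matrix with one normalized row per row of `newdata`.
#' @export
predict.metric_norm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$columns, drop = FALSE])
  L <- log(sweep(X, 2, object$eps, "+"))
  M <- sweep(sweep(L, 2, object$center, "-"), 2, object$scale_factor, "/")
  rownames(M) <- newdata$individual_id
  M
}

#' Broken-stick expected variance proportions
#'
#' \eqn{b_k = (1/p) \sum_{i=k}^{p} 1/i}: the expected proportion of the k-th
#' largest piece of a unit stick broken at p - 1 uniform random points. A
#' principal component is considered non-random while its observed variance
#' proportion exceeds this expectation.
#'
#' @param p number of variables.
#' @return Numeric vector of length `p`, strictly decreasing, summing to 1.
#' @export
broken_stick <- function(p) {
  vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, 0)
}

#' PCA with broken-stick component retention
#'
#' Eigendecomposition of the covariance of the normalized metric matrix
#' (via [stats::prcomp()]); components 1..K are retained where K is the
#' largest index such that every variance proportion up to K exceeds its
#' broken-stick expectation (contiguously from the first component), but
#' never fewer than `min_retain` components. The default floor of two
#' reflects that the movement-syndrome classification operates in a
#' (at least) two-dimensional component space (PC1-PC2), with the minor axes
#' adding no informative cluster structure.
#'
#' @param norm a `metric_norm` (or a plain numeric matrix).
#' @param min_retain minimum number of components to retain (default 2,
#'   capped at the number of available components).
#' @return A list of class `pca_bs`: `loadings`, `eigenvalues`, `proportion`,
#'   `broken_stick`, `n_retained`, `scores` (retained columns), plus the full
#'   score matrix `scores_full`.
#' @export
pca_broken_stick <- function(norm, min_retain = 2) {
  M <- if (inherits(norm, "metric_norm")) norm$M else as.matrix(norm)
  if (nrow(M) < 3L) stop("need at least 3 rows for PCA")
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  p <- ncol(M)
  bs <- broken_stick(p)
  nev <- length(ev)
  above <- prop > bs[seq_len(nev)]
  k <- if (above[1]) max(which(cumsum(!above) == 0)) else 1L
  k <- min(max(k, min_retain), nev, p)
  structure(list(loadings = pc$rotation, eigenvalues = ev, proportion = prop,
                 broken_stick = bs, n_retained = k,
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 scores_full = pc$x), class = "pca_bs")
}

#' Ward hierarchical clustering of PC scores
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean distances,
#' merging at each stage the pair of clusters whose fusion least increases
#' the total within-cluster sum of squares (`stats::hclust`, method
#' `"ward.D2"`).
#'
#' @param scores numeric matrix of retained principal-component scores (or a
#'   `pca_bs` object).
#' @return A list of class `cluster_tree`: the `hclust` object plus leaf
#'   labels; bootstrap support is attached by [bootstrap_support()].
#' @export
ward_cluster <- function(scores) {
  if (inherits(scores, "pca_bs")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  structure(list(hclust = hc, labels = hc$labels %||% as.character(seq_len(nrow(scores))),
                 support = NULL), class = "cluster_tree")
}

# leaf label sets of every internal node, as canonical strings
node_leaf_sets <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    members <- integer(0)
    for (j in 1:2) {
      v <- hc$merge[m, j]
      members <- c(members, if (v < 0) -v else sets[[v]])
    }
    sets[[m]] <- sort(members)
  }
  lapply(sets, function(s) paste(sort(labs[s]), collapse = "\r"))
}

#' Multiscale bootstrap support for cluster-tree nodes
#'
#' Feature (metric-column) resampling at a set of scales spanning 1: at scale
#' r, ceil(r * p) columns are drawn with replacement, the
#' normalize-PCA-Ward pipeline is re-run, and each original node's BP at that
#' scale is the fraction of replicates whose tree contains the same leaf set.
#' The approximately-unbiased (AU) value is obtained from the BP-versus-scale
#' curve by the standard two-parameter normal-quantile fit
#' (qnorm(1 - BP) = v * sqrt(r) + c / sqrt(r), AU = 1 - pnorm(v - c)).
#' With only five metric columns the support values are coarse; they order
#' nodes by stability rather than providing sharp significance.
#'
#' @param profiles the metric table the tree was built from.
#' @param tree a `cluster_tree` from the same profiles.
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param scales resampling ratios; must include 1.
#' @param seed RNG seed.
#' @param columns metric columns.
#' @param scale_mode normalization scale flag, as in [normalize_metrics()].
#' @return The `cluster_tree` with a `support` data.frame (node, bp, au).
#' @export
bootstrap_support <- function(profiles, tree, n_boot = 1000,
                              scales = seq(0.5, 1.4, by = 0.1), seed = 1,
                              columns = metric_columns, scale_mode = "sd") {
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!any(abs(scales - 1) < 1e-8)) stop("scales must include r = 1")
  set.seed(seed)
  hc <- tree$hclust
  orig_sets <- unlist(node_leaf_sets(hc))
  p <- length(columns)
  counts <- matrix(0, nrow = length(orig_sets), ncol = length(scales))
  for (si in seq_along(scales)) {
    p_star <- as.integer(ceiling(scales[si] * p))
    for (b in seq_len(n_boot)) {
      cols <- sample(columns, p_star, replace = TRUE)
      rep_tree <- tryCatch({
        nm <- normalize_metrics(profiles, columns = cols, scale = scale_mode)
        # duplicated resampled columns make colnames non-unique; normalize
        # handles them as independent columns
        pcx <- pca_broken_stick(nm)
        ward_cluster(pcx$scores)
      }, error = function(e) NULL)
      if (is.null(rep_tree)) next
      rep_sets <- unlist(node_leaf_sets(rep_tree$hclust))
      counts[, si] <- counts[, si] + (orig_sets %in% rep_sets)
    }
  }
  bp <- counts / n_boot
  at1 <- which(abs(scales - 1) < 1e-8)[1]
  au <- vapply(seq_len(nrow(bp)), function(i) fit_au(bp[i, ], scales, n_boot), 0)
  tree$support <- data.frame(node = seq_along(orig_sets),
                             bp = bp[, at1], au = au)
  tree$bp_by_scale <- bp
  tree$scales <- scales
  tree
}

# two-parameter fit of the multiscale BP curve -> AU value
fit_au <- function(bp, scales, n_boot) {
  eps <- 1 / (2 * n_boot)
  if (all(bp >= 1 - 1e-12)) return(1)
  if (all(bp <= 1e-12)) return(0)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  tau <- sqrt(scales)
  z <- stats::qnorm(1 - bpc)
  # weighted least squares, binomial weights as in the standard procedure
  w <- n_boot * stats::dnorm(z)^2 / pmax(bpc * (1 - bpc), 1e-10)
  X <- cbind(tau, 1 / tau)
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  if (!all(is.finite(c(v, cc)))) return(mean(bp))
  unname(1 - stats::pnorm(v - cc))
}

#' Cut a cluster tree
#'
#' Default rule: cut at the largest gap between successive merge heights,
#' measured on the log scale (i.e. the largest ratio of successive heights),
#' since Ward merge heights grow multiplicatively with cluster size and
#' separation. The search is restricted to cuts yielding between 2 and n/2
#' clusters (a partition into more than n/2 groups is not a clustering).
#' Alternatively a fixed number of clusters `k` can be requested.
#'
#' @param tree a `cluster_tree`.
#' @param k fixed number of clusters, or `NULL` (default) for the
#'   largest-gap rule.
#' @return Named integer vector of cluster memberships.
#' @export
cut_tree <- function(tree, k = NULL) {
  hc <- tree$hclust
  n <- length(hc$order)
  if (is.null(k)) {
    h <- hc$height
    if (length(h) < 2L) k <- 2L
    else {
      # cutting between merges m and m+1 leaves n - m clusters
      m_range <- which((n - seq_len(length(h) - 1L)) >= 2 &
                       (n - seq_len(length(h) - 1L)) <= max(2, floor(n / 2)))
      gaps <- log(pmax(h[m_range + 1L], 1e-300)) - log(pmax(h[m_range], 1e-300))
      k <- n - m_range[which.max(gaps)]
    }
  }
  stats::cutree(hc, k = k)
}

#' Label clusters by their simulated reference members
#'
#' Cuts the tree (largest-gap rule by default) and labels each cluster by the
#' majority syndrome among its reference (simulated) members; ties give
#' `"ambiguous"`, clusters without references give `"unclassified"`.
#'
#' @param tree a `cluster_tree` whose leaves include the reference ids.
#' @param reference_syndromes named character vector: reference individual id
#'   -> syndrome.
#' @param k optional fixed number of clusters (see [cut_tree()]).
#' @return A data.frame of class `syndrome_assignment`: `individual_id`,
#'   `cluster`, `syndrome`, `is_reference`.
#' @export
assign_syndromes <- function(tree, reference_syndromes, k = NULL) {
  cl <- cut_tree(tree, k = k)
  ids <- names(cl)
  is_ref <- ids %in% names(reference_syndromes)
  if (!any(is_ref)) warning("no reference individuals in the tree; all unclassified")
  lab_of <- vapply(sort(unique(cl)), function(g) {
    refs <- reference_syndromes[ids[cl == g & is_ref]]
    if (length(refs) == 0L) return("unclassified")
    tab <- sort(table(refs), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
  }, "")
  out <- data.frame(individual_id = ids, cluster = unname(cl),
                    syndrome = lab_of[cl], is_reference = is_ref,
                    stringsAsFactors = FALSE)
  class(out) <- c("syndrome_assignment", "data.frame")
  out
}

#' Export a cluster tree as Newick with support labels
#'
#' @param tree a `cluster_tree`, ideally after [bootstrap_support()].
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  if (!is.null(tree$support)) {
    # ape internal node numbering follows hclust merge order via as.phylo
    phy$node.label <- sprintf("au%.2f_bp%.2f", rev(tree$support$au),
                              rev(tree$support$bp))
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Run the syndrome-classification pipeline
#'
#' Validation mode (`profiles_empirical = NULL`): normalization and PCA are
#' fitted on the simulated reference profiles and the reference set is
#' clustered and self-labelled. Joint mode: normalization and PCA are fitted
#' on the empirical profiles only; reference profiles are projected through
#' the stored parameters and the combined score matrix is clustered, so
#' empirical individuals inherit the syndrome of the references they co-cluster
#' with.
#'
#' @param profiles_reference metric table of simulated reference movers
#'   (must carry a `species` column naming the syndrome).
#' @param profiles_empirical optional metric table of empirical individuals.
#' @param n_boot multiscale-bootstrap replicates (0 skips bootstrap support).
#' @param k fixed cluster count for the cut. The default (`NULL`) follows
#'   the reference-cohort override: when the tree consists of reference
#'   movers only (validation mode), `k` is the number of reference
#'   syndromes; otherwise the largest-gap rule decides. Pass `k = "gap"` to
#'   force the gap rule.
#' @param min_retain minimum retained components. Default: 2 in joint mode;
#'   in validation mode, one less than the number of reference syndromes
#'   (four syndromes span a three-dimensional discriminant space).
#' @param seed RNG seed for the bootstrap.
#' @param scale_mode normalization scaling (see [normalize_metrics()]).
#' @param out_dir optional directory; when given, writes `metrics.tsv`,
#'   `pca_loadings.tsv`, `scores.tsv`, `assignments.csv` and `dendrogram.nwk`.
#' @return A list of class `syndrome_pipeline`: `norm`, `pca`, `tree`,
#'   `assignment` (cut per `k`), `gap_k` (cluster count the largest-gap rule
#'   would give), `profiles`.
#' @export
run_pipeline <- function(profiles_reference, profiles_empirical = NULL,
                         n_boot = 0, k = NULL, min_retain = NULL, seed = 1,
                         scale_mode = "sd", out_dir = NULL) {
  ref_syn <- stats::setNames(profiles_reference$species,
                             profiles_reference$individual_id)
  validation <- is.null(profiles_empirical)
  if (is.null(min_retain))
    min_retain <- if (validation) max(2L, length(unique(ref_syn)) - 1L) else 2L
  if (is.null(k)) {
    k <- if (validation) length(unique(ref_syn)) else "gap"
  }
  if (identical(k, "gap")) k <- NULL
  if (validation) {
    norm <- normalize_metrics(profiles_reference, scale = scale_mode)
    M <- norm$M
    all_profiles <- profiles_reference
  } else {
    if (nrow(profiles_empirical) + nrow(profiles_reference) < 3L)
      stop("need at least 3 individuals")
    norm <- normalize_metrics(profiles_empirical, scale = scale_mode)
    M <- rbind(norm$M, predict(norm, profiles_reference))
    all_profiles <- rbind(profiles_empirical[names(profiles_reference)],
                          profiles_reference)
  }
  pca <- pca_broken_stick(norm, min_retain = min_retain)
  scores <- if (validation) pca$scores else
    (M %*% pca$loadings)[, seq_len(pca$n_retained), drop = FALSE]
  tree <- ward_cluster(scores)
  if (n_boot > 0)
    tree <- bootstrap_support(all_profiles, tree, n_boot = n_boot, seed = seed,
                              scale_mode = scale_mode)
  assignment <- assign_syndromes(tree, ref_syn, k = k)
  gap_k <- length(unique(cut_tree(tree)))
  res <- structure(list(norm = norm, pca = pca, tree = tree, scores = scores,
                        assignment = assignment, gap_k = gap_k,
                        profiles = all_profiles),
                   class = "syndrome_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metric_table(res$profiles, file.path(out_dir, "metrics.tsv"))
  load_tab <- rbind(res$pca$loadings,
                    `Cumulative % Variance` = 100 * cumsum(res$pca$proportion))
  utils::write.table(round(load_tab, 4), file.path(out_dir, "pca_loadings.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(round(res$scores, 6), file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.csv(res$assignment, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)
  write_tree_newick(res$tree, file.path(out_dir, "dendrogram.nwk"))
  invisible(out_dir)
}
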