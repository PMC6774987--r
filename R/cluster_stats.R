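# Leaf sets of every internal node of an hclust tree, as integer indices into
# the label order; canonical node ids are the sorted indices joined by ",".
hclust_nodesets <- function(merge) {
  n_nodes <- nrow(merge)
  sets <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    l <- merge[k, 1]; r <- merge[k, 2]
    sets[[k]] <- c(if (l < 0) -l else sets[[l]],
                   if (r < 0) -r else sets[[r]])
  }
  lapply(sets, sort.int)
}

nodeset_ids <- function(merge) {
  vapply(hclust_nodesets(merge), paste, character(1), collapse = ",")
}

#' Average-linkage (UPGMA) clustering
#'
#' Builds the standard UPGMA merge tree: at each step the two clusters with
#' the smallest average pairwise distance are merged, at a height equal to
#' that average. Heights are therefore non-decreasing and the tree-implied
#' (cophenetic) distances are ultrametric.
#'
#' @param distances symmetric numeric matrix with zero diagonal (or a
#'   `dist`), labelled.
#' @return A `supported_dendrogram`: list with the `hclust` tree, the input
#'   distance matrix, and an (initially empty) node-support table.
#' @seealso [multiscale_bootstrap()] to attach AU/BP/SE support.
#' @export
upgma <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-9))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12)) stop("distance diagonal must be 0")
  if (is.null(rownames(distances)))
    rownames(distances) <- colnames(distances) <- paste0("item", seq_len(nrow(distances)))
  h <- hclust(as.dist(distances), method = "average")
  support <- data.frame(node = nodeset_ids(h$merge),
                        leaves = vapply(hclust_nodesets(h$merge), function(s)
                          paste(h$labels[s], collapse = ";"), character(1)),
                        height = h$height,
                        au = NA_real_, bp = NA_real_, se = NA_real_,
                        unseen = FALSE, stringsAsFactors = FALSE)
  structure(list(hclust = h, distances = distances, support = support,
                 bootstrap = NULL),
            class = "supported_dendrogram")
}

#' @export
print.supported_dendrogram <- function(x, ...) {
  cat("supported_dendrogram:", length(x$hclust$labels), "leaves,",
      nrow(x$support), "internal nodes")
  if (!anyNA(x$support$au))
    cat(";", sum(x$support$au > 0.95), "node(s) with AU > 0.95")
  cat("\n")
  invisible(x)
}

#' Multiscale-bootstrap node support (AU/BP/SE) for a UPGMA tree
#'
#' Clusters the LSI matrix with average linkage and attaches, to every
#' internal node, the raw bootstrap probability (BP), the approximately
#' unbiased probability (AU) from multiscale-bootstrap extrapolation, and the
#' standard error of AU.
#'
#' Each item's profile is its vector of distances (`1 - LSI`) to every item.
#' At each scale ratio `r`, `ceiling(r * m)` of the `m` profile coordinates
#' are resampled with replacement `B` times; items are reclustered (average
#' linkage on Euclidean profile distance) and each original node's recovery
#' frequency `BP_r` is recorded. Per node, `qnorm(1 - BP_r)` is regressed on
#' `(sqrt(r), 1/sqrt(r))` by weighted least squares with binomial weights,
#' giving signed distance `v` and curvature `c`; then `AU = 1 - pnorm(v - c)`
#' and the AU standard error follows from the fit covariance by the delta
#' method. BP is reported as the raw recovery frequency at the scale closest
#' to 1.
#'
#' @param sim a `similarity_matrix` (entries in \[0, 1\], unit diagonal).
#' @param scales bootstrap scale ratios spanning 1; default ten values
#'   0.5-1.4.
#' @param B bootstrap replicates per scale (>= 100).
#' @param seed integer seed; identical seed and inputs give identical
#'   support values.
#' @param profiles optional explicit feature-profile matrix (rows =
#'   resampled coordinates, one column per item, columns matching the labels
#'   of `sim`). This sets the resampling axis when the similarity matrix was
#'   computed from underlying per-item feature vectors; by default each
#'   item's distance profile serves as its feature vector. The AU
#'   extrapolation is asymptotic in the number of profile rows, so support
#'   values from the short default profiles are the more approximate.
#' @return A `supported_dendrogram` whose `support` table has columns
#'   `node`, `leaves`, `height`, `au`, `bp`, `se`, `unseen`. Nodes never
#'   recovered in any replicate at any scale get `au = 0` and `unseen = TRUE`.
#'   Observed frequencies of 0 or 1 are clipped to `1/(2B)` and `1 - 1/(2B)`
#'   before the probit transform.
#' @references Shimodaira (2002) Syst. Biol. 51:492-508 (multiscale
#'   bootstrap and the AU p-value); Suzuki & Shimodaira (2006)
#'   Bioinformatics 22:1540-1542.
#' @export
multiscale_bootstrap <- function(sim, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000, seed = 1, profiles = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (B < 100) stop("B must be >= 100")
  if (any(scales <= 0)) stop("scales must be positive")
  D <- 1 - unclass(sim)
  diag(D) <- 0
  tree <- upgma(D)
  if (is.null(profiles)) {
    X <- D               # default: item profiles = distance rows
  } else {
    X <- as.matrix(profiles)
    if (ncol(X) != nrow(D) || !setequal(colnames(X), rownames(D)))
      stop("profiles must have one column per item of `sim`")
    X <- X[, rownames(D), drop = FALSE]
  }
  base_ids <- tree$support$node
  n_nodes <- length(base_ids)
  m <- nrow(X)           # resampled coordinates
  set.seed(as.integer(seed))
  counts <- matrix(0L, n_nodes, length(scales))
  for (si in seq_along(scales)) {
    m_r <- ceiling(scales[si] * m)
    hits <- integer(n_nodes)
    for (b in seq_len(B)) {
      rows <- sample.int(m, m_r, replace = TRUE)
      hb <- hclust(dist(t(X[rows, , drop = FALSE])), method = "average")
      hits <- hits + (base_ids %in% nodeset_ids(hb$merge))
    }
    counts[, si] <- hits
  }
  fit <- au_from_counts(counts, scales, B)
  at1 <- which.min(abs(scales - 1))
  tree$support$au <- fit$au
  tree$support$bp <- counts[, at1] / B
  tree$support$se <- fit$se
  tree$support$unseen <- rowSums(counts) == 0L
  tree$support$au[tree$support$unseen] <- 0
  tree$bootstrap <- list(scales = scales, B = B, seed = seed,
                         counts = counts)
  tree
}

# Probit-WLS multiscale fit: counts is nodes x scales. Returns AU and its
# delta-method standard error per node.
au_from_counts <- function(counts, scales, B) {
  lo <- 1 / (2 * B); hi <- 1 - lo
  sq <- sqrt(scales); isq <- 1 / sq
  au <- se <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    # degenerate nodes: recovered in every replicate at every scale (or in
    # none) leave the probit regression unidentified -- support is certain
    if (all(counts[i, ] == B)) { au[i] <- 1; se[i] <- 0; next }
    if (all(counts[i, ] == 0L)) { au[i] <- 0; se[i] <- 0; next }
    bp <- pmin(pmax(counts[i, ] / B, lo), hi)
    z <- qnorm(1 - bp)
    w <- B * dnorm(z)^2 / (bp * (1 - bp))
    fit <- lm(z ~ 0 + sq + isq, weights = w)
    v <- unname(coef(fit)[1]); cc <- unname(coef(fit)[2])
    au[i] <- 1 - pnorm(v - cc)
    vc <- stats::vcov(fit)
    var_vc <- vc[1, 1] + vc[2, 2] - 2 * vc[1, 2]
    se[i] <- dnorm(v - cc) * sqrt(max(var_vc, 0))
  }
  list(au = pmin(pmax(au, 0), 1), se = se)
}

#' Stable clusters (highest-level nodes above an AU threshold)
#'
#' Returns the maximal internal nodes whose AU support exceeds the threshold:
#' a qualifying node nested inside a larger qualifying node is not reported
#' separately, and the root never is. These are the boxed clusters used as
#' evidence when linking stopover singers to wintering grounds.
#'
#' @param tree a `supported_dendrogram` with support values.
#' @param au_threshold AU cutoff (default 0.95).
#' @return A list of character vectors of leaf labels (possibly empty), of
#'   class `stable_cluster_set`.
#' @export
stable_clusters <- function(tree, au_threshold = 0.95) {
  stopifnot(inherits(tree, "supported_dendrogram"))
  if (anyNA(tree$support$au))
    stop("tree has no support values; run multiscale_bootstrap() first")
  sets <- hclust_nodesets(tree$hclust$merge)
  n <- length(tree$hclust$labels)
  ok <- which(tree$support$au > au_threshold &
                lengths(sets) < n)   # exclude the root
  keep <- ok[vapply(ok, function(i)
    !any(vapply(ok, function(j)
      i != j && all(sets[[i]] %in% sets[[j]]), logical(1))), logical(1))]
  structure(lapply(keep, function(i) tree$hclust$labels[sets[[i]]]),
            au = tree$support$au[keep], class = "stable_cluster_set")
}

#' @export
print.stable_cluster_set <- function(x, ...) {
  cat("stable_cluster_set:", length(x), "cluster(s)\n")
  for (i in seq_along(x))
    cat(sprintf("  [AU=%.3f] %s\n", attr(x, "au")[i],
                paste(x[[i]], collapse = ", ")))
  invisible(x)
}

#' Cophenetic correlation coefficient (CCC)
#'
#' Pearson correlation between the original pairwise distances and the
#' tree-implied (cophenetic) distances; values above 0.8 indicate the
#' dendrogram represents the associations in the data well. Equals 1 exactly
#' when the input distances are ultrametric.
#'
#' @param tree a `supported_dendrogram`.
#' @param distances the distance matrix the tree was built from (defaults to
#'   the matrix stored in `tree`).
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(tree, distances = tree$distances) {
  stopifnot(inherits(tree, "supported_dendrogram"))
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (nrow(distances) < 3L)
    stop("cophenetic correlation needs at least 3 items")
  labs <- tree$hclust$labels
  d0 <- as.dist(distances[labs, labs])
  dc <- cophenetic(tree$hclust)
  # degenerate matrices (e.g. all items identical) leave Pearson undefined;
  # when the tree reproduces the distances exactly the fit is still perfect
  if (stats::sd(d0) == 0 || stats::sd(dc) == 0) {
    if (isTRUE(all.equal(as.numeric(d0), as.numeric(dc)))) return(1)
    return(NA_real_)
  }
  cor(d0, dc)
}

quote_newick <- function(label) {
  ifelse(grepl("[^A-Za-z0-9_.-]", label),
         paste0("'", gsub("'", "''", label), "'"),
         label)
}

#' Export a supported dendrogram as annotated Newick
#'
#' Branch lengths follow the usual hclust-to-phylogram convention (leaf depth
#' = merge height / 2, so two leaves merging at height 0.4 get branches of
#' 0.2). Internal nodes carry `AU=..|BP=..` labels when support is present.
#' Leaf labels containing spaces or other reserved characters are
#' single-quoted; the output parses in standard Newick readers (e.g.
#' `ape::read.tree`).
#'
#' @param tree a `supported_dendrogram`.
#' @param path optional file to write to.
#' @param digits digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "supported_dendrogram"))
  h <- tree$hclust
  has_support <- !anyNA(tree$support$au)
  node_label <- if (has_support)
    sprintf("AU=%.2f|BP=%.2f", tree$support$au, tree$support$bp)
  else rep("", nrow(tree$support))
  half <- h$height / 2
  render <- function(node, parent_half) {
    if (node < 0) {
      lab <- quote_newick(h$labels[-node])
      return(paste0(lab, ":", format(parent_half, digits = digits)))
    }
    inner <- paste(render(h$merge[node, 1], half[node]),
                   render(h$merge[node, 2], half[node]), sep = ",")
    paste0("(", inner, ")", node_label[node], ":",
           format(parent_half - half[node], digits = digits))
  }
  root <- nrow(h$merge)
  nwk <- paste0("(",
                render(h$merge[root, 1], half[root]), ",",
                render(h$merge[root, 2], half[root]),
                ")", node_label[root], ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Write the node-support table as CSV
#'
#' Columns `node_id`, `leaves`, `height`, `au`, `bp`, `se`.
#'
#' @param tree a `supported_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_support <- function(tree, path) {
  stopifnot(inherits(tree, "supported_dendrogram"))
  out <- tree$support[c("node", "leaves", "height", "au", "bp", "se")]
  names(out)[1] <- "node_id"
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
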