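# Hierarchical clustering (UPGMA), PCA, multiscale-bootstrap AU cluster
# support, and ANOVA group comparison with Holm adjustment.

#' Euclidean distance between sample rows
#'
#' Missing cells (e.g. perturbation scores of segments a sample did not
#' amplify) are imputed by the column mean before computing distances;
#' imputation is reported. Columns that are missing everywhere are dropped.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @return \code{\link[stats]{dist}} object.
#' @export
euclidean_distance <- function(x) {
  x <- as.matrix(x)
  if (any(rowSums(!is.na(x)) == 0)) {
    stop("validation error: a sample row has no observed features")
  }
  all_na_col <- colSums(!is.na(x)) == 0
  if (any(all_na_col)) {
    warning(sum(all_na_col), " all-missing feature column(s) dropped")
    x <- x[, !all_na_col, drop = FALSE]
  }
  if (anyNA(x)) {
    message(sum(is.na(x)), " missing cell(s) imputed by column mean")
    for (j in seq_len(ncol(x))) {
      na <- is.na(x[, j])
      if (any(na)) x[na, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  stats::dist(x, method = "euclidean")
}

# member label sets for every internal node of an hclust-style merge matrix
merge_members <- function(merge, labels) {
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    pick <- function(m) if (m < 0) labels[-m] else members[[m]]
    members[[i]] <- sort(c(pick(merge[i, 1]), pick(merge[i, 2])),
                         method = "radix")
  }
  members
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' unweighted mean of all cross-pair distances. Returns an annotated
#' dendrogram (AU/BP slots empty until \code{\link{multiscale_bootstrap_au}}
#' fills them).
#'
#' @param d a \code{\link[stats]{dist}} object or symmetric distance matrix
#'   with labels.
#' @return object of class \code{"annotated_dendrogram"}: list with
#'   \code{merge}, \code{height}, \code{labels}, \code{order} (as in
#'   \code{\link[stats]{hclust}}), \code{clusters} (member label sets per
#'   internal node), \code{au}, \code{bp} (NULL until bootstrapped) and the
#'   underlying \code{hclust} object.
#' @export
average_linkage <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 2L) stop("validation error: need at least two samples")
  if (anyNA(d) || any(!is.finite(d))) {
    stop("validation error: non-finite distances")
  }
  hc <- stats::hclust(d, method = "average")
  if (is.null(hc$labels)) hc$labels <- as.character(seq_len(attr(d, "Size")))
  structure(
    list(merge = hc$merge, height = hc$height, labels = hc$labels,
         order = hc$order, clusters = merge_members(hc$merge, hc$labels),
         au = NULL, bp = NULL, hclust = hc),
    class = "annotated_dendrogram"
  )
}

#' @export
print.annotated_dendrogram <- function(x, ...) {
  cat(sprintf("Average-linkage dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  if (!is.null(x$au)) {
    cat("Cluster support (AU / BP):\n")
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  {%s}: AU=%s BP=%s\n",
                  paste(x$clusters[[i]], collapse = ","),
                  format(round(x$au[i], 3)), format(round(x$bp[i], 3))))
    }
  }
  invisible(x)
}

#' Principal component analysis of a sample matrix
#'
#' Thin wrapper around \code{\link[stats]{prcomp}} that reports
#' explained-variance fractions (non-increasing, summing to 1). Defaults to
#' centered, unscaled rows: perturbation scores share units (percent), so no
#' per-feature standardization is applied unless requested.
#'
#' @param x numeric matrix, samples in rows.
#' @param center center columns (default TRUE).
#' @param unit_scale scale columns to unit variance (default FALSE).
#' @return list with \code{scores} (samples x components),
#'   \code{var_explained}, \code{sdev} and \code{rotation}.
#' @export
pca <- function(x, center = TRUE, unit_scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("validation error: PCA needs at least two samples")
  if (anyNA(x)) stop("validation error: PCA input contains missing values")
  p <- stats::prcomp(x, center = center, scale. = unit_scale)
  tot <- sum(p$sdev^2)
  if (tot <= .Machine$double.eps) {
    stop("validation error: zero-variance matrix, PCA undefined")
  }
  structure(
    list(scores = p$x, var_explained = p$sdev^2 / tot,
         sdev = p$sdev, rotation = p$rotation,
         center = center, unit_scale = unit_scale),
    class = "tcrep_pca"
  )
}

#' @export
print.tcrep_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples;",
      "explained variance:",
      paste0(round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 1),
             "%", collapse = ", "), "...\n")
  invisible(x)
}

mode_distance <- function(x, distance_mode, w = NULL) {
  if (distance_mode == "euclidean") {
    if (is.null(w)) {
      stats::dist(x)
    } else {
      stats::dist(sweep(x, 2, sqrt(w), "*"))
    }
  } else {
    stats::as.dist(1 - mh_similarity_matrix(x, w))
  }
}

cluster_signatures <- function(members) {
  vapply(members, paste, character(1), collapse = "\r")
}

# least-squares fit of qnorm(1 - BP_r) = v*sqrt(r) + c/sqrt(r); AU = P(Z > v - c).
# Scales where BP is exactly 0 or 1 are degenerate and excluded from the fit.
fit_au <- function(bp, scales, n_boot) {
  if (all(bp >= 1)) return(c(au = 1, v = NA_real_, c = NA_real_))
  if (all(bp <= 0)) return(c(au = 0, v = NA_real_, c = NA_real_))
  use <- bp > 0 & bp < 1
  if (sum(use) < 3L) return(c(au = NA_real_, v = NA_real_, c = NA_real_))
  eps <- 0.5 / (n_boot + 1)
  p <- pmin(pmax(bp[use], eps), 1 - eps)
  z <- stats::qnorm(1 - p)
  r <- scales[use]
  X <- cbind(sqrt(r), 1 / sqrt(r))
  cf <- qr.coef(qr(X), z)
  c(au = 1 - stats::pnorm(cf[1] - cf[2]), v = unname(cf[1]), c = unname(cf[2]))
}

#' Multiscale-bootstrap AU support for an average-linkage dendrogram
#'
#' Clusters samples by UPGMA on the chosen distance and attaches to every
#' cluster of the observed tree an approximately unbiased (AU) probability
#' and a bootstrap probability (BP), estimated by resampling \emph{features}
#' (clonotype columns, or TRBV x CDR3-length bins) with replacement at
#' several relative sizes \code{r}. For each scale, \code{round(r * F)}
#' feature columns are resampled, the tree is rebuilt, and BP_r is the
#' fraction of replicate trees containing the cluster. The normal-theory fit
#' \code{qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)} (ordinary least
#' squares over non-degenerate scales, BP clamped away from 0/1 before the
#' probit) yields \code{AU = 1 - pnorm(v - c)}; the reported BP is the
#' empirical value at \code{r = 1}. Clusters recovered in every replicate at
#' every scale (or in none) get AU = 1 (or 0) without fitting; clusters with
#' fewer than three non-degenerate scales get \code{AU = NA} while BP is
#' still reported.
#'
#' With \code{distance_mode = "morisita_horn"}, \code{x} must be a counts
#' matrix (\code{\link{repertoire_matrix}}) and the distance is 1 minus the
#' Morisita-Horn similarity recomputed from the resampled columns (a
#' clonotype drawn twice contributes twice, preserving abundance weighting).
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param distance_mode \code{"euclidean"} or \code{"morisita_horn"}.
#' @param scales relative resampling sizes; default
#'   \code{seq(0.5, 1.4, by = 0.1)} (must span values below and above 1).
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param seed optional integer seed.
#' @return an annotated dendrogram (see \code{\link{average_linkage}}) with
#'   \code{au} and \code{bp} vectors indexed like \code{clusters}, and a
#'   \code{bp_table} (clusters x scales) of raw bootstrap probabilities.
#' @export
multiscale_bootstrap_au <- function(x,
                                    distance_mode = c("euclidean", "morisita_horn"),
                                    scales = seq(0.5, 1.4, by = 0.1),
                                    n_boot = 1000, seed = NULL) {
  distance_mode <- match.arg(distance_mode)
  x <- as.matrix(x)
  if (min(scales) >= 1 || max(scales) <= 1) {
    stop("validation error: scales must span values below and above 1")
  }
  if (n_boot < 100) stop("validation error: n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  nf <- ncol(x)
  tree <- average_linkage(mode_distance(x, distance_mode))
  sigs <- cluster_signatures(tree$clusters)
  hits <- matrix(0, nrow = length(sigs), ncol = length(scales),
                 dimnames = list(NULL, as.character(scales)))
  for (si in seq_along(scales)) {
    f2 <- max(1L, round(scales[si] * nf))
    for (b in seq_len(n_boot)) {
      w <- as.numeric(stats::rmultinom(1L, f2, rep.int(1, nf)))
      bt <- stats::hclust(mode_distance(x, distance_mode, w),
                          method = "average")
      bsig <- cluster_signatures(merge_members(bt$merge, tree$labels))
      hits[, si] <- hits[, si] + (sigs %in% bsig)
    }
  }
  bp_table <- hits / n_boot
  fits <- t(apply(bp_table, 1, fit_au, scales = scales, n_boot = n_boot))
  closest <- which.min(abs(scales - 1))
  tree$au <- unname(fits[, "au"])
  tree$bp <- unname(bp_table[, closest])
  # degenerate all-0/all-1 clusters: report the constant as BP too
  allone <- apply(bp_table >= 1, 1, all)
  allzero <- apply(bp_table <= 0, 1, all)
  tree$bp[allone] <- 1
  tree$bp[allzero] <- 0
  tree$bp_table <- bp_table
  tree$scales <- scales
  tree$n_boot <- n_boot
  tree$distance_mode <- distance_mode
  tree
}

#' One-way ANOVA with Holm-adjusted pairwise comparisons
#'
#' Fixed-effects one-way analysis of variance of a per-sample scalar (e.g.
#' the overall perturbation score) across population groups, followed by all
#' pairwise Welch t-tests with Holm step-down adjustment. Groups with fewer
#' than two samples are excluded with a warning.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels, same length as \code{values}.
#' @return list with \code{f_statistic}, \code{p_value}, \code{df} and
#'   \code{pairwise} (data frame \code{group1}, \code{group2}, \code{p_raw},
#'   \code{p_holm}).
#' @export
group_comparison <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small) > 0L) {
    warning("group(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
    tab <- table(groups)
  }
  if (length(tab) < 2L) {
    stop("validation error: fewer than two groups with >= 2 samples")
  }
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  })
  p_holm <- rep(NA_real_, length(p_raw))
  ok <- !is.na(p_raw)
  p_holm[ok] <- stats::p.adjust(p_raw[ok], method = "holm")
  list(f_statistic = s[1, "F value"], p_value = s[1, "Pr(>F)"],
       df = c(s[1, "Df"], s[2, "Df"]),
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p_raw = p_raw, p_holm = p_holm,
                             stringsAsFactors = FALSE))
}
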