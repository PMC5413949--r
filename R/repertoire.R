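# Clonotype-level repertoire statistics: depth normalization, sharing,
# diversity/clonality, Morisita-Horn overlap, predominant-clonotype tables.

#' Construct a repertoire
#'
#' A repertoire is the multiset of TCR clonotypes observed in one sample,
#' stored as a named vector of read counts. Keys are opaque clonotype
#' identifiers (typically \code{"V|CDR3nt|J"} strings, see
#' \code{\link{read_clonotype_table}}).
#'
#' @param counts named numeric vector of positive integer read counts; names
#'   are clonotype keys and must be unique.
#' @param sample_id sample label.
#' @param population population label (e.g. \code{"Tfr"}, \code{"Tfh"}).
#' @return An object of class \code{"repertoire"} with elements
#'   \code{counts}, \code{sample_id}, \code{population}, \code{total}
#'   (total reads) and \code{richness} (number of distinct clonotypes).
#' @export
repertoire <- function(counts, sample_id = NA_character_,
                       population = NA_character_) {
  if (length(counts) == 0L) {
    stop("validation error: a repertoire must contain at least one clonotype")
  }
  if (is.null(names(counts)) || anyNA(names(counts)) || any(names(counts) == "")) {
    stop("validation error: all clonotype counts must be named")
  }
  if (anyDuplicated(names(counts))) {
    stop("validation error: duplicate clonotype keys in repertoire")
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("validation error: clonotype counts must be positive integers")
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  structure(
    list(counts = counts, sample_id = sample_id, population = population,
         total = sum(counts), richness = length(counts)),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("Repertoire '%s' (%s): %d clonotypes, %d reads\n",
              x$sample_id, x$population, x$richness, as.integer(x$total)))
  invisible(x)
}

# Multivariate hypergeometric draw: k reads taken uniformly without
# replacement from the expanded read multiset. Read indices are sampled
# without replacement and mapped back to clonotypes via the cumulative
# count boundaries.
rmvhyper <- function(counts, k) {
  idx <- sample.int(sum(counts), k)
  tabulate(findInterval(idx - 0.5, cumsum(counts)) + 1L,
           nbins = length(counts))
}

#' Downsample a repertoire to a fixed read depth
#'
#' Draws exactly \code{depth} reads uniformly \emph{without replacement} from
#' the repertoire's reads (multivariate hypergeometric sampling), so that
#' samples sequenced to different depths become comparable. Clonotypes drawn
#' zero times are absent from the result.
#'
#' @param rep a \code{\link{repertoire}}.
#' @param depth number of reads to retain; must satisfy
#'   \code{1 <= depth <= rep$total}.
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @return A \code{\link{repertoire}} with \code{total == depth}.
#' @export
downsample <- function(rep, depth, seed = NULL) {
  stopifnot(inherits(rep, "repertoire"))
  if (depth < 1) stop("validation error: depth must be >= 1")
  if (depth > rep$total) {
    stop(sprintf("validation error: depth %d exceeds total reads %d of sample '%s'",
                 as.integer(depth), as.integer(rep$total), rep$sample_id))
  }
  if (!is.null(seed)) set.seed(seed)
  drawn <- rmvhyper(rep$counts, depth)
  keep <- drawn > 0
  repertoire(stats::setNames(drawn[keep], names(rep$counts)[keep]),
             sample_id = rep$sample_id, population = rep$population)
}

#' Common sequencing depth of a set of repertoires
#'
#' The lowest total read count over samples: the depth every sample can be
#' downsampled to.
#'
#' @param reps list of \code{\link{repertoire}} objects.
#' @return integer depth.
#' @export
common_depth <- function(reps) {
  if (length(reps) == 0L) stop("validation error: no repertoires supplied")
  min(vapply(reps, function(r) r$total, numeric(1)))
}

#' Number of clonotypes shared between two repertoires
#'
#' @param a,b \code{\link{repertoire}} objects.
#' @return integer count of clonotype keys present in both.
#' @export
shared_clonotypes <- function(a, b) {
  length(intersect(names(a$counts), names(b$counts)))
}

#' Resampled pairwise clonotype sharing
#'
#' For each iteration every sample is independently downsampled to a common
#' depth and the number of shared clonotypes is recorded for every sample
#' pair; the mean and standard deviation over iterations summarise sharing at
#' equal depth (the numbers shown on Venn diagrams). The standard deviation
#' uses denominator \code{n} (descriptive s.d. of the finite resampling set);
#' set \code{sd_denominator = "n-1"} for the sample s.d.
#'
#' @param reps named list of \code{\link{repertoire}} objects (>= 2).
#' @param depth read depth for downsampling; defaults to
#'   \code{\link{common_depth}(reps)}.
#' @param iterations number of resampling iterations (default 100).
#' @param seed optional integer seed.
#' @param sd_denominator \code{"n"} (default) or \code{"n-1"}.
#' @return data frame with one row per unordered sample pair: \code{sample1},
#'   \code{sample2}, \code{mean_shared}, \code{sd_shared}, \code{iterations},
#'   \code{depth}.
#' @export
resampled_sharing <- function(reps, depth = common_depth(reps),
                              iterations = 100, seed = NULL,
                              sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  if (length(reps) < 2L) stop("validation error: need at least two repertoires")
  if (iterations < 1) stop("validation error: iterations must be >= 1")
  if (iterations == 1) {
    warning("iterations = 1: sd_shared reported as 0")
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- unname(vapply(reps, function(r) r$sample_id, character(1)))
  n <- length(reps)
  pairs <- utils::combn(n, 2)
  shared <- matrix(0, nrow = ncol(pairs), ncol = iterations)
  for (it in seq_len(iterations)) {
    keysets <- lapply(reps, function(r) names(downsample(r, depth)$counts))
    for (p in seq_len(ncol(pairs))) {
      shared[p, it] <- length(intersect(keysets[[pairs[1, p]]],
                                        keysets[[pairs[2, p]]]))
    }
  }
  m <- rowMeans(shared)
  if (iterations == 1) {
    s <- rep(0, length(m))
  } else if (sd_denominator == "n") {
    s <- sqrt(rowMeans((shared - m)^2))
  } else {
    s <- apply(shared, 1, stats::sd)
  }
  data.frame(sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
             mean_shared = m, sd_shared = s,
             iterations = iterations, depth = depth,
             stringsAsFactors = FALSE)
}

#' Clonality of a repertoire
#'
#' Clonality is one minus Pielou's evenness, where Pielou's evenness is
#' Shannon's entropy (log base 2) divided by the log2 of the number of
#' distinct clonotypes. It ranges from 0 (all clonotypes equally abundant,
#' maximally diverse) to 1 (a single clonotype, maximally clonal). A
#' repertoire with uniform counts returns exactly 0, and a monoclonal
#' repertoire returns 1 by convention (evenness is undefined at richness 1).
#'
#' @param rep a \code{\link{repertoire}}.
#' @return clonality score in [0, 1].
#' @seealso \code{\link{diversity_report}}
#' @export
clonality <- function(rep) {
  1 - pielou_evenness(rep$counts)
}

shannon_entropy <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

pielou_evenness <- function(counts) {
  s <- length(counts)
  if (s == 1L) return(0)
  # uniform counts are exactly maximally even; avoid returning 1 - epsilon
  if (diff(range(counts)) == 0) return(1)
  j <- shannon_entropy(counts) / log2(s)
  min(max(j, 0), 1)
}

#' Diversity report for a set of repertoires
#'
#' Per sample: richness (distinct clonotypes), Shannon entropy in bits,
#' Pielou evenness, and clonality (see \code{\link{clonality}}).
#'
#' @param reps a \code{\link{repertoire}} or list of them.
#' @return data frame with columns \code{sample_id}, \code{population},
#'   \code{richness}, \code{shannon_h}, \code{pielou_j}, \code{clonality}.
#' @export
diversity_report <- function(reps) {
  if (inherits(reps, "repertoire")) reps <- list(reps)
  rows <- lapply(reps, function(r) {
    data.frame(sample_id = r$sample_id, population = r$population,
               richness = r$richness,
               shannon_h = shannon_entropy(r$counts),
               pielou_j = pielou_evenness(r$counts),
               clonality = 1 - pielou_evenness(r$counts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Morisita-Horn similarity between two repertoires
#'
#' Abundance-weighted overlap in [0, 1]:
#' \deqn{MH = \frac{2 \sum_i x_i y_i}{(\lambda_x + \lambda_y) X Y}}
#' with \eqn{X = \sum x_i}, \eqn{Y = \sum y_i},
#' \eqn{\lambda_x = \sum x_i^2 / X^2} and \eqn{\lambda_y = \sum y_i^2 / Y^2}.
#' It is 1 for identical relative abundances, 0 for disjoint repertoires, and
#' invariant to scaling all counts of one sample (depth does not drive it).
#' \code{1 - MH} is used as a clustering distance.
#'
#' @param a,b \code{\link{repertoire}} objects.
#' @return similarity in [0, 1].
#' @export
morisita_horn <- function(a, b) {
  x <- a$counts
  y <- b$counts
  X <- sum(x)
  Y <- sum(y)
  lx <- sum(x^2) / X^2
  ly <- sum(y^2) / Y^2
  shared <- intersect(names(x), names(y))
  cross <- sum(x[shared] * y[shared])
  mh <- 2 * cross / ((lx + ly) * X * Y)
  min(max(mh, 0), 1)
}

#' Pairwise Morisita-Horn overlap matrix
#'
#' @param reps list of \code{\link{repertoire}} objects.
#' @return symmetric matrix of similarities with unit diagonal, labelled by
#'   sample id.
#' @export
overlap_matrix <- function(reps) {
  m <- repertoire_matrix(reps)
  sim <- mh_similarity_matrix(m)
  sim
}

#' Counts matrix of a repertoire set
#'
#' Samples x clonotypes matrix of read counts over the union of clonotype
#' keys; absent clonotypes are 0. This is the feature matrix consumed by
#' \code{\link{multiscale_bootstrap_au}} with
#' \code{distance_mode = "morisita_horn"}.
#'
#' @param reps list of \code{\link{repertoire}} objects.
#' @return numeric matrix with sample ids as row names and clonotype keys as
#'   column names.
#' @export
repertoire_matrix <- function(reps) {
  keys <- sort(unique(unlist(lapply(reps, function(r) names(r$counts)))),
               method = "radix")
  m <- matrix(0, nrow = length(reps), ncol = length(keys),
              dimnames = list(unname(vapply(reps, function(r) r$sample_id, character(1))),
                              keys))
  for (i in seq_along(reps)) {
    m[i, names(reps[[i]]$counts)] <- reps[[i]]$counts
  }
  m
}

# Morisita-Horn similarity of all row pairs of a counts matrix, optionally
# with non-negative column weights w (a column with weight k contributes as k
# identical clonotype columns -- used by the feature bootstrap).
mh_similarity_matrix <- function(m, w = NULL) {
  if (is.null(w)) {
    mw <- m
  } else {
    mw <- sweep(m, 2, w, "*")
  }
  tot <- rowSums(mw)
  sq <- rowSums(mw * m)
  zero <- tot == 0
  tot[zero] <- 1
  lam <- sq / tot^2
  lam[zero] <- 1
  cross <- tcrossprod(mw, m)
  sim <- 2 * cross / (outer(lam, lam, "+") * outer(tot, tot))
  sim[zero, ] <- 0
  sim[, zero] <- 0
  diag(sim) <- 1
  sim[sim > 1] <- 1
  sim[sim < 0] <- 0
  sim
}

#' Most predominant clonotypes of a repertoire
#'
#' The \code{k} highest-frequency clonotypes (fewer if richness < k). Ties in
#' count are broken by lexicographic clonotype key (C locale), making the
#' ranking deterministic.
#'
#' @param rep a \code{\link{repertoire}}.
#' @param k number of clonotypes to return (default 20).
#' @return data frame \code{key}, \code{count}, \code{frequency}, ordered by
#'   decreasing frequency.
#' @export
top_clonotypes <- function(rep, k = 20) {
  if (k < 1) stop("validation error: k must be >= 1")
  ord <- order(-rep$counts, names(rep$counts), method = "radix")
  take <- ord[seq_len(min(k, rep$richness))]
  data.frame(key = names(rep$counts)[take],
             count = rep$counts[take],
             frequency = rep$counts[take] / rep$total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative frequency of pooled predominant clonotypes
#'
#' Determines the top-\code{k} clonotypes of every sample, pools them into a
#' single (deduplicated) union list, and reports for each sample the summed
#' frequency of the union members it contains -- the quantity plotted as a
#' cumulative-frequency histogram. Also reports each sample's cumulative
#' share of its \emph{own} five most abundant clonotypes.
#'
#' @param reps list of \code{\link{repertoire}} objects.
#' @param k per-sample list length (default 20).
#' @return list with elements \code{union_keys} (character vector),
#'   \code{per_sample} (data frame \code{sample_id}, \code{population},
#'   \code{cumulative_frequency}, \code{top5_own_share}) and \code{top_lists}
#'   (per-sample \code{\link{top_clonotypes}} tables).
#' @export
cumulative_frequency_table <- function(reps, k = 20) {
  tops <- lapply(reps, top_clonotypes, k = k)
  names(tops) <- unname(vapply(reps, function(r) r$sample_id, character(1)))
  union_keys <- unique(unlist(lapply(tops, function(t) t$key)))
  per <- lapply(reps, function(r) {
    present <- intersect(union_keys, names(r$counts))
    data.frame(sample_id = r$sample_id, population = r$population,
               cumulative_frequency = sum(r$counts[present]) / r$total,
               top5_own_share = sum(top_clonotypes(r, 5)$frequency),
               stringsAsFactors = FALSE)
  })
  list(union_keys = union_keys,
       per_sample = do.call(rbind, c(per, list(make.row.names = FALSE))),
       top_lists = tops)
}

#' Frequency matrix of a focal clonotype list across samples
#'
#' For a chosen list of clonotype keys (e.g. the pooled top-20 clonotypes of
#' the Tfr samples), the frequency of each key in each sample (0 when
#' absent). Rows are deduplicated keys; this matrix feeds Euclidean /
#' average-linkage clustering of samples by their usage of the focal clones.
#'
#' @param focal_list character vector of clonotype keys (non-empty;
#'   duplicates are removed, first occurrence order kept).
#' @param reps list of \code{\link{repertoire}} objects.
#' @return matrix keys x samples of frequencies.
#' @export
focal_clonotype_matrix <- function(focal_list, reps) {
  if (length(focal_list) == 0L) {
    stop("validation error: focal clonotype list is empty")
  }
  focal_list <- unique(focal_list)
  ids <- unname(vapply(reps, function(r) r$sample_id, character(1)))
  m <- matrix(0, nrow = length(focal_list), ncol = length(reps),
              dimnames = list(focal_list, ids))
  for (j in seq_along(reps)) {
    r <- reps[[j]]
    present <- intersect(focal_list, names(r$counts))
    m[present, j] <- r$counts[present] / r$total
  }
  m
}
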