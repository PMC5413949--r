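# CDR3 spectratype analysis: segment exclusions, normalized per-TRBV
# CDR3-length profiles, reference profiles, deviation matrices and
# perturbation scores.

#' Default excluded TRBV segments
#'
#' In C57BL/6 mice TRBV21 and TRBV24 are pseudogenes; TRBV12-2 is commonly
#' dropped when it fails to amplify consistently across samples.
#'
#' @export
default_excluded_segments <- function() c("TRBV21", "TRBV24", "TRBV12-2")

#' Remove excluded TRBV segments from a peak table
#'
#' @param peaks spectratype peak data frame
#'   (\code{\link{read_spectratype_peaks}}).
#' @param excluded character vector of TRBV labels to drop; defaults to
#'   \code{\link{default_excluded_segments}()}.
#' @return filtered peak table with the retained segment set attached as
#'   attribute \code{"retained_segments"}.
#' @export
apply_segment_exclusions <- function(peaks,
                                     excluded = default_excluded_segments()) {
  keep <- !(peaks$trbv %in% excluded)
  if (!any(keep)) {
    stop("validation error: segment exclusion removed every TRBV segment")
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_segments") <- sort(unique(out$trbv))
  out
}

#' Normalize peak areas into CDR3-length frequency profiles
#'
#' For every (sample, TRBV segment), the frequency of each CDR3 length is its
#' peak area divided by the total area of all peaks in that segment's
#' profile. Segments whose total area is zero carry no information and are
#' absent from the result (reported via a message), never represented as
#' all-zero profiles.
#'
#' @param peaks spectratype peak data frame.
#' @return named list of per-sample spectratypes; each element is a list
#'   with \code{sample_id}, \code{population} and \code{profiles} (a named
#'   list mapping TRBV label to a frequency vector named by CDR3 length,
#'   each summing to 1).
#' @export
normalize_profiles <- function(peaks) {
  samples <- unique(peaks$sample_id)
  out <- lapply(samples, function(sid) {
    sub <- peaks[peaks$sample_id == sid, , drop = FALSE]
    pop <- unique(sub$population)[1]
    profiles <- list()
    for (seg in unique(sub$trbv)) {
      ss <- sub[sub$trbv == seg, , drop = FALSE]
      ss <- ss[order(ss$cdr3_length), , drop = FALSE]
      total <- sum(ss$area)
      if (total <= 0) {
        message("sample '", sid, "': segment ", seg,
                " has zero total area and is dropped")
        next
      }
      profiles[[seg]] <- stats::setNames(ss$area / total,
                                         as.character(ss$cdr3_length))
    }
    structure(list(sample_id = sid, population = pop, profiles = profiles),
              class = "sample_spectratype")
  })
  names(out) <- samples
  out
}

# union-support alignment of two frequency vectors named by CDR3 length
align_support <- function(p, q) {
  lens <- as.character(sort(unique(as.integer(c(names(p), names(q))))))
  pa <- stats::setNames(numeric(length(lens)), lens)
  qa <- pa
  pa[names(p)] <- p
  qa[names(q)] <- q
  list(p = pa, q = qa, lengths = as.integer(lens))
}

#' Build a reference spectratype from a group of samples
#'
#' Per segment, the reference frequency at each CDR3 length is the unweighted
#' mean over the samples covering that segment (lengths absent from a sample
#' contribute 0), renormalized to sum to 1. This is a profile-level average:
#' each sample contributes equally regardless of its total fluorescence.
#'
#' @param samples list of sample spectratypes
#'   (\code{\link{normalize_profiles}}).
#' @param label reference label recorded in outputs (e.g.
#'   \code{"Tfr group average"} or \code{"naive CD4"}).
#' @return reference spectratype: list with \code{label} and \code{profiles}.
#' @export
group_reference <- function(samples, label = "group average") {
  if (length(samples) == 0L) {
    stop("validation error: no samples to build a reference from")
  }
  segs <- unique(unlist(lapply(samples, function(s) names(s$profiles))))
  profiles <- list()
  for (seg in segs) {
    covering <- Filter(function(s) seg %in% names(s$profiles), samples)
    lens <- sort(unique(as.integer(unlist(
      lapply(covering, function(s) names(s$profiles[[seg]]))))))
    m <- matrix(0, nrow = length(covering), ncol = length(lens),
                dimnames = list(NULL, as.character(lens)))
    for (i in seq_along(covering)) {
      p <- covering[[i]]$profiles[[seg]]
      m[i, names(p)] <- p
    }
    avg <- colMeans(m)
    profiles[[seg]] <- avg / sum(avg)
  }
  structure(list(label = label, profiles = profiles),
            class = "reference_spectratype")
}

#' Per-length deviations of a sample from a reference
#'
#' For every retained segment shared by sample and reference, the signed
#' difference (sample frequency minus reference frequency) at each CDR3
#' length of the union support. On a common support the deviations of a
#' segment sum to zero; positive entries mark over-represented lengths
#' (candidate clonal expansions).
#'
#' @param sample a sample spectratype.
#' @param ref a reference spectratype (\code{\link{group_reference}}).
#' @return data frame \code{trbv}, \code{cdr3_length}, \code{deviation}.
#' @export
deviation_matrix <- function(sample, ref) {
  rows <- list()
  for (seg in names(sample$profiles)) {
    if (!(seg %in% names(ref$profiles))) {
      warning("segment ", seg, " absent from reference; skipped")
      next
    }
    al <- align_support(sample$profiles[[seg]], ref$profiles[[seg]])
    rows[[seg]] <- data.frame(trbv = seg, cdr3_length = al$lengths,
                              deviation = unname(al$p - al$q),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Perturbation score between two CDR3-length distributions
#'
#' Half the L1 distance between two normalized frequency vectors (total
#' variation distance), expressed in percent: 0 for identical profiles, 100
#' for disjoint supports. Vectors are aligned on the union of their CDR3
#' lengths (missing lengths count as frequency 0).
#'
#' @param p,q frequency vectors named by CDR3 length, each summing to 1.
#' @return score in [0, 100].
#' @export
perturbation_score <- function(p, q) {
  al <- align_support(p, q)
  100 * 0.5 * sum(abs(al$p - al$q))
}

#' Per-TRBV perturbation scores of samples against a reference
#'
#' For every sample and retained TRBV segment, the
#' \code{\link{perturbation_score}} between the sample's profile and the
#' reference profile; the per-sample overall score is the unweighted mean
#' over retained segments. Segments a sample failed to amplify are flagged
#' missing (\code{NA}) and excluded from that sample's mean -- a missing
#' amplification is not evidence of perturbation.
#'
#' @param samples list of sample spectratypes.
#' @param ref reference spectratype.
#' @return object of class \code{"perturbation_matrix"}: list with
#'   \code{scores} (samples x segments matrix, percent), \code{overall}
#'   (named per-sample means), \code{populations} and \code{reference} (the
#'   reference label).
#' @export
perturbation_scores <- function(samples, ref) {
  segs <- sort(names(ref$profiles))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  m <- matrix(NA_real_, nrow = length(samples), ncol = length(segs),
              dimnames = list(ids, segs))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (seg in segs) {
      if (seg %in% names(s$profiles)) {
        m[i, seg] <- perturbation_score(s$profiles[[seg]],
                                        ref$profiles[[seg]])
      }
    }
  }
  n_missing <- sum(is.na(m))
  if (n_missing > 0L) {
    message(n_missing, " missing sample x segment cell(s) excluded from row means")
  }
  structure(
    list(scores = m,
         overall = rowMeans(m, na.rm = TRUE),
         populations = stats::setNames(
           vapply(samples, function(s) s$population, character(1)), ids),
         reference = ref$label),
    class = "perturbation_matrix"
  )
}

#' @export
as.matrix.perturbation_matrix <- function(x, ...) x$scores

#' @export
print.perturbation_matrix <- function(x, ...) {
  cat(sprintf("Perturbation matrix: %d samples x %d TRBV segments (reference: %s)\n",
              nrow(x$scores), ncol(x$scores), x$reference))
  cat("Overall scores (%):\n")
  print(round(x$overall, 2))
  invisible(x)
}
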