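# Synthetic spectratype and repertoire generators with ground truth.
#
# The generators emulate the structure the downstream analysis assumes: five
# sorted T-cell populations with replicate mice, follicular/activated
# populations dominated by a few expanded clones, a Tfr clonotype pool
# largely contained in the Treg pool, and Gaussian-like per-TRBV CDR3-length
# profiles with planted single-length expansions in Tfh-like samples.

#' Configuration for the spectratype simulator
#'
#' @param n_segments number of TRBV segments (default 20, the retained set
#'   after pseudogene/dropout exclusions).
#' @param lengths CDR3-length support in nucleotides (default 8 in-frame
#'   lengths spaced 3 nt).
#' @param baseline_sd standard deviation, in length-step units, of the
#'   discretized Gaussian baseline profile centered mid-support.
#' @param populations named integer vector: replicates per population.
#' @param expansions data frame \code{population}, \code{trbv},
#'   \code{cdr3_length}, \code{delta}: planted single-length expansions,
#'   where \code{delta} in (0,1) is the mass fraction moved onto the length.
#'   Defaults to delta = 0.3 expansions in five segments of Tfh samples.
#' @param noise_sd sdlog of the multiplicative lognormal area noise applied
#'   per sample x segment x length.
#' @param area_scale mean total fluorescence area per profile.
#' @param seed integer seed; all randomness flows through it.
#' @return config list of class \code{"spectratype_sim_config"}.
#' @export
spectratype_sim_config <- function(n_segments = 20,
                                   lengths = seq(24, 45, by = 3),
                                   baseline_sd = 1.5,
                                   populations = c(Tfh = 3, Tfr = 3,
                                                   Treg = 3, Tconv = 3),
                                   expansions = NULL,
                                   noise_sd = 0.05,
                                   area_scale = 1e4,
                                   seed = 1) {
  segs <- paste0("TRBV", seq_len(n_segments))
  if (is.null(expansions)) {
    seg_idx <- unique(pmin(n_segments, c(2, 5, 9, 13, 16)))
    len_idx <- pmin(length(lengths), c(6, 3, 6, 2, 7))[seq_along(seg_idx)]
    expansions <- data.frame(
      population = "Tfh",
      trbv = segs[seg_idx],
      cdr3_length = lengths[len_idx],
      delta = 0.3,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(expansions) == 0L) {
    expansions <- data.frame(population = character(0), trbv = character(0),
                             cdr3_length = integer(0), delta = numeric(0),
                             stringsAsFactors = FALSE)
  }
  if (nrow(expansions) > 0L) {
    if (any(expansions$delta <= 0 | expansions$delta >= 1)) {
      stop("config error: expansion delta must be in (0, 1)")
    }
    if (!all(expansions$cdr3_length %in% lengths)) {
      stop("config error: expansion placed on a CDR3 length outside the support")
    }
    if (!all(expansions$trbv %in% segs)) {
      stop("config error: expansion placed on an unknown TRBV segment")
    }
  }
  idx <- seq_along(lengths)
  w <- stats::dnorm(idx, mean = (length(idx) + 1) / 2, sd = baseline_sd)
  baseline <- stats::setNames(w / sum(w), as.character(lengths))
  structure(list(n_segments = n_segments, segments = segs, lengths = lengths,
                 baseline = baseline, populations = populations,
                 expansions = expansions, noise_sd = noise_sd,
                 area_scale = area_scale, seed = seed),
            class = "spectratype_sim_config")
}

#' Simulate spectratype peak tables
#'
#' Per sample and TRBV segment, peak areas are proportional to the baseline
#' Gaussian-like length profile -- mixed with a planted single-length spike
#' where the configuration places an expansion -- times multiplicative
#' lognormal noise. An expansion of mass fraction \code{delta} at length L
#' makes the true profile \code{(1 - delta) * baseline + delta * 1[L]}, so
#' its exact perturbation against the baseline is
#' \code{100 * delta * (1 - baseline[L])} percent.
#'
#' @param cfg a \code{\link{spectratype_sim_config}}.
#' @return list with \code{peaks} (data frame in the
#'   \code{\link{read_spectratype_peaks}} dialect), \code{truth} (baseline
#'   profile and planted expansions) and \code{config}.
#' @export
simulate_spectratypes <- function(cfg) {
  stopifnot(inherits(cfg, "spectratype_sim_config"))
  set.seed(cfg$seed)
  rows <- list()
  for (pop in names(cfg$populations)) {
    for (m in seq_len(cfg$populations[[pop]])) {
      sid <- sprintf("%s_m%d", pop, m)
      for (seg in cfg$segments) {
        prof <- cfg$baseline
        exp_here <- cfg$expansions[cfg$expansions$population == pop &
                                     cfg$expansions$trbv == seg, , drop = FALSE]
        for (e in seq_len(nrow(exp_here))) {
          spike <- stats::setNames(numeric(length(prof)), names(prof))
          spike[as.character(exp_here$cdr3_length[e])] <- 1
          prof <- (1 - exp_here$delta[e]) * prof + exp_here$delta[e] * spike
        }
        noise <- if (cfg$noise_sd > 0) {
          stats::rlnorm(length(prof), 0, cfg$noise_sd)
        } else {
          rep(1, length(prof))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, population = pop, trbv = seg,
          cdr3_length = cfg$lengths,
          area = cfg$area_scale * unname(prof) * noise,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(peaks = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = list(baseline = cfg$baseline, expansions = cfg$expansions),
       config = cfg)
}

#' Configuration for the repertoire simulator
#'
#' Clonotype pools are laid out so that the Tfr pool is mostly contained in
#' the Treg pool (with matching abundance ranks, so shared clonotypes have
#' correlated frequencies), the remaining populations have mostly private
#' pools chained by small tail overlaps, and a small public pool is present
#' in every population. The polyclonal tail of each sample follows a
#' truncated power law over its pool's ranks; expanded clones are explicit
#' point masses whose keys are fixed per population, so replicate mice share
#' their dominant clonotypes. Default expanded-mass shares put the top-5
#' share near 50\% for Tfh and Tact and near 40\% for Tfr, with Tfh
#' slightly above Tact (Tfh being the most oligoclonal population), and no
#' expansion in Treg/Tconv.
#'
#' @param populations named integer vector: replicates per population.
#' @param reads_per_sample productive reads per sample (default 10000).
#' @param pool_size clonotype pool size per population.
#' @param tfr_treg_overlap fraction of the Tfr pool drawn from the top of
#'   the Treg pool (default 0.8).
#' @param cross_overlap fraction of each remaining pool shared (at rare
#'   ranks) with the previous population's pool (default 0.1).
#' @param public_size size of the public pool appended to every population.
#' @param alpha power-law exponent of the polyclonal rank-abundance law.
#' @param expanded named list per population: \code{n} expanded clones and
#'   their total frequency \code{share}.
#' @param noise_sd sdlog of per-sample lognormal jitter on polyclonal
#'   weights.
#' @param expansion_noise_sd sdlog of per-sample jitter on expanded-clone
#'   shares.
#' @param seed integer seed.
#' @return config list of class \code{"repertoire_sim_config"}.
#' @export
repertoire_sim_config <- function(populations = c(Tfr = 3, Tfh = 3, Treg = 4,
                                                  Tact = 4, Tconv = 4),
                                  reads_per_sample = 10000,
                                  pool_size = 5000,
                                  tfr_treg_overlap = 0.8,
                                  cross_overlap = 0.1,
                                  public_size = 250,
                                  alpha = 0.8,
                                  expanded = list(
                                    Tfh = list(n = 5, share = 0.55),
                                    Tact = list(n = 5, share = 0.48),
                                    Tfr = list(n = 5, share = 0.40),
                                    Treg = list(n = 0, share = 0),
                                    Tconv = list(n = 0, share = 0)),
                                  noise_sd = 0.3,
                                  expansion_noise_sd = 0.15,
                                  seed = 1) {
  if (reads_per_sample < 1) stop("config error: reads_per_sample must be >= 1")
  if (tfr_treg_overlap < 0 || tfr_treg_overlap > 1) {
    stop("config error: tfr_treg_overlap must be in [0, 1]")
  }
  for (pop in names(expanded)) {
    e <- expanded[[pop]]
    if (e$share < 0 || e$share >= 1) {
      stop("config error: expanded share must be in [0, 1)")
    }
    if (e$n > pool_size) {
      stop("config error: more expanded clones than pool keys")
    }
  }
  structure(list(populations = populations,
                 reads_per_sample = reads_per_sample,
                 pool_size = pool_size,
                 tfr_treg_overlap = tfr_treg_overlap,
                 cross_overlap = cross_overlap,
                 public_size = public_size,
                 alpha = alpha, expanded = expanded,
                 noise_sd = noise_sd,
                 expansion_noise_sd = expansion_noise_sd,
                 seed = seed),
            class = "repertoire_sim_config")
}

# one representative codon per amino acid (standard genetic code)
aa_codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

# synthesize n unique clonotype keys: V/J labels plus random in-frame CDR3s
# (canonical C...F amino-acid motif, nucleotide string by back-translation)
make_clonotype_keys <- function(n) {
  draw <- function(k) {
    v <- sprintf("TRAV%d", sample.int(21, k, replace = TRUE))
    j <- sprintf("TRAJ%d", sample.int(50, k, replace = TRUE))
    core_len <- sample(6:13, k, replace = TRUE)
    aa <- vapply(core_len, function(l) {
      paste0("CA", paste(sample(names(aa_codons), l, replace = TRUE),
                         collapse = ""), "F")
    }, character(1))
    nt <- vapply(aa, function(s) {
      paste(aa_codons[strsplit(s, "")[[1]]], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    data.frame(v_gene = v, j_gene = j, cdr3_nt = nt, cdr3_aa = aa,
               stringsAsFactors = FALSE)
  }
  keys <- draw(n)
  key_str <- function(d) paste(d$v_gene, d$cdr3_nt, d$j_gene, sep = "|")
  while (anyDuplicated(key_str(keys))) {
    dup <- duplicated(key_str(keys))
    keys[dup, ] <- draw(sum(dup))
  }
  keys$key <- key_str(keys)
  keys
}

# pool layout: per-population index vectors into the master key table,
# ordered from abundant to rare rank
build_pools <- function(cfg) {
  p <- cfg$pool_size
  ov <- round(cfg$tfr_treg_overlap * p)
  co <- round(cfg$cross_overlap * p)
  pub <- cfg$public_size
  blocks <- list()
  nxt <- 1L
  block <- function(size) {
    idx <- seq.int(nxt, length.out = size)
    nxt <<- nxt + size
    idx
  }
  A <- block(p)              # Treg pool
  B <- block(p - ov)         # Tfr-private
  C <- block(p - co)         # Tconv-private
  D <- block(p - co)         # Tact-private
  E <- block(p - co)         # Tfh-private
  P <- block(pub)            # public, appended (rare) everywhere
  pools <- list(
    Treg  = c(A, P),
    Tfr   = c(A[seq_len(ov)], B, P),
    Tconv = c(C, utils::tail(A, co), P),
    Tact  = c(D, utils::tail(C, co), P),
    Tfh   = c(E, utils::tail(D, co), P)
  )
  list(pools = pools, n_keys = nxt - 1L)
}

#' Simulate clonotype count tables for five T-cell populations
#'
#' Draws, for every replicate sample, a multinomial of
#' \code{reads_per_sample} reads over its population's clonotype pool. The
#' per-sample probability vector mixes (i) a truncated power-law polyclonal
#' tail over pool ranks (jittered per sample by lognormal noise) carrying
#' mass \code{1 - share}, and (ii) fixed expanded clonotypes carrying mass
#' \code{share}, split between clones proportionally to 1/rank and jittered
#' per sample. Expanded Tfh/Tact clones sit in the population-private pool
#' region and are identical across replicate mice; expanded Tfr clones are
#' the most abundant keys of the Treg pool, so the dominant Tfr clonotypes
#' are present in every Treg sample.
#'
#' @param cfg a \code{\link{repertoire_sim_config}}.
#' @return list with \code{table} (clonotype records in the
#'   \code{\link{read_clonotype_table}} dialect), \code{repertoires} (named
#'   list of \code{\link{repertoire}} objects), \code{truth} (pool key sets,
#'   expanded clones with their target shares, and the generator
#'   parameters) and \code{config}.
#' @export
simulate_repertoires <- function(cfg) {
  stopifnot(inherits(cfg, "repertoire_sim_config"))
  set.seed(cfg$seed)
  layout <- build_pools(cfg)
  keys <- make_clonotype_keys(layout$n_keys)
  pools <- layout$pools
  expanded_truth <- list()
  expanded_idx <- list()
  for (pop in names(cfg$populations)) {
    e <- cfg$expanded[[pop]]
    if (is.null(e) || e$n == 0) {
      expanded_idx[[pop]] <- integer(0)
      next
    }
    idx <- if (pop == "Tfr") {
      pools$Treg[seq_len(e$n)]   # top-ranked Treg-shared keys
    } else {
      pools[[pop]][seq_len(e$n)] # top-ranked keys of the own pool
    }
    expanded_idx[[pop]] <- idx
    wts <- (1 / seq_len(e$n))
    expanded_truth[[pop]] <- data.frame(
      population = pop, key = keys$key[idx],
      target_share = e$share * wts / sum(wts),
      stringsAsFactors = FALSE)
  }
  rows <- list()
  reps <- list()
  for (pop in names(cfg$populations)) {
    pool <- pools[[pop]]
    base_w <- seq_along(pool)^(-cfg$alpha)
    e <- cfg$expanded[[pop]]
    n_exp <- if (is.null(e)) 0L else e$n
    for (m in seq_len(cfg$populations[[pop]])) {
      sid <- sprintf("%s_m%d", pop, m)
      w <- base_w * stats::rlnorm(length(base_w), 0, cfg$noise_sd)
      w <- w / sum(w)
      prob <- w
      if (n_exp > 0L) {
        sh <- expanded_truth[[pop]]$target_share *
          stats::rlnorm(n_exp, 0, cfg$expansion_noise_sd)
        share_tot <- min(sum(sh), 0.95)
        sh <- sh * (share_tot / sum(sh))
        prob <- prob * (1 - share_tot)
        at <- match(expanded_idx[[pop]], pool)
        if (anyNA(at)) {
          stop("config error: expanded clones of ", pop,
               " fall outside its pool (overlap too small)")
        }
        prob[at] <- prob[at] + sh
      }
      counts <- as.numeric(stats::rmultinom(1L, cfg$reads_per_sample, prob))
      keep <- counts > 0
      kk <- keys[pool[keep], , drop = FALSE]
      rows[[sid]] <- data.frame(
        sample_id = sid, population = pop,
        v_gene = kk$v_gene, j_gene = kk$j_gene,
        cdr3_nt = kk$cdr3_nt, cdr3_aa = kk$cdr3_aa,
        count = counts[keep], stringsAsFactors = FALSE)
      reps[[sid]] <- repertoire(stats::setNames(counts[keep], kk$key),
                                sample_id = sid, population = pop)
    }
  }
  truth <- list(pools = lapply(pools, function(ix) keys$key[ix]),
                expanded = do.call(rbind, c(unname(expanded_truth),
                                            list(make.row.names = FALSE))),
                alpha = cfg$alpha, seed = cfg$seed)
  list(table = do.call(rbind, c(unname(rows), list(make.row.names = FALSE))),
       repertoires = reps, truth = truth, config = cfg)
}
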