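# Sliding-window Kyte-Doolittle hydropathy and the TM-helix predictor
# used as stage 2 of the screen. The predictor reports both passing
# segments (window mean >= threshold) and sub-threshold candidates
# (window mean inside a band just below the threshold); the candidates
# are what the pore-loop detector consumes.

.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
               L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
               S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy values
#'
#' @param seq Amino-acid string (X scores 0).
#' @return Numeric vector of per-residue hydropathy values.
#' @export
kd_hydropathy <- function(seq) {
  res <- seq_chars(seq)
  v <- unname(.KD_SCALE[res])
  v[is.na(v)] <- 0
  v
}

# Means of all windows of width w; result[i] is the mean over the window
# starting at 0-based position i - 1.
window_means <- function(values, w) {
  n <- length(values)
  if (n < w) return(numeric(0))
  cs <- c(0, cumsum(values))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

# Logistic transform mapping a window-mean hydropathy to a [0,1] score
# anchored at the TM threshold (score 0.5 at the threshold).
tm_probability <- function(mean_kd, threshold) {
  1 / (1 + exp(-2 * (mean_kd - threshold)))
}

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Computes mean Kyte-Doolittle hydropathy over all windows of width
#' \code{window}, forms maximal runs of window positions whose mean is at
#' least the sub-threshold band floor (probability \code{p_lo}), merging
#' runs separated by fewer than \code{merge_gap} positions, and reports
#' each run as a segment. A segment passes the TM test when its best
#' window mean reaches \code{threshold}; runs whose best mean lies inside
#' the band \code{[p_lo, threshold)} are reported as sub-threshold
#' candidates (\code{passes_test = FALSE}) -- these are the pore-loop-like
#' signals. The \code{probability_score} is a logistic transform of the
#' best window mean, anchored so the TM threshold maps to 0.5.
#'
#' Two extents are reported per segment: \code{start}/\code{end} is the
#' union of the run's windows, and \code{core_start}/\code{core_end} is
#' the intersection of the windows at the segment's level (passing
#' windows for TMs, band windows for candidates). The core is always
#' contained in the underlying hydrophobic stretch whenever some window
#' covers it exactly, which makes topology ordering robust to the
#' half-window bleed of the union extent. For runs too long to share a
#' common window, the core is the best-scoring window.
#'
#' @param seq Amino-acid string.
#' @param window Odd window width, >= 7.
#' @param threshold Mean-hydropathy threshold for a passing TM.
#' @param p_lo Probability-score floor of the sub-threshold band.
#' @param merge_gap Runs separated by fewer than this many window
#'   positions are merged.
#' @return data.frame with columns start, end, core_start, core_end
#'   (0-based half-open residue coordinates), max_mean,
#'   probability_score, passes_test; sorted by start. A sequence shorter
#'   than the window yields zero rows.
#' @export
predict_tm_segments <- function(seq, window = 19L, threshold = 1.6,
                                p_lo = 0.25, merge_gap = 3L) {
  if (window %% 2L != 1L || window < 7L)
    stop("window must be odd and >= 7")
  empty <- data.frame(start = integer(0), end = integer(0),
                      core_start = integer(0), core_end = integer(0),
                      max_mean = numeric(0), probability_score = numeric(0),
                      passes_test = logical(0))
  v <- kd_hydropathy(seq)
  mw <- window_means(v, window)
  if (!length(mw)) return(empty)
  lo_mean <- threshold + log(p_lo / (1 - p_lo)) / 2
  inband <- mw >= lo_mean
  if (!any(inband)) return(empty)
  starts0 <- which(inband) - 1L           # 0-based window starts
  brk <- c(0L, which(diff(starts0) >= merge_gap + 1L), length(starts0))
  out <- vector("list", length(brk) - 1L)
  for (g in seq_len(length(brk) - 1L)) {
    run <- starts0[(brk[g] + 1L):brk[g + 1L]]
    mm <- mw[run + 1L]
    best <- max(mm)
    passes <- best >= threshold
    lev <- if (passes) run[mm >= threshold] else run
    s1 <- min(lev); s2 <- max(lev)
    if (s2 < s1 + window) {
      cs <- s2; ce <- s1 + window
    } else {  # no common window: fall back to the best-scoring window
      b <- lev[which.max(mw[lev + 1L])]
      cs <- b; ce <- b + window
    }
    out[[g]] <- data.frame(start = min(run), end = max(run) + window,
                           core_start = cs, core_end = ce,
                           max_mean = best,
                           probability_score = tm_probability(best, threshold),
                           passes_test = passes)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Heuristic signal-peptide detector
#'
#' A documented heuristic stand-in for dedicated signal-peptide
#' predictors: reports TRUE when the first 25 residues contain a
#' hydrophobic core of at least 7 residues (7-residue window mean
#' Kyte-Doolittle hydropathy >= 1.8) preceded by at least one positively
#' charged residue (K/R) within the first 5 positions.
#'
#' @param seq Amino-acid string; sequences shorter than 30 residues give
#'   FALSE with a warning.
#' @param n_term Number of N-terminal residues examined.
#' @param core_window Width of the hydrophobic-core window.
#' @param core_threshold Mean hydropathy the core window must reach.
#' @return Logical flag.
#' @export
detect_signal_peptide <- function(seq, n_term = 25L, core_window = 7L,
                                  core_threshold = 1.8) {
  if (nchar(seq) < 30L) {
    warning("sequence shorter than 30 residues; signal peptide not assessed")
    return(FALSE)
  }
  res <- seq_chars(substr(seq, 1L, n_term))
  if (!any(res[1:5] %in% c("K", "R"))) return(FALSE)
  v <- unname(.KD_SCALE[res]); v[is.na(v)] <- 0
  mw <- window_means(v, core_window)
  if (!length(mw)) return(FALSE)
  # core must start after the first positive residue
  first_pos <- which(res[1:5] %in% c("K", "R"))[1L]
  ok <- which(mw >= core_threshold)
  any(ok > first_pos)
}
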