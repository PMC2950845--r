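# Region-wise alignment joining and per-column conservation
# classification following ClustalW/ClustalX conventions: a column is
# "identical" (one residue type, no gaps), "strongly conserved" (all
# residues within one strong group, the ':' mark) or "weakly conserved"
# (one weak group, the '.' mark); anything else, including any gap, is
# unconserved.

.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV",
                    "MILF", "HY", "FYW")
.WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
                  "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")

.REGION_ORDER <- c("S1", "channel", "S2")

#' Join per-region alignments into one region-annotated alignment
#'
#' Domains are aligned separately and then joined: the input alignments
#' are concatenated horizontally in the canonical region order (S1,
#' channel, S2; other region names follow in input order) and the column
#' interval of each region is recorded. All inputs must contain the same
#' sequence ids.
#'
#' @param alignments Named list of character matrices (rows = sequences,
#'   rownames = ids), e.g. \code{list(S1 = ..., channel = ..., S2 = ...)}.
#' @return Object of class \code{region_alignment}: list with
#'   \code{alignment} (character matrix) and \code{boundaries} (named
#'   list region -> \code{c(start, end)} 0-based half-open column
#'   intervals).
#' @export
join_alignments <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  ord <- c(intersect(.REGION_ORDER, names(alignments)),
           setdiff(names(alignments), .REGION_ORDER))
  alignments <- alignments[ord]
  ids <- rownames(alignments[[1L]])
  if (is.null(ids)) stop("alignments must have sequence ids as rownames")
  for (nm in names(alignments)) {
    other <- rownames(alignments[[nm]])
    if (!setequal(other, ids))
      stop("alignment '", nm, "' has mismatched ids: ",
           paste(union(setdiff(other, ids), setdiff(ids, other)),
                 collapse = ", "))
    alignments[[nm]] <- alignments[[nm]][ids, , drop = FALSE]
  }
  widths <- vapply(alignments, ncol, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths
  boundaries <- Map(function(s, e) c(s, e), starts, ends)
  structure(list(alignment = do.call(cbind, alignments),
                 boundaries = boundaries),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat("region_alignment:", nrow(x$alignment), "sequences,",
      ncol(x$alignment), "columns;",
      paste(sprintf("%s [%d,%d)", names(x$boundaries),
                    vapply(x$boundaries, `[`, 0, 1L),
                    vapply(x$boundaries, `[`, 0, 2L)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify one alignment column
#'
#' @param column Character vector of residues and gap characters ("-").
#' @return One of "identical", "strong", "weak", "none". Any gap gives
#'   "none" (ClustalW prints no consensus symbol under gapped columns).
#' @export
classify_column <- function(column) {
  stopifnot(length(column) >= 1L)
  if (any(column %in% c("-", ".", "~"))) return("none")
  u <- unique(column)
  if (length(u) == 1L) return("identical")
  in_group <- function(groups) {
    for (g in groups) {
      if (all(u %in% seq_chars(g))) return(TRUE)
    }
    FALSE
  }
  if (in_group(.STRONG_GROUPS)) return("strong")
  if (in_group(.WEAK_GROUPS)) return("weak")
  "none"
}

#' Summarize conservation per region
#'
#' Counts identical, strongly conserved and weakly conserved columns in
#' each region of a joined alignment; denominators are the region column
#' counts.
#'
#' @param x A \code{region_alignment} (or a plain character matrix, which
#'   is treated as a single region named "all").
#' @return data.frame: region, columns_total, identical,
#'   strongly_conserved, weakly_conserved.
#' @export
summarize_conservation <- function(x) {
  if (is.matrix(x))
    x <- structure(list(alignment = x,
                        boundaries = list(all = c(0L, ncol(x)))),
                   class = "region_alignment")
  stopifnot(inherits(x, "region_alignment"))
  cls <- vapply(seq_len(ncol(x$alignment)),
                function(j) classify_column(x$alignment[, j]),
                character(1L))
  rows <- lapply(names(x$boundaries), function(nm) {
    b <- x$boundaries[[nm]]
    cc <- if (b[2L] > b[1L]) cls[(b[1L] + 1L):b[2L]] else character(0)
    data.frame(region = nm, columns_total = b[2L] - b[1L],
               identical = sum(cc == "identical"),
               strongly_conserved = sum(cc == "strong"),
               weakly_conserved = sum(cc == "weak"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check full conservation of the key binding residues
#'
#' The glutamate-binding domain carries an invariant arginine in S1
#' (contacting the alpha-carboxy group of L-glutamate) and an invariant
#' aspartate in S2 (contacting the alpha-amino group). Given the anchor
#' columns of these residues within their regions, reports whether each
#' is fully conserved across the alignment.
#'
#' @param x A \code{region_alignment} with \code{S1} and \code{S2}
#'   regions.
#' @param s1_anchor,s2_anchor 0-based column offsets of the anchors
#'   within the S1 / S2 regions.
#' @param s1_residue,s2_residue Expected residues (default R and D).
#' @return Named logical vector \code{c(s1 = ..., s2 = ...)}.
#' @export
key_residue_check <- function(x, s1_anchor, s2_anchor,
                              s1_residue = "R", s2_residue = "D") {
  stopifnot(inherits(x, "region_alignment"))
  if (nrow(x$alignment) == 0L) stop("alignment has no rows")
  one <- function(region, anchor, residue) {
    b <- x$boundaries[[region]]
    if (is.null(b)) stop("alignment has no region '", region, "'")
    if (anchor < 0L || anchor >= b[2L] - b[1L])
      stop("anchor column ", anchor, " outside region '", region, "'")
    col <- x$alignment[, b[1L] + anchor + 1L]
    all(col == residue)
  }
  c(s1 = one("S1", s1_anchor, s1_residue),
    s2 = one("S2", s2_anchor, s2_residue))
}
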