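#' Window coordinates around an anchor
#'
#' Shared coordinate convention for every windowed computation: 0-based
#' offsets, half-open `[start, end)`. A window of `size` bp centered at
#' `center` relative to `anchor_pos` spans
#' `[anchor_pos + center - floor(size/2), anchor_pos + center + ceiling(size/2))`.
#'
#' @param center offset of the window center relative to the anchor
#'   (negative = upstream).
#' @param size window size in bp.
#' @param anchor_pos anchor position (0-based).
#' @return integer length-2 vector `c(start, end)`, half-open.
#' @export
anchored_window <- function(center, size, anchor_pos) {
  start <- anchor_pos + center - size %/% 2L
  c(as.integer(start), as.integer(start + size))
}

# Cumulative A/T indicator: cum[p + 1] = number of A/T bases in seq[0, p).
at_cumsum <- function(sequence) {
  c(0L, cumsum(strsplit(sequence, "")[[1]] %in% c("A", "T")))
}

#' A/T (or G/C) fraction of a window anchored on a position
#'
#' Windows truncated at sequence boundaries report the fraction over the
#' bases that fall inside the sequence, with a `truncated` attribute;
#' windows entirely outside return `NA` (never 0).
#'
#' @param seq DNA string.
#' @param center window center offset relative to `anchor_pos`.
#' @param size window size in bp.
#' @param anchor_pos anchor (0-based), e.g. the main cleavage site.
#' @param feature `"at_content"` (default) or `"gc_content"`.
#' @return fraction in `[0, 1]`, or `NA` if the window misses the
#'   sequence entirely.
#' @export
window_at_content <- function(seq, center, size, anchor_pos,
                              feature = c("at_content", "gc_content")) {
  feature <- match.arg(feature)
  win <- anchored_window(center, size, anchor_pos)
  len <- nchar(seq)
  lo <- max(win[1], 0L)
  hi <- min(win[2], len)
  if (hi <= lo) return(NA_real_)
  cs <- at_cumsum(seq)
  at <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  val <- if (feature == "at_content") at else 1 - at
  if (lo != win[1] || hi != win[2]) attr(val, "truncated") <- TRUE
  val
}

# Feature values for all constructs at one (size, offset) grid cell,
# using precomputed cumulative A/T matrices. Vectorized across constructs.
cell_feature <- function(cum, lens, anchors, center, size, gc = FALSE) {
  start <- anchors + center - size %/% 2L
  end <- start + size
  lo <- pmax(start, 0L)
  hi <- pmin(end, lens)
  inside <- hi - lo
  n <- length(lens)
  val <- rep(NA_real_, n)
  ok <- which(inside > 0L & !is.na(anchors))
  if (length(ok)) {
    at <- (cum[cbind(ok, hi[ok] + 1L)] - cum[cbind(ok, lo[ok] + 1L)]) /
      inside[ok]
    val[ok] <- if (gc) 1 - at else at
  }
  val
}

# Precompute the ragged cumulative-A/T table as a padded matrix.
cum_matrix <- function(seqs) {
  lens <- nchar(seqs)
  m <- matrix(NA_integer_, length(seqs), max(lens) + 1L)
  for (i in seq_along(seqs)) m[i, seq_len(lens[i] + 1L)] <- at_cumsum(seqs[i])
  list(cum = m, lens = lens)
}

construct_anchors <- function(constructs, anchor) {
  if (anchor == "utr_start") {
    rep(0L, length(constructs))
  } else {
    vapply(constructs, function(x) as.integer(x$cleavage_site), 0L)
  }
}

#' Correlate windowed sequence features with expression across a grid
#'
#' For every combination of window size and center offset, computes the
#' Pearson correlation across constructs between the window's A/T (or
#' G/C) fraction and expression. Constructs are aligned either by the
#' main cleavage site or by the start of the 3'UTR (first base after the
#' stop codon). Constructs whose window falls entirely outside their
#' sequence are dropped from that cell (tracked in `n_used`); truncated
#' windows contribute their truncated fraction. Cells with fewer than 3
#' contributing constructs, or a constant feature, are undefined (`NA`).
#'
#' @param constructs list of [construct()] objects with expression and a
#'   defined anchor (at least 3).
#' @param sizes window sizes in bp (default 10, 20, ..., 100).
#' @param offsets window-center offsets relative to the anchor (default
#'   -200 to +50 in steps of 5).
#' @param anchor `"cleavage_site"` (default) or `"utr_start"`.
#' @param feature `"at_content"` (default) or `"gc_content"`.
#' @param log_expression correlate with log expression (default `FALSE`).
#' @return object of class `ScanGrid`: list with `sizes`, `offsets`,
#'   `anchor`, `feature`, matrices `r` and `n_used` (sizes x offsets).
#' @export
feature_expression_scan <- function(constructs,
                                    sizes = seq(10L, 100L, by = 10L),
                                    offsets = seq(-200L, 50L, by = 5L),
                                    anchor = c("cleavage_site", "utr_start"),
                                    feature = c("at_content", "gc_content"),
                                    log_expression = FALSE) {
  anchor <- match.arg(anchor)
  feature <- match.arg(feature)
  expr <- vapply(constructs, `[[`, 0, "expression")
  if (sum(!is.na(expr)) < 3L) {
    stop_format("need at least 3 constructs with expression")
  }
  if (log_expression) expr <- log(expr)
  if (sd(expr, na.rm = TRUE) == 0) {
    stop_format("all expression values identical; correlations undefined")
  }
  seqs <- vapply(constructs, `[[`, "", "sequence")
  cm <- cum_matrix(seqs)
  anchors <- construct_anchors(constructs, anchor)
  gc <- feature == "gc_content"
  r <- n_used <- matrix(NA_real_, length(sizes), length(offsets),
                        dimnames = list(sizes, offsets))
  feats <- vector("list", length(sizes) * length(offsets))
  ci <- 0L
  for (si in seq_along(sizes)) {
    for (oi in seq_along(offsets)) {
      v <- cell_feature(cm$cum, cm$lens, anchors, offsets[oi], sizes[si], gc)
      ok <- !is.na(v) & !is.na(expr)
      n_used[si, oi] <- sum(ok)
      if (sum(ok) >= 3L && sd(v[ok]) > 0) {
        r[si, oi] <- cor(v[ok], expr[ok])
      }
      ci <- ci + 1L
      feats[[ci]] <- v
    }
  }
  structure(
    list(sizes = sizes, offsets = offsets, anchor = anchor,
         feature = feature, r = r, n_used = n_used),
    features = feats, expression = expr, class = "ScanGrid"
  )
}

#' @export
print.ScanGrid <- function(x, ...) {
  pk <- scan_argmax(x)
  cat(sprintf("<ScanGrid> %s vs expression, anchored on %s: %d x %d cells; peak r = %.3f at size %d, offset %d\n",
              x$feature, x$anchor, length(x$sizes), length(x$offsets),
              pk$r, pk$size, pk$offset))
  invisible(x)
}

#' Location of the strongest correlation in a scan grid
#'
#' @param grid a [feature_expression_scan()] result.
#' @return list with `size`, `offset` and the signed `r` at the cell of
#'   maximum absolute correlation.
#' @export
scan_argmax <- function(grid) {
  idx <- which(abs(grid$r) == max(abs(grid$r), na.rm = TRUE),
               arr.ind = TRUE)[1L, ]
  list(size = grid$sizes[idx[1L]], offset = grid$offsets[idx[2L]],
       r = grid$r[idx[1L], idx[2L]])
}

#' Export a scan grid in long format
#'
#' @param grid a `ScanGrid`.
#' @return data.frame with columns `size`, `offset`, `r`, `n_used`.
#' @export
scan_grid_table <- function(grid) {
  data.frame(
    size = rep(grid$sizes, times = length(grid$offsets)),
    offset = rep(grid$offsets, each = length(grid$sizes)),
    r = as.vector(grid$r),
    n_used = as.vector(grid$n_used)
  )
}

#' Permutation null for the peak correlation of a scan grid
#'
#' Shuffles expression across constructs and recomputes the maximum
#' absolute grid correlation per shuffle, reusing the window features of
#' an already-computed grid. Used to calibrate whether an observed peak
#' exceeds chance: family-wise over the whole grid.
#'
#' @param grid a [feature_expression_scan()] result.
#' @param n_perm number of shuffles (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of null max-|r| values, with attribute `q95`
#'   (their 95th percentile).
#' @export
scan_permutation_null <- function(grid, n_perm = 1000L, seed = 1L) {
  feats <- attr(grid, "features")
  expr <- attr(grid, "expression")
  # precompute centered features per cell once
  prepped <- lapply(feats, function(v) {
    ok <- which(!is.na(v) & !is.na(expr))
    if (length(ok) < 3L) return(NULL)
    x <- v[ok] - mean(v[ok])
    nx <- sqrt(sum(x^2))
    if (nx == 0) return(NULL)
    list(idx = ok, x = x / nx)
  })
  prepped <- Filter(Negate(is.null), prepped)
  with_seed(seed, {
    nulls <- vapply(seq_len(n_perm), function(p) {
      y <- sample(expr)
      max(vapply(prepped, function(cell) {
        yy <- y[cell$idx]
        yy <- yy - mean(yy)
        ny <- sqrt(sum(yy^2))
        if (ny == 0) return(0) else abs(sum(cell$x * yy) / ny)
      }, 0))
    }, 0)
    attr(nulls, "q95") <- unname(quantile(nulls, 0.95))
    nulls
  })
}

#' Positional G/C profiles for expression-grouped genes
#'
#' Genes are split into a bottom quantile, a top quantile and the middle
#' rest by expression; for each offset in `span` the group mean of the
#' G/C fraction in a `window`-bp window centered at that offset (relative
#' to the anchor) is reported. Genes whose window misses their sequence
#' at an offset are excluded there.
#'
#' @param constructs list of [construct()]s with expression and anchor.
#' @param low_q,high_q extreme-group quantiles (defaults 0.2 and 0.2,
#'   i.e. bottom and top 20%).
#' @param window window size in bp (default 20).
#' @param span integer offsets relative to the anchor (default -200..50).
#' @param anchor `"cleavage_site"` or `"utr_start"`.
#' @return data.frame: `offset`, `group` (low/mid/high), `mean_gc`, `n`.
#' @export
grouped_gc_profile <- function(constructs, low_q = 0.2, high_q = 0.2,
                               window = 20L, span = -200L:50L,
                               anchor = c("cleavage_site", "utr_start")) {
  anchor <- match.arg(anchor)
  expr <- vapply(constructs, `[[`, 0, "expression")
  qs <- quantile(expr, c(low_q, 1 - high_q))
  group <- ifelse(expr <= qs[1L], "low", ifelse(expr >= qs[2L], "high", "mid"))
  for (g in c("low", "high")) {
    if (sum(group == g) == 0L) {
      stop_format("empty %s-expression group at quantile %.2f", g,
                  if (g == "low") low_q else high_q)
    }
    if (sum(group == g) < 5L) {
      warning(sprintf("%s-expression group has fewer than 5 genes", g),
              call. = FALSE)
    }
  }
  seqs <- vapply(constructs, `[[`, "", "sequence")
  cm <- cum_matrix(seqs)
  anchors <- construct_anchors(constructs, anchor)
  out <- list()
  for (off in span) {
    v <- cell_feature(cm$cum, cm$lens, anchors, off, as.integer(window),
                      gc = TRUE)
    for (g in c("low", "mid", "high")) {
      sel <- group == g & !is.na(v)
      out[[length(out) + 1L]] <- data.frame(
        offset = off, group = g,
        mean_gc = if (any(sel)) mean(v[sel]) else NA_real_,
        n = sum(sel))
    }
  }
  do.call(rbind, out)
}

#' k-mer association with expression
#'
#' Counts every k-mer (overlapping occurrences) in the chosen region of
#' each construct, correlates the counts with expression by Spearman
#' rank correlation, and attaches a permutation p-value from expression
#' shuffles. Constructs whose region is shorter than `k` contribute a
#' count of 0 and are flagged.
#'
#' @param constructs list of [construct()]s with expression.
#' @param k k-mer length, 3..8.
#' @param region `"whole_utr"` (positions 0..cleavage_site; falls back to
#'   the whole construct, flagged, when the site is unknown) or a window
#'   `list(center =, size =)` anchored on the cleavage site.
#' @param n_perm number of expression shuffles (default 1000).
#' @param seed RNG seed.
#' @return data.frame sorted by `|rho|` descending: `kmer`, `total_count`,
#'   `rho`, `p_perm`. Attribute `n_short` counts constructs with region
#'   shorter than k.
#' @export
kmer_expression_association <- function(constructs, k = 4L,
                                        region = "whole_utr",
                                        n_perm = 1000L, seed = 1L) {
  if (k < 3L || k > 8L) stop_format("k must be between 3 and 8")
  expr <- vapply(constructs, `[[`, 0, "expression")
  regions <- vapply(constructs, function(cn) {
    if (identical(region, "whole_utr")) {
      if (is.na(cn$cleavage_site)) cn$sequence
      else substr(cn$sequence, 1L, cn$cleavage_site + 1L)
    } else {
      win <- anchored_window(region$center, region$size, cn$cleavage_site)
      substr(cn$sequence, max(win[1], 0L) + 1L,
             min(win[2], nchar(cn$sequence)))
    }
  }, "")
  n_short <- sum(nchar(regions) < k)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(regions), width = k)
  ranked <- apply(counts, 2L, rank)
  ry <- rank(expr)
  rho <- suppressWarnings(as.vector(cor(ranked, ry)))
  with_seed(seed, {
    exceed <- integer(ncol(counts))
    for (p in seq_len(n_perm)) {
      rp <- sample(ry)
      null_rho <- suppressWarnings(as.vector(cor(ranked, rp)))
      exceed <- exceed + (!is.na(null_rho) & !is.na(rho) &
                            abs(null_rho) >= abs(rho))
    }
    res <- data.frame(kmer = colnames(counts),
                      total_count = colSums(counts),
                      rho = rho,
                      p_perm = (1L + exceed) / (n_perm + 1L))
    res$p_perm[is.na(res$rho)] <- NA_real_
    res <- res[order(-abs(res$rho)), ]
    rownames(res) <- NULL
    attr(res, "n_short") <- n_short
    res
  })
}

#' Known 3' end processing motifs
#'
#' Default degenerate patterns for the two canonical yeast 3' processing
#' elements: the A/T-rich efficiency element (consensus `TAYRTA`, with
#' the literal `TATATA` as its strongest form) and the A-rich positioning
#' element (`AAWAAA`). Patterns are fully configurable; these defaults
#' follow the 3'-processing literature.
#'
#' @return data.frame with columns `name`, `pattern`.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("efficiency_element", "efficiency_element", "positioning_element"),
    pattern = c("TAYRTA", "TATATA", "AAWAAA"),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for degenerate motif matches
#'
#' All exact IUPAC-degenerate matches on the given strand; overlapping
#' matches are reported, starts are 0-based.
#'
#' @param seq DNA string.
#' @param patterns data.frame with `name` and `pattern` columns (IUPAC
#'   degenerate DNA); defaults to [default_motifs()].
#' @return data.frame with columns `name`, `pattern`, `start` (0-based).
#' @export
motif_scan <- function(seq, patterns = default_motifs()) {
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  subject <- Biostrings::DNAString(toupper(seq))
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- toupper(patterns$pattern[i])
    ch <- strsplit(pat, "")[[1]]
    bad <- setdiff(ch, valid)
    if (!nzchar(pat) || length(bad)) {
      stop_format("pattern '%s': invalid IUPAC code '%s'", pat,
                  if (length(bad)) bad[1] else "(empty)")
    }
    hits <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (!length(hits)) return(NULL)
    data.frame(name = patterns$name[i], pattern = pat,
               start = Biostrings::start(hits) - 1L)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    return(data.frame(name = character(), pattern = character(),
                      start = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Whole-UTR sequence features
#'
#' Length, base composition and a secondary-structure pairing score for
#' the 3'UTR (positions 0..cleavage_site). The pairing score is the
#' maximum number of nested base pairs (Watson-Crick plus G-T wobble,
#' minimum loop 3) from dynamic programming -- a declared proxy for
#' folding energy, not a thermodynamic minimum free energy; externally
#' computed energies can be attached via `energy`.
#'
#' @param construct a [construct()]. When the cleavage site is unknown
#'   the features are computed over the full construct and flagged.
#' @param energy optional externally computed folding energy (kcal/mol)
#'   to attach verbatim.
#' @return list: `utr_length`, `gc_fraction`, `at_fraction`,
#'   `pairing_score`, `energy`, `over_full_construct` flag.
#' @export
global_utr_features <- function(construct, energy = NA_real_) {
  full <- is.na(construct$cleavage_site)
  utr <- if (full) construct$sequence
         else substr(construct$sequence, 1L, construct$cleavage_site + 1L)
  bases <- strsplit(utr, "")[[1]]
  at <- mean(bases %in% c("A", "T"))
  list(
    gene_id = construct$gene_id,
    utr_length = nchar(utr),
    gc_fraction = 1 - at,
    at_fraction = at,
    pairing_score = nussinov_maxpairs(utr, 3L),
    energy = energy,
    over_full_construct = full
  )
}
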