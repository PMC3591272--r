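# Small fixtures shared across test files. Everything is built in code.

# A minimal valid time course: constant OD, linearly rising YFP.
toy_timecourse <- function(n = 10L, well = "A1", strain = "s1",
                           dt = 1000, od = 1, yfp_rate = 1, mch = 5) {
  t <- seq(0, by = dt, length.out = n)
  time_course(well, strain, t, rep(od, n), yfp_rate * t, rep(mch, n))
}

# Deterministic two-construct reference for mapping tests.
toy_reference <- function() {
  set.seed(421)
  s1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE), collapse = "")
  list(G1 = construct("G1", s1), G2 = construct("G2", s2))
}

# Build a synthetic 3'RACE read by the primer rule: UMI + poly(T) +
# revcomp of the transcript end. Written independently of the package's
# simulator so trimming/mapping tests are not self-referential.
manual_race_read <- function(seq_chr, site, frag_len = 80, tail = 18,
                             umi = strrep("ACGT", 3)) {
  a <- max(0L, site - frag_len + 1L)
  frag <- substr(seq_chr, a + 1L, site + 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  paste0(umi, strrep("T", tail), rc)
}

# Brute-force OLS via normal equations; independent oracle for the
# nested-regression F-test.
oracle_nested_f <- function(y, xr, xf) {
  rss <- function(X) {
    X <- cbind(1, as.matrix(X))
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  n <- length(y)
  rss_r <- rss(xr)
  rss_f <- rss(xf)
  d <- ncol(as.matrix(xf)) - ncol(as.matrix(xr))
  df2 <- n - ncol(as.matrix(xf)) - 1L
  F <- ((rss_r - rss_f) / d) / (rss_f / df2)
  list(rss_r = rss_r, rss_f = rss_f, F = F,
       p = pf(F, d, df2, lower.tail = FALSE))
}

# Exhaustive maximum-base-pair oracle (min loop 3, WC + GU) for short
# strings; checks the dynamic-programming kernel.
oracle_maxpairs <- function(s, min_loop = 3L) {
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (pairs_ok(ch[k], ch[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + 1L + rec(k + 1L, j - 1L))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# Expand an IUPAC pattern to a regular expression; brute-force motif
# oracle.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(pattern, "")[[1]], function(c) {
    e <- map[[c]]
    if (nchar(e) == 1L) e else paste0("[", e, "]")
  }, ""), collapse = "")
}

oracle_motif_starts <- function(seq, pattern) {
  rx <- iupac_regex(pattern)
  n <- nchar(seq)
  w <- nchar(pattern)
  which(vapply(seq_len(n - w + 1L), function(i) {
    grepl(paste0("^", rx), substr(seq, i, i + w - 1L))
  }, TRUE)) - 1L
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

total_variation <- function(p, q) {
  pos <- union(names(p), names(q))
  a <- setNames(rep(0, length(pos)), pos)
  b <- a
  a[names(p)] <- p
  b[names(q)] <- q
  sum(abs(a - b)) / 2
}
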