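# Interval algebra on closed-open [start, end) intervals.
# Intervals are two-column numeric matrices (start, end); all helpers return
# disjoint, sorted sets. Internal only — budgets and the segment sampler are
# built on these.

iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (nrow(m) && any(m[, 2L] <= m[, 1L]))
    stop("interval end must exceed start", call. = FALSE)
  m
}

iv_empty <- function() cbind(start = numeric(0), end = numeric(0))

# Merge overlapping or touching intervals into a disjoint sorted set.
iv_union <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(iv_empty())
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  s <- m[1L, 1L]; e <- m[1L, 2L]
  out <- list()
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    if (m[i, 1L] > e) {
      out[[length(out) + 1L]] <- c(s, e)
      s <- m[i, 1L]; e <- m[i, 2L]
    } else {
      e <- max(e, m[i, 2L])
    }
  }
  out[[length(out) + 1L]] <- c(s, e)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# Intersection of two interval sets (each first reduced to disjoint form).
iv_intersect <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a[i, 1L], b[j, 1L]); e <- min(a[i, 2L], b[j, 2L])
    if (e > s) out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(iv_empty())
  iv_union(do.call(rbind, out))
}

# Set difference a \ b.
iv_diff <- function(a, b) {
  a <- iv_union(a); b <- iv_union(b)
  if (nrow(a) == 0L) return(iv_empty())
  if (nrow(b) == 0L) return(a)
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1L]; e <- a[i, 2L]
    pieces <- list(c(s, e))
    for (j in seq_len(nrow(b))) {
      nxt <- list()
      for (p in pieces) {
        bs <- b[j, 1L]; be <- b[j, 2L]
        if (be <= p[1L] || bs >= p[2L]) {
          nxt[[length(nxt) + 1L]] <- p
        } else {
          if (bs > p[1L]) nxt[[length(nxt) + 1L]] <- c(p[1L], bs)
          if (be < p[2L]) nxt[[length(nxt) + 1L]] <- c(be, p[2L])
        }
      }
      pieces <- nxt
    }
    out <- c(out, pieces)
  }
  if (!length(out)) return(iv_empty())
  iv_union(do.call(rbind, out))
}

iv_length <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(0)
  sum(m[, 2L] - m[, 1L])
}

# Does [s, e) overlap any interval in m?
iv_overlaps <- function(m, s, e) {
  if (is.null(m) || nrow(m) == 0L) return(FALSE)
  any(s < m[, 2L] & e > m[, 1L])
}

# Is point t covered (closed-open convention)?
iv_covers <- function(m, t) {
  if (is.null(m) || nrow(m) == 0L) return(rep(FALSE, length(t)))
  vapply(t, function(x) any(x >= m[, 1L] & x < m[, 2L]), logical(1L))
}
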