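# Brute-force shortest-path oracle: enumerate all simple paths between
# every ordered pair (lengths = 1/weight), find the minimum length, the
# number of minimal paths and which intermediates they pass through.
brute_paths <- function(m, tol = 1e-9) {
  n <- nrow(m)
  L <- ifelse(m > 0, 1 / m, Inf)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  through <- array(0, c(n, n, n))   # [s, t, v] minimal paths via v
  recurse <- function(path, len, t, acc) {
    v <- path[length(path)]
    if (v == t) { acc[[length(acc) + 1L]] <- list(path = path, len = len); return(acc) }
    for (w in seq_len(n)) {
      if (is.finite(L[v, w]) && !(w %in% path))
        acc <- recurse(c(path, w), len + L[v, w], t, acc)
    }
    acc
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    all_paths <- recurse(s, 0, t, list())
    if (!length(all_paths)) next
    lens <- vapply(all_paths, `[[`, 0, "len")
    dmin <- min(lens)
    minimal <- all_paths[lens <= dmin + tol]
    dist[s, t] <- dmin
    sigma[s, t] <- length(minimal)
    for (p in minimal) {
      mid <- setdiff(p$path, c(s, t))
      for (v in mid) through[s, t, v] <- through[s, t, v] + 1
    }
  }
  list(dist = dist, sigma = sigma, through = through)
}

brute_betweenness <- function(m) {
  n <- nrow(m)
  bp <- brute_paths(m)
  vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v || bp$sigma[s, t] == 0) next
      tot <- tot + bp$through[s, t, v] / bp$sigma[s, t]
    }
    tot
  }, 0)
}

brute_closeness <- function(m, direction) {
  n <- nrow(m)
  D <- brute_paths(m)$dist
  vapply(seq_len(n), function(v) {
    d <- if (direction == "in") D[-v, v] else D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, 0)
}
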