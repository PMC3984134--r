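# Independent brute-force oracles and shared fixtures. Oracles deliberately
# avoid the package's own code paths.

# Goodman-Kruskal gamma by explicit pair enumeration.
brute_gamma <- function(x, y, r = 0) {
  nc <- 0L
  nd <- 0L
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (abs(dx) > r && abs(dy) > r) {
        if (sign(dx) == sign(dy)) nc <- nc + 1L else nd <- nd + 1L
      }
    }
  }
  list(gamma = if (nc + nd == 0L) NA_real_ else (nc - nd) / (nc + nd),
       nc = nc, nd = nd)
}

# Transitive closure of the prefix-containment relation (union-find).
brute_containment_partition <- function(strings) {
  n <- length(strings)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (startsWith(strings[j], strings[i])) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))  # canonical labels
}

# Column-majority consensus for equal-length, gap-free sequences; ties go to
# the anchor sequence's base.
brute_column_majority <- function(seqs, anchor = 1L) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  paste(vapply(seq_len(ncol(mat)), function(k) {
    tab <- table(mat[, k])
    top <- names(tab)[tab == max(tab)]
    if (mat[anchor, k] %in% top) mat[anchor, k] else sort(top)[1]
  }, character(1)), collapse = "")
}

# Small default simulation panel shared across tests.
test_panel <- function(seed = 11, ...) {
  build_type_panel(seed = seed, ...)
}

# Memoized heavy end-to-end runs so several test blocks can share one.
.run_cache <- new.env(parent = emptyenv())

cached_pipeline_run <- function(key, cfg_fun) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, cfg_fun(), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
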