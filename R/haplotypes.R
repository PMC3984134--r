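# Within-type haplotype analysis: mutation distances that count an indel run
# as a single change, inference of intra-genomic variant groups from
# cross-sample proportion correlations, and minimum-spanning haplotype
# networks.

#' Mutation distance between two haplotype sequences
#'
#' Global alignment distance counting substitution columns plus the number of
#' contiguous indel runs, each run counting as a single mutation regardless
#' of its length (insertions and deletions treated like single nucleotide
#' polymorphisms).
#'
#' @param seq_a,seq_b sequences (non-empty).
#' @return integer mutation count.
#' @export
pairwise_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (seq_a == seq_b) return(0L)
  # canonical argument order: co-optimal alignments can differ between
  # (a, b) and (b, a), so fix the orientation to keep the distance symmetric
  pair <- sort(c(seq_a, seq_b), method = "radix")
  al <- align_pair(pair[1], pair[2])
  a <- strsplit(al$aligned_a, "")[[1]]
  b <- strsplit(al$aligned_b, "")[[1]]
  gap <- a == "-" | b == "-"
  subs <- sum(!gap & a != b)
  runs <- if (any(gap)) sum(rle(gap)$values) else 0L
  as.integer(subs + runs)
}

#' Within-type haplotype proportion matrix
#'
#' Percent of each sample's reads of one type carried by each of that type's
#' references (haplotypes). Rows sum to 100 where the type is present.
#'
#' @param abundance an `abundance_table`.
#' @param type_name the type to extract.
#' @return samples x haplotypes matrix of within-type percentages (NA rows
#'   where the type has no reads).
#' @export
haplotype_proportions <- function(abundance, type_name) {
  ann <- abundance$annotations
  refs <- ann$reference_id[!is.na(ann$type_name) & ann$type_name == type_name]
  refs <- intersect(refs, colnames(abundance$counts))
  if (length(refs) == 0L) stop("no references annotated as ", type_name, call. = FALSE)
  cm <- abundance$counts[, refs, drop = FALSE]
  tot <- rowSums(cm)
  100 * sweep(cm, 1L, ifelse(tot == 0, NA_real_, tot), "/")
}

#' Infer intra-genomic variant groups
#'
#' Intra-genomic variants of one genome are expected to co-vary in proportion
#' across samples. For every haplotype pair, gamma and its permutation
#' p-value are computed across samples; an edge is drawn when gamma > 0 and
#' p < alpha, and connected components of the resulting graph are the
#' putative single-genome variant groups. Haplotypes with no variance across
#' samples stay isolated and are flagged.
#'
#' @param proportion_matrix samples x haplotypes matrix (e.g. from
#'   [haplotype_proportions()]); rows with any NA are dropped.
#' @param alpha per-pair significance level (default 0.05, raw p-values as
#'   reported; see `bonferroni`).
#' @param n_perm permutations per pair (default 1000).
#' @param seed RNG seed.
#' @param tolerance_r tie tolerance for gamma.
#' @param bonferroni apply Bonferroni correction across pairs (default FALSE).
#' @return object of class `intragenomic_groups`: list with `groups` (named
#'   list of haplotype id vectors), `edges` (data.frame pair, gamma, p),
#'   `flagged` (zero-variance haplotypes).
#' @export
infer_intragenomic <- function(proportion_matrix, alpha = 0.05, n_perm = 1000,
                               seed = 1, tolerance_r = 0, bonferroni = FALSE) {
  pm <- proportion_matrix[stats::complete.cases(proportion_matrix), , drop = FALSE]
  if (nrow(pm) < 3L) stop("need >= 3 samples with data", call. = FALSE)
  haps <- colnames(pm)
  nh <- length(haps)
  novar <- apply(pm, 2L, function(v) length(unique(v)) < 2L)
  edges <- list()
  pairs <- if (nh >= 2L) utils::combn(nh, 2L, simplify = FALSE) else list()
  n_tests <- max(1L, length(pairs))
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    if (novar[i] || novar[j]) next
    g <- gamma_correlation(pm[, i], pm[, j], tolerance_r)
    if (g$undefined) next
    gp <- gamma_permutation_p(pm[, i], pm[, j], tolerance_r, n_perm,
                              seed = seed + k)
    edges[[length(edges) + 1L]] <- data.frame(
      hap_a = haps[i], hap_b = haps[j], gamma = gp$gamma, p_value = gp$p_value,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(hap_a = character(0), hap_b = character(0),
               gamma = numeric(0), p_value = numeric(0), stringsAsFactors = FALSE)
  thr <- if (bonferroni) alpha / n_tests else alpha
  sig <- edges[edges$gamma > 0 & edges$p_value < thr, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sig[, c("hap_a", "hap_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = haps))
  comp <- igraph::components(g)
  groups <- split(haps, comp$membership[haps])
  names(groups) <- sprintf("group_%d", seq_along(groups))
  structure(
    list(groups = groups, edges = edges, significant_edges = sig,
         flagged = haps[novar], alpha = thr),
    class = "intragenomic_groups"
  )
}

#' @export
print.intragenomic_groups <- function(x, ...) {
  cat(sprintf("<intragenomic_groups> %d group(s): %s\n", length(x$groups),
              paste(vapply(x$groups, function(g) paste(g, collapse = "+"),
                           character(1)), collapse = " | ")))
  invisible(x)
}

#' Build a haplotype network
#'
#' Identical haplotypes (mutation distance 0) are collapsed with their read
#' totals summed; all-pairs mutation distances ([pairwise_distance()]) then
#' define a minimum-spanning network: the union of all minimum spanning
#' trees, so tied alternative connections are retained.
#'
#' @param haplotype_sequences named character vector of sequences.
#' @param read_totals numeric vector of total reads per haplotype (defaults
#'   to 1 each).
#' @return object of class `haplotype_network`: list with `nodes`
#'   (data.frame `node_id`, `members`, `reads`), `edges` (data.frame
#'   `node_a`, `node_b`, `distance`), and the full `distances` matrix.
#' @export
build_network <- function(haplotype_sequences, read_totals = NULL) {
  n <- length(haplotype_sequences)
  if (n == 0L) stop("need >= 1 haplotype", call. = FALSE)
  ids <- names(haplotype_sequences) %||% sprintf("hap_%d", seq_len(n))
  reads <- read_totals %||% rep(1, n)

  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- pairwise_distance(haplotype_sequences[[i]],
                                              haplotype_sequences[[j]])
    }
  }

  # collapse zero-distance nodes
  gz <- igraph::graph_from_adjacency_matrix(D == 0L, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gz)$membership
  node_ids <- vapply(seq_len(max(comp)), function(c) {
    sort(ids[comp == c])[1]
  }, character(1))
  nodes <- data.frame(
    node_id = node_ids,
    members = vapply(seq_len(max(comp)), function(c) {
      paste(sort(ids[comp == c]), collapse = ",")
    }, character(1)),
    reads = vapply(seq_len(max(comp)), function(c) sum(reads[comp == c]),
                   numeric(1)),
    stringsAsFactors = FALSE
  )
  nn <- nrow(nodes)
  Dn <- matrix(0L, nn, nn, dimnames = list(nodes$node_id, nodes$node_id))
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    if (a < b) {
      Dn[a, b] <- Dn[b, a] <- min(D[comp == a, comp == b])
    }
  }

  edges <- data.frame(node_a = character(0), node_b = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (nn > 1L) {
    # union of all MSTs: an edge of weight w belongs to some MST iff it joins
    # two different components of the graph restricted to edges lighter than w
    pairs <- utils::combn(nn, 2L)
    w <- Dn[cbind(pairs[1, ], pairs[2, ])]
    for (uw in sort(unique(w))) {
      lighter <- which(w < uw)
      gl <- igraph::graph_from_data_frame(
        data.frame(from = nodes$node_id[pairs[1, lighter]],
                   to = nodes$node_id[pairs[2, lighter]]),
        directed = FALSE, vertices = data.frame(name = nodes$node_id))
      memb <- igraph::components(gl)$membership
      for (k in which(w == uw)) {
        a <- nodes$node_id[pairs[1, k]]
        b <- nodes$node_id[pairs[2, k]]
        if (memb[a] != memb[b]) {
          edges <- rbind(edges, data.frame(node_a = a, node_b = b,
                                           distance = uw,
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, distances = Dn),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a haplotype network to edge-list and graph files
#'
#' @param network a `haplotype_network`.
#' @param edges_path TSV path for the edge list.
#' @param graphml_path optional GraphML path.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, edges_path, graphml_path = NULL) {
  write_tsv_file(network$edges, edges_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = network$nodes[, c("node_id", "reads")])
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(list(edges = edges_path, graphml = graphml_path))
}
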