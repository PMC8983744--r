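# Shared fixtures and independent oracles, all built in code.

toy_db <- function() toy_germline()

# Write a tiny germline FASTA + metadata pair to tempfiles; `edit` can
# tamper with individual fields to provoke validation errors.
write_mini_germline <- function(edit = identity) {
  v1 <- paste0(strrep("GCT", 30), "TGT", "GCG", "AGA")   # 99 nt, anchor 90
  v2 <- paste0(strrep("ACC", 30), "TGT", "GCG", "AGA")
  j1 <- paste0("ACTACTACT", "TTT", "GGT", strrep("CAA", 4))
  segs <- data.frame(
    id = c("V1*01", "V2*01", "D1*01", "J1*01"),
    locus = "IGH",
    segment_type = c("V", "V", "D", "J"),
    functionality = c("functional", "pseudogene", "functional", "functional"),
    sequence = c(v1, v2, "GGTATAACTGGAACGAC", j1),
    anchor_offset = c(90L, 90L, NA, 9L),
    reading_frame = c(0L, 0L, NA, 0L),
    stringsAsFactors = FALSE)
  segs <- edit(segs)
  fa <- tempfile(fileext = ".fasta")
  md <- tempfile(fileext = ".tsv")
  writeLines(as.vector(rbind(paste0(">", segs$id), segs$sequence)), fa)
  write.table(segs[, setdiff(names(segs), "sequence")], md,
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, metadata = md)
}

# Independently coded Welch routine (textbook formulas), the cross-check
# oracle for welch_test().
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Independently coded Shannon entropy (direct evaluation).
shannon_oracle <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# --- brute-force NJ oracle: enumerate unrooted topologies, least-squares
# branch fit, return the best tree's fitted path-distance matrix.

# all unrooted binary topologies on taxa 1..n (n = 4 or 5), each as an
# edge list on nodes (tips 1..n, internal n+1, ...)
.enum_topologies <- function(n) {
  if (n == 4) {
    pairs <- list(c(1, 2), c(1, 3), c(1, 4))
    lapply(pairs, function(p) {
      rest <- setdiff(1:4, p)
      # internal nodes 5, 6; edges: tips->internals + internal edge
      rbind(c(5, p[1]), c(5, p[2]), c(6, rest[1]), c(6, rest[2]), c(5, 6))
    })
  } else if (n == 5) {
    # shape is fixed (internal path 6-7-8); 15 labelled trees = choice of
    # the middle leaf (5) x pairing of the remaining four (3)
    out <- list()
    for (mid in 1:5) {
      rest <- setdiff(1:5, mid)
      pairings <- list(list(rest[1:2], rest[3:4]),
                       list(rest[c(1, 3)], rest[c(2, 4)]),
                       list(rest[c(1, 4)], rest[c(2, 3)]))
      for (pp in pairings) {
        out[[length(out) + 1L]] <- rbind(
          c(6, pp[[1]][1]), c(6, pp[[1]][2]), c(7, mid),
          c(8, pp[[2]][1]), c(8, pp[[2]][2]), c(6, 7), c(7, 8))
      }
    }
    out
  } else stop("only 4 or 5 taxa")
}

# path (edge-incidence) matrix between tip pairs for an edge list
.path_matrix <- function(edges, n) {
  g <- lapply(seq_len(max(edges)), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    g[[a]] <- c(g[[a]], e); g[[b]] <- c(g[[b]], e)
  }
  other_end <- function(e, v) setdiff(edges[e, ], v)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs))) {
    # DFS from pairs[r,1] to pairs[r,2]
    path <- NULL
    dfs <- function(v, target, used, eds) {
      if (v == target) { path <<- eds; return(TRUE) }
      for (e in g[[v]]) {
        if (e %in% used) next
        if (dfs(other_end(e, v), target, c(used, e), c(eds, e))) return(TRUE)
      }
      FALSE
    }
    dfs(pairs[r, 1], pairs[r, 2], integer(0), integer(0))
    A[r, path] <- 1
  }
  A
}

# least-squares fit of branch lengths for every topology; returns the best
# (minimum residual sum of squares) as list(edges, lengths, fitted, rss)
nj_oracle <- function(d) {
  n <- nrow(d)
  dvec <- d[lower.tri(d)]
  # lower.tri order is column-major pairs; rebuild in combn order
  pairs <- t(combn(n, 2))
  dvec <- d[cbind(pairs[, 1], pairs[, 2])]
  best <- NULL
  for (edges in .enum_topologies(n)) {
    A <- .path_matrix(edges, n)
    fit <- qr.solve(A, dvec)
    rss <- sum((A %*% fit - dvec)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(edges = edges, lengths = fit,
                   fitted = as.numeric(A %*% fit), rss = rss, pairs = pairs)
  }
  best
}

# tip-to-tip path distances of an ape phylo, in combn order
phylo_tip_dists <- function(tree) {
  cm <- ape::cophenetic.phylo(tree)
  n <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  pairs <- t(combn(n, 2))
  cm <- cm[labs, labs]
  cm[cbind(pairs[, 1], pairs[, 2])]
}

gene_of <- function(x) sub("[*].*$", "", x)
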