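# Minimum spanning arborescence (Chu-Liu/Edmonds, cycle contraction).
#
# Edges are given as integer endpoint vectors plus weights; `id` carries the
# caller's edge identity through contractions. Ties must be resolved by the
# caller via edge order: among equal-weight incoming edges the earliest row
# wins (which.min), so a pre-sorted edge list makes the result deterministic.

.minArborescence <- function(nNodes, from, to, w, root,
                             id = seq_along(from)) {
  stopifnot(length(from) == length(to), length(to) == length(w))
  .rec(seq_len(nNodes), data.frame(u = from, v = to, w = w, id = id), root)
}

.rec <- function(nodes, E, root) {
  nonroot <- setdiff(nodes, root)
  nNodes <- max(nodes)
  bestRow <- integer(nNodes)              # row in E of chosen incoming edge
  for (v in nonroot) {
    rows <- which(E$v == v & E$u != v)
    if (!length(rows))
      stop("ARBOR_ORPHAN:", v, call. = FALSE)
    bestRow[v] <- rows[which.min(E$w[rows])]
  }
  parent <- integer(nNodes)
  parent[nonroot] <- E$u[bestRow[nonroot]]
  # look for a cycle among parent pointers
  color <- integer(nNodes)                # 0 unseen, 1 in progress, 2 done
  color[root] <- 2L
  cycle <- NULL
  for (s in nonroot) {
    if (color[s] != 0L) next
    path <- integer(0); v <- s
    while (color[v] == 0L) {
      color[v] <- 1L; path <- c(path, v); v <- parent[v]
    }
    if (color[v] == 1L) {                 # found a new cycle through v
      cycle <- path[seq(match(v, path), length(path))]
      color[path] <- 2L
      break
    }
    color[path] <- 2L
  }
  if (is.null(cycle))
    return(E$id[bestRow[nonroot]])
  inC <- logical(nNodes); inC[cycle] <- TRUE
  super <- nNodes + 1L
  u2 <- ifelse(inC[E$u], super, E$u)
  v2 <- ifelse(inC[E$v], super, E$v)
  keep <- u2 != v2
  w2 <- E$w
  ent <- keep & (v2 == super)
  w2[ent] <- w2[ent] - E$w[bestRow[E$v[ent]]]
  E2 <- data.frame(u = u2[keep], v = v2[keep], w = w2[keep],
                   id = E$id[keep])
  # remember which original edge each contracted row stands for
  orig <- E[keep, , drop = FALSE]
  sel <- .rec(c(setdiff(nodes, cycle), super), E2, root)
  # the chosen edge entering the supernode breaks the cycle at its target
  entIds <- orig$id[orig$v %in% cycle]
  star <- intersect(sel, entIds)
  if (length(star) != 1L)
    stop("internal error: supernode should be entered exactly once")
  vStar <- orig$v[match(star, orig$id)]
  keepCycle <- E$id[bestRow[setdiff(cycle, vStar)]]
  c(sel, keepCycle)
}

# Brute force used nowhere in the package itself; the test suite enumerates
# arborescences independently.
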