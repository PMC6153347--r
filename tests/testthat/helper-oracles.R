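## Brute-force reference implementations used only to validate the package
## against independent logic on small instances.

## Fold enumeration by an explicit double loop.
bruteFolds <- function(labels) {
  out <- NULL
  for (t in seq_along(labels)) {
    if (labels[t] != "true") next
    for (f in seq_along(labels)) {
      if (labels[f] != "false") next
      out <- rbind(out, c(t, f))
    }
  }
  out
}

## Connected components by breadth-first search over an explicit
## neighbour check.
bruteComponents <- function(idx, dims, connectivity = 6L) {
  n <- length(idx)
  co <- arrayInd(idx, dims)
  isNb <- function(i, j) {
    d <- abs(co[i, ] - co[j, ])
    switch(as.character(connectivity),
           "6" = sum(d) == 1L,
           "18" = max(d) == 1L && sum(d) <= 2L,
           "26" = max(d) == 1L && sum(d) >= 1L)
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && isNb(v, j)) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

## Cluster filter built on bruteComponents.
bruteClusterFilter <- function(idx, dims, minSize, connectivity = 6L) {
  if (length(idx) == 0L) return(idx)
  comp <- bruteComponents(idx, dims, connectivity)
  sizes <- table(comp)
  idx[comp %in% as.integer(names(sizes)[sizes >= minSize])]
}

## Dice by explicit set counting.
bruteDice <- function(a, b) {
  inter <- 0L
  for (v in a) if (v %in% b) inter <- inter + 1L
  if (length(a) + length(b) == 0L) return(0)
  2 * inter / (length(a) + length(b))
}

## Exact Mann-Whitney p by enumerating every assignment of the pooled
## values to the two groups (double-loop U statistic).
bruteMannWhitney <- function(x, y) {
  uOf <- function(g1, g2) {
    u <- 0
    for (a in g1) for (b in g2) {
      if (a > b) u <- u + 1 else if (a == b) u <- u + 0.5
    }
    u
  }
  pool <- c(x, y)
  n1 <- length(x)
  sets <- utils::combn(length(pool), n1)
  obs <- uOf(x, y)
  nulls <- apply(sets, 2L, function(i) uOf(pool[i], pool[-i]))
  list(U = obs,
       p = min(1, 2 * min(mean(nulls <= obs), mean(nulls >= obs))))
}

## Partition equality: same grouping structure regardless of label ids.
samePartition <- function(a, b) {
  length(a) == length(b) && all(outer(a, a, "==") == outer(b, b, "=="))
}
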